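test_that("KS identities: identical samples give D = 0, separated give D = 1", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(ksTwoSample(x, x)$D, 0)
  expect_equal(ksTwoSample(1:5, 11:15)$D, 1)
  expect_error(ksTwoSample(1, 1:5), "at least 2")
})

test_that("D matches a brute-force pooled-ECDF oracle, ties included", {
  expect_equal(ksTwoSample(c(1, 2, 3), c(2, 3, 4))$D,
               oracleKsD(c(1, 2, 3), c(2, 3, 4)))
  set.seed(12)
  for (rep in 1:100) {
    na <- sample(2:50, 1); nb <- sample(2:50, 1)
    # integer draws force heavy ties
    a <- sample(1:8, na, TRUE)
    b <- sample(1:8, nb, TRUE) + stats::rbinom(1, 1, 0.5)
    expect_equal(suppressWarnings(ksTwoSample(a, b)$D), oracleKsD(a, b))
  }
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(4)
  a <- stats::rlnorm(30); b <- stats::rlnorm(40, 0.4)
  d0 <- ksTwoSample(a, b)$D
  expect_equal(ksTwoSample(log(a), log(b))$D, d0)
  expect_equal(ksTwoSample(a^3, b^3)$D, d0)
  expect_equal(ksTwoSample(-1 / a, -1 / b)$D, d0)
})

test_that("KS p-values agree with the reference implementation", {
  set.seed(6)
  for (rep in 1:20) {
    a <- stats::rnorm(sample(5:15, 1))
    b <- stats::rnorm(sample(5:15, 1), 0.4)
    mine <- ksTwoSample(a, b)
    ref <- stats::ks.test(a, b, exact = mine$method == "exact")
    expect_equal(mine$D, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  a <- stats::rnorm(150); b <- stats::rnorm(130, 0.2)
  mine <- ksTwoSample(a, b)
  expect_identical(mine$method, "asymptotic")
  ref <- stats::ks.test(a, b, exact = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # exact path against the exact Smirnov distribution
  ex <- ksTwoSample(stats::rnorm(10), stats::rnorm(12), exact = TRUE)
  refEx <- 1 - stats::psmirnov(ex$D - 1e-9, c(10, 12), two.sided = TRUE,
                               exact = TRUE)
  expect_equal(ex$p_value, refEx, tolerance = 1e-9)
})

test_that("t test matches the hand-computed pooled formula and t.test", {
  res <- tTwoSample(c(1, 2, 3), c(4, 5, 6), "student")
  expect_equal(res$t, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  set.seed(3)
  a <- stats::rnorm(12, 1, 2); b <- stats::rnorm(20, 0, 1)
  w <- tTwoSample(a, b, "welch")
  refW <- stats::t.test(a, b)
  expect_equal(w$t, unname(refW$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(refW$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, refW$p.value, tolerance = 1e-12)
})

test_that("t test symmetry and degenerate cases", {
  a <- c(1, 2, 3, 5); b <- c(2, 4, 4, 8, 9)
  r1 <- tTwoSample(a, b); r2 <- tTwoSample(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p_value, r2$p_value)
  same <- tTwoSample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(tTwoSample(c(1, 1, 1), c(2, 2, 2), "student"),
               "zero pooled variance")
})

test_that("genotype comparison applies the declared test per metric", {
  set.seed(10)
  ids <- sprintf("c%03d", 1:40)
  grouping <- stats::setNames(rep(c("wt", "mut"), each = 20), ids)
  data <- rbind(
    data.frame(id = ids, metric = "frequency",
               value = c(stats::rnorm(20, 1), stats::rnorm(20, 3))),
    data.frame(id = ids, metric = "fraction_active",
               value = stats::runif(40)))
  rep <- compareGenotypes(data, grouping,
                          tests = c(fraction_active = "t"))
  expect_equal(rep$metric, c("fraction_active", "frequency"))
  expect_equal(rep$test, c("t_student", "ks"))
  expect_lt(rep$p_value[rep$metric == "frequency"], 0.001)
  expect_equal(rep$n_a + rep$n_b, c(40, 40))
  # unknown ids and single groups are rejected
  expect_error(compareGenotypes(data, grouping[-1]), "missing from grouping")
  expect_error(compareGenotypes(data, stats::setNames(rep("wt", 40), ids)),
               "two groups")
})

test_that("null replicates reject at about the nominal 5% level", {
  set.seed(77)
  nRep <- 200
  ksRej <- tRej <- logical(nRep)
  for (i in seq_len(nRep)) {
    a <- stats::rnorm(60); b <- stats::rnorm(60)
    ksRej[i] <- ksTwoSample(a, b)$p_value < 0.05
    tRej[i] <- tTwoSample(a, b)$p_value < 0.05
  }
  # binomial 3-sigma bands around 5%
  expect_lt(abs(mean(tRej) - 0.05), 3 * sqrt(0.05 * 0.95 / nRep) + 1e-9)
  expect_lte(mean(ksRej), 0.05 + 3 * sqrt(0.05 * 0.95 / nRep))
})
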