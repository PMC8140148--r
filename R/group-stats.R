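# Two-sample tests implemented from first principles: the exact two-sided
# Kolmogorov-Smirnov D with asymptotic (or exact) p-values, and the
# unpaired t test (Student or Welch). Base R's ks.test / t.test are used
# only as independent cross-checks in the test suite.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over pooled sample points of the absolute difference
#' of the two right-continuous ECDFs, computed exactly from the sorted
#' samples (ties are handled by evaluating at pooled unique points). The
#' p-value comes from the exact Smirnov null distribution (lattice-path
#' recursion) whenever the samples are tie-free and na*nb <= 10^4 — the
#' asymptotic approximation is visibly conservative at the study's
#' per-group sample sizes — and from the asymptotic Kolmogorov
#' distribution with effective sample size n = na*nb/(na+nb) otherwise.
#'
#' @param a,b numeric samples, each with >= 2 finite values.
#' @param exact force (TRUE) or suppress (FALSE) the exact p-value; the
#'   exact path requires tie-free samples.
#' @return List: \code{D}, \code{p_value}, \code{n_effective},
#'   \code{method}.
#' @examples
#' ksTwoSample(1:10, 3:12)
#' @export
ksTwoSample <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("samples must be finite")
  na <- length(a); nb <- length(b)
  pts <- sort(unique(c(a, b)))
  # right-continuous ECDFs evaluated at the pooled unique points
  Fa <- findInterval(pts, sort(a)) / na
  Fb <- findInterval(pts, sort(b)) / nb
  D <- max(abs(Fa - Fb))
  nEff <- na * nb / (na + nb)
  hasTies <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (na * nb <= 10000) && !hasTies
  if (exact && hasTies) {
    warning("ties present; falling back to the asymptotic p-value")
    exact <- FALSE
  }
  if (exact) {
    # D under H0 is discrete on multiples of 1/(na*nb): P(D >= Dobs) is
    # 1 - P(D <= Dobs - half a lattice step)
    p <- 1 - .smirnovCdfLE(D - 0.5 / (na * nb), na, nb)
    method <- "exact"
  } else {
    p <- .kolmogorovTailP(sqrt(nEff) * D)
    method <- "asymptotic"
  }
  list(D = D, p_value = min(max(p, 0), 1), n_effective = nEff,
       method = method)
}

# Asymptotic two-sided tail: P(sup|B| > lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
.kolmogorovTailP <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Exact P(D <= q) for tie-free samples by the classic lattice-path
# recursion: the fraction of the C(m+n, m) equally likely interleavings
# whose path (i, j) keeps |i/m - j/n| <= q throughout. The running factor
# w = i/(i+n) folds the binomial normalization into the recursion so the
# accumulator stays within floating range.
.smirnovCdfLE <- function(q, m, n) {
  tol <- 1e-12
  u <- as.numeric((0:n) / n <= q + tol)
  for (i in 1:m) {
    w <- i / (i + n)
    u[1L] <- if (i / m > q + tol) 0 else w * u[1L]
    for (j in 1:n) {
      u[j + 1L] <- if (abs(i / m - j / n) > q + tol) 0 else
        w * u[j + 1L] + u[j]
    }
  }
  u[n + 1L]
}

#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test with either the pooled-variance (Student)
#' or the Welch unequal-variance statistic; p from the t distribution
#' tail (regularized incomplete beta).
#'
#' @param a,b numeric samples with >= 2 values each.
#' @param variant "student" (pooled variance) or "welch".
#' @return List: \code{t}, \code{df}, \code{p_value}, \code{variant},
#'   \code{mean_a}, \code{mean_b}.
#' @examples
#' tTwoSample(c(1, 2, 3), c(4, 5, 6))$t  # -3.674...
#' @export
tTwoSample <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0 && mean(a) == mean(b)) {
    # identical constants: no evidence of difference
    return(list(t = 0, df = na + nb - 2, p_value = 1, variant = variant,
                mean_a = mean(a), mean_b = mean(b)))
  }
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) stop("zero pooled variance; t statistic undefined")
    tStat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    if (se2 == 0) stop("zero variance in both groups; t statistic undefined")
    tStat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  # two-sided tail via the regularized incomplete beta function:
  # P(|T| > t) = I_{df/(df+t^2)}(df/2, 1/2)
  x <- df / (df + tStat^2)
  p <- stats::pbeta(x, df / 2, 0.5)
  list(t = tStat, df = df, p_value = min(max(p, 0), 1), variant = variant,
       mean_a = mean(a), mean_b = mean(b))
}

#' Compare metric distributions between two groups
#'
#' The study's two workhorse comparisons applied to a tidy metric table:
#' pooled per-ROI (or per-synapse) metric distributions are compared with
#' the two-sample KS test, per-FOV summary metrics (fractions of active
#' cells) with the unpaired t test. Which test a metric gets is declared
#' via \code{tests}; the default is KS.
#'
#' @param data data.frame with columns \code{id}, \code{metric},
#'   \code{value}.
#' @param grouping named character vector mapping every \code{id} to a
#'   group label; exactly two groups are required.
#' @param tests named character vector mapping metric names to "ks" or
#'   "t"; unlisted metrics default to "ks".
#' @param tVariant t-test variant, default "student".
#' @return data.frame, one row per metric (sorted): metric, test,
#'   group labels, per-group n/mean/median, statistic, p_value.
#' @export
compareGenotypes <- function(data, grouping, tests = character(0),
                             tVariant = "student") {
  stopifnot(is.data.frame(data),
            all(c("id", "metric", "value") %in% names(data)))
  unknown <- setdiff(unique(data$id), names(grouping))
  if (length(unknown)) {
    stop("ids missing from grouping: ", paste(unknown, collapse = ", "))
  }
  data$group <- unname(grouping[data$id])
  groups <- sort(unique(data$group))
  if (length(groups) != 2L) {
    stop("exactly two groups are required, got ", length(groups))
  }
  rows <- lapply(sort(unique(data$metric)), function(m) {
    sub <- data[data$metric == m, ]
    a <- sub$value[sub$group == groups[1L]]
    b <- sub$value[sub$group == groups[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      stop(sprintf("metric '%s': both groups need >= 2 values", m))
    }
    which <- if (m %in% names(tests)) tests[[m]] else "ks"
    if (which == "ks") {
      res <- ksTwoSample(a, b)
      stat <- res$D; p <- res$p_value; testName <- "ks"
    } else if (which == "t") {
      res <- tTwoSample(a, b, tVariant)
      stat <- res$t; p <- res$p_value; testName <- paste0("t_", tVariant)
    } else {
      stop("unknown test '", which, "' for metric '", m, "'")
    }
    data.frame(metric = m, test = testName,
               group_a = groups[1L], group_b = groups[2L],
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               median_a = stats::median(a), median_b = stats::median(b),
               statistic = stat, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
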