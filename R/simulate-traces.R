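# Synthetic GCaMP-like calcium traces with known ground truth.

#' Configuration for calcium-trace simulation
#'
#' Bundles and validates every parameter of the trace generator. Defaults
#' mirror the acquisition and analysis conditions of an anesthetized
#' 30 Hz two-photon recording: double-exponential transient kernel with
#' GCaMP6m-like kinetics (tau_rise 0.07 s, tau_decay 0.8 s), homogeneous
#' Poisson event trains, additive shared neuropil contamination at
#' coefficient 0.7, and white Gaussian sensor noise. Amplitude and noise
#' defaults give somatic transients about 12 times the per-frame noise
#' floor, a typical SNR for somata at this frame rate.
#'
#' @param n_cells number of cells (>= 1).
#' @param duration_s recording length in seconds (> 0).
#' @param frame_rate_hz acquisition rate, Hz (default 30).
#' @param event_rate_hz per-cell Poisson event rate, Hz (>= 0).
#' @param amp_mean,amp_sd event amplitude distribution, dF/F units
#'   (Gaussian, truncated at 0).
#' @param tau_rise_s,tau_decay_s kernel time constants, seconds;
#'   tau_decay_s must exceed tau_rise_s.
#' @param baseline_f baseline fluorescence, arbitrary units (> 0).
#' @param noise_sd per-frame Gaussian noise SD, fluorescence units (>= 0).
#' @param neuropil_coeff contamination coefficient in [0, 1] (default 0.7).
#' @param np_mean_f,np_sd_f mean level and fluctuation SD of the shared
#'   neuropil trace, fluorescence units.
#' @param seed master RNG seed (integer).
#' @return A validated list of class \code{TraceSimConfig}.
#' @examples
#' cfg <- traceSimConfig(n_cells = 5, duration_s = 20, seed = 1)
#' cfg$n_frames
#' @export
traceSimConfig <- function(n_cells, duration_s, frame_rate_hz = 30,
                           event_rate_hz = 0.1, amp_mean = 0.5, amp_sd = 0.1,
                           tau_rise_s = 0.07, tau_decay_s = 0.8,
                           baseline_f = 100, noise_sd = 4,
                           neuropil_coeff = 0.7,
                           np_mean_f = 30, np_sd_f = 5, seed = 1L) {
  .assertScalar(n_cells, "n_cells", min = 1, integer = TRUE)
  .assertScalar(duration_s, "duration_s", min = 0, strictMin = TRUE)
  .assertScalar(frame_rate_hz, "frame_rate_hz", min = 0, strictMin = TRUE)
  .assertScalar(event_rate_hz, "event_rate_hz", min = 0)
  .assertScalar(amp_mean, "amp_mean", min = 0)
  .assertScalar(amp_sd, "amp_sd", min = 0)
  .assertScalar(tau_rise_s, "tau_rise_s", min = 0, strictMin = TRUE)
  .assertScalar(tau_decay_s, "tau_decay_s", min = 0, strictMin = TRUE)
  if (tau_decay_s <= tau_rise_s) {
    stop("'tau_decay_s' must exceed 'tau_rise_s'", call. = FALSE)
  }
  .assertScalar(baseline_f, "baseline_f", min = 0, strictMin = TRUE)
  .assertScalar(noise_sd, "noise_sd", min = 0)
  .assertScalar(neuropil_coeff, "neuropil_coeff", min = 0, max = 1)
  .assertScalar(np_mean_f, "np_mean_f", min = 0)
  .assertScalar(np_sd_f, "np_sd_f", min = 0)
  .assertScalar(seed, "seed", integer = TRUE)
  nFrames <- round(duration_s * frame_rate_hz)
  if (nFrames < 1L) {
    stop("'duration_s' x 'frame_rate_hz' must give at least one frame",
         call. = FALSE)
  }
  structure(list(
    n_cells = as.integer(n_cells), duration_s = duration_s,
    frame_rate_hz = frame_rate_hz, event_rate_hz = event_rate_hz,
    amp_mean = amp_mean, amp_sd = amp_sd,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    baseline_f = baseline_f, noise_sd = noise_sd,
    neuropil_coeff = neuropil_coeff,
    np_mean_f = np_mean_f, np_sd_f = np_sd_f,
    seed = as.integer(seed), n_frames = as.integer(nFrames)
  ), class = "TraceSimConfig")
}

#' Double-exponential calcium transient kernel
#'
#' K(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) normalized to peak 1 for
#' t >= 0 and 0 for t < 0.
#'
#' @param t numeric times in seconds.
#' @param tau_rise_s,tau_decay_s time constants, tau_decay_s > tau_rise_s.
#' @return Kernel values, peak exactly 1.
#' @export
transientKernel <- function(t, tau_rise_s = 0.07, tau_decay_s = 0.8) {
  if (tau_decay_s <= tau_rise_s) stop("tau_decay_s must exceed tau_rise_s")
  tPeak <- log(tau_decay_s / tau_rise_s) * tau_rise_s * tau_decay_s /
    (tau_decay_s - tau_rise_s)
  peak <- exp(-tPeak / tau_decay_s) - exp(-tPeak / tau_rise_s)
  k <- ifelse(t >= 0, (exp(-t / tau_decay_s) - exp(-t / tau_rise_s)) / peak, 0)
  k
}

#' Simulate homogeneous Poisson event trains
#'
#' Draws per-cell event times and amplitudes only (no trace rendering).
#' Useful on its own for statistical calibration at scale; called
#' internally by \code{\link{simulateTraces}}.
#'
#' @param n_cells number of cells.
#' @param duration_s recording length, seconds.
#' @param event_rate_hz Poisson rate, Hz.
#' @param amp_mean,amp_sd amplitude distribution (Gaussian truncated at 0).
#' @param seed master seed; events and amplitudes use dedicated substreams.
#' @return List with \code{times} and \code{amps}, each a list of numeric
#'   vectors (times sorted, within [0, duration_s)).
#' @export
simulateEventTrains <- function(n_cells, duration_s, event_rate_hz,
                                amp_mean = 0.5, amp_sd = 0.1, seed = 1L) {
  times <- withSubstream(seed, "events", {
    counts <- stats::rpois(n_cells, event_rate_hz * duration_s)
    lapply(counts, function(k) sort(stats::runif(k, 0, duration_s)))
  })
  amps <- withSubstream(seed, "amps", {
    lapply(times, function(tt) pmax(stats::rnorm(length(tt), amp_mean, amp_sd), 0))
  })
  list(times = times, amps = amps)
}

#' Simulate calcium fluorescence traces with ground truth
#'
#' Renders per-cell observed traces as
#' \code{baseline_f * (1 + sum_events amp * K(t - t_event)) +
#' neuropil_coeff * neuropil(t) + N(0, noise_sd)}, with K the
#' double-exponential kernel. Event times follow a homogeneous Poisson
#' process. The shared neuropil trace is a slow Gaussian process (white
#' noise random walk smoothed at 1 Hz, standardized to \code{np_sd_f}
#' around \code{np_mean_f}), the slow common background regime the
#' compensation step targets. Identical config (including seed) gives
#' bit-identical output.
#'
#' @param config a \code{\link{traceSimConfig}}.
#' @return List with elements \code{observed} (frames x cells matrix),
#'   \code{signal} (noise- and neuropil-free cell traces),
#'   \code{neuropil} (shared neuropil trace), \code{truth}
#'   (\linkS4class{GroundTruth}) and \code{config}.
#' @examples
#' sim <- simulateTraces(traceSimConfig(n_cells = 2, duration_s = 10, seed = 3))
#' dim(sim$observed)
#' @export
simulateTraces <- function(config) {
  if (!inherits(config, "TraceSimConfig")) {
    stop("config must come from traceSimConfig()")
  }
  nF <- config$n_frames
  fs <- config$frame_rate_hz
  tGrid <- (seq_len(nF) - 1L) / fs

  trains <- simulateEventTrains(config$n_cells, config$duration_s,
                                config$event_rate_hz, config$amp_mean,
                                config$amp_sd, seed = config$seed)

  signal <- matrix(config$baseline_f, nrow = nF, ncol = config$n_cells)
  for (i in seq_len(config$n_cells)) {
    ev <- trains$times[[i]]
    am <- trains$amps[[i]]
    if (length(ev)) {
      s <- numeric(nF)
      for (j in seq_along(ev)) {
        rel <- tGrid - ev[j]
        live <- which(rel >= 0 & rel <= 8 * config$tau_decay_s)
        if (length(live)) {
          s[live] <- s[live] + am[j] *
            transientKernel(rel[live], config$tau_rise_s, config$tau_decay_s)
        }
      }
      signal[, i] <- config$baseline_f * (1 + s)
    }
  }

  neuropil <- .simulateNeuropil(nF, fs, config$np_mean_f, config$np_sd_f,
                                config$seed)

  noise <- withSubstream(config$seed, "noise", {
    matrix(stats::rnorm(nF * config$n_cells, 0, config$noise_sd),
           nrow = nF, ncol = config$n_cells)
  })
  observed <- signal + config$neuropil_coeff * neuropil + noise

  truth <- new("GroundTruth",
    eventTimes = trains$times, eventAmps = trains$amps,
    trueRate = config$event_rate_hz, neuropilTrace = neuropil,
    neuropilCoeff = config$neuropil_coeff,
    appliedShifts = matrix(integer(0), 0, 2))

  list(observed = observed, signal = signal, neuropil = neuropil,
       truth = truth, config = config)
}

# Slow shared neuropil background: random-walk increments smoothed with a
# 1 Hz zero-phase low-pass, then standardized to the requested mean/SD.
.simulateNeuropil <- function(nFrames, frameRate, meanF, sdF, seed) {
  if (sdF == 0 && meanF == 0) return(numeric(nFrames))
  withSubstream(seed, "neuropil", {
    if (nFrames < 4L || sdF == 0) {
      return(rep(meanF, nFrames))
    }
    walk <- cumsum(stats::rnorm(nFrames))
    cutoff <- min(1, frameRate / 4)  # degrade gracefully at low frame rates
    sm <- .zeroPhaseLowpass(walk, frameRate, cutoff)
    s <- stats::sd(sm)
    if (s == 0) return(rep(meanF, nFrames))
    out <- meanF + (sm - mean(sm)) / s * sdF
    pmax(out, 0)
  })
}
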