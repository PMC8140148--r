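# Zero-phase Butterworth low-pass filtering on plain numeric vectors.
#
# signal::filtfilt applies the filter forward and backward but does not pad,
# so step/DC inputs acquire edge transients. We pad by odd reflection (the
# signal is mirrored and flipped about each endpoint value) before the
# forward-backward pass and trim afterwards; a constant input then passes
# through exactly and the DC gain stays 1 to numerical precision.

.zeroPhaseLowpass <- function(x, frameRate, cutoffHz, order = 4L) {
  n <- length(x)
  if (cutoffHz >= frameRate / 2) {
    stop("cutoff frequency must be below the Nyquist frequency (frameRate/2)")
  }
  if (cutoffHz <= 0) stop("cutoff frequency must be positive")
  if (n < 2L) return(x)
  bf <- signal::butter(order, cutoffHz / (frameRate / 2), type = "low")
  padlen <- min(n - 1L, max(15L, 10L * ceiling(frameRate / cutoffHz)))
  pre <- 2 * x[1L] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(padlen + 1L):(padlen + n)]
}
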