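#' Zero-phase band-pass filter for tremor analysis
#'
#' Filters a 1-D signal to the tremor band (default 2-10 Hz) with a
#' forward-backward (zero-phase) Butterworth band-pass. The forward-backward
#' pass squares the magnitude response, giving better than 20 dB attenuation
#' one octave below the lower edge and at `hi + (hi - lo)/2`, while leaving
#' in-band amplitude and phase intact.
#'
#' @param series numeric vector.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `lo < hi < fs/2`.
#' @param order per-pass Butterworth order given to [signal::butter()]
#'   (default 4).
#' @return filtered numeric vector of the same length.
#' @export
band_pass <- function(series, fs, lo = 2, hi = 10, order = 4) {
  stopifnot(is.numeric(series), lo > 0, lo < hi, hi < fs / 2)
  flt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  n_coef <- length(flt$a) - 1L          # transfer-function order of one pass
  if (length(series) < 3 * n_coef)
    stop("segment too short to filter")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass on short segments
  series <- series - mean(series)   # DC is out of band; removing it first
                                    # keeps the reflection padding centred
  n <- length(series)
  np <- min(n - 1L, 10L * n_coef)
  padded <- c(2 * series[1] - series[(np + 1):2],
              series,
              2 * series[n] - series[(n - 1):(n - np)])
  out <- signal::filtfilt(flt, padded)
  as.numeric(out[(np + 1):(np + n)])
}

#' Dominant tremor axis by principal component analysis
#'
#' Band-passes each axis of a triaxial signal to 2-10 Hz and finds the first
#' principal axis of the resulting 3-D cloud: the single direction capturing
#' the most in-band variance. The band-passed signal is projected onto that
#' axis to give the 1-D movement-parameter series used for amplitude
#' extraction. The axis sign is fixed so its first nonzero component is
#' positive (PCA sign is otherwise arbitrary).
#'
#' @param signal3d 3 x n matrix (rows = x, y, z) of position or angular
#'   velocity samples.
#' @param fs sampling rate in Hz.
#' @param lo,hi tremor band in Hz.
#' @return a list of class `axis_projection` with `axis` (unit 3-vector),
#'   `series` (projected band-passed signal) and `variance_fraction`
#'   (fraction of band-passed variance explained by the axis).
#' @export
dominant_axis <- function(signal3d, fs, lo = 2, hi = 10) {
  signal3d <- as.matrix(signal3d)
  if (nrow(signal3d) != 3 && ncol(signal3d) == 3) signal3d <- t(signal3d)
  stopifnot(nrow(signal3d) == 3, ncol(signal3d) >= 3)
  bp <- t(apply(signal3d, 1, band_pass, fs = fs, lo = lo, hi = hi))
  if (all(abs(bp) < 1e-12)) stop("no variance in band")
  cc <- stats::cov(t(bp))
  eg <- eigen(cc, symmetric = TRUE)
  axis <- eg$vectors[, 1]
  nz <- which(abs(axis) > 1e-12)[1]
  if (axis[nz] < 0) axis <- -axis
  structure(list(axis = axis,
                 series = as.numeric(crossprod(bp, axis)),
                 variance_fraction = eg$values[1] / sum(eg$values)),
            class = "axis_projection")
}

#' Hand displacement from triaxial acceleration
#'
#' Double-integrates triaxial acceleration to displacement in the frequency
#' domain, restricted to the tremor band: each axis is Fourier transformed,
#' divided by \eqn{-(2\pi f)^2}, zeroed outside `lo`-`hi` Hz, and inverse
#' transformed. Restricting to the band sidesteps the low-frequency drift
#' that time-domain double integration would accumulate. A sinusoidal
#' acceleration of amplitude `a` at frequency `f` yields displacement
#' amplitude `a / (2 pi f)^2`.
#'
#' @param accel3d 3 x n matrix of accelerations in m/s^2 (a single numeric
#'   vector is treated as one axis).
#' @param fs sampling rate in Hz; must exceed 20 Hz.
#' @param lo,hi band in Hz.
#' @return displacement matrix of the same shape, in millimetres.
#' @export
accel_to_displacement <- function(accel3d, fs, lo = 2, hi = 10) {
  if (fs <= 20) stop("fs must exceed 20 Hz: 2-10 Hz band not resolvable")
  vec_in <- is.null(dim(accel3d))
  a <- if (vec_in) matrix(accel3d, nrow = 1) else as.matrix(accel3d)
  if (nrow(a) != 3 && ncol(a) == 3 && !vec_in) a <- t(a)
  n <- ncol(a)
  if (n / fs < 1.5) stop("need at least 1.5 s of acceleration data")
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  keep <- abs(f) >= lo & abs(f) <= hi
  h <- ifelse(keep, -1 / (2 * pi * f)^2, 0)
  h[!is.finite(h)] <- 0
  disp <- t(apply(a, 1, function(x) Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n))
  disp <- disp * 1000  # m -> mm
  if (vec_in) as.numeric(disp) else disp
}
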