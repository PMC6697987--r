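#' Welch analysis settings
#'
#' Settings for [welch_psd()]. The defaults are chosen for very short
#' clinical segments: a rectangular window (tapering discards too much of a
#' 1.5-3 s segment), 1-s segments with 50% overlap, and zero-padding to a
#' fine frequency grid so the +/- 1 Hz tremor band always contains many bins.
#'
#' @param seg_s Welch segment length in seconds; the actual segment is
#'   `min(seg_s, full window)`.
#' @param overlap fractional overlap between successive segments.
#' @param df_max maximum frequency-grid spacing in Hz (zero-padding target).
#' @param min_window_s shortest analysable window in seconds.
#' @return a list of class `welch_config`.
#' @export
welch_config <- function(seg_s = 1, overlap = 0.5, df_max = 0.0625,
                         min_window_s = 1.5) {
  stopifnot(seg_s > 0, overlap >= 0, overlap < 1, df_max > 0, min_window_s > 0)
  structure(list(seg_s = seg_s, overlap = overlap, df_max = df_max,
                 min_window_s = min_window_s), class = "welch_config")
}

#' Welch power spectral density
#'
#' One-sided PSD of a short segment by Welch's method with a rectangular
#' window: the segment is split into `seg_s`-second pieces at 50% overlap,
#' each piece is mean-removed, zero-padded to a grid no coarser than
#' `df_max`, and the periodograms are averaged. The density is scaled so
#' that `sum(psd) * df` equals the signal variance (Parseval).
#'
#' @param segment numeric vector.
#' @param fs sampling rate in Hz.
#' @param cfg a [welch_config()].
#' @return a list of class `tremor_spectrum` with `freqs` (Hz), `psd`
#'   (signal-units^2/Hz), `df`, `fs`, `t_s` (sampling period) and `seg_s`
#'   (realised segment length in seconds). The tremor annotations `f_t`,
#'   `f1`, `f2`, `n_band_bins` are `NA` until set by [locate_tremor_peak()] /
#'   [ata_band()] (see [tremor_spectrum()]).
#' @export
welch_psd <- function(segment, fs, cfg = welch_config()) {
  stopifnot(is.numeric(segment), fs > 0)
  n <- length(segment)
  if (n / fs < cfg$min_window_s)
    stop("below minimum window: segment shorter than ", cfg$min_window_s, " s")
  m <- min(round(cfg$seg_s * fs), n)
  nfft <- 2^ceiling(log2(max(fs / cfg$df_max, m)))
  step <- max(1L, floor(m * (1 - cfg$overlap)))
  starts <- seq.int(1L, n - m + 1L, by = step)
  acc <- numeric(nfft %/% 2 + 1L)
  for (s0 in starts) {
    x <- segment[s0:(s0 + m - 1L)]
    x <- x - mean(x)
    z <- stats::fft(c(x, numeric(nfft - m)))
    pxx <- Mod(z[1:(nfft %/% 2 + 1L)])^2 / (fs * m)
    pxx[2:(nfft %/% 2)] <- 2 * pxx[2:(nfft %/% 2)]
    acc <- acc + pxx
  }
  structure(list(freqs = seq(0, nfft %/% 2) * fs / nfft,
                 psd = acc / length(starts),
                 df = fs / nfft, fs = fs, t_s = 1 / fs, seg_s = m / fs,
                 duration_s = n / fs,
                 f_t = NA_real_, f1 = NA_real_, f2 = NA_real_,
                 n_band_bins = NA_integer_),
            class = "tremor_spectrum")
}

#' @export
print.tremor_spectrum <- function(x, ...) {
  cat(sprintf("<tremor_spectrum> %d bins, df = %.4g Hz, fs = %g Hz\n",
              length(x$freqs), x$df, x$fs))
  if (!is.na(x$f_t))
    cat(sprintf("  tremor peak f_T = %.3g Hz, ATA band [%.3g, %.3g] Hz (%d bins)\n",
                x$f_t, x$f1, x$f2, x$n_band_bins))
  invisible(x)
}

#' Locate the nominal tremor frequency
#'
#' The tremor frequency is the frequency of the maximum PSD bin within the
#' 2-10 Hz band; out-of-band bins are ignored. Ties resolve to the lowest
#' frequency.
#'
#' @param spec a `tremor_spectrum`.
#' @param lo,hi search band in Hz.
#' @return the tremor frequency in Hz.
#' @export
locate_tremor_peak <- function(spec, lo = 2, hi = 10) {
  idx <- which(spec$freqs >= lo - 1e-9 & spec$freqs <= hi + 1e-9)
  if (length(idx) == 0) stop("spectrum does not cover the ", lo, "-", hi, " Hz band")
  x <- spec$psd[idx]
  if (all(x <= 0)) stop("no peak: spectrum is zero in the ", lo, "-", hi, " Hz band")
  spec$freqs[idx[which.max(x)]]   # which.max takes the first (lowest f) on ties
}

#' Tremor band around the peak
#'
#' Boundary frequencies `f1 = max(2, f_t - 1)` and `f2 = min(10, f_t + 1)`,
#' allowing for a broad peak while clamping to the analysed 2-10 Hz band.
#'
#' @param f_t tremor frequency in Hz, within 2-10.
#' @param lo,hi clamp bounds in Hz.
#' @return numeric vector `c(f1, f2)`.
#' @export
ata_band <- function(f_t, lo = 2, hi = 10) {
  stopifnot(f_t >= lo - 1e-9, f_t <= hi + 1e-9)
  c(max(lo, f_t - 1), min(hi, f_t + 1))
}

#' Annotated tremor spectrum of a segment
#'
#' Convenience wrapper: Welch PSD, peak location and ATA band in one step.
#'
#' @inheritParams welch_psd
#' @param lo,hi analysis band in Hz.
#' @return a `tremor_spectrum` with `f_t`, `f1`, `f2`, `n_band_bins` set.
#' @export
tremor_spectrum <- function(segment, fs, cfg = welch_config(), lo = 2, hi = 10) {
  spec <- welch_psd(segment, fs, cfg)
  spec$f_t <- locate_tremor_peak(spec, lo, hi)
  band <- ata_band(spec$f_t, lo, hi)
  spec$f1 <- band[1]
  spec$f2 <- band[2]
  spec$n_band_bins <- sum(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  spec
}

# Integral of |sinc(u)| = |sin(pi u)/(pi u)| over [u1, u2], by fine trapezoid.
# This is the spectral mass of a rectangular-window sinusoid line shape in
# units of the segment bandwidth, used to calibrate the ATA estimator.
sinc_mass <- function(u1, u2, step = 1e-3) {
  u <- seq(u1, u2, by = step)
  if (length(u) < 2) return(0)
  y <- abs(sin(pi * u) / (pi * u))
  y[!is.finite(y)] <- 1    # u = 0
  sum((y[-1] + y[-length(y)]) / 2) * step
}

#' Average tremor amplitude (ATA)
#'
#' Sums the square-root PSD over the tremor band `[f1, f2]` and applies a
#' fixed calibration so that a pure sinusoid of zero-to-peak amplitude `A`
#' returns its peak-to-peak amplitude `2A`, independent of sampling rate and
#' segment duration:
#' \deqn{ATA = \kappa \, \Delta f \sum_{f_1}^{f_2} \sqrt{X(f)},\qquad
#'       \kappa = \frac{2\sqrt{2 T_w}}{I}}
#' where \eqn{T_w} is the Welch segment length and \eqn{I} the integral of
#' the rectangular-window line shape \eqn{|\mathrm{sinc}((f-f_T)T_w)|} over
#' the band. The calibration constant is a fixed analytic function of the
#' band geometry only (it corrects for band clamping near 2 and 10 Hz); it is
#' never fitted to data.
#'
#' @param spec a `tremor_spectrum` with `f_t`, `f1`, `f2` set (see
#'   [tremor_spectrum()]).
#' @return amplitude in the units of the input signal, peak-to-peak sense.
#' @export
ata <- function(spec) {
  if (is.na(spec$f1) || is.na(spec$f2) || is.na(spec$f_t))
    stop("spectrum has no tremor band; use tremor_spectrum() first")
  idx <- which(spec$freqs >= spec$f1 - 1e-9 & spec$freqs <= spec$f2 + 1e-9)
  if (length(idx) == 0) stop("no frequency bins in the ATA band")
  mass <- sinc_mass((spec$f1 - spec$f_t) * spec$seg_s,
                    (spec$f2 - spec$f_t) * spec$seg_s)
  kappa <- 2 * sqrt(2 * spec$seg_s) / mass
  kappa * spec$df * sum(sqrt(spec$psd[idx]))
}

# Local extrema of a discrete series by strict sign change of first
# differences; plateaus collapse to their left edge. Returns the indices of
# minima and maxima in index order.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(minima = integer(0), maxima = integer(0), all = integer(0)))
  s <- sign(diff(x))
  if (all(s == 0)) return(list(minima = integer(0), maxima = integer(0), all = integer(0)))
  # plateau collapse to left edge: a zero-run adopts the sign that follows it
  filled <- s
  nxt <- 0
  for (i in rev(seq_along(s))) {
    if (s[i] != 0) nxt <- s[i] else filled[i] <- nxt
  }
  # at position i (2..n-1): max if filled[i-1] > 0 and filled[i] < 0
  i <- 2:(n - 1)
  maxima <- i[filled[i - 1] > 0 & filled[i] < 0]
  minima <- i[filled[i - 1] < 0 & filled[i] > 0]
  list(minima = minima, maxima = maxima, all = sort(c(minima, maxima)))
}

#' Heuristic rejection of a tremor amplitude estimate
#'
#' Applies, in order, the rejection rules used to exclude unreliable
#' estimates before averaging:
#' \enumerate{
#'   \item the analysed window must be at least 1.5 s long;
#'   \item the tremor band `f_TB` (bounded by the PSD local minima nearest
#'     the peak within 1.5 Hz either side, clamped to 2-10 Hz) must carry
#'     mean power at least the median of the comparison band `f_CB` (the
#'     rest of 2-10 Hz);
#'   \item the power range over `f_TB` must stand out from the fluctuation
#'     of the comparison band: it is rejected if smaller than twice the 70th
#'     percentile of the absolute differences between consecutive local
#'     extrema of `X(f_CB)`, or smaller than their mean plus three standard
#'     deviations.
#' }
#' Rule 3 is only evaluated when rule 2 passes. If the comparison band has
#' fewer than three local extrema the fluctuation statistics are undefined;
#' the estimate is then accepted by default with the note
#' `"sparse_comparison_band"`.
#'
#' @param spec a `tremor_spectrum` with `f_t` set.
#' @param duration_s duration of the analysed window in seconds.
#' @param min_duration_s rejection threshold for rule 1 (default 1.5 s).
#' @param lo,hi analysis band in Hz.
#' @return a list of class `rejection_report` with fields `accepted`,
#'   `duration_ok`, `f_tb`, `f_cb` (bin indices), `delta_tb`, `delta_cb`,
#'   `p50_cb`, `p70_deltas`, `mean_delta_cb`, `sd_delta_cb`, `reasons`
#'   (identifiers of failed rules) and `notes`.
#' @export
reject_estimate <- function(spec, duration_s, min_duration_s = 1.5,
                            lo = 2, hi = 10) {
  reasons <- character(0)
  notes <- character(0)
  duration_ok <- duration_s >= min_duration_s - 1e-9
  if (!duration_ok) reasons <- c(reasons, "short_window")

  ib <- which(spec$freqs >= lo - 1e-9 & spec$freqs <= hi + 1e-9)
  x <- spec$psd[ib]
  f <- spec$freqs[ib]
  p <- which.max(x)

  ext <- local_extrema(x)
  lcand <- ext$minima[ext$minima < p & f[p] - f[ext$minima] <= 1.5 + 1e-9]
  rcand <- ext$minima[ext$minima > p & f[ext$minima] - f[p] <= 1.5 + 1e-9]
  lb <- if (length(lcand)) max(lcand) else min(which(f >= f[p] - 1.5 - 1e-9))
  rb <- if (length(rcand)) min(rcand) else max(which(f <= f[p] + 1.5 + 1e-9))
  tb <- lb:rb
  cb <- setdiff(seq_along(x), tb)

  delta_tb <- max(x[tb]) - min(x[tb])
  p50_cb <- NA_real_
  delta_cb <- numeric(0)
  p70 <- NA_real_; mu <- NA_real_; sdv <- NA_real_

  if (length(cb) == 0) {
    notes <- c(notes, "empty_comparison_band")
  } else {
    p50_cb <- stats::quantile(x[cb], 0.5, names = FALSE)
    if (mean(x[tb]) < p50_cb) {
      reasons <- c(reasons, "low_band_power")
    } else {
      # rule 3, evaluated per contiguous run of the comparison band
      runs <- split(cb, cumsum(c(1, diff(cb) != 1)))
      n_ext <- 0L
      for (r in runs) {
        e <- local_extrema(x[r])$all
        n_ext <- n_ext + length(e)
        if (length(e) >= 2) delta_cb <- c(delta_cb, abs(diff(x[r][e])))
      }
      if (n_ext < 3 || length(delta_cb) < 2) {
        notes <- c(notes, "sparse_comparison_band")
      } else {
        p70 <- stats::quantile(delta_cb, 0.7, names = FALSE)
        mu <- mean(delta_cb)
        sdv <- stats::sd(delta_cb)
        if (delta_tb < 2 * p70) reasons <- c(reasons, "flat_peak_p70")
        if (delta_tb < mu + 3 * sdv) reasons <- c(reasons, "flat_peak_sd")
      }
    }
  }

  structure(list(accepted = length(reasons) == 0,
                 duration_ok = duration_ok,
                 f_tb = ib[tb], f_cb = ib[cb],
                 delta_tb = delta_tb, delta_cb = delta_cb,
                 p50_cb = p50_cb, p70_deltas = p70,
                 mean_delta_cb = mu, sd_delta_cb = sdv,
                 reasons = reasons, notes = notes),
            class = "rejection_report")
}

#' Representative amplitude for one instance of a task
#'
#' Runs the full per-repetition chain (Welch PSD, peak location, ATA band,
#' rejection heuristics, ATA) on each repetition segment of one movement
#' parameter, then averages the natural log of the surviving ATA values into
#' a single representative estimate. If no repetition survives the result is
#' null (`NA`).
#'
#' @param repetition_segments list of numeric vectors (one per repetition;
#'   the clinical protocol uses three).
#' @param fs sampling rate in Hz.
#' @param cfg a [welch_config()].
#' @param parameter_id movement-parameter name carried into the result.
#' @param lo,hi analysis band in Hz.
#' @return a list of class `amplitude_estimate` with `parameter_id`,
#'   `log_ata` (`NA` when no repetition was accepted), `n_reps_used`,
#'   `f_t_mean` (mean tremor frequency over accepted repetitions) and
#'   `rejection_reports`.
#' @export
instance_amplitude <- function(repetition_segments, fs, cfg = welch_config(),
                               parameter_id = "", lo = 2, hi = 10) {
  stopifnot(length(repetition_segments) >= 1)
  reports <- vector("list", length(repetition_segments))
  logs <- c(); fts <- c()
  for (k in seq_along(repetition_segments)) {
    seg <- repetition_segments[[k]]
    dur <- length(seg) / fs
    if (dur < cfg$min_window_s) {
      reports[[k]] <- structure(list(accepted = FALSE, duration_ok = FALSE,
                                     reasons = "short_window", notes = character(0)),
                                class = "rejection_report")
      next
    }
    spec <- try(tremor_spectrum(seg, fs, cfg, lo, hi), silent = TRUE)
    if (inherits(spec, "try-error")) {
      reports[[k]] <- structure(list(accepted = FALSE, duration_ok = TRUE,
                                     reasons = "no_peak", notes = character(0)),
                                class = "rejection_report")
      next
    }
    rep_k <- reject_estimate(spec, dur, cfg$min_window_s, lo, hi)
    reports[[k]] <- rep_k
    if (rep_k$accepted) {
      a <- ata(spec)
      if (a > 0) {
        logs <- c(logs, log(a))
        fts <- c(fts, spec$f_t)
      }
    }
  }
  structure(list(parameter_id = parameter_id,
                 log_ata = if (length(logs)) mean(logs) else NA_real_,
                 n_reps_used = length(logs),
                 f_t_mean = if (length(fts)) mean(fts) else NA_real_,
                 rejection_reports = reports),
            class = "amplitude_estimate")
}
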