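# shared fixtures, built in code

# pure sinusoid sampled at fs for dur seconds
make_sine <- function(freq, fs, dur, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# peak-to-peak amplitude of the central portion of a series (avoids filter
# edge transients)
mid_peak_amp <- function(x, trim = 0.2) {
  n <- length(x)
  idx <- seq.int(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  (max(x[idx]) - min(x[idx])) / 2
}

# a spectrum object with a hand-constructed PSD, for direct ATA/rejection
# checks that bypass Welch estimation
manual_spectrum <- function(freqs, psd, f_t = NA, seg_s = 1) {
  spec <- structure(list(freqs = freqs, psd = psd, df = freqs[2] - freqs[1],
                         fs = 2 * max(freqs), t_s = 1 / (2 * max(freqs)),
                         seg_s = seg_s, duration_s = NA_real_,
                         f_t = f_t, f1 = NA_real_, f2 = NA_real_,
                         n_band_bins = NA_integer_),
                    class = "tremor_spectrum")
  if (!is.na(f_t)) {
    band <- ata_band(f_t)
    spec$f1 <- band[1]; spec$f2 <- band[2]
    spec$n_band_bins <- sum(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  }
  spec
}

# a small multichannel recording of sinusoids
make_recording <- function(fs = 100, dur = 10, subject_id = "s1",
                           day_id = "d1", instance_id = 1L) {
  movement_recording(
    list(wrist.flexion = make_sine(5, fs, dur),
         elbow.flexion = make_sine(4, fs, dur, amp = 2)),
    fs, subject_id, day_id, instance_id)
}

# brute-force Benjamini-Hochberg step-up, the independent oracle for bh_fdr
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (k in rev(seq_len(m))) {
    running <- min(running, p[ord[k]] * m / k)
    adj[ord[k]] <- min(1, running)
  }
  adj
}
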