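#' Simulate a cohort of measurement vectors with known ground truth
#'
#' Generates per-subject tremor measurement vectors under the generative
#' model the personalised metrics assume: each subject has a fixed
#' non-negative characteristic profile `c`; each day carries a log-normal
#' scale factor `s_d = exp(eta_d)` (between-day drift of overall severity);
#' each day additionally wobbles the profile by additive Gaussian noise, and
#' each instance adds its own within-day noise:
#' \deqn{a_{d,i} = s_d c + \delta_d + \epsilon_{d,i}}
#' Noise magnitudes are expressed relative to the subject's profile norm:
#' an element-wise SD of `sd * ||c|| / sqrt(n_params)`, so that e.g.
#' `within_day_sd = 0.15` means instance noise with vector norm about 15% of
#' the profile norm. Optional dropout replaces elements with nulls at a
#' fixed rate, mimicking rejected amplitude estimates.
#'
#' Defaults mirror the clinical study design: 24 subjects, two instances per
#' day on each of two days, 15 joint parameters, moderate between-day drift
#' and within-day variability.
#'
#' @param n_subjects,n_params,n_days,n_instances cohort dimensions.
#' @param scale_sd SD of the per-day log-scale factor `eta_d`.
#' @param profile_noise_sd day-level profile wobble, relative (see above).
#' @param within_day_sd instance-level noise, relative (see above).
#' @param dropout probability that an element is null.
#' @param seed RNG seed; identical seeds reproduce outputs exactly.
#' @return list with `vectors` (long [tibble::tibble()]: `subject_id`,
#'   `day_id`, `instance_id`, `parameter_id`, `value`) and `truth` (list
#'   with `profiles` matrix, `day_log_scale` matrix, `severity` matrix
#'   `s_d * ||c||`, `params`, `seed`).
#' @export
simulate_cohort_vectors <- function(n_subjects = 24, n_params = 15,
                                    n_days = 2, n_instances = 2,
                                    scale_sd = 0.5, profile_noise_sd = 0.1,
                                    within_day_sd = 0.15, dropout = 0,
                                    seed = 1) {
  stopifnot(scale_sd >= 0, profile_noise_sd >= 0, within_day_sd >= 0,
            dropout >= 0, dropout <= 1)
  set.seed(seed)
  params <- sprintf("joint.%02d", seq_len(n_params))
  profiles <- matrix(abs(stats::rnorm(n_subjects * n_params, mean = 1, sd = 0.5)),
                     n_subjects, n_params,
                     dimnames = list(paste0("s", seq_len(n_subjects)), params))
  eta <- matrix(stats::rnorm(n_subjects * n_days, 0, scale_sd),
                n_subjects, n_days,
                dimnames = list(rownames(profiles), paste0("d", seq_len(n_days))))
  rows <- vector("list", n_subjects * n_days * n_instances)
  k <- 0
  severity <- eta
  for (s in seq_len(n_subjects)) {
    cvec <- profiles[s, ]
    nrm <- sqrt(sum(cvec^2))
    el_sd <- nrm / sqrt(n_params)
    for (d in seq_len(n_days)) {
      s_d <- exp(eta[s, d])
      severity[s, d] <- s_d * nrm
      delta <- stats::rnorm(n_params, 0, profile_noise_sd * el_sd)
      for (i in seq_len(n_instances)) {
        eps <- stats::rnorm(n_params, 0, within_day_sd * el_sd)
        a <- s_d * cvec + delta + eps
        if (dropout > 0) a[stats::runif(n_params) < dropout] <- NA_real_
        k <- k + 1
        rows[[k]] <- tibble::tibble(subject_id = paste0("s", s),
                                    day_id = paste0("d", d),
                                    instance_id = i,
                                    parameter_id = params,
                                    value = unname(a))
      }
    }
  }
  list(vectors = dplyr::bind_rows(rows),
       truth = list(profiles = profiles, day_log_scale = eta,
                    severity = severity, params = params, seed = seed))
}

#' Simulate raw movement recordings for a cohort
#'
#' Turns per-instance parameter amplitudes into raw 1-D movement signals the
#' spectral pipeline can analyse: each parameter's series is a sinusoidal
#' tremor (zero-to-peak amplitude from the supplied vector, random phase,
#' tremor frequency drawn once per subject and stable across visits)
#' embedded in broadband white noise and a slow (< 1 Hz) voluntary-movement
#' drift. Each recording contains `n_reps` consecutive repetition windows of
#' `duration_s` seconds, matching the clinical protocol of scoring several
#' repetitions per instance.
#'
#' @param vectors long table as produced by [simulate_cohort_vectors()]
#'   (`value` is interpreted as the zero-to-peak tremor amplitude; negative
#'   or null values give a tremor-free series).
#' @param fs sampling rate in Hz.
#' @param duration_s duration of one repetition window in seconds.
#' @param n_reps repetitions per instance.
#' @param tremor_freq_range two-element range in Hz (within 2-10) from which
#'   each subject's tremor frequency is drawn.
#' @param noise_floor SD of the additive white noise, in signal units.
#' @param drift_amp amplitude of the sub-tremor-band voluntary drift.
#' @param seed RNG seed.
#' @return list with `recordings` (list of [movement_recording()], one per
#'   subject/day/instance) and `annotations` (tibble of repetition windows:
#'   `subject_id`, `day_id`, `instance_id`, `start_s`, `end_s`, `label`).
#' @export
simulate_recordings <- function(vectors, fs = 100, duration_s = 3, n_reps = 3,
                                tremor_freq_range = c(3, 6),
                                noise_floor = 0.05, drift_amp = 1, seed = 1) {
  stopifnot(tremor_freq_range[1] >= 2, tremor_freq_range[2] <= 10,
            tremor_freq_range[1] <= tremor_freq_range[2])
  set.seed(seed)
  subjects <- unique(vectors$subject_id)
  f_subj <- stats::setNames(stats::runif(length(subjects), tremor_freq_range[1],
                                         tremor_freq_range[2]), subjects)
  total_s <- duration_s * n_reps
  t <- seq(0, total_s - 1 / fs, by = 1 / fs)
  keys <- unique(vectors[c("subject_id", "day_id", "instance_id")])
  recs <- vector("list", nrow(keys))
  ann <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    key <- keys[k, ]
    dv <- vectors[vectors$subject_id == key$subject_id &
                    vectors$day_id == key$day_id &
                    vectors$instance_id == key$instance_id, ]
    f0 <- f_subj[[key$subject_id]]
    channels <- lapply(seq_len(nrow(dv)), function(j) {
      amp <- dv$value[j]
      if (is.na(amp) || amp <= 0) amp <- 0
      amp * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(length(t), 0, noise_floor) +
        drift_amp * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
    })
    names(channels) <- dv$parameter_id
    recs[[k]] <- movement_recording(channels, fs,
                                    subject_id = key$subject_id,
                                    day_id = key$day_id,
                                    instance_id = key$instance_id)
    ann[[k]] <- tibble::tibble(subject_id = key$subject_id,
                               day_id = key$day_id,
                               instance_id = key$instance_id,
                               start_s = duration_s * (seq_len(n_reps) - 1),
                               end_s = duration_s * seq_len(n_reps),
                               label = paste0("rep", seq_len(n_reps)))
  }
  list(recordings = recs, annotations = dplyr::bind_rows(ann),
       tremor_freqs = f_subj)
}

#' Simulate coarse observer scores from latent severities
#'
#' Maps each subject/visit latent severity onto clinical-scale-like scores:
#' an observed-severity item `A = clip(round(gain_a * latent), 0, 4)` (a
#' single coarse 0-4 item, which saturates), and task/self-report sums `B`
#' and `C` formed by summing several 0-4 items whose per-item gains are
#' log-normally perturbed, giving them finer effective resolution than `A`.
#' A latent severity of exactly zero maps to zero on every item.
#'
#' @param truth the `truth` element of [simulate_cohort_vectors()] (its
#'   `severity` matrix supplies the latents), or a numeric matrix of
#'   latent severities (subjects x visits).
#' @param scale_max top of the integer scale.
#' @param gain_a multiplicative gain applied before rounding for item A.
#' @param n_items number of items summed for B and C.
#' @param item_noise_sd SD (log scale) of the per-item gain perturbation.
#' @param mean_days_between mean simulated days between visits.
#' @param seed RNG seed.
#' @return [tibble::tibble()] with `subject_id`, `visit`, `ftmtrs_a`,
#'   `ftmtrs_b`, `ftmtrs_c`, `days_since_visit1`.
#' @export
simulate_observer_scores <- function(truth, scale_max = 4, gain_a = 0.5,
                                     n_items = 5, item_noise_sd = 0.5,
                                     mean_days_between = 154, seed = 1) {
  sev <- if (is.list(truth)) truth$severity else truth
  stopifnot(is.matrix(sev), all(is.finite(sev)))
  set.seed(seed)
  clip <- function(v) pmin(pmax(v, 0), scale_max)
  n_sub <- nrow(sev); n_vis <- ncol(sev)
  days2 <- round(pmax(stats::rnorm(n_sub, mean_days_between, 60), 7))
  rows <- list()
  for (s in seq_len(n_sub)) for (v in seq_len(n_vis)) {
    latent <- sev[s, v]
    a <- clip(round(gain_a * latent))
    b <- sum(clip(round(latent * exp(stats::rnorm(n_items, 0, item_noise_sd)))))
    cc <- sum(clip(round(latent * exp(stats::rnorm(n_items, 0, item_noise_sd)))))
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = if (!is.null(rownames(sev))) rownames(sev)[s] else paste0("s", s),
      visit = v, ftmtrs_a = a, ftmtrs_b = b, ftmtrs_c = cc,
      days_since_visit1 = if (v == 1) 0 else days2[s] * (v - 1))
  }
  dplyr::bind_rows(rows)
}
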