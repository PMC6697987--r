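#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis chain with its default:
#' the 2-10 Hz tremor band, the 1.5 s minimum window, the Welch settings,
#' the joint-count range for the N-family, and the same-day denominator
#' convention of the variability adjustment.
#'
#' @param lo,hi tremor band in Hz.
#' @param min_window_s minimum analysable window in seconds.
#' @param welch a [welch_config()].
#' @param hand_params parameter names treated as the heterogeneous hand pair
#'   (z-scored before combination).
#' @param n_range N values for the joint-metric family.
#' @param denominator `"absolute"` or `"signed"` (see [variability_adjust()]).
#' @param zscore_hand whether to z-score the hand pair.
#' @param seed default RNG seed for simulation helpers.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(lo = 2, hi = 10, min_window_s = 1.5,
                            welch = welch_config(min_window_s = min_window_s),
                            hand_params = c("hand.disp", "hand.rot"),
                            n_range = 2:15,
                            denominator = c("absolute", "signed"),
                            zscore_hand = TRUE, seed = 1) {
  denominator <- match.arg(denominator)
  structure(list(lo = lo, hi = hi, min_window_s = min_window_s, welch = welch,
                 hand_params = hand_params, n_range = n_range,
                 denominator = denominator, zscore_hand = zscore_hand,
                 seed = seed),
            class = "pipeline_config")
}

# Infer channel kind from a channel name.
infer_channel_kind <- function(nm) {
  if (grepl("accel[._]?x$", nm)) return("acceleration_x")
  if (grepl("accel[._]?y$", nm)) return("acceleration_y")
  if (grepl("accel[._]?z$", nm)) return("acceleration_z")
  if (grepl("(gyro|rot)[._]?x$", nm)) return("angular_velocity_x")
  if (grepl("(gyro|rot)[._]?y$", nm)) return("angular_velocity_y")
  if (grepl("(gyro|rot)[._]?z$", nm)) return("angular_velocity_z")
  "joint_angle"
}

#' Read a recording from CSV
#'
#' Expects one column per channel (an optional `t` column in seconds is
#' dropped); channel kinds are inferred from the names: `*accel_x/y/z`
#' become accelerations, `*gyro_x/y/z` (or `rot_x/y/z`) angular velocities,
#' anything else a joint angle in degrees.
#'
#' @param path CSV file.
#' @param fs sampling rate in Hz (not stored in the CSV).
#' @param subject_id,day_id,instance_id identity labels.
#' @return a [movement_recording()].
#' @export
read_recording_csv <- function(path, fs, subject_id = "s1", day_id = "d1",
                               instance_id = 1L) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$t <- NULL
  kinds <- vapply(names(df), infer_channel_kind, character(1))
  movement_recording(as.list(df), fs, subject_id, day_id, instance_id, kinds)
}

#' Read window annotations from CSV
#'
#' Columns: `subject_id, day_id, instance_id, start_s, end_s, label`.
#'
#' @param path CSV file.
#' @return a [tibble::tibble()].
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subject_id = "character",
                                             day_id = "character"))
  need <- c("subject_id", "day_id", "instance_id", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$label)) df$label <- ""
  tibble::as_tibble(df)
}

#' Read cohort reference scores from CSV
#'
#' Columns: `subject_id, visit, ftmtrs_a, ftmtrs_b, ftmtrs_c` and optionally
#' `days_since_visit1`. Missing visit-2 rows are allowed.
#'
#' @param path CSV file.
#' @return a [tibble::tibble()].
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "",
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "visit", "ftmtrs_a", "ftmtrs_b", "ftmtrs_c")
  if (!all(need %in% names(df)))
    stop("score file must have columns: ", paste(need, collapse = ", "))
  tibble::as_tibble(df)
}

#' The packaged clinical cohort score table
#'
#' FTMTRS scores of the 24-person multiple-sclerosis tremor cohort on each
#' of two visits (subjects 2 and 15 did not return for a second visit):
#' the dominant-limb intention-tremor item (A), the dominant-hand
#' task-performance sum (B) and the self-assessed impact sum excluding
#' speaking (C), with days between visits.
#'
#' @return a [tibble::tibble()] with columns `subject_id`, `sex`, `age`,
#'   `visit`, `ftmtrs_a`, `ftmtrs_b`, `ftmtrs_c`, `days_since_visit1`.
#' @export
ftmtrs_cohort <- function() {
  path <- system.file("extdata", "ftmtrs_cohort.csv", package = "tremorprofile")
  df <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  tibble::as_tibble(df)
}

#' Write / read an amplitude table
#'
#' Long CSV with columns `subject_id, day_id, instance_id, parameter_id,
#' log_ata, n_reps_used, f_t_mean`. Nulls are written as empty fields
#' (never `"NA"` or 0 - zero is a legal amplitude).
#'
#' @param amplitudes the table.
#' @param path CSV file.
#' @return `read_amplitude_table` returns a [tibble::tibble()].
#' @export
write_amplitude_table <- function(amplitudes, path) {
  utils::write.csv(amplitudes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_amplitude_table
#' @export
read_amplitude_table <- function(path) {
  df <- utils::read.csv(path, na.strings = "",
                        colClasses = c(subject_id = "character",
                                       day_id = "character",
                                       parameter_id = "character"))
  tibble::as_tibble(df)
}

#' Write / read per-subject profiles as JSON
#'
#' Stores each subject's characteristic vector (parameter order, values,
#' valid-measurement counts, variant); nulls map to JSON null.
#'
#' @param profiles named list (subject id -> [characteristic_vector()]).
#' @param path JSON file.
#' @return `read_profiles_json` returns the named list back.
#' @export
write_profiles_json <- function(profiles, path) {
  obj <- lapply(profiles, function(cv)
    list(params = cv$params, values = cv$values, m = cv$m, variant = cv$variant))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(x) {
    structure(list(values = vapply(x$values, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)),
                   m = vapply(x$m, as.integer, integer(1)),
                   params = unlist(x$params), variant = x$variant),
              class = "characteristic_vector")
  })
}

#' Extract the amplitude table from recordings
#'
#' Runs the kinematic and spectral chain over every recording: annotated
#' repetition windows are sliced out; acceleration triads become hand
#' displacement in the dominant tremor axis (`<prefix>.disp`, mm), angular
#' velocity triads become hand rotation in the dominant axis
#' (`<prefix>.rot`), joint-angle channels are analysed as-is; per movement
#' parameter, the repetitions of an instance are reduced to one
#' representative log-ATA by [instance_amplitude()].
#'
#' @param recordings list of [movement_recording()] objects.
#' @param annotations tibble of repetition windows (see
#'   [read_annotations_csv()]).
#' @param config a [pipeline_config()].
#' @return list with `amplitudes` (long tibble: `subject_id`, `day_id`,
#'   `instance_id`, `parameter_id`, `log_ata`, `n_reps_used`, `f_t_mean`)
#'   and `log` (tibble of rejections/exclusions with machine-readable
#'   reasons).
#' @export
extract_amplitudes <- function(recordings, annotations,
                               config = pipeline_config()) {
  rows <- list()
  logs <- list()
  note <- function(stage, key, param, reason) {
    logs[[length(logs) + 1]] <<- tibble::tibble(
      stage = stage, subject_id = key$subject_id, day_id = key$day_id,
      instance_id = key$instance_id, parameter_id = param, reason = reason)
  }
  for (rec in recordings) {
    key <- list(subject_id = rec$subject_id, day_id = rec$day_id,
                instance_id = rec$instance_id)
    ann <- annotations[annotations$subject_id == rec$subject_id &
                         annotations$day_id == rec$day_id &
                         annotations$instance_id == rec$instance_id, ]
    if (nrow(ann) == 0) {
      note("windowing", key, NA_character_, "no annotated windows")
      next
    }
    wins <- extract_windows(rec, lapply(seq_len(nrow(ann)), function(i)
      analysis_window(ann$start_s[i], ann$end_s[i],
                      if (is.null(ann$label)) "" else ann$label[i])))
    # build the per-parameter repetition segments
    kinds <- rec$kinds
    triad <- function(kind_prefix) {
      nm <- names(kinds)[startsWith(kinds, kind_prefix)]
      split(nm, sub("[._]?(accel|gyro|rot)[._]?[xyz]$", "", nm))
    }
    segs <- list()   # parameter_id -> list of repetition series
    for (ch in names(kinds)[kinds == "joint_angle"])
      segs[[ch]] <- lapply(wins, function(w) w$channels[[ch]])
    for (grp in names(tri <- triad("acceleration"))) {
      chs <- tri[[grp]]
      if (length(chs) != 3) next
      pid <- paste0(grp, ".disp")
      segs[[pid]] <- lapply(wins, function(w) {
        a3 <- do.call(rbind, w$channels[chs])
        disp <- try(accel_to_displacement(a3, rec$fs, config$lo, config$hi),
                    silent = TRUE)
        if (inherits(disp, "try-error")) return(numeric(0))
        pr <- try(dominant_axis(disp, rec$fs, config$lo, config$hi), silent = TRUE)
        if (inherits(pr, "try-error")) numeric(0) else pr$series
      })
    }
    for (grp in names(tri <- triad("angular_velocity"))) {
      chs <- tri[[grp]]
      if (length(chs) != 3) next
      pid <- paste0(grp, ".rot")
      segs[[pid]] <- lapply(wins, function(w) {
        g3 <- do.call(rbind, w$channels[chs])
        pr <- try(dominant_axis(g3, rec$fs, config$lo, config$hi), silent = TRUE)
        if (inherits(pr, "try-error")) numeric(0) else pr$series
      })
    }
    for (pid in names(segs)) {
      est <- instance_amplitude(segs[[pid]], rec$fs, config$welch, pid,
                                config$lo, config$hi)
      for (k in seq_along(est$rejection_reports)) {
        rr <- est$rejection_reports[[k]]
        if (!is.null(rr) && !rr$accepted)
          note("rejection", key, pid,
               paste0("rep", k, ":", paste(rr$reasons, collapse = "+")))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = key$subject_id, day_id = key$day_id,
        instance_id = key$instance_id, parameter_id = pid,
        log_ata = est$log_ata, n_reps_used = est$n_reps_used,
        f_t_mean = est$f_t_mean)
    }
  }
  list(amplitudes = dplyr::bind_rows(rows), log = dplyr::bind_rows(logs))
}

#' Per-subject change table
#'
#' Computes, for every subject with two days of two instances each, the
#' variability-adjusted change metrics: the joint-movement family (mean,
#' scale, scale2, profile at each N in `n_range`) and, when hand parameters
#' are present, the univariate hand changes and the combined-hand scale and
#' profile on the z-scored pair.
#'
#' @param amplitudes long amplitude table (`log_ata` or `value` column).
#' @param config a [pipeline_config()].
#' @return list with `changes` (tibble: `subject_id`, `day_p`, `day_q`,
#'   `metric_id`, `variant`, `n_joints`, `d_raw_1`, `d_raw_2`, `denom`,
#'   `d_adj`) and `log` (exclusions).
#' @export
compute_changes <- function(amplitudes, config = pipeline_config()) {
  params <- unique(amplitudes$parameter_id)
  joint_params <- setdiff(params, config$hand_params)
  hand_params <- intersect(config$hand_params, params)
  n_range <- config$n_range[config$n_range <= length(joint_params) &
                              config$n_range >= 1]
  structs <- amplitude_structures(amplitudes, params)
  rows <- list(); logs <- list()
  metric_fn <- list(mean = function(aA, aB, ac) mean_difference(aA, aB),
                    scale = scale_change, scale2 = scale2_change,
                    profile = profile_change)
  for (sid in names(structs)) {
    subj <- structs[[sid]]
    days <- names(subj)
    if (length(days) < 2 || length(subj[[1]]) < 2 || length(subj[[2]]) < 2) {
      logs[[length(logs) + 1]] <- tibble::tibble(
        stage = "change", subject_id = sid, day_id = NA_character_,
        instance_id = NA_integer_, parameter_id = NA_character_,
        reason = "fewer than two days with two instances")
      next
    }
    p2 <- lapply(subj[[1]][1:2], identity)
    q2 <- lapply(subj[[2]][1:2], identity)
    emit <- function(metric_id, variant, N, ps, a_c) {
      fn <- metric_fn[[metric_id]]
      sl <- function(v) v[ps]
      d1 <- fn(sl(p2[[1]]), sl(q2[[1]]), a_c)
      d2 <- fn(sl(p2[[2]]), sl(q2[[2]]), a_c)
      va <- variability_adjust(lapply(p2, sl), lapply(q2, sl), a_c,
                               metric_id, config$denominator)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        subject_id = sid, day_p = days[1], day_q = days[2],
        metric_id = metric_id, variant = variant, n_joints = N,
        d_raw_1 = as.numeric(d1), d_raw_2 = as.numeric(d2),
        denom = va$denominator, d_adj = va$d_adj)
      if (!is.na(va$reason))
        logs[[length(logs) + 1]] <<- tibble::tibble(
          stage = "change", subject_id = sid, day_id = NA_character_,
          instance_id = NA_integer_, parameter_id = metric_id,
          reason = va$reason)
    }
    if (length(joint_params) >= 2) {
      mat <- subject_matrix(subj, params)[, joint_params, drop = FALSE]
      a_c_full <- characteristic_vector(mat)
      for (N in n_range) {
        ps <- joint_params[select_top_n(a_c_full, N)$indices]
        red <- characteristic_vector(mat[, ps, drop = FALSE])
        for (m in names(metric_fn))
          emit(m, if (m == "scale2") "squared" else "plain", N, ps, red)
      }
    }
    for (hp in hand_params) emit("mean", "plain", NA_integer_, hp, NULL)
    if (length(hand_params) == 2) {
      hmat <- subject_matrix(subj, hand_params)
      z <- try(zscore_normalize(hmat), silent = TRUE)
      if (!inherits(z, "try-error")) {
        a_ch <- characteristic_vector(z$values)
        st <- z$stats
        zs <- function(v) (v[hand_params] - st$mu) / st$sigma
        p2z <- lapply(p2, zs); q2z <- lapply(q2, zs)
        for (m in c("scale", "profile")) {
          d1 <- metric_fn[[m]](p2z[[1]], q2z[[1]], a_ch)
          d2 <- metric_fn[[m]](p2z[[2]], q2z[[2]], a_ch)
          va <- variability_adjust(p2z, q2z, a_ch, m, config$denominator)
          rows[[length(rows) + 1]] <- tibble::tibble(
            subject_id = sid, day_p = days[1], day_q = days[2],
            metric_id = paste0("hand_", m), variant = "plain",
            n_joints = NA_integer_, d_raw_1 = as.numeric(d1),
            d_raw_2 = as.numeric(d2), denom = va$denominator, d_adj = va$d_adj)
        }
      }
    }
  }
  list(changes = dplyr::bind_rows(rows), log = dplyr::bind_rows(logs))
}

#' Run the full pipeline
#'
#' Orchestrates extract -> profile -> change -> evaluate: amplitude
#' extraction from annotated recordings, per-subject characteristic
#' vectors, the variability-adjusted change table, and (when scores are
#' supplied) the Spearman/FDR evaluation against reference-score changes.
#' Deterministic given fixed inputs; every dropped or rejected item appears
#' in the returned log with a reason code. Per-subject failures do not
#' abort the run.
#'
#' @param recordings list of [movement_recording()] objects.
#' @param annotations window annotation tibble.
#' @param scores optional cohort score tibble.
#' @param config a [pipeline_config()].
#' @return list with `amplitudes`, `profiles` (named list of
#'   [characteristic_vector()]), `changes`, `evaluation` (`NULL` without
#'   scores) and `log`.
#' @export
run_pipeline <- function(recordings, annotations, scores = NULL,
                         config = pipeline_config()) {
  ex <- extract_amplitudes(recordings, annotations, config)
  amplitudes <- ex$amplitudes
  params <- unique(amplitudes$parameter_id)
  joint_params <- setdiff(params, config$hand_params)
  structs <- amplitude_structures(amplitudes, params)
  profiles <- lapply(structs, function(subj)
    characteristic_vector(subject_matrix(subj, params)[, joint_params, drop = FALSE]))
  ch <- compute_changes(amplitudes, config)
  evaluation <- NULL
  if (!is.null(scores))
    evaluation <- evaluate_metric_family(amplitudes, scores,
                                         hand_params = config$hand_params,
                                         n_range = config$n_range,
                                         denominator = config$denominator)
  list(amplitudes = amplitudes, profiles = profiles, changes = ch$changes,
       evaluation = evaluation, log = dplyr::bind_rows(ex$log, ch$log))
}
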