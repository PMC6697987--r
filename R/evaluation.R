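#' Squared Spearman rank correlation
#'
#' Tie-corrected Spearman correlation of two paired series with its
#' two-sided asymptotic p-value (t approximation). Pairs containing any null
#' are dropped; fewer than three complete pairs yields a null result.
#' Rank correlation avoids undue influence of outliers and any assumption
#' about the data distribution; the squared coefficient is reported as the
#' explained rank variance, with the sign retained separately.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `rho2`, `p`, `n` (complete pairs used). `rho`,
#'   `rho2`, `p` are `NA` when `n < 3`.
#' @export
spearman_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, rho2 = NA_real_, p = NA_real_, n = n))
  # identical (or exactly reversed) rankings are exact, not approximate
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (all(rx == ry))
    return(list(rho = 1, rho2 = 1, p = 0, n = n))
  if (all(rx == n + 1 - ry))
    return(list(rho = -1, rho2 = 1, p = 0, n = n))
  ct <- tryCatch(
    suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                     exact = FALSE)),
    error = function(e) NULL)   # constant series and similar degeneracies
  if (is.null(ct) || is.na(ct$estimate))
    return(list(rho = NA_real_, rho2 = NA_real_, p = NA_real_, n = n))
  rho <- unname(ct$estimate)
  list(rho = rho, rho2 = rho^2, p = ct$p.value, n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment of a family of p-values:
#' monotone in the sorted order and capped at 1. The adjusted value, pFDR,
#' is used as a conservative replacement for the p-value when a family of
#' related metric variants is screened.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in the original order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Paired t-test with degenerate-input handling
#'
#' Two-sided Student's paired t-test of `after` versus `before`. Incomplete
#' pairs are dropped. If every paired difference is exactly zero the test is
#' degenerate; a "no change" sentinel (`t = 0`, `p = 1`) is returned rather
#' than an error, since clinical score columns are frequently near-constant.
#' Nonzero constant differences (zero variance, nonzero mean) are an error.
#'
#' @param before,after numeric vectors of equal length.
#' @return list with `t`, `p`, `df`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(before, after) {
  ok <- stats::complete.cases(before, after)
  d <- after[ok] - before[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  if (all(d == 0))
    return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, n = n))
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences")
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), n = n)
}

#' Effect of scale discretisation on absolute correlations
#'
#' Numerical experiment: draw `n` values from a continuous uniform
#' distribution, copy them, round the copy to a given number of equally
#' spaced levels spanning the range, and report the squared Spearman
#' correlation between original and rounded series per level count. With
#' two levels the squared correlation drops to about 0.75; it rises
#' monotonically towards 1 as the scale gets finer, and `levels = Inf`
#' (no rounding) gives exactly 1.
#'
#' @param n sample count.
#' @param levels integer vector of level counts (each `>= 2`); `Inf` means
#'   no rounding.
#' @param seed RNG seed.
#' @return [tibble::tibble()] with `levels` and `rho2`.
#' @export
discretization_experiment_abs <- function(n = 100000,
                                          levels = c(2, 3, 4, 5, 10, 20, 50, 100),
                                          seed = 1) {
  stopifnot(n >= 1000, all(levels >= 2))
  set.seed(seed)
  x <- stats::runif(n)
  rho2 <- vapply(levels, function(L) {
    y <- if (is.infinite(L)) x else round(x * (L - 1)) / (L - 1)
    spearman_r2(x, y)$rho2
  }, numeric(1))
  tibble::tibble(levels = levels, rho2 = rho2)
}

#' Effect of scale discretisation on change correlations
#'
#' Numerical experiment on a bounded 0-4 integer scale: continuous values
#' `x` (uniform on 0-4) are copied to `y`; zero-mean Gaussian changes of
#' standard deviation `sigma` are added to both; `y` is rounded to integers
#' before and after the change; the squared Spearman correlation between
#' the continuous change and the discretised change is reported per
#' `sigma`. Changes much larger than the scale interval (1) correlate near
#' 1; changes smaller than the interval are largely invisible to the coarse
#' scale. With `clip_bounds = TRUE` the rounded values are additionally
#' clipped to the 0-4 range, mimicking a saturating clinical scale (which
#' also caps the achievable correlation at large `sigma`).
#'
#' @param sigmas positive standard deviations of the change distribution.
#' @param n sample count.
#' @param seed RNG seed.
#' @param clip_bounds clip shifted values to the scale range before
#'   rounding (default `FALSE`).
#' @return [tibble::tibble()] with `sigma` and `rho2` (`NA` if the change is
#'   degenerate, i.e. zero variance).
#' @export
discretization_experiment_change <- function(sigmas = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                                             n = 100000, seed = 1,
                                             clip_bounds = FALSE) {
  stopifnot(all(sigmas >= 0))   # sigma = 0 yields the degenerate NA result
  set.seed(seed)
  x <- stats::runif(n, 0, 4)
  clip <- if (clip_bounds) function(v) pmin(pmax(v, 0), 4) else identity
  rho2 <- vapply(sigmas, function(s) {
    dx <- stats::rnorm(n, 0, s)
    dy <- round(clip(x + dx)) - round(clip(x))
    if (stats::sd(dx) == 0 || stats::sd(dy) == 0) return(NA_real_)
    spearman_r2(dx, dy)$rho2
  }, numeric(1))
  tibble::tibble(sigma = sigmas, rho2 = rho2)
}

# Reshape a long amplitude table into per-subject measurement structures:
# list(subject -> list(days -> list(instance matrices rows))). Parameter
# order (the canonical order) is fixed across the analysis.
amplitude_structures <- function(amplitudes, params) {
  stopifnot(all(c("subject_id", "day_id", "instance_id", "parameter_id") %in%
                  names(amplitudes)))
  value_col <- if ("log_ata" %in% names(amplitudes)) "log_ata" else "value"
  out <- list()
  for (sid in unique(amplitudes$subject_id)) {
    da <- amplitudes[amplitudes$subject_id == sid, ]
    days <- sort(unique(da$day_id))
    subj <- list()
    for (d in days) {
      dd <- da[da$day_id == d, ]
      inst <- sort(unique(dd$instance_id))
      vecs <- lapply(inst, function(i) {
        di <- dd[dd$instance_id == i, ]
        v <- stats::setNames(rep(NA_real_, length(params)), params)
        hit <- match(di$parameter_id, params)
        v[hit[!is.na(hit)]] <- di[[value_col]][!is.na(hit)]
        v
      })
      names(vecs) <- as.character(inst)
      subj[[as.character(d)]] <- vecs
    }
    out[[as.character(sid)]] <- subj
  }
  out
}

# All measurement vectors of one subject as a matrix (rows = instances).
subject_matrix <- function(subj_struct, params) {
  rows <- unlist(subj_struct, recursive = FALSE)
  do.call(rbind, lapply(rows, function(v) v[params]))
}

#' Evaluate metric families against reference-score changes
#'
#' The full statistical harness: builds per-subject measurement vectors from
#' a long amplitude table, forms characteristic vectors, computes
#' variability-adjusted change metrics between the first two days (two
#' instances each), and correlates them (Spearman) with the change in each
#' reference clinical score. Joint-movement metrics are evaluated across a
#' range of `N` (the number of most-tremulous joints retained) and
#' Benjamini-Hochberg adjusted within each (metric, reference) family.
#' Hand metrics (univariate differences, plus scale/profile on the z-scored
#' displacement+rotation pair) and the maximum-amplitude joint are evaluated
#' individually and are not BH-adjusted. Absolute (single-visit)
#' correlations of the summary amplitude against raw scores are also
#' reported. Metrics with fewer than three contributing subjects are
#' omitted.
#'
#' @param amplitudes long table with columns `subject_id`, `day_id`,
#'   `instance_id`, `parameter_id`, `log_ata` (or `value`); `NA` = null.
#' @param scores table with columns `subject_id`, `visit` (1, 2) and the
#'   reference columns.
#' @param hand_params character vector naming the (heterogeneous) hand
#'   parameters; all other parameters are treated as joint rotations.
#' @param n_range integers: the `N` values for the joint-metric family.
#' @param references score columns to correlate against.
#' @param denominator passed to [variability_adjust()].
#' @return [tibble::tibble()] with `metric_id`, `type` (`"change"` or
#'   `"absolute"`), `reference`, `n_joints`, `rho`, `rho2`, `p`, `p_fdr`
#'   (`NA` where no family adjustment applies) and `n_points`.
#' @export
evaluate_metric_family <- function(amplitudes, scores,
                                   hand_params = c("hand.disp", "hand.rot"),
                                   n_range = 2:15,
                                   references = c("ftmtrs_b", "ftmtrs_c"),
                                   denominator = "absolute") {
  params <- unique(amplitudes$parameter_id)
  joint_params <- setdiff(params, hand_params)
  hand_params <- intersect(hand_params, params)
  n_range <- n_range[n_range >= 1 & n_range <= max(1, length(joint_params))]
  structs <- amplitude_structures(amplitudes, params)
  subjects <- names(structs)

  # per-subject z-score stats for the heterogeneous hand pair, over the cohort
  hand_stats <- NULL
  if (length(hand_params) == 2) {
    allmat <- do.call(rbind, lapply(subjects, function(s)
      subject_matrix(structs[[s]], hand_params)))
    hand_stats <- try(zscore_normalize(allmat)$stats, silent = TRUE)
    if (inherits(hand_stats, "try-error")) hand_stats <- NULL
  }

  adj <- function(subj, ps, metric, a_c, zstats = NULL) {
    days <- names(subj)
    if (length(days) < 2) return(NA_real_)
    get2 <- function(d) {
      vs <- subj[[d]]
      if (length(vs) < 2) return(NULL)
      lapply(vs[1:2], function(v) {
        v <- v[ps]
        if (!is.null(zstats)) {
          st <- zstats[match(ps, zstats$parameter), ]
          v <- (v - st$mu) / st$sigma
        }
        v
      })
    }
    p2 <- get2(days[1]); q2 <- get2(days[2])
    if (is.null(p2) || is.null(q2)) return(NA_real_)
    variability_adjust(p2, q2, a_c, metric, denominator)$d_adj
  }

  rows <- list()
  add <- function(metric_id, type, reference, n_joints, vals, dscore, family = NA) {
    r <- spearman_r2(vals, dscore)
    if (r$n < 3 || is.na(r$rho)) return(invisible(NULL))   # degenerate/constant
    rows[[length(rows) + 1]] <<- tibble::tibble(
      metric_id = metric_id, type = type, reference = reference,
      n_joints = n_joints, rho = r$rho, rho2 = r$rho2, p = r$p,
      p_fdr = NA_real_, family = family, n_points = r$n)
    invisible(NULL)
  }

  # score changes per subject
  sc <- scores
  dscore <- function(ref) {
    vapply(subjects, function(s) {
      v1 <- sc[[ref]][sc$subject_id == s & sc$visit == 1]
      v2 <- sc[[ref]][sc$subject_id == s & sc$visit == 2]
      if (length(v1) == 1 && length(v2) == 1) v2 - v1 else NA_real_
    }, numeric(1))
  }
  absscore <- function(ref, visit) {
    vapply(subjects, function(s) {
      v <- sc[[ref]][sc$subject_id == s & sc$visit == visit]
      if (length(v) == 1) v else NA_real_
    }, numeric(1))
  }

  # precompute per-subject characteristic vectors
  cv_joint <- lapply(subjects, function(s) {
    mat <- subject_matrix(structs[[s]], params)[, joint_params, drop = FALSE]
    characteristic_vector(mat)
  })
  names(cv_joint) <- subjects

  for (ref in references) {
    ds <- dscore(ref)

    # univariate hand metrics
    for (hp in hand_params) {
      vals <- vapply(subjects, function(s)
        adj(structs[[s]], hp, "mean", NULL), numeric(1))
      add(paste0(hp, "_change"), "change", ref, NA_integer_, vals, ds)
    }

    # combined hand scale/profile on z-scored pair
    if (length(hand_params) == 2 && !is.null(hand_stats)) {
      for (metric in c("scale", "profile")) {
        vals <- vapply(subjects, function(s) {
          mat <- subject_matrix(structs[[s]], hand_params)
          zm <- sweep(sweep(mat, 2, hand_stats$mu, "-"), 2, hand_stats$sigma, "/")
          a_c <- characteristic_vector(zm)
          adj(structs[[s]], hand_params, metric, a_c, hand_stats)
        }, numeric(1))
        add(paste0("hand_", metric), "change", ref, NA_integer_, vals, ds)
      }
    }

    # maximum-amplitude joint (univariate)
    if (length(joint_params) >= 1) {
      vals <- vapply(subjects, function(s) {
        a_c <- cv_joint[[s]]
        if (all(is.na(a_c$values))) return(NA_real_)
        top <- select_top_n(a_c, 1)
        adj(structs[[s]], joint_params[top$indices], "mean", NULL)
      }, numeric(1))
      add("joint_max", "change", ref, 1L, vals, ds)
    }

    # joint family over N
    if (length(joint_params) >= 2) {
      for (metric in c("mean", "scale", "scale2", "profile")) {
        fam <- paste("joint", metric, ref, sep = "_")
        for (N in n_range) {
          vals <- vapply(subjects, function(s) {
            a_c <- cv_joint[[s]]
            if (all(is.na(a_c$values))) return(NA_real_)
            top <- select_top_n(a_c, N)
            ps <- joint_params[top$indices]
            red <- characteristic_vector(
              subject_matrix(structs[[s]], params)[, ps, drop = FALSE])
            adj(structs[[s]], ps, metric, red)
          }, numeric(1))
          add(paste0("joint_", metric), "change", ref, as.integer(N), vals, ds, fam)
        }
      }
    }

    # absolute (single-visit) correlations from summary amplitudes
    for (visit_idx in 1:1) {
      mean_amp <- vapply(subjects, function(s) {
        subj <- structs[[s]]
        if (length(subj) < visit_idx) return(NA_real_)
        vs <- subj[[visit_idx]]
        vals <- vapply(vs, function(v) mean_amplitude(v[joint_params])$a_bar,
                       numeric(1))
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      }, numeric(1))
      add("joint_mean_amplitude", "absolute", ref, NA_integer_,
          mean_amp, absscore(ref, visit_idx))
      for (hp in hand_params) {
        amp <- vapply(subjects, function(s) {
          subj <- structs[[s]]
          if (length(subj) < visit_idx) return(NA_real_)
          vals <- vapply(subj[[visit_idx]], function(v) v[[hp]], numeric(1))
          if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
        }, numeric(1))
        add(paste0(hp, "_amplitude"), "absolute", ref, NA_integer_,
            amp, absscore(ref, visit_idx))
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  # BH adjustment within each joint-metric N-family
  for (f in unique(stats::na.omit(out$family))) {
    sel <- which(!is.na(out$family) & out$family == f)
    out$p_fdr[sel] <- bh_fdr(out$p[sel])
  }
  dplyr::select(out, -"family")
}
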