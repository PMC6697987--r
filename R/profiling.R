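#' Z-score normalisation of measurement vectors
#'
#' Converts heterogeneous movement parameters (e.g. hand displacement in mm
#' and hand rotation in deg/s) to comparable z-scores: each non-null value is
#' centred on the cohort mean of its parameter and divided by the cohort
#' standard deviation (sample convention, divide by n - 1). Nulls (`NA`)
#' propagate unchanged. Homogeneous parameter sets (all joint angles) should
#' not be normalised, as that would inflate joints with negligible tremor.
#'
#' @param values numeric matrix, rows = measurements, columns = parameters
#'   (`NA` = null).
#' @param stats optional data frame with columns `parameter`, `mu`, `sigma`
#'   to apply externally supplied statistics; when omitted they are estimated
#'   from `values` (requiring at least two non-null entries per parameter).
#' @return list with `values` (normalised matrix) and `stats` (the data
#'   frame used).
#' @export
zscore_normalize <- function(values, stats = NULL) {
  values <- as.matrix(values)
  params <- colnames(values)
  if (is.null(params)) params <- paste0("p", seq_len(ncol(values)))
  if (is.null(stats)) {
    mu <- sig <- numeric(ncol(values))
    for (j in seq_len(ncol(values))) {
      v <- values[, j][!is.na(values[, j])]
      if (length(v) < 2)
        stop("parameter '", params[j], "': need at least 2 non-null values to estimate z-score statistics")
      mu[j] <- mean(v)
      sig[j] <- stats::sd(v)
    }
    stats <- data.frame(parameter = params, mu = mu, sigma = sig)
  } else {
    stats <- stats[match(params, stats$parameter), ]
    if (anyNA(stats$parameter)) stop("supplied stats do not cover all parameters")
  }
  if (any(stats$sigma == 0))
    stop("parameter '", stats$parameter[which(stats$sigma == 0)[1]],
         "': zero standard deviation, cannot z-score")
  out <- sweep(sweep(values, 2, stats$mu, "-"), 2, stats$sigma, "/")
  list(values = out, stats = stats)
}

#' Characteristic vector of a subject
#'
#' The personalised tremor profile: for each movement parameter, the mean of
#' the subject's valid (non-null) measurement-vector entries across all
#' available task executions. Parameters with no valid measurement stay null.
#'
#' @param values numeric matrix (rows = the subject's measurement vectors,
#'   columns = parameters, `NA` = null) or a single numeric vector.
#' @param variant `"plain"` or `"squared"` (see [square_tune()]).
#' @return list of class `characteristic_vector` with `values`, `m` (count
#'   of valid contributing measurements per parameter), `params`, `variant`.
#' @export
characteristic_vector <- function(values, variant = "plain") {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1,
                                             dimnames = list(NULL, names(values)))
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1)
  params <- colnames(values)
  if (is.null(params)) params <- paste0("p", seq_len(ncol(values)))
  m <- colSums(!is.na(values))
  v <- ifelse(m > 0, colMeans(values, na.rm = TRUE), NA_real_)
  structure(list(values = unname(v), m = unname(m), params = params,
                 variant = variant),
            class = "characteristic_vector")
}

#' @export
print.characteristic_vector <- function(x, ...) {
  cat(sprintf("<characteristic_vector> (%s) over %d parameters\n",
              x$variant, length(x$values)))
  print(stats::setNames(round(x$values, 4), x$params))
  invisible(x)
}

#' Square-tuned characteristic vector
#'
#' Exaggerates the influence of the most tremulous parameters by squaring
#' each element of the characteristic vector (before renormalisation in the
#' change metrics). Nulls are preserved. This is the profile used by the
#' scale2 change metric.
#'
#' @param a_c a plain-variant [characteristic_vector()].
#' @return a `characteristic_vector` with `variant = "squared"`.
#' @export
square_tune <- function(a_c) {
  stopifnot(inherits(a_c, "characteristic_vector"), a_c$variant == "plain")
  a_c$values <- a_c$values^2
  a_c$variant <- "squared"
  a_c
}

# Joint null exclusion: indices where aA, aB and ac are all non-null.
cv_values <- function(a_c) if (inherits(a_c, "characteristic_vector")) a_c$values else as.numeric(a_c)

common_support <- function(aA, aB, ac) {
  which(!is.na(aA) & !is.na(aB) & !is.na(ac))
}

#' Scale change between two measurements
#'
#' The component of the measurement difference parallel to the subject's
#' characteristic vector: `d_S = (aB - aA) . unit(a_c)`. Positive values
#' indicate a scaling-up of the subject's typical tremor blend. Parameters
#' null in any of the three vectors are excluded from all three before the
#' characteristic vector is renormalised to unit length.
#'
#' @param aA,aB measurement vectors (numeric, `NA` = null).
#' @param a_c the characteristic vector ([characteristic_vector()] or
#'   numeric).
#' @return signed scalar; `NA` with attribute `reason` when no common
#'   non-null parameters remain or the reduced characteristic vector has
#'   zero norm.
#' @export
scale_change <- function(aA, aB, a_c) {
  ac <- cv_values(a_c)
  idx <- common_support(aA, aB, ac)
  if (length(idx) == 0)
    return(structure(NA_real_, reason = "no common non-null parameters"))
  nrm <- sqrt(sum(ac[idx]^2))
  if (nrm == 0)
    return(structure(NA_real_, reason = "characteristic vector has zero norm on common support"))
  sum((aB[idx] - aA[idx]) * ac[idx] / nrm)
}

#' Scale2 change between two measurements
#'
#' The scale change computed against the element-wise squared (then
#' renormalised) characteristic vector, weighting the most tremulous
#' parameters more heavily.
#'
#' @inheritParams scale_change
#' @param a_c the *plain* characteristic vector; squaring happens internally
#'   (a pre-squared `characteristic_vector` with `variant = "squared"` is
#'   used as-is).
#' @return signed scalar or `NA` with `reason`.
#' @export
scale2_change <- function(aA, aB, a_c) {
  if (inherits(a_c, "characteristic_vector") && a_c$variant == "squared") {
    ac2 <- a_c
  } else if (inherits(a_c, "characteristic_vector")) {
    ac2 <- square_tune(a_c)
  } else {
    ac2 <- as.numeric(a_c)^2
  }
  scale_change(aA, aB, ac2)
}

#' Profile change between two measurements
#'
#' The magnitude of the measurement-difference component perpendicular to
#' the characteristic vector: the part of the change that alters the
#' subject's tremor blend rather than its overall scale. Always
#' non-negative, hence direction-free. Computed as the norm of the
#' orthogonal rejection, which coincides with the cross-product magnitude in
#' two or three dimensions and generalises it to any dimension.
#'
#' @inheritParams scale_change
#' @return scalar `>= 0`, or `NA` with `reason`.
#' @export
profile_change <- function(aA, aB, a_c) {
  ac <- cv_values(a_c)
  idx <- common_support(aA, aB, ac)
  if (length(idx) == 0)
    return(structure(NA_real_, reason = "no common non-null parameters"))
  nrm <- sqrt(sum(ac[idx]^2))
  if (nrm == 0)
    return(structure(NA_real_, reason = "characteristic vector has zero norm on common support"))
  u <- ac[idx] / nrm
  d <- aB[idx] - aA[idx]
  sqrt(max(0, sum(d^2) - sum(d * u)^2))
}

#' Mean difference between two measurement vectors
#'
#' The mean, over the parameters non-null in both measurements, of the
#' element-wise difference `aB - aA`. The conventional multivariate change
#' metric the personalised metrics are compared against.
#'
#' @param aA,aB measurement vectors (numeric, `NA` = null).
#' @return scalar, or `NA` with `reason` when no parameter is non-null in
#'   both.
#' @export
mean_difference <- function(aA, aB) {
  idx <- which(!is.na(aA) & !is.na(aB))
  if (length(idx) == 0)
    return(structure(NA_real_, reason = "no common non-null parameters"))
  mean(aB[idx] - aA[idx])
}

#' Summary amplitude of one measurement vector
#'
#' The mean of the non-null components: a single severity value for
#' comparing one multivariate measurement against a clinical score.
#'
#' @param a_i measurement vector (numeric, `NA` = null).
#' @return list with `a_bar` (`NA` if all components null) and `n` (count of
#'   non-null components).
#' @export
mean_amplitude <- function(a_i) {
  idx <- which(!is.na(a_i))
  list(a_bar = if (length(idx)) mean(a_i[idx]) else NA_real_, n = length(idx))
}

#' All four change metrics for one measurement pair
#'
#' @inheritParams scale_change
#' @return a [tibble::tibble()] with `d_s`, `d_s2`, `d_p`, `d_m` and
#'   `n_common`.
#' @export
change_metrics <- function(aA, aB, a_c) {
  ac <- cv_values(a_c)
  tibble::tibble(d_s = as.numeric(scale_change(aA, aB, a_c)),
                 d_s2 = as.numeric(scale2_change(aA, aB, a_c)),
                 d_p = as.numeric(profile_change(aA, aB, a_c)),
                 d_m = as.numeric(mean_difference(aA, aB)),
                 n_common = length(common_support(aA, aB, ac)))
}

#' Select the N most tremulous parameters
#'
#' Ranks parameters by their characteristic-vector values in descending
#' order (nulls ranked last; ties broken by the canonical parameter order)
#' and retains the first `N`. The full ranking is returned for joint-rank
#' histograms.
#'
#' @param a_c a [characteristic_vector()] (or numeric vector).
#' @param N number of parameters to keep, `1 <= N <= length(a_c)`.
#' @return list with `indices` (the selected column indices), `params`
#'   (their names, when available) and `ranking` (full permutation, best
#'   first).
#' @export
select_top_n <- function(a_c, N) {
  v <- cv_values(a_c)
  params <- if (inherits(a_c, "characteristic_vector")) a_c$params else names(v)
  stopifnot(N >= 1, N <= length(v))
  key <- ifelse(is.na(v), -Inf, v)
  ranking <- order(-key, seq_along(v))   # stable: canonical order breaks ties
  idx <- ranking[seq_len(N)]
  list(indices = idx,
       params = if (!is.null(params)) params[idx] else NULL,
       ranking = ranking)
}

#' Variability-adjusted change between two days
#'
#' Controls a change metric for the subject's intrinsic short-term
#' variability: the average between-day metric (first instances compared
#' across days, and second instances compared across days) is divided by the
#' average magnitude of the same-day metric (the two instances of each day
#' compared). Values near or below 1 indicate change indistinguishable from
#' the subject's own within-visit variability.
#'
#' With `denominator = "absolute"` (default) the same-day differences enter
#' as magnitudes, so signed metrics cannot cancel in the denominator while
#' the numerator keeps its sign; `"signed"` uses the raw same-day values.
#'
#' @param day_p,day_q lists of two measurement vectors each (the first and
#'   second recordings of days p and q).
#' @param a_c the subject's characteristic vector (ignored by the mean
#'   metric).
#' @param metric one of `"scale"`, `"scale2"`, `"profile"`, `"mean"`, or a
#'   function `f(aA, aB, a_c)`.
#' @param denominator `"absolute"` or `"signed"`.
#' @return list with `numerator`, `denominator`, `d_adj` (`NA` with `reason`
#'   when an instance is missing, a component metric is null, or the
#'   denominator is zero), and `metric`.
#' @export
variability_adjust <- function(day_p, day_q, a_c = NULL,
                               metric = c("scale", "scale2", "profile", "mean"),
                               denominator = c("absolute", "signed")) {
  denominator <- match.arg(denominator)
  if (is.character(metric)) {
    metric_id <- match.arg(metric)
    fn <- switch(metric_id,
                 scale   = function(aA, aB, ac) scale_change(aA, aB, ac),
                 scale2  = function(aA, aB, ac) scale2_change(aA, aB, ac),
                 profile = function(aA, aB, ac) profile_change(aA, aB, ac),
                 mean    = function(aA, aB, ac) mean_difference(aA, aB))
  } else {
    metric_id <- "custom"
    fn <- metric
  }
  bad <- function(reason) list(numerator = NA_real_, denominator = NA_real_,
                               d_adj = NA_real_, reason = reason, metric = metric_id)
  if (length(day_p) < 2 || length(day_q) < 2 ||
      any(vapply(c(day_p[1:2], day_q[1:2]), is.null, logical(1))))
    return(bad("a day lacks two instances"))
  cross <- c(fn(day_p[[1]], day_q[[1]], a_c), fn(day_p[[2]], day_q[[2]], a_c))
  same <- c(fn(day_p[[1]], day_p[[2]], a_c), fn(day_q[[1]], day_q[[2]], a_c))
  if (anyNA(cross) || anyNA(same)) return(bad("null component metric"))
  den <- if (denominator == "absolute") mean(abs(same)) else mean(same)
  if (den == 0) return(bad("zero same-day variability"))
  list(numerator = mean(cross), denominator = den,
       d_adj = mean(cross) / den, reason = NA_character_, metric = metric_id)
}
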