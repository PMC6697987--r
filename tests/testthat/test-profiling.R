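test_that("z-score normalisation uses population SD and propagates nulls", {
  m <- matrix(c(1, 3, 2, NA), ncol = 2, dimnames = list(NULL, c("a", "b")))
  z <- zscore_normalize(m[, 1, drop = FALSE])
  expect_equal(as.numeric(z$values), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  ident <- zscore_normalize(m, stats = data.frame(parameter = c("a", "b"),
                                                  mu = 0, sigma = 1))
  expect_equal(ident$values, m)
  expect_true(is.na(ident$values[2, "b"]))

  const <- matrix(c(1, 1, 1), ncol = 1, dimnames = list(NULL, "flat"))
  expect_error(zscore_normalize(const), "flat")
  expect_error(zscore_normalize(matrix(c(1, NA), ncol = 1)), "at least 2")
})

test_that("characteristic vectors average valid measurements per parameter", {
  one <- characteristic_vector(c(1, 2))
  expect_equal(one$values, c(1, 2))
  expect_equal(one$m, c(1, 1))

  two <- characteristic_vector(rbind(c(1, 2), c(3, 4)))
  expect_equal(two$values, c(2, 3))

  holey <- characteristic_vector(rbind(c(1, NA), c(3, 4)))
  expect_equal(holey$values, c(2, 4))
  expect_equal(holey$m, c(2, 1))

  allna <- characteristic_vector(rbind(c(1, NA), c(2, NA)))
  expect_true(is.na(allna$values[2]))
  expect_equal(allna$m, c(2, 0))
})

test_that("square tuning squares elements and preserves nulls", {
  cv <- characteristic_vector(rbind(c(3, 4, 0, 1), c(3, 4, 0, NA)))
  cv$values[4] <- NA  # force a null element
  sq <- square_tune(cv)
  expect_equal(sq$values[1:3], c(9, 16, 0))
  expect_true(is.na(sq$values[4]))
  expect_equal(sq$variant, "squared")
  expect_error(square_tune(sq), "plain")
})

test_that("scale change projects the difference onto the unit profile", {
  expect_equal(scale_change(c(0, 0), c(3, 4), c(3, 4)), 5)
  expect_equal(scale_change(c(0, 0), c(-4, 3), c(3, 4)), 0)
  expect_equal(scale_change(c(1, 1), c(2, 3), c(3, 4)), 2.2)

  # scale2 against the squared, renormalised profile
  expect_equal(scale2_change(c(0, 0), c(1, 1), c(3, 4)), 25 / sqrt(337))

  # degenerate cases return null with a reason
  miss <- scale_change(c(NA, 1), c(2, NA), c(1, 1))
  expect_true(is.na(miss))
  expect_match(attr(miss, "reason"), "no common")
  zero <- scale_change(c(0, 0), c(1, 1), c(0, 0))
  expect_true(is.na(zero))
  expect_match(attr(zero, "reason"), "zero norm")
})

test_that("profile change is the perpendicular component norm", {
  expect_equal(profile_change(c(1, 2), c(1, 2), c(3, 4)), 0)
  expect_equal(profile_change(c(0, 0), c(-4, 3), c(3, 4)), 5)
  expect_equal(profile_change(c(1, 1), c(2, 3), c(3, 4)), 0.4)
})

test_that("mean difference and summary amplitude follow the null-exclusion rules", {
  expect_equal(mean_difference(c(0, 0), c(2, 4)), 3)
  expect_equal(mean_difference(c(1, NA), c(3, 5)), 2)
  expect_equal(mean_difference(c(1, 2), c(1, 2)), 0)
  expect_true(is.na(mean_difference(c(NA, NA), c(1, 2))))

  expect_equal(mean_amplitude(c(1, 3)), list(a_bar = 2, n = 2L))
  expect_equal(mean_amplitude(c(2, NA)), list(a_bar = 2, n = 1L))
  expect_true(is.na(mean_amplitude(c(NA, NA))$a_bar))
})

test_that("top-N selection ranks by profile value with nulls last and stable ties", {
  cv <- characteristic_vector(c(5, NA, 2, 3))
  top2 <- select_top_n(cv, 2)
  expect_equal(top2$indices, c(1, 4))
  expect_equal(select_top_n(cv, 4)$indices, c(1, 4, 3, 2))

  tie <- select_top_n(c(2, 2), 1)
  expect_equal(tie$indices, 1)
})

test_that("variability adjustment scales change by same-day variability", {
  # scalar single-parameter vectors; mean difference is plain subtraction
  p <- list(0, 1); q <- list(2, 4)   # cross {2, 3}; same-day {1, 2}
  va <- variability_adjust(p, q, NULL, "mean")
  expect_equal(va$numerator, 2.5)
  expect_equal(va$denominator, 1.5)
  expect_equal(va$d_adj, 5 / 3)

  # all differences equal -> adjusted change of exactly 1
  cc <- 0.7
  va1 <- variability_adjust(list(0, cc), list(cc, 2 * cc), NULL, "mean")
  expect_equal(va1$d_adj, 1)

  # zero same-day variability -> null with reason
  va0 <- variability_adjust(list(1, 1), list(3, 3), NULL, "mean")
  expect_true(is.na(va0$d_adj))
  expect_match(va0$reason, "zero same-day")

  # missing instance -> null
  vam <- variability_adjust(list(1), list(2, 3), NULL, "mean")
  expect_match(vam$reason, "lacks two instances")

  # signed denominator mode can differ in sign handling
  vs <- variability_adjust(list(0, -1), list(2, 1), NULL, "mean",
                           denominator = "signed")
  expect_equal(vs$denominator, -1)
  va_abs <- variability_adjust(list(0, -1), list(2, 1), NULL, "mean")
  expect_equal(va_abs$denominator, 1)
})

test_that("change metric geometry: Pythagoras, symmetry and invariances", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(2:17, 1)
    aA <- rnorm(n); aB <- rnorm(n); ac <- abs(rnorm(n)) + 0.05
    ds <- scale_change(aA, aB, ac)
    dp <- profile_change(aA, aB, ac)
    expect_equal(ds^2 + dp^2, sum((aB - aA)^2), tolerance = 1e-9)
    expect_equal(scale_change(aB, aA, ac), -ds, tolerance = 1e-12)
    expect_equal(profile_change(aB, aA, ac), dp, tolerance = 1e-12)
    expect_equal(mean_difference(aB, aA), -mean_difference(aA, aB),
                 tolerance = 1e-12)
    # positive rescaling of the profile changes nothing
    lam <- runif(1, 0.1, 10)
    expect_equal(scale_change(aA, aB, lam * ac), ds, tolerance = 1e-9)
    expect_equal(scale2_change(aA, aB, lam * ac),
                 scale2_change(aA, aB, ac), tolerance = 1e-9)
    expect_equal(profile_change(aA, aB, lam * ac), dp, tolerance = 1e-9)
  }
})

test_that("translation along the profile axis moves scale only", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    aA <- rnorm(n); ac <- abs(rnorm(n)) + 0.05
    u <- ac / sqrt(sum(ac^2))
    k <- rnorm(1, 0, 3)
    aB <- aA + k * u
    expect_equal(scale_change(aA, aB, ac), k, tolerance = 1e-9)
    expect_equal(profile_change(aA, aB, ac), 0, tolerance = 1e-6)
  }
})

test_that("with a single parameter the scale change equals the mean change", {
  set.seed(43)
  for (i in 1:20) {
    aA <- rnorm(1); aB <- rnorm(1)
    expect_equal(scale_change(aA, aB, abs(rnorm(1)) + 0.1),
                 mean_difference(aA, aB), tolerance = 1e-12)
  }
})

test_that("profile change matches the cross-product oracle in 2-D and 3-D", {
  set.seed(44)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (i in 1:50) {
    aA <- rnorm(2); aB <- rnorm(2); ac <- abs(rnorm(2)) + 0.05
    u <- ac / sqrt(sum(ac^2))
    d <- aB - aA
    expect_equal(profile_change(aA, aB, ac), abs(d[1] * u[2] - d[2] * u[1]),
                 tolerance = 1e-9)
    aA3 <- rnorm(3); aB3 <- rnorm(3); ac3 <- abs(rnorm(3)) + 0.05
    u3 <- ac3 / sqrt(sum(ac3^2))
    expect_equal(profile_change(aA3, aB3, ac3),
                 sqrt(sum(cross3(aB3 - aA3, u3)^2)), tolerance = 1e-9)
  }
})

test_that("change_metrics bundles the four metrics with the common support size", {
  cm <- change_metrics(c(1, 1, NA), c(2, 3, 4), c(3, 4, 5))
  expect_equal(cm$d_s, 2.2)
  expect_equal(cm$d_p, 0.4)
  expect_equal(cm$d_m, 1.5)
  expect_equal(cm$n_common, 2L)
})
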