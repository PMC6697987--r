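test_that("Spearman correlation is rank-based, tie-aware, and null-safe", {
  r <- spearman_r2(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r$rho, 0.5)
  expect_equal(r$rho2, 0.25)

  set.seed(51)
  x <- rnorm(30)
  mono <- spearman_r2(x, exp(x))
  expect_equal(mono$rho2, 1)
  neg <- spearman_r2(x, -x)
  expect_equal(neg$rho, -1)
  expect_equal(neg$rho2, 1)

  # monotone transforms of either variable leave rho unchanged
  y <- rnorm(30)
  base <- spearman_r2(x, y)$rho
  expect_equal(spearman_r2(exp(x), y)$rho, base)
  expect_equal(spearman_r2(x, y^3)$rho, base)

  few <- spearman_r2(c(1, 2, NA), c(1, NA, 3))
  expect_true(is.na(few$rho2))
  expect_lt(few$n, 3)
})

test_that("BH adjustment matches the hand-worked examples and the oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(52)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("paired t-test drops incomplete pairs and survives degenerate input", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- paired_t_test(c(0, 0), c(1, -1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(paired_t_test(c(0, 0, 0), c(1, 1, 1)), "zero variance")
  expect_error(paired_t_test(c(1, NA), c(2, 3)), "at least 2")

  set.seed(53)
  b <- rnorm(15); a <- b + rnorm(15, 0.3)
  ours <- paired_t_test(b, a)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
})

test_that("discretisation of an absolute scale lowers rank correlation gracefully", {
  e <- discretization_experiment_abs(n = 20000, levels = c(2, 5, 100, Inf),
                                     seed = 7)
  expect_equal(e$rho2[e$levels == 2], 0.75, tolerance = 0.02)
  expect_true(all(diff(e$rho2) >= -1e-12))
  expect_equal(e$rho2[is.infinite(e$levels)], 1)
})

test_that("change correlation on a coarse 0-4 scale depends on change size", {
  e <- discretization_experiment_change(sigmas = c(0.1, 1, 10), n = 20000,
                                        seed = 8)
  expect_lt(e$rho2[1], 0.5)
  expect_gt(e$rho2[3], 0.9)
  expect_true(all(diff(e$rho2) > 0))

  degen <- discretization_experiment_change(sigmas = 0, n = 2000, seed = 8)
  expect_true(is.na(degen$rho2))

  clipped <- discretization_experiment_change(sigmas = 10, n = 20000, seed = 8,
                                              clip_bounds = TRUE)
  expect_lt(clipped$rho2, 0.9)   # saturation caps the achievable correlation
})

# analytically constructed cohort: same-day differences identical across
# subjects, cross-day change proportional to k, scores equal to k
perfect_cohort <- function(n_sub = 8, delta = 0.2) {
  rows <- list(); scores <- list()
  for (k in seq_len(n_sub)) {
    vecs <- list(d1 = list(c(1, 1), c(1, 1) + delta),
                 d2 = list(c(1 + k, 1 + k), c(1 + k, 1 + k) + delta))
    for (d in names(vecs)) for (i in 1:2) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = paste0("s", k), day_id = d, instance_id = i,
        parameter_id = c("joint.01", "joint.02"),
        log_ata = vecs[[d]][[i]])
    }
    scores[[length(scores) + 1]] <- tibble::tibble(
      subject_id = paste0("s", k), visit = 1:2,
      ftmtrs_a = 0L, ftmtrs_b = c(0, k), ftmtrs_c = c(0, k))
  }
  list(amplitudes = dplyr::bind_rows(rows), scores = dplyr::bind_rows(scores))
}

test_that("a perfect monotone severity link yields rho2 = 1 for scale metrics", {
  ch <- perfect_cohort()
  ev <- evaluate_metric_family(ch$amplitudes, ch$scores,
                               hand_params = character(0), n_range = 2)
  sc <- ev[ev$metric_id %in% c("joint_scale", "joint_scale2") &
             ev$reference == "ftmtrs_c" & ev$type == "change", ]
  expect_equal(nrow(sc), 2)
  expect_equal(sc$rho2, c(1, 1))
  expect_true(all(sc$n_points == 8))
})

test_that("constant metrics and under-sized families are omitted", {
  ch <- perfect_cohort(n_sub = 4)
  # make ftmtrs_b constant: its change correlations must drop out
  ch$scores$ftmtrs_b <- 1L
  ev <- evaluate_metric_family(ch$amplitudes, ch$scores,
                               hand_params = character(0), n_range = 2)
  expect_false(any(ev$reference == "ftmtrs_b" & ev$type == "change"))
  expect_true(any(ev$reference == "ftmtrs_c"))
})

test_that("joint-family p-values are BH-adjusted within their family", {
  set.seed(55)
  sim <- simulate_cohort_vectors(n_subjects = 12, n_params = 5, seed = 55)
  amp <- dplyr::rename(sim$vectors, log_ata = value)
  sc <- simulate_observer_scores(sim$truth, seed = 56)
  ev <- evaluate_metric_family(amp, sc, hand_params = character(0), n_range = 2:5)
  fam <- ev[ev$metric_id == "joint_scale2" & ev$reference == "ftmtrs_c" &
              ev$type == "change", ]
  expect_gt(nrow(fam), 1)
  expect_equal(fam$p_fdr, bh_bruteforce(fam$p))
  expect_true(all(fam$p_fdr >= fam$p - 1e-12))
  # non-family metrics carry no FDR adjustment
  expect_true(all(is.na(ev$p_fdr[ev$metric_id == "joint_max"])))
})
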