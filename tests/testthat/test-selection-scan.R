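test_that("a fixed difference gives FST of one; monomorphic sites are undefined", {
  fixed <- wc_fst_site(0, 0, 10, 10, 0, 0)
  expect_true(fixed$defined)
  expect_equal(fixed$theta_hat, 1)
  expect_equal(fixed$b, 0)
  expect_equal(fixed$c, 0)

  mono <- wc_fst_site(10, 0, 0, 8, 0, 0)
  expect_false(mono$defined)
  expect_true(is.na(mono$theta_hat))

  empty <- wc_fst_site(0, 0, 0, 10, 0, 0)
  expect_false(empty$defined)
})

test_that("FST components match the independent ANOVA coding exactly", {
  set.seed(3)
  for (rep in 1:300) {
    nA <- sample(2:12, 1); nB <- sample(2:12, 1)
    da <- rbinom(nA, 2, runif(1, 0.05, 0.95))
    db <- rbinom(nB, 2, runif(1, 0.05, 0.95))
    ca <- dose_counts(da); cb <- dose_counts(db)
    got <- wc_fst_site(ca[1], ca[2], ca[3], cb[1], cb[2], cb[3])
    want <- wc_anova_oracle(da, db)
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$b, want$b, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    if (got$defined) expect_equal(got$theta_hat, want$theta, tolerance = 1e-12)
  }
})

test_that("negative FST estimates are retained for the background", {
  set.seed(4)
  sites <- draw_fst_sites(400, 15)
  wc <- wc_fst_site(sites$bg_a[, 1], sites$bg_a[, 2], sites$bg_a[, 3],
                    sites$bg_b[, 1], sites$bg_b[, 2], sites$bg_b[, 3])
  expect_true(any(wc$theta_hat < 0, na.rm = TRUE)) # unstructured populations
})

test_that("percentile background flags only strict outliers", {
  vals <- c(rep(0.01, 99), 0.9)
  bg <- fst_background(vals, focal = c(0.9, 0.01))
  expect_true(bg$focal$above_p95[1])
  expect_true(bg$focal$above_p97.5[1])
  expect_false(bg$focal$above_p95[2])

  same <- fst_background(rep(0.05, 50), focal = 0.05)
  expect_false(same$focal$above_p95[1]) # equality is not "above"

  expect_error(fst_background(rep(0.1, 10)), "at least 20")

  # thresholds are invariant under permutation of site order
  set.seed(5)
  v <- runif(200)
  expect_identical(fst_background(v)$thresholds,
                   fst_background(sample(v))$thresholds)
})

test_that("an injected outlier site is the one flagged", {
  set.seed(6)
  sites <- draw_fst_sites(500, 40, p_focal = c(0.85, 0.10))
  wc_bg <- wc_fst_site(sites$bg_a[, 1], sites$bg_a[, 2], sites$bg_a[, 3],
                       sites$bg_b[, 1], sites$bg_b[, 2], sites$bg_b[, 3])
  wc_f <- wc_fst_site(sites$focal_a[1], sites$focal_a[2], sites$focal_a[3],
                      sites$focal_b[1], sites$focal_b[2], sites$focal_b[3])
  bg <- fst_background(c(wc_bg$theta_hat, wc_f$theta_hat),
                       focal = wc_f$theta_hat)
  expect_true(bg$focal$above_p95[1])
  expect_gt(wc_f$theta_hat, max(wc_bg$theta_hat, na.rm = TRUE))
})

test_that("Tajima constants and D match an independent direct evaluation", {
  k <- tajima_constants(10)
  expect_equal(k$a1, sum(1 / 1:9))
  set.seed(8)
  counts <- sample(1:9, 25, replace = TRUE)
  d <- tajimas_d(counts, 10)
  expect_equal(d$D, tajima_direct_oracle(counts, 10), tolerance = 1e-12)
  expect_identical(d$S, 25L)
})

test_that("D is exactly zero when pi equals S/a1 and undefined when S = 0", {
  # n = 4: eight singletons and three doubletons give pi = 6 = S/a1 exactly
  counts <- c(rep(1L, 8), rep(2L, 3))
  d <- tajimas_d(counts, 4)
  expect_equal(d$pi, d$S / tajima_constants(4)$a1, tolerance = 1e-12)
  expect_equal(d$D, 0, tolerance = 1e-12)

  mono <- tajimas_d(integer(), 10)
  expect_false(mono$defined)
  expect_true(is.na(mono$D))
})

test_that("window tiling is half-open with 1-based input positions", {
  sites <- data.frame(pos = c(1L, 15000L, 15001L, 30001L), count = 2L)
  scan <- windowed_scan(sites, n_chromosomes = 10, window_len = 15000L)
  expect_identical(scan$windows$S[scan$windows$window == 0L], 2L)
  expect_identical(scan$windows$S[scan$windows$window == 1L], 1L)
  expect_identical(scan$windows$S[scan$windows$window == 2L], 1L)
})

test_that("locus summary compares the focal windows to the chromosome", {
  # identical windows: locus mean equals the median, no flags
  sites <- do.call(rbind, lapply(0:29, function(w) {
    data.frame(pos = w * 15000L + c(10L, 20L, 30L), count = c(1L, 2L, 5L))
  }))
  scan <- windowed_scan(sites, n_chromosomes = 12,
                        focal_windows = c(10L, 11L, 12L))
  s <- scan$summary
  expect_equal(s$locus_mean_D, s$percentiles[["p50"]])
  expect_false(s$below_p5); expect_false(s$above_p95)
  expect_false(s$below_median)
  expect_true(all(diff(s$percentiles) >= 0))

  # all focal windows empty: locus summary undefined
  empty_focal <- windowed_scan(sites, n_chromosomes = 12,
                               focal_windows = c(40L, 41L), n_windows = 45L)
  expect_false(empty_focal$summary$locus_defined)
})

test_that("sweep windows depress D relative to paired neutral windows", {
  spec_sweep <- window_sim_spec(n_chromosomes = 20L, theta_w = 15,
                                n_windows = 200L, sweep_windows = 0:199,
                                sweep_rare_skew = 3)
  spec_neut <- window_sim_spec(n_chromosomes = 20L, theta_w = 15,
                               n_windows = 200L)
  d_of <- function(sites) {
    out <- windowed_scan(sites, attr(sites, "n_chromosomes"), n_windows = 200L)
    out$windows$D
  }
  d_sweep <- d_of(simulate_windows(spec_sweep, 21))
  d_neut <- d_of(simulate_windows(spec_neut, 22))
  expect_lt(mean(d_sweep, na.rm = TRUE), mean(d_neut, na.rm = TRUE))
})
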