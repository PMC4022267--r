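test_that("empirical 1D p-values interpolate the ECDF with clamping", {
  cloud <- 1:100
  expect_equal(empirical_p1d(cloud, 50.5, "right"), 0.5, tolerance = 0.01)
  # brute-force count oracle: fraction of cloud values >= observed
  expect_lt(abs(empirical_p1d(cloud, 90.5, "right") - mean(cloud >= 90.5)),
            0.005)
  # clamp rule at the extremes
  expect_equal(empirical_p1d(cloud, -10, "left"), 1 / 101)
  expect_equal(empirical_p1d(cloud, 1e6, "right"), 1 / 101)
  expect_equal(empirical_p1d(cloud, 50.5, "two"), 1, tolerance = 0.02)
  expect_error(empirical_p1d(rep(NA_real_, 10), 1, "right"), "empty")
  expect_warning(empirical_p1d(1:10, 5, "right"), "coarse")
})

test_that("density-tailed 1D p-value ranks points by kernel density", {
  x <- withr::with_seed(31, rnorm(2000))
  # at the mode nearly all points have lower density; far out nearly none
  expect_gt(empirical_p1d(x, 0, "density"), 0.9)
  expect_lt(empirical_p1d(x, 6, "density"), 0.01)
})

test_that("1D chi2 and dw tests are calibrated under a true H0", {
  ms1 <- builtin_models("MS1")
  cond <- default_conditions("static")
  p_chi2 <- p_dw <- numeric(100)
  for (i in 1:100) {
    ds <- make_fixture("static", "MS1", seed = 4000 + i)
    p_chi2[i] <- chi2_test(ms1, ds, B = 100, seed = 4500 + i)$p_value
    p_dw[i] <- dw_test(ms1, ds, B = 100, seed = 4500 + i)$p_value
  }
  # ties warning suppressed: boundary p-values are clamped to 1/(B+1)
  expect_gt(suppressWarnings(ks.test(p_chi2, "punif")$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(p_dw, "punif")$p.value), 0.01)
  # power > size: data from MS2 tested under MS1 is rejected more often
  p_wrong <- vapply(1:60, function(i) {
    ds <- make_fixture("static", "MS2", seed = 6000 + i)
    chi2_test(ms1, ds, B = 100, seed = 6500 + i)$p_value
  }, numeric(1))
  expect_gt(mean(p_wrong < 0.05), 0.05)
})

test_that("testing the interpolant itself fails with a degenerate-fit error", {
  ds <- make_fixture("static", "MS1", seed = 32)
  expect_error(dw_test(builtin_models("FLEX"), ds, B = 20, seed = 1),
               class = "bootgof_degenerate_fit")
})

test_that("simplistic combinations compute the four formulas", {
  comb <- combine_simplistic(0.2, 0.6)
  expect_equal(comb, structure(list(p_min = 0.2, p_max = 0.6, p_mean = 0.4,
                                    p_prod = 0.12),
                               note = "demonstration-only: unsound"))
  same <- combine_simplistic(0.3, 0.3)
  expect_equal(same$p_min, 0.3)
  expect_equal(same$p_max, 0.3)
  expect_equal(same$p_mean, 0.3)
  expect_equal(same$p_prod, 0.09)
  expect_error(combine_simplistic(1.2, 0.5))
})

test_that("2D test with a FLEX help model collapses to the 1D chi2 density test", {
  ms1 <- builtin_models("MS1")
  flex <- builtin_models("FLEX")
  ds <- make_fixture("static", "MS1", seed = 33)
  res <- gof2d_test(ms1, ds, flex, B = 2000, seed = 34, grid_n = 64)
  expect_true(any(grepl("constant", res$warnings)))
  # density-tailed 1D chi2 p on the same cloud. The grid integral and the
  # cloud-point rank estimate the same mass but differ by an O(bandwidth)
  # smoothing bias on this skewed distribution, so the check is loose.
  f <- fit_model(ms1, ds)
  samples <- boot_samples(ms1, f$theta_hat, ds, B = 2000, seed = 34)
  cloud <- build_cloud(samples, list(ms1), "chi2")
  p1d <- empirical_p1d(cloud$stats[, "chi2"], f$chi2, "density")
  expect_lt(abs(res$p_value - p1d), 0.05)
})

test_that("the competing-model 2D test runs with both models as H0", {
  ds <- make_fixture("static", "MS1", seed = 35)
  res <- gof2d_test(builtin_models("MS1"), ds, builtin_models("MS2"),
                    B = 150, seed = 36, grid_n = 64, h0 = "both")
  expect_length(res, 2)
  expect_match(res[[1]]$test_name, "h0=MS1", fixed = TRUE)
  expect_match(res[[2]]$test_name, "h0=MS2", fixed = TRUE)
  for (r in res) {
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
    expect_identical(r$rejected, r$p_value < r$alpha)
  }
})

test_that("LHR test centers at p ~ 1 and equals the chi2 test under FLEX", {
  ms1 <- builtin_models("MS1")
  ds <- make_fixture("static", "MS1", seed = 37)
  # observed LHR at the cloud median: two-tailed p near 1. Emulate by
  # testing the true model against itself-like competitor on H0 data.
  res <- lhr_test(ms1, builtin_models("MS2"), ds, B = 300, seed = 38)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # FLEX competitor: LHR cloud is the chi2 cloud, p matches two-tailed chi2
  res_flex <- lhr_test(ms1, builtin_models("FLEX"), ds, B = 300, seed = 39)
  res_chi2 <- chi2_test(ms1, ds, B = 300, seed = 39, tail = "two")
  expect_equal(res_flex$p_value, res_chi2$p_value, tolerance = 1e-12)
  expect_true(length(res_flex$warnings) > 0)
})

test_that("test results serialize to JSON with provenance", {
  ds <- make_fixture("static", "MS1", seed = 40)
  res <- chi2_test(builtin_models("MS1"), ds, B = 60, seed = 41)
  js <- jsonlite::fromJSON(write_test_result(res))
  expect_equal(js$test_name, "chi2")
  expect_equal(js$p_value, res$p_value)
  expect_equal(js$cloud_ref$seed, 41)
  path <- withr::local_tempfile(fileext = ".json")
  write_test_result(res, path)
  expect_true(file.exists(path))
})
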