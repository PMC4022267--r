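test_that("residuals and chi-square follow their definitions", {
  ds <- gof_dataset(0:2, value = c(1, 2, 3), sigma = 1)
  expect_equal(gof_residuals(ds, c(1, 2, 3)), c(0, 0, 0))
  expect_equal(gof_residuals(gof_dataset(0:2, c(3, 1, 2), 1), c(1, 2, 2)),
               c(2, -1, 0))
  expect_equal(chi2_statistic(ds, c(0, 0, 0)), 14)  # 1 + 4 + 9
  expect_equal(chi2_statistic(ds, c(1, 2, 3)), 0)
  expect_error(gof_residuals(ds, 1:2), "match")
})

test_that("chi-square is invariant to signal reordering and additive over blocks", {
  withr::with_seed(42, {
    y <- rnorm(8, 5); yhat <- rnorm(8, 5); sg <- runif(8, 0.3, 1)
  })
  d <- gof_design(c(1:4, 1:4), rep(c("a", "b"), each = 4))
  ds <- gof_dataset(d, y, sg)
  # swap the two signal blocks
  perm <- c(5:8, 1:4)
  d_sw <- gof_design(c(1:4, 1:4), rep(c("b", "a"), each = 4))
  ds_sw <- gof_dataset(d_sw, y[perm], sg[perm])
  expect_equal(chi2_statistic(ds, yhat), chi2_statistic(ds_sw, yhat[perm]))
  # additivity over disjoint signal blocks
  ds_a <- gof_dataset(gof_design(1:4, "a"), y[1:4], sg[1:4])
  ds_b <- gof_dataset(gof_design(1:4, "b"), y[5:8], sg[5:8])
  expect_equal(chi2_statistic(ds, yhat),
               chi2_statistic(ds_a, yhat[1:4]) + chi2_statistic(ds_b, yhat[5:8]))
})

test_that("Durbin-Watson matches hand-computed cases", {
  expect_equal(dw_statistic(c(3, 3, 3, 3)), 0)      # constant residuals
  expect_equal(dw_statistic(c(1, -1, 1, -1)), 3)    # 12 / 4
  # differences never cross a signal boundary
  r <- c(1, 2, 3, -3, -2, -1)
  sig <- rep(c("a", "b"), each = 3)
  manual <- (sum(diff(r[1:3])^2) + sum(diff(r[4:6])^2)) / sum(r^2)
  expect_equal(dw_statistic(r, sig), manual)
  expect_false(isTRUE(all.equal(dw_statistic(r), dw_statistic(r, sig))))
  expect_error(dw_statistic(rep(0, 5)), class = "bootgof_degenerate_fit")
})

test_that("Durbin-Watson stays in [0, 4] on random and adversarial residuals", {
  withr::with_seed(99, {
    cases <- c(
      lapply(1:40, function(i) rnorm(sample(3:60, 1))),
      lapply(c(0.99, -0.99), function(phi)    # strong (anti)correlation
        as.numeric(arima.sim(list(ar = phi), 50))),
      list(rep(c(1, -1), 25),                 # alternating: near 4
           rep(1, 30) + rnorm(30, sd = 1e-8), # near-constant: near 0
           c(rep(0, 20), 5, rep(0, 20)),      # single spike
           c(1e-12, rep(c(1e8, -1e8), 10)))   # extreme scale mix
    )
    for (r in cases) {
      dw <- dw_statistic(r)
      expect_gte(dw, 0)
      expect_lte(dw, 4)
    }
  })
})

test_that("white residuals give Durbin-Watson near 2 on average", {
  withr::with_seed(1234, {
    dws <- replicate(2000, dw_statistic(rnorm(100)))
  })
  # exact null expectation is 2 * (n - 1) / n = 1.98 for n = 100
  expect_equal(mean(dws), 1.98, tolerance = 0.01)
})

test_that("LHR/LHP statistics and their rotation identities hold", {
  expect_equal(lhr_statistic(5, 5), 0)
  expect_equal(lhr_statistic(14, 3), 11)
  expect_equal(lhp_statistic(5, 5), 10)
  expect_equal(lhp_statistic(14, 3), 17)
  withr::with_seed(8, {
    c1 <- rchisq(200, 9); c2 <- rchisq(200, 9)
  })
  lhr <- lhr_statistic(c1, c2); lhp <- lhp_statistic(c1, c2)
  expect_equal(lhr + lhp, 2 * c1)
  expect_equal(lhp - lhr, 2 * c2)
  # the map is a 45-degree rotation scaled by sqrt(2): pairwise Euclidean
  # distances between cloud points are preserved up to that factor
  i <- 1:50; j <- 51:100
  d_orig <- sqrt((c1[i] - c1[j])^2 + (c2[i] - c2[j])^2)
  d_rot <- sqrt((lhr[i] - lhr[j])^2 + (lhp[i] - lhp[j])^2)
  expect_equal(d_rot, sqrt(2) * d_orig, tolerance = 1e-12)
})
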