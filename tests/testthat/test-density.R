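test_that("2D KDE bin masses are non-negative and sum to one", {
  z <- gauss_cloud(500, seed = 21)
  g <- kde2d_cloud(z, grid_n = 64)
  expect_true(all(g$mass >= 0))
  expect_equal(sum(g$mass), 1, tolerance = 1e-9)
  # grid covers the cloud extent padded by 3 bandwidths
  expect_lte(min(g$gx), min(z[, 1]) - 2.99 * g$bw[1])
  expect_gte(max(g$gx), max(z[, 1]) + 2.99 * g$bw[1])
})

test_that("2D KDE matches MASS::kde2d with matched bandwidths and grid", {
  skip_if_not_installed("MASS")
  z <- gauss_cloud(400, seed = 22)
  h <- c(bw.nrd0(z[, 1]), bw.nrd0(z[, 2]))
  lims <- c(min(z[, 1]) - 3 * h[1], max(z[, 1]) + 3 * h[1],
            min(z[, 2]) - 3 * h[2], max(z[, 2]) + 3 * h[2])
  g <- kde2d_cloud(z, grid_n = 50, bw = h)
  # MASS parameterizes the Gaussian kernel sd as h/4
  m <- MASS::kde2d(z[, 1], z[, 2], h = 4 * h, n = 50, lims = lims)
  expect_equal(g$density, m$z, tolerance = 1e-10)
})

test_that("KDE of a large Gaussian cloud reproduces quadrant masses", {
  z <- gauss_cloud(10000, seed = 23)
  g <- kde2d_cloud(z, grid_n = 96)
  quad <- function(sx, sy) sum(g$mass[outer(sign(g$gx) == sx,
                                            sign(g$gy) == sy, `&`)])
  for (sx in c(-1, 1)) for (sy in c(-1, 1))
    expect_lt(abs(quad(sx, sy) - 0.25), 0.02)
})

test_that("collapsed clouds degrade to a flagged 1D density", {
  B <- 300
  y <- withr::with_seed(24, rnorm(B))
  flat <- cbind(rep(2, B), y)
  expect_warning(g <- kde2d_cloud(flat, grid_n = 64),
                 class = "bootgof_collapsed_cloud")
  expect_equal(g$collapsed, 1L)
  expect_equal(sum(g$mass), 1, tolerance = 1e-9)
  expect_error(kde2d_cloud(cbind(rep(1, B), rep(2, B))), "zero spread")
  # p-value from the collapsed grid equals the 1D density-tail p
  p2 <- p_value_2d(g, c(2, 1.5))
  p1 <- empirical_p1d(y, 1.5, tail = "density")
  expect_lt(abs(p2 - p1), 0.02)
})

test_that("2D p-value is ~1 at the mode and ~0 far outside the cloud", {
  z <- gauss_cloud(2000, seed = 25)
  g <- kde2d_cloud(z, grid_n = 64)
  expect_gt(p_value_2d(g, c(0, 0)), 0.9)
  expect_lt(p_value_2d(g, c(8, 8)), 0.01)
})

test_that("2D p-value agrees with the brute-force density-rank oracle", {
  # coarse consistency check at small B (the grid integral and the point
  # rank converge to each other as B grows; the tight +/-0.02 agreement is
  # asserted at B = 1e4 in the acceptance suite)
  for (seed in c(26, 27)) {
    z <- gauss_cloud(1500, seed = seed)
    z[, 2] <- 0.5 * z[, 1] + z[, 2]          # tilted cloud
    g <- kde2d_cloud(z, grid_n = 96)
    for (obs in list(c(1, 1), c(-1.5, 0.5), c(2.5, 2.5))) {
      rho_pts <- bootgof:::kde2_eval(z[, 1], z[, 2], g$bw, z[, 1], z[, 2])
      rho_obs <- bootgof:::kde2_eval(z[, 1], z[, 2], g$bw, obs[1], obs[2])
      p_bf <- mean(rho_pts < rho_obs)
      expect_lt(abs(p_value_2d(g, obs) - p_bf), 0.03)
    }
  }
})

test_that("doubling the grid leaves 2D p-values essentially unchanged", {
  z <- gauss_cloud(4000, seed = 28)
  obs <- c(1.2, -0.7)
  p64 <- p_value_2d(kde2d_cloud(z, grid_n = 64), obs)
  p128 <- p_value_2d(kde2d_cloud(z, grid_n = 128), obs)
  expect_lt(abs(p128 - p64), 0.005)
})

test_that("cloud geometry reports correlation, angle, and collapse", {
  z <- gauss_cloud(10000, seed = 29)
  iso <- cloud_geometry(z)
  expect_lt(abs(iso$correlation), 0.05)
  expect_false(any(iso$collapsed))
  # perfectly correlated equal-variance columns: 45 degrees
  x <- withr::with_seed(30, rnorm(500))
  corr <- cloud_geometry(cbind(x, x))
  expect_equal(corr$angle_deg, 45, tolerance = 1e-6)
  expect_equal(corr$correlation, 1, tolerance = 1e-12)
  flat <- cloud_geometry(cbind(rep(0, 100), seq_len(100)))
  expect_true(flat$collapsed[1])
  expect_match(flat$advice, "one dimension")
})
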