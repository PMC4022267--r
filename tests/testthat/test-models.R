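test_that("built-in static models evaluate their closed forms", {
  ms1 <- builtin_models("MS1")
  expect_equal(simulate_model(ms1, c(2, 1), gof_design(c(0, 1, 2))),
               c(1, 3, 5))
  ms2 <- builtin_models("MS2")
  expect_equal(simulate_model(ms2, c(1, 0), gof_design(c(0, 1, 2)))[1], 1)
  expect_error(builtin_models("NOPE"), "registry")
})

test_that("MD1 predictions match the analytic decay and t = 0 initial value", {
  md1 <- builtin_models("MD1")
  d <- gof_design(c(0, 1, log(4) / 0.5))
  y <- simulate_model(md1, 0.5, d)
  expect_equal(y[1], 10)
  expect_equal(y[3], 2.5, tolerance = 1e-12)
  md2 <- builtin_models("MD2")
  expect_equal(simulate_model(md2, 3.3, gof_design(c(0, 0.5, 1)))[1], 10)
})

test_that("MD1/MD2 exact solutions agree with numeric ODE integration", {
  skip_if_not_installed("deSolve")
  tt <- seq(0, 10, length.out = 9)[-1]
  d <- gof_design(tt)
  for (theta in c(0.01, 0.1, 0.7, 2, 5)) {
    num <- deSolve::ode(c(x = 10), c(0, tt),
                        function(t, x, p) list(-p * x), theta,
                        rtol = 1e-10, atol = 1e-12)
    expect_equal(simulate_model(builtin_models("MD1"), theta, d),
                 unname(num[-1, 2]), tolerance = 1e-6)
  }
  d3 <- gof_design(seq(0, 3, length.out = 11)[-1])
  for (theta in c(0.5, 2, 5)) {
    num <- deSolve::ode(c(x = 10), c(0, d3$coordinate),
                        function(t, x, p) list(-p * x / (0.01 + x)), theta,
                        rtol = 1e-10, atol = 1e-12)
    expect_equal(simulate_model(builtin_models("MD2"), theta, d3),
                 unname(num[-1, 2]), tolerance = 1e-5)
  }
})

test_that("noise-free fits recover the generating parameters", {
  cond <- default_conditions("static")
  ds <- noise_free_dataset(builtin_models("MS1"), c(4, 5), cond$design)
  f <- fit_model(builtin_models("MS1"), ds)
  expect_equal(f$theta_hat, c(4, 5), tolerance = 1e-12)
  expect_lt(f$chi2, 1e-18)

  dd <- default_conditions("dynamic")$design
  ds2 <- noise_free_dataset(builtin_models("MD2"), 0.8, dd, sigma = 0.75)
  f2 <- fit_model(builtin_models("MD2"), ds2)
  expect_equal(f2$theta_hat, 0.8, tolerance = 1e-6)
  expect_lt(f2$chi2, 1e-8)

  ds3 <- noise_free_dataset(builtin_models("MD1"), 0.7, dd, sigma = 0.75)
  f3 <- fit_model(builtin_models("MD1"), ds3)
  expect_equal(f3$theta_hat, 0.7, tolerance = 1e-6)
})

test_that("linear WLS fit is start-independent and sigma-scale invariant", {
  ds <- make_fixture("static", "MS1", seed = 7)
  f1 <- fit_model(builtin_models("MS1"), ds)
  # idempotent: refitting the model to its own prediction recovers theta
  ds_self <- gof_dataset(ds$design, f1$predicted, ds$sigma)
  f_self <- fit_model(builtin_models("MS1"), ds_self)
  expect_equal(f_self$theta_hat, f1$theta_hat, tolerance = 1e-12)
  expect_lt(f_self$chi2, 1e-20)
  # scaling all sigma by c leaves theta unchanged, divides chi2 by c^2
  for (c_scale in c(0.5, 2, 10)) {
    ds_c <- gof_dataset(ds$design, ds$value, ds$sigma * c_scale)
    f_c <- fit_model(builtin_models("MS1"), ds_c)
    expect_equal(f_c$theta_hat, f1$theta_hat, tolerance = 1e-10)
    expect_equal(f_c$chi2, f1$chi2 / c_scale^2, tolerance = 1e-10)
  }
})

test_that("hyper-flexible interpolant and constant help models fit as defined", {
  ds <- make_fixture("static", "MS2", seed = 3)
  f_flex <- fit_model(builtin_models("FLEX"), ds)
  expect_equal(f_flex$chi2, 0)
  expect_equal(f_flex$residuals, rep(0, 11))
  f_const <- fit_model(builtin_models("CONST"), ds)
  # equal sigma: the weighted mean is the plain mean
  expect_equal(unname(f_const$theta_hat), mean(ds$value), tolerance = 1e-12)
})

test_that("fit chi2 equals the independently recomputed statistic", {
  for (id in c("MS1", "MS2", "MD1")) {
    case <- if (id == "MD1") "dynamic" else "static"
    ds <- make_fixture(case, id, seed = 5)
    f <- fit_model(builtin_models(id), ds)
    expect_equal(f$chi2, chi2_statistic(ds, f$predicted), tolerance = 1e-12)
  }
})

test_that("design and dataset validation rejects malformed inputs", {
  expect_error(gof_design(c(0, 1)), "at least 3")
  expect_error(gof_design(c(0, 1, 1)), "strictly increasing")
  expect_error(gof_dataset(0:3, value = 1:4, sigma = 0), "positive")
  expect_error(gof_dataset(0:3, value = 1:3, sigma = 1), "match")
  # two signals may repeat coordinates across (not within) signals
  d2 <- gof_design(c(0, 1, 2, 0, 1, 2), rep(c("a", "b"), each = 3))
  expect_s3_class(d2, "gof_design")
})

test_that("ode_model wraps a user ODE as a predictor", {
  skip_if_not_installed("deSolve")
  m <- ode_model("user_decay", 1L,
                 rhs = function(t, x, p) list(-p[1] * x),
                 x0 = c(x = 10), bounds = c(1e-3, 10))
  d <- gof_design(c(0.5, 1, 2))
  expect_equal(simulate_model(m, 0.7, d), 10 * exp(-0.7 * d$coordinate),
               tolerance = 1e-7)
})
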