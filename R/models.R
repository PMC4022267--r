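#' Define a predictor model
#'
#' A predictor model is anything that maps a parameter vector and a design to
#' predicted outputs. This covers static regression curves, analytic ODE
#' solutions, and arbitrary user-supplied simulators. The `fit_strategy`
#' tells [fit_model()] how the chi-square objective is minimized:
#'
#' * `"linear_basis"`: predictions are `basis(design) %*% theta`; fitted
#'   exactly by weighted least squares.
#' * `"scalar_search"`: low-dimensional bounded search; fitted by
#'   deterministic multi-start 1D minimization over `bounds`.
#' * `"constant"`: one level per signal; fitted by the per-signal weighted
#'   mean.
#' * `"interpolant"`: reproduces any data exactly (the hyper-flexible model);
#'   its cost is identically zero.
#' * `"fixed"`: no free parameters; nothing is fitted.
#'
#' @param model_id short name used in registries and output.
#' @param n_params number of free parameters (`NA` for the interpolant,
#'   whose parameter count equals the number of data points).
#' @param predict function `(theta, design) -> numeric`, deterministic for
#'   fixed arguments, returning one prediction per design row.
#' @param fit_strategy one of the strategies above.
#' @param bounds for `"scalar_search"`: length-2 lower/upper parameter bounds
#'   (a 2-row matrix for multi-parameter models is accepted but only 1D
#'   search is built in).
#' @param basis for `"linear_basis"`: function `design -> model matrix`.
#'
#' @return An object of class `predictor_model`.
#' @seealso [builtin_models()], [fit_model()], [simulate_model()]
#' @export
predictor_model <- function(model_id, n_params, predict,
                            fit_strategy = c("linear_basis", "scalar_search",
                                             "constant", "interpolant",
                                             "fixed"),
                            bounds = NULL, basis = NULL) {
  fit_strategy <- match.arg(fit_strategy)
  stopifnot(is.function(predict))
  if (fit_strategy == "linear_basis" && !is.function(basis))
    stop("linear_basis models need a basis() function")
  if (fit_strategy == "scalar_search") {
    if (is.null(bounds) || length(bounds) != 2L || bounds[1] >= bounds[2])
      stop("scalar_search models need bounds = c(lower, upper)")
  }
  structure(list(model_id = model_id, n_params = n_params, predict = predict,
                 fit_strategy = fit_strategy, bounds = bounds, basis = basis),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat("<predictor_model> ", x$model_id, ": ",
      if (is.na(x$n_params)) "n (interpolant)" else x$n_params,
      " parameter(s), fit by ", x$fit_strategy, "\n", sep = "")
  invisible(x)
}

# Michaelis-Menten decay x' = -theta*x/(0.01+x), x(0)=10, via its implicit
# solution x + Km*log(x) = x0 + Km*log(x0) - theta*t, solved for x by
# safeguarded Newton in z = log(x) (globally convergent here: the map
# z -> e^z + Km*z is convex and increasing, and the start z0 = log(x0)
# lies at or above the root for t >= 0).
mm_decay_solution <- function(theta, tt, x0 = 10, Km = 0.01) {
  target <- x0 + Km * log(x0) - theta * tt
  z <- rep(log(x0), length(tt))
  for (it in 1:200) {
    ez <- exp(z)
    f <- ez + Km * z - target
    if (all(abs(f) < 1e-12)) break
    z <- z - f / (ez + Km)
  }
  exp(z)
}

#' Built-in test-case and help models
#'
#' The registry used throughout the package's examples and evaluation
#' harness:
#'
#' * `MS1` straight line: `theta1 * x + theta2`.
#' * `MS2` exponential curve: `theta1 * exp(x) + theta2`.
#' * `MD1` mass-action decay: `x1' = -theta * x1`, `x1(0) = 10`, observed
#'   directly; predictions use the exact solution `10 * exp(-theta * t)`.
#' * `MD2` Michaelis-Menten decay: `x1' = -theta * x1 / (0.01 + x1)`,
#'   `x1(0) = 10`; predictions solve the implicit exact solution.
#' * `CONST` help model: approximates each signal by its (weighted) mean.
#' * `FLEX` hyper-flexible help model: interpolates any dataset exactly,
#'   so its cost is always zero.
#'
#' @param id optional model id; if given, that single model is returned and
#'   an unknown id raises an error listing the registry.
#' @return A named list of [predictor_model()] objects, or one model.
#' @examples
#' m <- builtin_models("MD1")
#' simulate_model(m, 0.5, gof_design(c(0, 1, 2)))
#' @export
builtin_models <- function(id = NULL) {
  reg <- list(
    MS1 = predictor_model(
      "MS1", 2L,
      predict = function(theta, design) theta[1] * design$coordinate + theta[2],
      fit_strategy = "linear_basis",
      basis = function(design) cbind(x = design$coordinate, intercept = 1)),
    MS2 = predictor_model(
      "MS2", 2L,
      predict = function(theta, design)
        theta[1] * exp(design$coordinate) + theta[2],
      fit_strategy = "linear_basis",
      basis = function(design) cbind(ex = exp(design$coordinate),
                                     intercept = 1)),
    MD1 = predictor_model(
      "MD1", 1L,
      predict = function(theta, design)
        10 * exp(-theta[1] * design$coordinate),
      fit_strategy = "scalar_search", bounds = c(1e-3, 10)),
    MD2 = predictor_model(
      "MD2", 1L,
      predict = function(theta, design)
        mm_decay_solution(theta[1], design$coordinate),
      fit_strategy = "scalar_search", bounds = c(1e-2, 100)),
    CONST = predictor_model(
      "CONST", 1L,
      predict = function(theta, design) {
        idx <- signal_index(design)
        out <- numeric(nrow(design))
        for (k in seq_along(idx)) out[idx[[k]]] <- theta[k]
        out
      },
      fit_strategy = "constant"),
    FLEX = predictor_model(
      "FLEX", NA_integer_,
      predict = function(theta, design) {
        if (length(theta) != nrow(design))
          stop("FLEX needs one parameter per design point")
        as.numeric(theta)
      },
      fit_strategy = "interpolant")
  )
  if (is.null(id)) return(reg)
  if (!id %in% names(reg))
    stop("unknown model id '", id, "'; registry: ",
         paste(names(reg), collapse = ", "))
  reg[[id]]
}

#' Simulate a model on a design
#'
#' Evaluates the noise-free predicted outputs of a model at the design
#' points for a given parameter vector.
#'
#' @param model a [predictor_model()].
#' @param theta parameter vector of length `model$n_params`.
#' @param design a [gof_design()] (a [gof_dataset()] is accepted; its design
#'   is used).
#' @return numeric vector of predictions, one per design row.
#' @export
simulate_model <- function(model, theta, design) {
  if (inherits(design, "gof_dataset")) design <- design$design
  if (!inherits(design, "gof_design")) design <- gof_design(design)
  theta <- as.numeric(theta)
  if (!is.na(model$n_params) && length(theta) != model$n_params)
    stop("model '", model$model_id, "' expects ", model$n_params,
         " parameter(s), got ", length(theta))
  yhat <- model$predict(theta, design)
  if (length(yhat) != nrow(design) || any(!is.finite(yhat)))
    stop("simulation of model '", model$model_id, "' at theta = (",
         paste(signif(theta, 6), collapse = ", "),
         ") returned non-finite or mis-shaped output")
  as.numeric(yhat)
}

#' Fitting options
#'
#' @param n_starts number of log-spaced sub-intervals searched by the
#'   multi-start 1D minimizer (scalar_search models).
#' @param tol convergence tolerance on the parameter passed to
#'   [stats::optimize()].
#' @param extra_starts optional extra starting parameter values added to the
#'   multi-start schedule (e.g. the fit to the observed data when refitting
#'   bootstrap samples).
#' @return list of options for [fit_model()].
#' @export
fit_options <- function(n_starts = 4L, tol = 1e-8, extra_starts = NULL) {
  list(n_starts = as.integer(n_starts), tol = tol, extra_starts = extra_starts)
}

# Multi-start bounded 1D minimization: optimize() on log-spaced sub-intervals
# (linear spacing if the lower bound is <= 0), keeping the best minimum.
scalar_search_fit <- function(objective, bounds, options) {
  lo <- bounds[1]; hi <- bounds[2]
  k <- max(1L, options$n_starts)
  cuts <- if (lo > 0) exp(seq(log(lo), log(hi), length.out = k + 1L))
          else seq(lo, hi, length.out = k + 1L)
  best <- NULL
  for (i in seq_len(k)) {
    opt <- stats::optimize(objective, lower = cuts[i], upper = cuts[i + 1L],
                           tol = options$tol)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  for (th in options$extra_starts) {
    if (is.finite(th) && th >= lo && th <= hi) {
      f <- objective(th)
      if (f < best$objective) {
        # polish inside a small bracket around the candidate
        w <- (hi - lo) * 1e-3
        opt <- stats::optimize(objective, lower = max(lo, th - w),
                               upper = min(hi, th + w), tol = options$tol)
        best <- if (opt$objective < f)
          opt else list(minimum = th, objective = f)
      }
    }
  }
  list(theta = best$minimum, chi2 = best$objective, n_restarts = k)
}

weighted_mean_by_signal <- function(design, y, w) {
  idx <- signal_index(design)
  vapply(idx, function(ii) sum(w[ii] * y[ii]) / sum(w[ii]), numeric(1))
}

#' Fit a model to a dataset by minimizing the chi-square statistic
#'
#' The objective is the weighted residual sum of squares
#' `sum(((y - yhat) / sigma)^2)` with the per-point `sigma` taken from the
#' dataset. Linear-basis models are solved exactly by weighted least
#' squares; scalar-search models by deterministic multi-start bounded
#' minimization; the constant model by per-signal weighted means; the
#' interpolant reproduces the data (cost zero).
#'
#' @param model a [predictor_model()].
#' @param dataset a [gof_dataset()].
#' @param options a [fit_options()] list.
#' @return An object of class `gof_fit`: list with `model_id`, `theta_hat`,
#'   `chi2`, `residuals`, `predicted`, `converged`, `n_restarts_used`.
#' @examples
#' ds <- make_fixture("static", "MS1", seed = 1)
#' fit_model(builtin_models("MS1"), ds)
#' @export
fit_model <- function(model, dataset, options = fit_options()) {
  stopifnot(inherits(model, "predictor_model"), inherits(dataset, "gof_dataset"))
  design <- dataset$design
  y <- dataset$value
  sigma <- dataset$sigma
  w <- 1 / sigma^2
  n_restarts <- 0L
  theta <- switch(
    model$fit_strategy,
    linear_basis = {
      X <- model$basis(design)
      # weighted normal equations; exact for these small bases
      A <- crossprod(X, X * w)
      as.numeric(solve(A, crossprod(X, y * w)))
    },
    scalar_search = {
      obj <- function(th) {
        yh <- model$predict(th, design)
        sum(((y - yh) / sigma)^2)
      }
      res <- scalar_search_fit(obj, model$bounds, options)
      n_restarts <- res$n_restarts
      res$theta
    },
    constant = weighted_mean_by_signal(design, y, w),
    interpolant = y,
    fixed = numeric(0)
  )
  predicted <- model$predict(theta, design)
  resid <- y - predicted
  chi2 <- sum((resid / sigma)^2)
  structure(list(model_id = model$model_id, theta_hat = theta, chi2 = chi2,
                 residuals = resid, predicted = predicted,
                 converged = is.finite(chi2),
                 n_restarts_used = n_restarts),
            class = "gof_fit")
}

#' @export
print.gof_fit <- function(x, ...) {
  cat("<gof_fit> model ", x$model_id, ": chi2 = ", format(x$chi2),
      if (length(x$theta_hat))
        paste0(", theta_hat = (",
               paste(signif(x$theta_hat, 6), collapse = ", "), ")") else "",
      "\n", sep = "")
  invisible(x)
}

# Batch fit: one model against many replicate value vectors sharing the same
# design and sigma (columns of Y). Linear-basis and constant strategies are
# solved for all columns at once; scalar search loops with the chi2 objective
# evaluated per column.
fit_model_batch <- function(model, Y, design, sigma, options = fit_options()) {
  Y <- as.matrix(Y)
  B <- ncol(Y)
  w <- 1 / sigma^2
  switch(
    model$fit_strategy,
    linear_basis = {
      X <- model$basis(design)
      A <- crossprod(X, X * w)
      Theta <- solve(A, crossprod(X, Y * w))        # p x B
      Pred <- X %*% Theta
      R <- Y - Pred
      list(theta = Theta, resid = R, chi2 = colSums((R / sigma)^2))
    },
    constant = {
      idx <- signal_index(design)
      Pred <- matrix(0, nrow(Y), B)
      Theta <- matrix(0, length(idx), B)
      for (k in seq_along(idx)) {
        ii <- idx[[k]]
        mk <- colSums(Y[ii, , drop = FALSE] * w[ii]) / sum(w[ii])
        Theta[k, ] <- mk
        Pred[ii, ] <- rep(mk, each = length(ii))
      }
      R <- Y - Pred
      list(theta = Theta, resid = R, chi2 = colSums((R / sigma)^2))
    },
    interpolant = list(theta = Y, resid = matrix(0, nrow(Y), B),
                       chi2 = numeric(B)),
    fixed = {
      Pred <- matrix(model$predict(numeric(0), design), nrow(Y), B)
      R <- Y - Pred
      list(theta = matrix(numeric(0), 0, B), resid = R,
           chi2 = colSums((R / sigma)^2))
    },
    scalar_search = {
      Theta <- numeric(B); chi2 <- numeric(B)
      R <- matrix(0, nrow(Y), B)
      for (b in seq_len(B)) {
        yb <- Y[, b]
        obj <- function(th)
          sum(((yb - model$predict(th, design)) / sigma)^2)
        res <- scalar_search_fit(obj, model$bounds, options)
        Theta[b] <- res$theta
        rb <- yb - model$predict(res$theta, design)
        R[, b] <- rb
        chi2[b] <- sum((rb / sigma)^2)
      }
      list(theta = matrix(Theta, 1, B), resid = R, chi2 = chi2)
    }
  )
}

#' Wrap an ODE right-hand side as a predictor model
#'
#' Convenience constructor for user models whose predictions require numeric
#' integration (uses \pkg{deSolve}). The built-in dynamic test cases do not
#' use this route: their exact solutions are available.
#'
#' @param model_id name; @param n_params parameter count.
#' @param rhs function `(t, x, theta) -> list(dxdt)` as in
#'   [deSolve::ode()] (with `theta` passed via `parms`).
#' @param x0 function `theta -> initial state` (or a fixed numeric vector).
#' @param observe function `(x_matrix, theta) -> numeric` mapping the state
#'   trajectory (rows = time points) to the observed output; defaults to the
#'   first state.
#' @param bounds,fit_strategy passed to [predictor_model()].
#' @param rtol,atol integration tolerances.
#' @return A [predictor_model()].
#' @export
ode_model <- function(model_id, n_params, rhs, x0,
                      observe = function(x, theta) x[, 1],
                      bounds = NULL, fit_strategy = "scalar_search",
                      rtol = 1e-8, atol = 1e-10) {
  if (!requireNamespace("deSolve", quietly = TRUE))
    stop("ode_model() requires the deSolve package")
  init <- if (is.function(x0)) x0 else function(theta) x0
  predict <- function(theta, design) {
    tt <- design$coordinate
    times <- sort(unique(c(0, tt)))
    sol <- deSolve::ode(y = init(theta), times = times, func = rhs,
                        parms = theta, rtol = rtol, atol = atol)
    if (any(!is.finite(sol)))
      stop("ODE integration of '", model_id, "' failed (non-finite state) ",
           "at theta = (", paste(signif(theta, 6), collapse = ", "), ")")
    x <- sol[match(tt, sol[, 1]), -1, drop = FALSE]
    observe(x, theta)
  }
  predictor_model(model_id, n_params, predict, fit_strategy = fit_strategy,
                  bounds = bounds)
}
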