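# Derive a per-purpose RNG seed from a base seed and integer keys.
# Kept below 2^31 - 1; doubles are exact here (products < 2^53).
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Generate parametric bootstrap samples
#'
#' Under the null hypothesis that the (fitted) model is true, each bootstrap
#' sample is the model's noise-free simulation at `theta_hat` plus i.i.d.
#' Gaussian noise with the stated per-point standard deviation -- a new
#' realization of the noise on the same signals and coordinates as the
#' observed data. Each sample has its own RNG stream keyed by the base seed
#' and the sample index, so results are reproducible and independent of
#' evaluation order.
#'
#' @param model a [predictor_model()].
#' @param theta_hat parameter vector used for simulation (normally the fit
#'   to the observed data).
#' @param design a [gof_design()] or [gof_dataset()] (design and, if absent
#'   in `sigma`, noise levels are taken from it).
#' @param sigma per-point noise sd (scalar recycled); defaults to the
#'   dataset's sigma when `design` is a dataset.
#' @param B number of samples (cloud size); default 1000.
#' @param seed integer base seed.
#' @return An object of class `boot_samples`: list with the `n x B` value
#'   matrix `Y`, the design, `sigma`, and generator metadata.
#' @examples
#' ds <- make_fixture("dynamic", "MD1", seed = 1)
#' bs <- boot_samples(builtin_models("MD1"), 0.7, ds, B = 10, seed = 1)
#' @export
boot_samples <- function(model, theta_hat, design, sigma = NULL,
                         B = 1000L, seed = 1L) {
  if (inherits(design, "gof_dataset")) {
    if (is.null(sigma)) sigma <- design$sigma
    design <- design$design
  }
  if (!inherits(design, "gof_design")) design <- gof_design(design)
  stopifnot(B >= 1)
  sigma <- rep_len(as.numeric(sigma), nrow(design))
  if (any(sigma < 0)) stop("sigma must be non-negative")
  yhat <- simulate_model(model, theta_hat, design)
  n <- nrow(design)
  Y <- matrix(0, n, B)
  for (b in seq_len(B)) {
    eps <- withr::with_seed(derive_seed(seed, 1L, b), stats::rnorm(n))
    Y[, b] <- yhat + sigma * eps
  }
  structure(list(Y = Y, design = design, sigma = sigma,
                 meta = list(model_id = model$model_id,
                             theta = as.numeric(theta_hat),
                             seed = as.integer(seed), B = as.integer(B))),
            class = "boot_samples")
}

#' @export
print.boot_samples <- function(x, ...) {
  cat("<boot_samples> B = ", x$meta$B, " samples from ", x$meta$model_id,
      " on ", nrow(x$design), " points (seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' Convert bootstrap samples to a list of datasets
#'
#' @param samples a [boot_samples()] object.
#' @return list of [gof_dataset()] with provenance kind `"bootstrap"`.
#' @export
as_datasets <- function(samples) {
  stopifnot(inherits(samples, "boot_samples"))
  lapply(seq_len(ncol(samples$Y)), function(b)
    gof_dataset(samples$design, samples$Y[, b], samples$sigma,
                provenance = c(list(kind = "bootstrap", sample_index = b),
                               samples$meta)))
}

cloud_statistics <- c("chi2", "dw", "chi2_2", "dw_2", "lhr", "lhp")

#' Build a cloud of goodness-of-fit statistic vectors
#'
#' Fits every listed model to every bootstrap sample (each fit independent)
#' and evaluates the requested statistics on each fit, giving the `B x k`
#' empirical joint null distribution ("cloud") of the statistic vector.
#'
#' Statistic names: `"chi2"` and `"dw"` refer to the first fitted model,
#' `"chi2_2"`/`"dw_2"` to the second, and `"lhr"`/`"lhp"` are the
#' difference/sum of the two models' chi-squares (both models required).
#'
#' @param samples a [boot_samples()] object (or list of [gof_dataset()]
#'   sharing one design and sigma).
#' @param models list of one or two [predictor_model()]s to refit.
#' @param statistics character vector of statistic names (the cloud columns).
#' @param options [fit_options()] used for every refit.
#' @param fail_policy `"drop"` (drop samples whose fit produced non-finite
#'   statistics, hard error above `max_fail_frac`) or `"error"`.
#' @param max_fail_frac maximum tolerated dropped fraction (default 0.01).
#' @return An object of class `boot_cloud`: list with `stats` (`B x k`
#'   matrix, named columns), `fitted_models`, `meta`.
#' @export
build_cloud <- function(samples, models, statistics = c("chi2", "dw"),
                        options = fit_options(), fail_policy = c("drop", "error"),
                        max_fail_frac = 0.01) {
  fail_policy <- match.arg(fail_policy)
  if (inherits(samples, "gof_dataset")) samples <- list(samples)
  if (is.list(samples) && !inherits(samples, "boot_samples")) {
    Y <- vapply(samples, function(d) d$value, numeric(length(samples[[1]]$value)))
    design <- samples[[1]]$design
    sigma <- samples[[1]]$sigma
    meta <- list(B = length(samples))
  } else {
    Y <- samples$Y; design <- samples$design; sigma <- samples$sigma
    meta <- samples$meta
  }
  if (inherits(models, "predictor_model")) models <- list(models)
  bad <- setdiff(statistics, cloud_statistics)
  if (length(bad))
    stop("unknown statistic(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(cloud_statistics, collapse = ", "))
  needs2 <- any(statistics %in% c("chi2_2", "dw_2", "lhr", "lhp"))
  if (needs2 && length(models) < 2L)
    stop("statistics ", paste(intersect(statistics, c("chi2_2", "dw_2", "lhr", "lhp")),
                              collapse = ", "), " need two models")
  fits <- lapply(models[seq_len(if (needs2) 2L else 1L)],
                 fit_model_batch, Y = Y, design = design, sigma = sigma,
                 options = options)
  sig <- design$signal_id
  col_of <- function(name) {
    switch(name,
      chi2   = fits[[1]]$chi2,
      dw     = dw_statistic_cols(fits[[1]]$resid, sig),
      chi2_2 = fits[[2]]$chi2,
      dw_2   = dw_statistic_cols(fits[[2]]$resid, sig),
      lhr    = lhr_statistic(fits[[1]]$chi2, fits[[2]]$chi2),
      lhp    = lhp_statistic(fits[[1]]$chi2, fits[[2]]$chi2))
  }
  stats_mat <- vapply(statistics, col_of, numeric(ncol(Y)))
  if (length(statistics) == 1L) stats_mat <- matrix(stats_mat, ncol = 1)
  colnames(stats_mat) <- statistics
  ok <- apply(is.finite(stats_mat), 1, all)
  if (any(!ok)) {
    if (fail_policy == "error")
      stop(sum(!ok), " bootstrap fit(s) produced non-finite statistics")
    frac <- mean(!ok)
    if (frac > max_fail_frac)
      stop("dropped fraction of failed fits (", signif(frac, 3),
           ") exceeds ", max_fail_frac, ": cloud unrepresentative")
    warning("dropped ", sum(!ok), " bootstrap sample(s) with failed fits")
    stats_mat <- stats_mat[ok, , drop = FALSE]
  }
  structure(list(stats = stats_mat,
                 fitted_models = vapply(models, `[[`, "", "model_id"),
                 meta = meta),
            class = "boot_cloud")
}

#' @export
print.boot_cloud <- function(x, ...) {
  cat("<boot_cloud> ", nrow(x$stats), " x ", ncol(x$stats), " [",
      paste(colnames(x$stats), collapse = ", "), "] from model(s) ",
      paste(x$fitted_models, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write / read a cloud as CSV (statistics) with a JSON metadata sidecar
#'
#' @param cloud a `boot_cloud`; @param path CSV path (sidecar gets
#'   `.json` appended).
#' @return `write_cloud()` the path, invisibly; `read_cloud()` a
#'   `boot_cloud`.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "boot_cloud"))
  utils::write.csv(as.data.frame(cloud$stats), path, row.names = FALSE)
  jsonlite::write_json(list(fitted_models = cloud$fitted_models,
                            meta = cloud$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  stats_mat <- as.matrix(utils::read.csv(path))
  side <- paste0(path, ".json")
  info <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(fitted_models = character(0), meta = list())
  structure(list(stats = stats_mat, fitted_models = info$fitted_models,
                 meta = info$meta),
            class = "boot_cloud")
}
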