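#' Empirical p-value from a one-dimensional bootstrap distribution
#'
#' The empirical CDF `F` is interpolated linearly between order statistics
#' (plotting positions `i / (B + 1)`), so an observed value outside the
#' cloud range is clamped to `[1/(B+1), 1 - 1/(B+1)]`, keeping log-p finite.
#' Tails:
#' * `"right"`: `1 - F(observed)` (large statistic = bad fit; chi-square),
#' * `"left"`: `F(observed)` (small statistic = bad fit; Durbin-Watson with
#'   only positive autocorrelation of interest),
#' * `"two"`: `2 * min(F, 1 - F)`, capped at 1,
#' * `"density"`: fraction of cloud points whose 1D Gaussian-kernel density
#'   is below the density at the observed value (the 1D analogue of the 2D
#'   highest-density-region p-value).
#'
#' @param cloud_column numeric vector: bootstrap values of one statistic.
#' @param observed the observed statistic.
#' @param tail tail mode, see above.
#' @return p-value in `[0, 1]`.
#' @examples
#' empirical_p1d(1:100, 90.5, "right")  # about 0.10
#' @export
empirical_p1d <- function(cloud_column, observed,
                          tail = c("right", "left", "two", "density")) {
  tail <- match.arg(tail)
  x <- as.numeric(cloud_column)
  x <- x[is.finite(x)]
  B <- length(x)
  if (B == 0L) stop("empty (or all non-finite) cloud column")
  if (B < 50L)
    warning("cloud column has only ", B,
            " values; empirical p-values will be coarse")
  if (!is.finite(observed)) stop("observed statistic must be finite")
  if (tail == "density") {
    h <- silverman_bw(x)
    if (!is.finite(h)) stop("cloud column has zero spread")
    d_obs <- kde1_eval(x, h, observed)
    p <- mean(kde1_eval(x, h, x) < d_obs)
    return(max(p, 1 / (B + 1)))
  }
  xs <- sort(x)
  pp <- seq_len(B) / (B + 1)
  Fo <- stats::approx(xs, pp, xout = observed, rule = 2, ties = "ordered")$y
  p <- switch(tail,
              right = 1 - Fo,
              left = Fo,
              two = min(1, 2 * min(Fo, 1 - Fo)))
  min(max(p, 1 / (B + 1)), if (tail == "two") 1 else 1 - 1 / (B + 1))
}

new_test_result <- function(test_name, p_value, observed_stats, tail,
                            alpha, cloud_ref = NULL, warnings = character(0)) {
  structure(list(test_name = test_name, p_value = p_value,
                 observed_stats = observed_stats, tail = tail,
                 alpha = alpha, rejected = p_value < alpha,
                 cloud_ref = cloud_ref, warnings = warnings),
            class = "gof_test_result")
}

#' @export
print.gof_test_result <- function(x, ...) {
  cat("<gof_test_result> ", x$test_name, ": p = ", format(signif(x$p_value, 4)),
      " (", x$tail, "-tail, alpha = ", x$alpha, ") -> ",
      if (x$rejected) "REJECT H0" else "no rejection", "\n", sep = "")
  if (length(x$observed_stats))
    cat("  observed: ",
        paste(names(x$observed_stats), signif(unlist(x$observed_stats), 5),
              sep = " = ", collapse = ", "), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' @param result a `gof_test_result`; @param path optional file path; if
#'   omitted the JSON string is returned.
#' @export
write_test_result <- function(result, path = NULL) {
  stopifnot(inherits(result, "gof_test_result"))
  obj <- unclass(result)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# shared pipeline: fit observed data, sample, build cloud
test_pipeline <- function(models, dataset, statistics, B, seed, options) {
  fits <- lapply(models, fit_model, dataset = dataset, options = options)
  h0_fit <- fits[[1]]
  refit_opts <- options
  refit_opts$extra_starts <- c(options$extra_starts,
                               if (models[[1]]$fit_strategy == "scalar_search")
                                 h0_fit$theta_hat)
  samples <- boot_samples(models[[1]], h0_fit$theta_hat, dataset,
                          B = B, seed = seed)
  cloud <- build_cloud(samples, models, statistics, options = refit_opts)
  list(fits = fits, samples = samples, cloud = cloud)
}

#' Bootstrapped one-dimensional chi-square and Durbin-Watson tests
#'
#' Full pipeline: fit the model to the data, generate `B` parametric
#' bootstrap samples from the fitted model, refit the model to every sample,
#' and locate the observed statistic in the resulting empirical
#' distribution. Default tails follow standard usage: right-tailed for
#' chi-square (reject residuals that are too big) and left-tailed for
#' Durbin-Watson (reject residuals that are too positively correlated).
#'
#' @param model a [predictor_model()] (the null hypothesis).
#' @param dataset a [gof_dataset()].
#' @param B cloud size; @param seed base seed; @param alpha significance
#'   level; @param tail tail mode for [empirical_p1d()].
#' @param options [fit_options()].
#' @return A `gof_test_result`.
#' @export
chi2_test <- function(model, dataset, B = 1000L, seed = 1L, alpha = 0.05,
                      tail = "right", options = fit_options()) {
  pl <- test_pipeline(list(model), dataset, "chi2", B, seed, options)
  p <- empirical_p1d(pl$cloud$stats[, "chi2"], pl$fits[[1]]$chi2, tail)
  new_test_result("chi2", p, list(chi2 = pl$fits[[1]]$chi2), tail, alpha,
                  cloud_ref = pl$cloud$meta)
}

#' @rdname chi2_test
#' @export
dw_test <- function(model, dataset, B = 1000L, seed = 1L, alpha = 0.05,
                    tail = "left", options = fit_options()) {
  pl <- test_pipeline(list(model), dataset, c("chi2", "dw"), B, seed, options)
  dw_obs <- dw_statistic(pl$fits[[1]]$residuals, dataset$design$signal_id)
  p <- empirical_p1d(pl$cloud$stats[, "dw"], dw_obs, tail)
  new_test_result("dw", p, list(dw = dw_obs), tail, alpha,
                  cloud_ref = pl$cloud$meta)
}

#' Simplistic combinations of two bootstrapped p-values
#'
#' The four naive ways of merging a chi-square p-value and a Durbin-Watson
#' p-value into one: `min` (reject if either test rejects), `max` (reject
#' only if both reject), the arithmetic `mean`, and the `prod`uct (the
#' "joint probability"). None of these is a calibrated p-value -- `min` and
#' `prod` are strikingly liberal and `max` highly conservative -- and they
#' are provided for demonstration only; output is flagged accordingly.
#'
#' @param p_chi2,p_dw p-values in `[0, 1]`.
#' @return named list `p_min`, `p_max`, `p_mean`, `p_prod`, with attribute
#'   `note = "demonstration-only: unsound"`.
#' @export
combine_simplistic <- function(p_chi2, p_dw) {
  stopifnot(p_chi2 >= 0, p_chi2 <= 1, p_dw >= 0, p_dw <= 1)
  structure(list(p_min = min(p_chi2, p_dw),
                 p_max = max(p_chi2, p_dw),
                 p_mean = (p_chi2 + p_dw) / 2,
                 p_prod = p_chi2 * p_dw),
            note = "demonstration-only: unsound")
}

#' Bootstrapped two-dimensional joint-density test
#'
#' The joint test of a model against a second goodness-of-fit axis:
#'
#' 1. Fit the model to the data; compute the observed statistic pair.
#' 2. Generate `B` parametric bootstrap samples from the fitted model (H0).
#' 3. Refit the model(s) to every sample and form the 2D cloud: chi-square
#'    vs Durbin-Watson (`second = "dw"`), or chi-square vs the chi-square of
#'    a second (help or competing) model (`second = <predictor_model>`).
#' 4. Estimate the cloud's 2D kernel density over a grid; the cutoff is the
#'    equidensity contour through the observed pair.
#' 5. The p-value is the probability mass at density below the observed
#'    density ([p_value_2d()]); reject if below `alpha`.
#'
#' With a competing second model, `h0 = "both"` repeats the procedure with
#' each model serving as H0 (two results: each, either or both models can
#' be rejected).
#'
#' @param model a [predictor_model()] under test (H0 for `h0 = "model1"`).
#' @param dataset a [gof_dataset()].
#' @param second `"dw"` or a second [predictor_model()].
#' @param h0 `"model1"` or `"both"` (the latter only with a model `second`).
#' @param grid_n,bw passed to [kde2d_cloud()].
#' @inheritParams chi2_test
#' @return A `gof_test_result`, or a list of two (one per H0) for
#'   `h0 = "both"`.
#' @export
gof2d_test <- function(model, dataset, second = "dw", B = 1000L, seed = 1L,
                       alpha = 0.05, grid_n = 128L, bw = NULL,
                       h0 = c("model1", "both"), options = fit_options()) {
  h0 <- match.arg(h0)
  use_dw <- identical(second, "dw")
  if (!use_dw && !inherits(second, "predictor_model"))
    stop("'second' must be \"dw\" or a predictor_model")
  if (h0 == "both") {
    if (use_dw) stop("h0 = \"both\" needs a second model, not \"dw\"")
    return(list(
      gof2d_test(model, dataset, second, B, seed, alpha, grid_n, bw,
                 "model1", options),
      gof2d_test(second, dataset, model, B, seed, alpha, grid_n, bw,
                 "model1", options)))
  }
  models <- if (use_dw) list(model) else list(model, second)
  stat_names <- if (use_dw) c("chi2", "dw") else c("chi2", "chi2_2")
  pl <- test_pipeline(models, dataset, stat_names, B, seed, options)
  obs <- if (use_dw)
    c(pl$fits[[1]]$chi2,
      dw_statistic(pl$fits[[1]]$residuals, dataset$design$signal_id))
  else c(pl$fits[[1]]$chi2, pl$fits[[2]]$chi2)
  warn <- character(0)
  grid <- withCallingHandlers(
    kde2d_cloud(pl$cloud, grid_n = grid_n, bw = bw),
    bootgof_collapsed_cloud = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  p <- p_value_2d(grid, obs)
  name <- if (use_dw) "2d_chi2_dw"
          else paste0("2d_chi2_chi2[h0=", model$model_id, "]")
  res <- new_test_result(name, p,
                         stats::setNames(as.list(obs), stat_names),
                         "density", alpha, cloud_ref = pl$cloud$meta,
                         warnings = warn)
  res$grid <- grid
  res
}

#' Bootstrapped log-likelihood-ratio test for two (non-nested) models
#'
#' Builds the empirical distribution of the chi-square difference
#' `chi2(model1) - chi2(model2)` by sampling from the chosen H0 model and
#' refitting both models to every sample, then locates the observed LHR in
#' it with a two-tailed empirical p-value. The models need not be nested.
#'
#' @param model1,model2 [predictor_model()]s.
#' @param h0 which model generates the bootstrap samples: `"model1"`,
#'   `"model2"`, or `"both"` (a list of two results).
#' @inheritParams chi2_test
#' @return A `gof_test_result` (or list of two for `h0 = "both"`).
#' @export
lhr_test <- function(model1, model2, dataset, h0 = c("model1", "model2", "both"),
                     B = 1000L, seed = 1L, alpha = 0.05, tail = "two",
                     options = fit_options()) {
  h0 <- match.arg(h0)
  if (h0 == "both")
    return(list(
      lhr_test(model1, model2, dataset, "model1", B, seed, alpha, tail, options),
      lhr_test(model1, model2, dataset, "model2", B, seed, alpha, tail, options)))
  models <- if (h0 == "model1") list(model1, model2) else list(model2, model1)
  pl <- test_pipeline(models, dataset, c("chi2", "chi2_2"), B, seed, options)
  chi2_1 <- if (h0 == "model1") pl$fits[[1]]$chi2 else pl$fits[[2]]$chi2
  chi2_2 <- if (h0 == "model1") pl$fits[[2]]$chi2 else pl$fits[[1]]$chi2
  obs <- lhr_statistic(chi2_1, chi2_2)
  lhr_cloud <- if (h0 == "model1")
    lhr_statistic(pl$cloud$stats[, "chi2"], pl$cloud$stats[, "chi2_2"])
  else lhr_statistic(pl$cloud$stats[, "chi2_2"], pl$cloud$stats[, "chi2"])
  warn <- character(0)
  if (is_collapsed(pl$cloud$stats[, "chi2_2"]) ||
      is_collapsed(pl$cloud$stats[, "chi2"]))
    warn <- paste("one model's bootstrap chi-square is constant (e.g. a",
                  "hyper-flexible help model): the LHR distribution is just",
                  "the other model's (sign-flipped) chi-square distribution")
  p <- empirical_p1d(lhr_cloud, obs, tail)
  new_test_result(paste0("lhr[h0=", models[[1]]$model_id, "]"), p,
                  list(lhr = obs, chi2_m1 = chi2_1, chi2_m2 = chi2_2),
                  tail, alpha, cloud_ref = pl$cloud$meta, warnings = warn)
}
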