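all_eval_tests <- c("chi2", "dw", "min", "max", "mean", "prod",
                    "2d_chi2_dw", "2d_chi2_chi2", "lhr", "lhp")

#' Define an evaluation scenario
#'
#' A scenario is the benchmark design used to measure soundness and power:
#' each of two models in turn serves as the data-generating truth for
#' `n_datasets` noisy replicate datasets; every dataset is then tested with
#' each model serving as H0, by every configured test. With both models as
#' truth and as H0 this yields `2 * n_datasets` true-H0 p-values (false
#' positives when rejected) and `2 * n_datasets` false-H0 p-values (true
#' positives when rejected) per test.
#'
#' @param models list of exactly two [predictor_model()]s.
#' @param true_params list of two parameter vectors (truth for each model).
#' @param design a [gof_design()].
#' @param sigma noise sd (scalar or per point).
#' @param tests character subset of
#'   `c("chi2","dw","min","max","mean","prod","2d_chi2_dw","2d_chi2_chi2",`
#'   `"lhr","lhp")`.
#' @param n_datasets replicate datasets per true model (>= 10).
#' @param B bootstrap cloud size.
#' @param base_seed integer seed from which all dataset and bootstrap
#'   streams are derived.
#' @param grid_n KDE grid size for the 2D tests.
#' @param options [fit_options()] for every fit.
#' @return list of class `gof_scenario`.
#' @export
gof_scenario <- function(models, true_params, design, sigma,
                         tests = all_eval_tests, n_datasets = 500L,
                         B = 1000L, base_seed = 1L, grid_n = 128L,
                         options = fit_options()) {
  stopifnot(length(models) == 2L, length(true_params) == 2L)
  if (n_datasets < 10L) stop("n_datasets must be >= 10")
  bad <- setdiff(tests, all_eval_tests)
  if (length(bad)) stop("unknown test(s): ", paste(bad, collapse = ", "))
  if (!inherits(design, "gof_design")) design <- gof_design(design)
  sigma <- rep_len(as.numeric(sigma), nrow(design))
  if (any(sigma <= 0)) stop("sigma must be positive")
  structure(list(models = models, true_params = true_params, design = design,
                 sigma = sigma, tests = tests,
                 n_datasets = as.integer(n_datasets), B = as.integer(B),
                 base_seed = as.integer(base_seed), grid_n = as.integer(grid_n),
                 options = options),
            class = "gof_scenario")
}

# All configured tests evaluated from one (dataset, H0) cloud. The fits of
# both models to the observed data and to the common bootstrap samples are
# shared across tests: cheaper and statistically identical to separate runs.
eval_tests_from_cloud <- function(cloud, fits, h0_idx, dataset, tests, grid_n) {
  other <- 3L - h0_idx
  chi2_obs <- fits[[h0_idx]]$chi2
  stats_mat <- cloud$stats
  out <- list()
  need_dw <- any(tests %in% c("dw", "min", "max", "mean", "prod", "2d_chi2_dw"))
  if (need_dw) {
    dw_obs <- dw_statistic(fits[[h0_idx]]$residuals, dataset$design$signal_id)
    p_dw <- empirical_p1d(stats_mat[, "dw"], dw_obs, "left")
  }
  p_chi2 <- empirical_p1d(stats_mat[, "chi2"], chi2_obs, "right")
  if ("chi2" %in% tests) out$chi2 <- p_chi2
  if ("dw" %in% tests) out$dw <- p_dw
  if (any(tests %in% c("min", "max", "mean", "prod"))) {
    comb <- combine_simplistic(p_chi2, p_dw)
    if ("min" %in% tests) out$min <- comb$p_min
    if ("max" %in% tests) out$max <- comb$p_max
    if ("mean" %in% tests) out$mean <- comb$p_mean
    if ("prod" %in% tests) out$prod <- comb$p_prod
  }
  if ("2d_chi2_dw" %in% tests) {
    grid <- suppressWarnings(kde2d_cloud(stats_mat[, c("chi2", "dw")],
                                         grid_n = grid_n))
    out$`2d_chi2_dw` <- p_value_2d(grid, c(chi2_obs, dw_obs))
  }
  if (any(tests %in% c("2d_chi2_chi2", "lhr", "lhp"))) {
    chi2_obs2 <- fits[[other]]$chi2
    if ("2d_chi2_chi2" %in% tests) {
      grid <- suppressWarnings(kde2d_cloud(stats_mat[, c("chi2", "chi2_2")],
                                           grid_n = grid_n))
      out$`2d_chi2_chi2` <- p_value_2d(grid, c(chi2_obs, chi2_obs2))
    }
    if ("lhr" %in% tests)
      out$lhr <- empirical_p1d(
        lhr_statistic(stats_mat[, "chi2"], stats_mat[, "chi2_2"]),
        lhr_statistic(chi2_obs, chi2_obs2), "two")
    if ("lhp" %in% tests)
      out$lhp <- empirical_p1d(
        lhp_statistic(stats_mat[, "chi2"], stats_mat[, "chi2_2"]),
        lhp_statistic(chi2_obs, chi2_obs2), "two")
  }
  out
}

#' Run an evaluation scenario
#'
#' Simulates the replicate datasets, runs every configured test with each
#' model as H0, and assembles the long-format p-value matrix from which
#' [roc_curve()] and [type1_calibration()] summaries are computed.
#'
#' @param scenario a [gof_scenario()].
#' @param progress print a line per true model/dataset block.
#' @return An object of class `gof_evaluation`: list with `p_matrix` (data
#'   frame: `dataset`, `truth`, `h0`, `test`, `p`, `h0_true`), the scenario,
#'   and `failures` (count of hard test failures, recorded per cell as NA).
#' @export
run_scenario <- function(scenario, progress = FALSE) {
  stopifnot(inherits(scenario, "gof_scenario"))
  sc <- scenario
  needs2 <- any(sc$tests %in% c("2d_chi2_chi2", "lhr", "lhp"))
  stat_names <- c("chi2",
                  if (any(sc$tests %in% c("dw", "min", "max", "mean", "prod",
                                          "2d_chi2_dw"))) "dw",
                  if (needs2) "chi2_2")
  rows <- list()
  n_fail <- 0L
  for (t_idx in 1:2) {
    truth <- sc$models[[t_idx]]
    y_true <- simulate_model(truth, sc$true_params[[t_idx]], sc$design)
    n <- nrow(sc$design)
    for (d in seq_len(sc$n_datasets)) {
      if (progress && d %% 50L == 1L)
        message("truth ", truth$model_id, ", dataset ", d, "/", sc$n_datasets)
      data_seed <- derive_seed(sc$base_seed, 2L, t_idx, d)
      y <- y_true + sc$sigma * withr::with_seed(data_seed, stats::rnorm(n))
      ds <- gof_dataset(sc$design, y, sc$sigma,
                        provenance = list(kind = "synthetic",
                                          true_model = truth$model_id,
                                          seed = data_seed))
      fits <- lapply(sc$models, fit_model, dataset = ds, options = sc$options)
      for (h0_idx in 1:2) {
        models_h0 <- if (h0_idx == 1L) sc$models else rev(sc$models)
        fits_h0 <- if (h0_idx == 1L) fits else rev(fits)
        boot_seed <- derive_seed(sc$base_seed, 3L, t_idx, d, h0_idx)
        refit_opts <- sc$options
        if (models_h0[[1]]$fit_strategy == "scalar_search" ||
            (needs2 && models_h0[[2]]$fit_strategy == "scalar_search"))
          refit_opts$extra_starts <- c(sc$options$extra_starts,
                                       unlist(lapply(fits_h0, `[[`, "theta_hat")))
        ps <- tryCatch({
          samples <- boot_samples(models_h0[[1]], fits_h0[[1]]$theta_hat, ds,
                                  B = sc$B, seed = boot_seed)
          cloud <- build_cloud(samples, models_h0, stat_names,
                               options = refit_opts)
          eval_tests_from_cloud(cloud, fits_h0, 1L, ds, sc$tests, sc$grid_n)
        }, error = function(e) {
          n_fail <<- n_fail + 1L
          stats::setNames(as.list(rep(NA_real_, length(sc$tests))), sc$tests)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = d, truth = truth$model_id,
          h0 = models_h0[[1]]$model_id,
          test = names(ps), p = unlist(ps, use.names = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  p_matrix <- do.call(rbind, rows)
  p_matrix$h0_true <- p_matrix$truth == p_matrix$h0
  total_cells <- 2L * sc$n_datasets * 2L
  if (n_fail / total_cells > 0.05)
    stop("more than 5% of test cells failed (", n_fail, "/", total_cells, ")")
  structure(list(p_matrix = p_matrix, scenario = sc, failures = n_fail),
            class = "gof_evaluation")
}

#' @export
print.gof_evaluation <- function(x, ...) {
  cat("<gof_evaluation> ", nrow(x$p_matrix), " p-values: ",
      x$scenario$n_datasets, " datasets/truth, B = ", x$scenario$B,
      ", tests: ", paste(x$scenario$tests, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract true-H0 / false-H0 p-values for one test
#'
#' @param evaluation a [run_scenario()] result; @param test test name.
#' @return list with `p_true_h0` and `p_false_h0` numeric vectors.
#' @export
p_values_by_truth <- function(evaluation, test) {
  pm <- evaluation$p_matrix
  pm <- pm[pm$test == test & is.finite(pm$p), ]
  list(p_true_h0 = pm$p[pm$h0_true], p_false_h0 = pm$p[!pm$h0_true])
}

#' ROC curve and partial AUC of a test's p-values
#'
#' A rejection at level `alpha` is `p < alpha`. The false positive rate is
#' the rejection rate among true-H0 p-values, the true positive rate among
#' false-H0 p-values; the curve is evaluated at every distinct p-value plus
#' a fixed alpha grid. The partial AUC integrates the curve (trapezoid rule)
#' over FPR in `[0, fpr_limit]` and is normalized by `fpr_limit`; an
#' uninformative test (ROC on the identity line) gives about
#' `fpr_limit / 2`, i.e. 0.05 at the default limit, and a perfect test 1.
#'
#' @param p_false_h0 p-values obtained when H0 is false (should be small).
#' @param p_true_h0 p-values obtained when H0 is true (should be uniform).
#' @param fpr_limit upper FPR bound of the partial AUC (default 0.1, the
#'   practically relevant region).
#' @return list of class `gof_roc`: data frame `curve` (`threshold`, `fpr`,
#'   `tpr`), `pauc` (normalized partial AUC), `auc` (full).
#' @export
roc_curve <- function(p_false_h0, p_true_h0, fpr_limit = 0.1) {
  stopifnot(length(p_false_h0) > 0, length(p_true_h0) > 0)
  thr <- sort(unique(c(0, 10^seq(-4, 0, length.out = 81),
                       p_false_h0, p_true_h0, 1, 1.000001)))
  fpr <- vapply(thr, function(a) mean(p_true_h0 < a), numeric(1))
  tpr <- vapply(thr, function(a) mean(p_false_h0 < a), numeric(1))
  curve <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc <- trapz(fpr, tpr)
  tpr_at <- function(f0) stats::approx(fpr, tpr, xout = f0, ties = max,
                                       rule = 2)$y
  keep <- fpr <= fpr_limit
  fx <- c(fpr[keep], fpr_limit)
  fy <- c(tpr[keep], tpr_at(fpr_limit))
  o <- order(fx, fy)
  pauc <- trapz(fx[o], fy[o]) / fpr_limit
  structure(list(curve = curve, pauc = pauc, auc = auc,
                 fpr_limit = fpr_limit),
            class = "gof_roc")
}

#' @export
print.gof_roc <- function(x, ...) {
  cat("<gof_roc> AUC = ", format(signif(x$auc, 4)), ", partial AUC (FPR < ",
      x$fpr_limit, ", normalized) = ", format(signif(x$pauc, 4)), "\n",
      sep = "")
  invisible(x)
}

#' Type-I-error calibration of true-H0 p-values
#'
#' For each significance level alpha the observed false positive rate (the
#' fraction of true-H0 p-values below alpha) is compared to alpha inside an
#' exact binomial band. The verdict is `"liberal"` if the observed rate
#' exceeds the band anywhere (too many false rejections -- unacceptable),
#' `"conservative"` if it only falls below it, and `"sound"` otherwise.
#'
#' @param p_true_h0 p-values under a true H0.
#' @param alphas significance levels evaluated.
#' @param level coverage of the binomial band (default 0.99).
#' @return list of class `gof_calibration`: data frame `curve`
#'   (`alpha`, `observed_fpr`, `lower`, `upper`), and `verdict`.
#' @export
type1_calibration <- function(p_true_h0,
                              alphas = c(0.01, 0.025, 0.05, 0.1, 0.2),
                              level = 0.99) {
  p <- p_true_h0[is.finite(p_true_h0)]
  stopifnot(length(p) > 0)
  n <- length(p)
  obs <- vapply(alphas, function(a) mean(p < a), numeric(1))
  lo <- stats::qbinom((1 - level) / 2, n, alphas) / n
  hi <- stats::qbinom(1 - (1 - level) / 2, n, alphas) / n
  verdict <- if (any(obs > hi)) "liberal"
             else if (any(obs < lo)) "conservative"
             else "sound"
  structure(list(curve = data.frame(alpha = alphas, observed_fpr = obs,
                                    lower = lo, upper = hi),
                 n = n, verdict = verdict),
            class = "gof_calibration")
}

#' @export
print.gof_calibration <- function(x, ...) {
  cat("<gof_calibration> n = ", x$n, ", verdict: ", x$verdict, "\n", sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Summarize an evaluation: partial AUC and calibration per test
#'
#' @param object a `gof_evaluation`; @param fpr_limit partial-AUC limit;
#'   @param ... unused.
#' @return data frame with one row per test: `test`, `pauc`, `auc`,
#'   `fpr_at_05` (observed FPR at alpha = 0.05), `verdict`.
#' @export
summary.gof_evaluation <- function(object, fpr_limit = 0.1, ...) {
  tests <- object$scenario$tests
  rows <- lapply(tests, function(te) {
    pv <- p_values_by_truth(object, te)
    roc <- roc_curve(pv$p_false_h0, pv$p_true_h0, fpr_limit)
    cal <- type1_calibration(pv$p_true_h0)
    data.frame(test = te, pauc = roc$pauc, auc = roc$auc,
               fpr_at_05 = mean(pv$p_true_h0 < 0.05),
               verdict = cal$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an evaluation to CSV (+ JSON summary sidecar)
#'
#' @param evaluation a `gof_evaluation`; @param path CSV path for the long
#'   p-matrix; a JSON summary is written next to it.
#' @export
write_evaluation <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "gof_evaluation"))
  utils::write.csv(evaluation$p_matrix, path, row.names = FALSE)
  sm <- summary(evaluation)
  jsonlite::write_json(
    list(summary = sm,
         n_datasets = evaluation$scenario$n_datasets,
         B = evaluation$scenario$B,
         base_seed = evaluation$scenario$base_seed,
         tests = evaluation$scenario$tests,
         failures = evaluation$failures),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
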