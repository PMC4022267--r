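#' Residuals of a prediction
#'
#' @param dataset a [gof_dataset()].
#' @param predicted numeric vector of predictions matching the design.
#' @return numeric vector `y - yhat`, order-preserving.
#' @export
gof_residuals <- function(dataset, predicted) {
  stopifnot(inherits(dataset, "gof_dataset"))
  predicted <- as.numeric(predicted)
  if (length(predicted) != length(dataset$value))
    stop("predicted length [", length(predicted),
         "] does not match dataset [", length(dataset$value), "]")
  dataset$value - predicted
}

#' Chi-square goodness-of-fit statistic
#'
#' Weighted residual sum of squares `sum(((y - yhat)/sigma)^2)` over all
#' points and all signals, with the per-point noise level `sigma` treated
#' as known.
#'
#' @inheritParams gof_residuals
#' @return non-negative scalar.
#' @examples
#' ds <- gof_dataset(0:2, value = c(1, 2, 3), sigma = 1)
#' chi2_statistic(ds, c(0, 0, 0))  # 1 + 4 + 9 = 14
#' @export
chi2_statistic <- function(dataset, predicted) {
  r <- gof_residuals(dataset, predicted)
  if (any(dataset$sigma <= 0)) stop("all sigma must be positive")
  sum((r / dataset$sigma)^2)
}

#' Durbin-Watson statistic of residual autocorrelation
#'
#' `sum(diff(r)^2) / sum(r^2)`, with adjacent differences taken within each
#' signal only (never across signal boundaries) and the denominator over all
#' residuals. The statistic lies in `[0, 4]`: near 2 for white residuals,
#' near 0 under positive autocorrelation, near 4 under negative.
#'
#' A residual vector that is identically (numerically) zero leaves the
#' statistic undefined; this raises an error of class
#' `bootgof_degenerate_fit` (a "surprisingly good" fit, e.g. the
#' hyper-flexible interpolant).
#'
#' @param residuals numeric vector of residuals.
#' @param signal_id optional signal labels (same length); residuals are
#'   grouped by signal in the numerator.
#' @return scalar in `[0, 4]`.
#' @examples
#' dw_statistic(c(1, -1, 1, -1))  # 12 / 4 = 3
#' @export
dw_statistic <- function(residuals, signal_id = NULL) {
  r <- as.numeric(residuals)
  den <- sum(r^2)
  if (den == 0 || !is.finite(den)) {
    cond <- structure(
      class = c("bootgof_degenerate_fit", "error", "condition"),
      list(message = "all residuals are zero: Durbin-Watson statistic undefined (degenerate, surprisingly good fit)",
           call = sys.call(-1)))
    stop(cond)
  }
  if (is.null(signal_id)) {
    num <- sum(diff(r)^2)
  } else {
    grp <- split(r, factor(signal_id, levels = unique(signal_id)))
    num <- sum(vapply(grp, function(g) sum(diff(g)^2), numeric(1)))
  }
  num / den
}

# dw for every column of a residual matrix sharing one design (vectorized)
dw_statistic_cols <- function(R, signal_id = NULL) {
  den <- colSums(R^2)
  if (any(den == 0))
    stop(structure(
      class = c("bootgof_degenerate_fit", "error", "condition"),
      list(message = "a bootstrap refit has all-zero residuals: Durbin-Watson undefined",
           call = NULL)))
  if (is.null(signal_id)) {
    D <- R[-1, , drop = FALSE] - R[-nrow(R), , drop = FALSE]
    num <- colSums(D^2)
  } else {
    idx <- split(seq_len(nrow(R)), factor(signal_id, levels = unique(signal_id)))
    num <- 0
    for (ii in idx) {
      D <- R[ii[-1], , drop = FALSE] - R[ii[-length(ii)], , drop = FALSE]
      num <- num + colSums(D^2)
    }
  }
  num / den
}

#' Log-likelihood ratio and product statistics for two models
#'
#' Under known Gaussian noise the log-likelihood of a model is, up to a
#' constant, `-chi2/2`, so twice the log-likelihood ratio of model 2 to
#' model 1 is the chi-square difference. `lhr_statistic()` returns
#' `chi2_m1 - chi2_m2` (large positive values: the tested model 1 fits
#' worse; the two-tailed test makes the sign convention immaterial).
#' `lhp_statistic()` returns the sum `chi2_m1 + chi2_m2`. Jointly the map
#' `(chi2_1, chi2_2) -> (LHR, LHP)` is a 45-degree rotation scaled by
#' `sqrt(2)`.
#'
#' @param chi2_m1,chi2_m2 non-negative chi-square values of the two models.
#' @return scalar.
#' @export
lhr_statistic <- function(chi2_m1, chi2_m2) {
  stopifnot(all(chi2_m1 >= 0), all(chi2_m2 >= 0))
  chi2_m1 - chi2_m2
}

#' @rdname lhr_statistic
#' @export
lhp_statistic <- function(chi2_m1, chi2_m2) {
  stopifnot(all(chi2_m1 >= 0), all(chi2_m2 >= 0))
  chi2_m1 + chi2_m2
}
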