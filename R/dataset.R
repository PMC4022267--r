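#' Observation design
#'
#' A design records where a model is evaluated: the ordered coordinates
#' (time points for dynamic models, regressor values for static models)
#' of every measurement signal, plus an optional constant exogenous input.
#'
#' @param coordinate numeric vector of evaluation points. Must be strictly
#'   increasing within each signal.
#' @param signal_id character vector (or single value, recycled) labelling
#'   the measurement signal each coordinate belongs to.
#' @param input optional named list describing a constant exogenous input.
#'
#' @return An object of class `gof_design`: a data frame with columns
#'   `signal_id` and `coordinate` and attribute `input`.
#' @examples
#' d <- gof_design(seq(0, 3, length.out = 11))
#' @export
gof_design <- function(coordinate, signal_id = "y1", input = NULL) {
  coordinate <- as.numeric(coordinate)
  signal_id <- rep_len(as.character(signal_id), length(coordinate))
  d <- data.frame(signal_id = signal_id, coordinate = coordinate,
                  stringsAsFactors = FALSE)
  for (sig in unique(d$signal_id)) {
    x <- d$coordinate[d$signal_id == sig]
    if (length(x) < 3L)
      stop("design needs at least 3 points per signal (signal '", sig, "' has ",
           length(x), "); adjacent-residual statistics need >= 2 pairs")
    if (any(diff(x) <= 0))
      stop("coordinates must be strictly increasing within signal '", sig, "'")
  }
  attr(d, "input") <- input
  class(d) <- c("gof_design", "data.frame")
  d
}

n_points <- function(design) nrow(design)

signal_index <- function(design) {
  # list of row indices per signal, preserving row order
  split(seq_len(nrow(design)), factor(design$signal_id,
                                      levels = unique(design$signal_id)))
}

#' Dataset of noisy observations
#'
#' Bundles a design with measured values and the per-point noise standard
#' deviations assumed known throughout (no variance estimation is done).
#'
#' @param design a [gof_design()], or a numeric coordinate vector which is
#'   passed to [gof_design()].
#' @param value numeric vector of measured values, one per design row.
#' @param sigma numeric vector (or scalar, recycled) of per-point noise
#'   standard deviations; all must be positive.
#' @param provenance a list recording how the data arose (kind
#'   `"observed"`, `"bootstrap"` or `"synthetic"`, plus generator metadata
#'   such as the true model, true parameters and seed).
#'
#' @return An object of class `gof_dataset`.
#' @examples
#' ds <- gof_dataset(gof_design(0:4), value = c(10, 8, 6, 4, 2), sigma = 0.5)
#' @export
gof_dataset <- function(design, value, sigma,
                        provenance = list(kind = "observed")) {
  if (!inherits(design, "gof_design")) design <- gof_design(design)
  value <- as.numeric(value)
  sigma <- rep_len(as.numeric(sigma), nrow(design))
  if (length(value) != nrow(design))
    stop("length(value) [", length(value), "] must match the design [",
         nrow(design), " points]")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigma must be finite and positive")
  if (any(!is.finite(value)))
    stop("all values must be finite")
  if (is.null(provenance$kind)) provenance$kind <- "observed"
  structure(list(design = design, value = value, sigma = sigma,
                 provenance = provenance),
            class = "gof_dataset")
}

#' @export
print.gof_dataset <- function(x, ...) {
  sigs <- unique(x$design$signal_id)
  cat("<gof_dataset> ", nrow(x$design), " points, ", length(sigs),
      " signal(s): ", paste(sigs, collapse = ", "), "\n", sep = "")
  cat("  coordinate range: [", min(x$design$coordinate), ", ",
      max(x$design$coordinate), "]\n", sep = "")
  cat("  sigma: ", if (length(unique(x$sigma)) == 1L)
    format(x$sigma[1]) else paste0("per-point, mean ", format(mean(x$sigma))),
    "\n", sep = "")
  cat("  provenance: ", x$provenance$kind, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gof_dataset <- function(x, ...) {
  data.frame(signal_id = x$design$signal_id,
             coordinate = x$design$coordinate,
             value = x$value, sigma = x$sigma,
             stringsAsFactors = FALSE)
}
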