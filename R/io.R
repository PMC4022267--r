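#' Read / write a dataset as CSV with a JSON provenance sidecar
#'
#' The CSV is long format with required header columns `signal_id`,
#' `coordinate`, `value`, `sigma`. Full double precision is kept on
#' round-trip. Provenance travels in `<path>.json` when present.
#'
#' @param path CSV file path.
#' @param dataset a [gof_dataset()].
#' @param sidecar write/read the JSON provenance sidecar (default TRUE).
#' @return `read_dataset()` a [gof_dataset()]; `write_dataset()` the path,
#'   invisibly.
#' @export
read_dataset <- function(path, sidecar = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("signal_id", "coordinate", "value", "sigma")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("dataset file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("coordinate", "value", "sigma")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-finite ", col, " in row ", bad[1], " of '", path, "'")
  }
  bad_sigma <- which(df$sigma <= 0)
  if (length(bad_sigma))
    stop("non-positive sigma in row ", bad_sigma[1], " of '", path, "'")
  prov <- list(kind = "observed")
  side <- paste0(path, ".json")
  if (sidecar && file.exists(side))
    prov <- jsonlite::read_json(side, simplifyVector = TRUE)
  # gof_design() validates monotone coordinates and reports the signal
  gof_dataset(gof_design(df$coordinate, df$signal_id), df$value, df$sigma,
              provenance = prov)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "gof_dataset"))
  df <- as.data.frame(dataset)
  # format() would truncate doubles; write with full precision
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("signal_id,coordinate,value,sigma", con)
  writeLines(paste(df$signal_id,
                   sprintf("%.17g", df$coordinate),
                   sprintf("%.17g", df$value),
                   sprintf("%.17g", df$sigma), sep = ","), con)
  if (sidecar)
    jsonlite::write_json(dataset$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default study conditions for the built-in test cases
#'
#' The static case uses 11 equidistant regressor points on `[0, 2]` with
#' noise sd 0.5 and true parameters MS1 `(4, 5)`, MS2 `(2, 3)` (mean output
#' around 5-10, so the noise is on the order of 5-10% of the average model
#' output); the dynamic case uses 11 equidistant time points on `[0, 3]`
#' with noise sd 0.75 and true parameters MD1 `0.7`, MD2 `5` (visible decay
#' from 10 over the window).
#'
#' @param case `"static"` or `"dynamic"`.
#' @return list with `design`, `sigma`, and named list `true_params`.
#' @export
default_conditions <- function(case = c("static", "dynamic")) {
  case <- match.arg(case)
  if (case == "static")
    list(design = gof_design(seq(0, 2, length.out = 11)),
         sigma = 0.5,
         true_params = list(MS1 = c(4, 5), MS2 = c(2, 3)))
  else
    list(design = gof_design(seq(0, 3, length.out = 11)),
         sigma = 0.75,
         true_params = list(MD1 = 0.7, MD2 = 5))
}

#' Generate a synthetic fixture dataset
#'
#' Simulates the declared default design and true parameters for a built-in
#' test-case model and adds i.i.d. Gaussian noise at the case's default
#' level (sd 0.5 static, 0.75 dynamic). Everything is recorded in the
#' dataset's provenance.
#'
#' @param case `"static"` or `"dynamic"`.
#' @param true_model id of the generating model (`"MS1"`/`"MS2"` static,
#'   `"MD1"`/`"MD2"` dynamic).
#' @param seed integer seed.
#' @param true_params,sigma,design optional overrides of the defaults.
#' @return a [gof_dataset()] with provenance kind `"synthetic"`.
#' @examples
#' make_fixture("static", "MS1", seed = 1)
#' @export
make_fixture <- function(case = c("static", "dynamic"), true_model, seed = 1L,
                         true_params = NULL, sigma = NULL, design = NULL) {
  case <- match.arg(case)
  cond <- default_conditions(case)
  if (!true_model %in% names(cond$true_params))
    stop("true_model for the ", case, " case must be one of: ",
         paste(names(cond$true_params), collapse = ", "))
  if (is.null(true_params)) true_params <- cond$true_params[[true_model]]
  if (is.null(sigma)) sigma <- cond$sigma
  if (is.null(design)) design <- cond$design
  model <- builtin_models(true_model)
  yhat <- simulate_model(model, true_params, design)
  sigma <- rep_len(sigma, nrow(design))
  y <- yhat + sigma * withr::with_seed(derive_seed(seed, 7L),
                                       stats::rnorm(nrow(design)))
  gof_dataset(design, y, sigma,
              provenance = list(kind = "synthetic", case = case,
                                true_model = true_model,
                                true_params = true_params,
                                seed = as.integer(seed)))
}

run_config_keys <- c("model", "model2", "dataset", "fixture_case",
                     "fixture_true_model", "test", "B", "alpha", "tail",
                     "grid_n", "bandwidth", "seed", "out", "n_datasets",
                     "log_level")

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected before any computation.
#'
#' @param path file ending in `.yaml`/`.yml` (needs the \pkg{yaml} package)
#'   or `.json`.
#' @return named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config needs the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(run_config_keys, collapse = ", "))
  if (!is.null(cfg$B) && cfg$B < 1) stop("config: B must be >= 1")
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    stop("config: alpha must be in (0, 1)")
  cfg
}
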