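# Shared helpers: fixed-truth models and tiny builders used across tests.

# A model with no free parameters: predicts a fixed decay curve. With known
# sigma its bootstrap chi-square column has an exact chi-square(N) null.
fixed_truth_model <- function(theta = 0.7) {
  predictor_model("TRUTH0", 0L,
                  predict = function(th, design)
                    10 * exp(-theta * design$coordinate),
                  fit_strategy = "fixed")
}

static_models <- function() list(builtin_models("MS1"), builtin_models("MS2"))

dynamic_models <- function() list(builtin_models("MD1"), builtin_models("MD2"))

# noise-free dataset simulated from a model (sigma kept positive)
noise_free_dataset <- function(model, theta, design, sigma = 0.5) {
  gof_dataset(design, simulate_model(model, theta, design), sigma,
              provenance = list(kind = "synthetic", true_model = model$model_id,
                                true_params = theta))
}

# standard bivariate normal cloud wrapped as a plain matrix
gauss_cloud <- function(B, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(2 * B), ncol = 2))
}
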