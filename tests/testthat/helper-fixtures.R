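# Shared fixtures, built in code at test time.

# Session-level cache so expensive shared computations run once per suite.
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

exp_condition <- function(id) get_condition(make_condition_grid(), id)

# Noise-free synthetic data set for a model/experiment at the sparse
# default sampling schedule.
noise_free_data <- function(model_id, experiment_id) {
  cached(paste0("nf-", model_id, "-", experiment_id),
         generate_experiment(model_id, literature_params(model_id),
                             exp_condition(experiment_id),
                             noise = list(rho = 0, sigma0 = 0), seed = 1L))
}

# The reduced-scale Sobol analyses shared by the acceptance tests
# (base N = 256, default six conditions, full 201-point grid).
acceptance_sobol <- function(model_id) {
  cached(paste0("sobol-", model_id),
         suppressMessages(run_sobol_analysis(model_id, base_n = 256,
                                             seed = 1L)))
}

# Scalar test functions evaluated over a design (rows -> scalar output).
apply_rows <- function(design, f) apply(design, 1L, f)

expect_equal_tol <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%.4f - %.4f| <= %.4f", object, expected, tol))
}
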