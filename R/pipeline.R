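#' Run configuration for the end-to-end pipeline
#'
#' A single configuration list drives the pipeline stages
#' ([pipeline_simulate()], [pipeline_generate()], [pipeline_sensitivity()],
#' [pipeline_fit()], [pipeline_crossval()], [pipeline_report()]).  Every
#' field has a documented default matching the package's canonical study
#' settings: solver tolerances `1e-3`/`1e-6`, 201 output points over
#' 500 min, Saltelli base sample 2048 with span 2.6 and screening
#' threshold 0.1, noise `max(0.05 C, 0.5 mM)`, and MCMC with
#' `omega = 6e-3`.
#'
#' @param path Optional YAML file whose top-level keys override the
#'   defaults.
#' @param ... Further overrides (take precedence over the file).
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL, ...) {
  cfg <- list(
    model_id = "model1",
    param_source = "literature",      # or a parameter file path
    experiments = 1:13,
    rel_tol = 1e-3, abs_tol = 1e-6,
    horizon = 500, n_points = 201,
    sensitivity = list(base_n = 2048, span = 2.6, threshold = 0.1,
                       second_order = TRUE,
                       conditions = c(1L, 2L, 6L, 7L, 10L, 13L)),
    noise = default_noise_spec(),
    mcmc = list(n_iter = 50000, burn_in = 10000, omega = 6e-3),
    seed = 1L,
    output_dir = "amoxkin-output")
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  structure(cfg, class = "run_config")
}

resolve_config_params <- function(cfg) {
  if (identical(cfg$param_source, "literature"))
    literature_params(cfg$model_id)
  else read_params(cfg$param_source)
}

# Short stable hash of a configuration (polynomial rolling hash over its
# deparsed form), recorded in every run manifest so artifacts can be
# traced to settings.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(cfg, stage, files) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stage = stage, config_hash = config_hash(unclass(cfg)),
         seed = cfg$seed, package_version = as.character(
           utils::packageVersion("amoxkin")),
         files = files),
    file.path(cfg$output_dir, paste0(stage, "-manifest.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Pipeline stages
#'
#' Thin, file-producing wrappers over the package functions; each stage
#' writes its outputs (CSV/JSON) plus a manifest recording the
#' configuration hash, seed and package version into
#' `config$output_dir`.  Later stages consume earlier stages' files by
#' path and raise an actionable error naming the stage to run first when
#' an input is missing.
#'
#' \describe{
#'   \item{`pipeline_simulate()`}{noise-free time courses for the selected
#'     experiments.}
#'   \item{`pipeline_generate()`}{synthetic noisy data sets for the full
#'     condition grid.}
#'   \item{`pipeline_sensitivity()`}{Sobol analysis: long-format index CSV
#'     + JSON aggregate/screening summary.}
#'   \item{`pipeline_fit()`}{MCMC fit on one generated data set (chain CSV
#'     + posterior summary JSON), estimating the screened-in set.}
#'   \item{`pipeline_crossval()`}{cross-validation rRMSE matrix.}
#'   \item{`pipeline_report()`}{model comparison table over both models'
#'     fits.}
#' }
#'
#' @param config A `run_config` from [load_run_config()].
#' @param experiment_id Calibration experiment for `pipeline_fit()`.
#' @return Each stage invisibly returns the paths of the files it wrote.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config = load_run_config()) {
  params <- resolve_config_params(config)
  grid <- make_condition_grid()
  times <- default_time_grid(config$horizon, config$n_points)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (id in config$experiments) {
    tc <- simulate_batch(config$model_id, params, get_condition(grid, id),
                         times = times, rel_tol = config$rel_tol,
                         abs_tol = config$abs_tol)
    f <- file.path(config$output_dir,
                   sprintf("simulated-%s-exp%02d.csv", config$model_id, id))
    write_timecourse(tc, f)
    files <- c(files, f)
  }
  write_manifest(config, "simulate", files)
  invisible(files)
}

#' @rdname pipeline
#' @export
pipeline_generate <- function(config = load_run_config()) {
  params <- resolve_config_params(config)
  data <- generate_study(config$model_id, params,
                         noise = config$noise, seed = config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(data)) {
    f <- file.path(config$output_dir,
                   sprintf("synthetic-%s-%s.csv", config$model_id, nm))
    write_timecourse(data[[nm]], f)
    files <- c(files, f)
  }
  write_manifest(config, "generate", files)
  invisible(files)
}

#' @rdname pipeline
#' @export
pipeline_sensitivity <- function(config = load_run_config()) {
  params <- resolve_config_params(config)
  sc <- config$sensitivity
  grid <- make_condition_grid()
  conds <- structure(grid[grid$experiment_id %in% sc$conditions, ],
                     class = class(grid))
  res <- run_sobol_analysis(config$model_id, params, span = sc$span,
                            base_n = sc$base_n,
                            second_order = isTRUE(sc$second_order),
                            conditions = conds,
                            times = default_time_grid(config$horizon,
                                                      config$n_points),
                            seed = config$seed,
                            rel_tol = config$rel_tol,
                            abs_tol = config$abs_tol)
  message("sensitivity design rows: ", nrow(res$design))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(config$output_dir,
                   sprintf("sobol-%s.csv", config$model_id))
  json <- file.path(config$output_dir,
                    sprintf("sobol-%s-summary.json", config$model_id))
  write_sobol_result(res, csv, json, threshold = sc$threshold)
  write_manifest(config, "sensitivity", c(csv, json))
  invisible(c(csv, json))
}

#' @rdname pipeline
#' @export
pipeline_fit <- function(config = load_run_config(), experiment_id = 1L) {
  data_file <- file.path(config$output_dir,
                         sprintf("synthetic-%s-exp%d.csv", config$model_id,
                                 experiment_id))
  if (!file.exists(data_file))
    stop("missing synthetic data set ", data_file,
         "; run pipeline_generate() first", call. = FALSE)
  summary_file <- file.path(config$output_dir,
                            sprintf("sobol-%s-summary.json", config$model_id))
  if (!file.exists(summary_file))
    stop("missing sensitivity summary ", summary_file,
         "; run pipeline_sensitivity() first", call. = FALSE)
  data <- read_timecourse(data_file)
  screening <- jsonlite::read_json(summary_file, simplifyVector = TRUE)
  chain <- run_mcmc(data, config$model_id,
                    estimated = screening$estimated,
                    n_iter = config$mcmc$n_iter,
                    burn_in = config$mcmc$burn_in,
                    omega = config$mcmc$omega, seed = config$seed)
  csv <- file.path(config$output_dir,
                   sprintf("chain-%s-exp%d.csv", config$model_id,
                           experiment_id))
  json <- file.path(config$output_dir,
                    sprintf("posterior-%s-exp%d.json", config$model_id,
                            experiment_id))
  write_chain(chain, csv, json)
  write_manifest(config, "fit", c(csv, json))
  invisible(c(csv, json))
}

#' @rdname pipeline
#' @export
pipeline_crossval <- function(config = load_run_config()) {
  files <- file.path(config$output_dir,
                     sprintf("synthetic-%s-exp%d.csv", config$model_id,
                             config$experiments))
  if (!all(file.exists(files)))
    stop("missing synthetic data sets; run pipeline_generate() first",
         call. = FALSE)
  datasets <- lapply(files, read_timecourse)
  names(datasets) <- paste0("exp", config$experiments)
  summary_file <- file.path(config$output_dir,
                            sprintf("sobol-%s-summary.json", config$model_id))
  estimated <- if (file.exists(summary_file))
    jsonlite::read_json(summary_file, simplifyVector = TRUE)$estimated
  else NULL
  cv <- cross_validate(datasets, config$model_id, estimated = estimated,
                       n_iter = config$mcmc$n_iter,
                       burn_in = config$mcmc$burn_in,
                       omega = config$mcmc$omega, seed = config$seed)
  f <- file.path(config$output_dir,
                 sprintf("crossval-%s.csv", config$model_id))
  write_crossval(cv, f)
  write_manifest(config, "crossval", f)
  invisible(f)
}

#' @rdname pipeline
#' @export
pipeline_report <- function(config = load_run_config()) {
  entries <- list()
  for (model in c("model1", "model2")) {
    json <- file.path(config$output_dir,
                      sprintf("posterior-%s-exp%d.json", model,
                              config$experiments[1]))
    data_file <- file.path(config$output_dir,
                           sprintf("synthetic-%s-exp%d.csv", config$model_id,
                                   config$experiments[1]))
    if (!file.exists(json) || !file.exists(data_file)) next
    post <- jsonlite::read_json(json, simplifyVector = TRUE)
    s <- post$summary
    pars <- stats::setNames(s$mean, s$parameter)
    data <- read_timecourse(data_file)
    entries[[model]] <- fit_metrics(pars, data, model,
                                    k = sum(!s$fixed))
  }
  if (length(entries) < 2L)
    stop("need fits for both models; run pipeline_fit() for each",
         call. = FALSE)
  cmp <- compare_models(entries)
  f <- file.path(config$output_dir, "model-comparison.csv")
  utils::write.csv(data.frame(model = rownames(cmp), as.data.frame(cmp)),
                   f, row.names = FALSE)
  write_manifest(config, "report", f)
  invisible(f)
}
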