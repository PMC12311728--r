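#' Simulate a batch reaction
#'
#' Integrates either kinetic model over a batch run with a stiff implicit
#' multistep scheme (backward-differentiation formulas, via
#' [deSolve::ode()] with `method = "bdf"`).  Default tolerances are
#' `rel_tol = 1e-3`, `abs_tol = 1e-6`; the default output grid is 201
#' equally spaced points over 500 min.  The initial state is
#' `(C_AN = 0, C_AOH = 0, C_NH = condition$C_NH0, C_AB = condition$C_AB0)`.
#'
#' By default the right-hand side runs as compiled C code for speed; the
#' pure-R rate laws ([rhs_model1()] / [rhs_model2()]) are available through
#' `engine = "R"` and agree with the compiled path to integrator accuracy.
#'
#' @param model_id `"model1"` or `"model2"`.
#' @param params The matching parameter object (or named vector).
#' @param condition A `batch_condition` (see [make_condition_grid()]) or a
#'   list with `C_NH0`, `C_AB0` and optionally `C_E`, `experiment_id`.
#' @param times Output time grid (min), strictly increasing from 0.
#' @param C_E Enzyme load (IU mL^-1); overrides `condition$C_E` if given.
#' @param rel_tol,abs_tol Integrator tolerances.
#' @param use_knh See [rate_ester_consumption()].
#' @param engine `"compiled"` (default) or `"R"`.
#' @return A `timecourse`: a data frame with columns `time_min`, `C_AN_mM`,
#'   `C_AB_mM`, `C_NH_mM`, `C_AOH_mM` and attributes `model_id`,
#'   `condition_id`, `C_E`.
#' @export
simulate_batch <- function(model_id, params, condition,
                           times = default_time_grid(),
                           C_E = NULL, rel_tol = 1e-3, abs_tol = 1e-6,
                           use_knh = FALSE,
                           engine = c("compiled", "R")) {
  model_id <- match.arg(model_id, c("model1", "model2"))
  engine <- match.arg(engine)
  params <- as_params(params, model_id)
  if (is.null(C_E)) C_E <- condition$C_E
  if (is.null(C_E)) C_E <- default_enzyme_load()
  C_E <- as_enzyme_load(C_E)
  if (rel_tol <= 0 || abs_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  if (!is.finite(condition$C_NH0) || !is.finite(condition$C_AB0) ||
      condition$C_NH0 < 0 || condition$C_AB0 < 0)
    stop("initial concentrations must be finite and non-negative",
         call. = FALSE)

  y0 <- c(C_AN = 0, C_AOH = 0, C_NH = condition$C_NH0,
          C_AB = condition$C_AB0)

  out <- integrate_model(model_id, params, y0, times, C_E, rel_tol, abs_tol,
                         use_knh, engine)
  if (inherits(out, "sim_failure"))
    stop("integration failed near t = ", signif(out$t_fail, 4), " min",
         call. = FALSE)

  tc <- data.frame(time_min = out[, "time"],
                   C_AN_mM = out[, "C_AN"], C_AB_mM = out[, "C_AB"],
                   C_NH_mM = out[, "C_NH"], C_AOH_mM = out[, "C_AOH"])
  rownames(tc) <- NULL
  cmin <- min(tc$C_AN_mM, tc$C_AB_mM, tc$C_NH_mM, tc$C_AOH_mM)
  if (cmin < -10 * abs_tol)
    warning(sprintf(paste0(
      "simulated concentrations go negative (min %.3g mM); the rate laws ",
      "are evaluated as written, which can drive species below zero for ",
      "some parameter sets"), cmin), call. = FALSE)
  structure(tc,
            class = c("timecourse", "data.frame"),
            model_id = model_id,
            condition_id = condition$experiment_id %||% NA_integer_,
            C_E = C_E)
}

#' Default simulation output grid
#'
#' 201 equally spaced time points over 500 min.
#' @param horizon Batch duration (min).
#' @param n_points Number of output points including t = 0.
#' @return Numeric vector of times.
#' @export
default_time_grid <- function(horizon = 500, n_points = 201) {
  seq(0, horizon, length.out = n_points)
}

# Low-level integration used by the simulator and the sensitivity ensemble.
# Returns a deSolve matrix, or an object of class "sim_failure" rather than
# raising, so ensemble callers can drop failed runs cheaply.
integrate_model <- function(model_id, params, y0, times, C_E,
                            rel_tol = 1e-3, abs_tol = 1e-6,
                            use_knh = FALSE, engine = "compiled") {
  res <- if (engine == "compiled") {
    parms <- if (model_id == "model1") {
      c(params[["kcat1"]], params[["kcat2"]], params[["Km1"]], params[["Km2"]],
        params[["kAB"]], params[["kAN"]], params[["kAOH"]], params[["kNH"]],
        params[["KEN"]], params[["Tmax"]], C_E, as.numeric(use_knh))
    } else {
      c(params[["KN"]], params[["KP"]], params[["KS"]], params[["k_m4"]],
        params[["k2"]], params[["k3"]], params[["k4"]], params[["k5"]], C_E)
    }
    fn <- if (model_id == "model1") "amx_derivs_model1" else "amx_derivs_model2"
    ini <- if (model_id == "model1") "amx_init_model1" else "amx_init_model2"
    try(suppressWarnings(deSolve::ode(
      y = y0, times = times, func = fn, parms = parms,
      dllname = "amoxkin", initfunc = ini,
      method = "bdf", rtol = rel_tol, atol = abs_tol)), silent = TRUE)
  } else {
    rhs <- if (model_id == "model1") {
      function(t, y, parms) list(unname(rhs_model1(t, y, params, C_E, use_knh)))
    } else {
      function(t, y, parms) list(unname(rhs_model2(t, y, params, C_E)))
    }
    try(suppressWarnings(deSolve::ode(
      y = y0, times = times, func = rhs, parms = NULL,
      method = "bdf", rtol = rel_tol, atol = abs_tol)), silent = TRUE)
  }
  if (inherits(res, "try-error"))
    return(structure(list(t_fail = NA_real_), class = "sim_failure"))
  if (nrow(res) < length(times) || any(!is.finite(res))) {
    t_fail <- if (nrow(res) >= 1) res[nrow(res), "time"] else times[1]
    return(structure(list(t_fail = t_fail), class = "sim_failure"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check conservation of mass in a simulated time course
#'
#' The reaction network conserves two linear combinations: the beta-lactam
#' nucleus total `C_AN + C_NH` and the acyl moiety total
#' `C_AB + C_AN + C_AOH`.  This reports, for each, the maximum over time of
#' `|sum(t) - sum(0)| / sum(0)` (or absolute drift when the initial sum is
#' zero) and flags pass/fail at a threshold.
#'
#' @param tc A `timecourse` (or any data frame in the same column layout).
#' @param threshold Maximum tolerated relative drift (default `1e-3`).
#' @return A list with `drift` (named numeric, the two max drifts),
#'   `relative` (logical, per combination), `threshold` and `pass`.
#' @export
check_mass_balance <- function(tc, threshold = 1e-3) {
  if (nrow(tc) < 1L) stop("empty time course", call. = FALSE)
  sums <- cbind(nucleus = tc$C_AN_mM + tc$C_NH_mM,
                acyl = tc$C_AB_mM + tc$C_AN_mM + tc$C_AOH_mM)
  drift <- numeric(2); relative <- logical(2)
  for (j in 1:2) {
    s0 <- sums[1, j]
    if (abs(s0) > 0) {
      drift[j] <- max(abs(sums[, j] - s0)) / abs(s0); relative[j] <- TRUE
    } else {
      drift[j] <- max(abs(sums[, j] - s0)); relative[j] <- FALSE
    }
  }
  names(drift) <- colnames(sums)
  list(drift = drift, relative = stats::setNames(relative, colnames(sums)),
       threshold = threshold, pass = all(drift < threshold))
}

#' Read and write time-course CSV files
#'
#' Time courses are stored as tidy CSV with columns `time_min`, `C_AN_mM`,
#' `C_AB_mM`, `C_NH_mM`, `C_AOH_mM` (noisy data sets append `sigma_*`
#' columns), preceded by `#`-prefixed metadata header lines
#' (`# key: value`) recording model, condition, enzyme load and seed.
#'
#' @param tc A `timecourse` or `noisy_timecourse`.
#' @param path Output CSV path.
#' @return `write_timecourse()` returns `path` invisibly;
#'   `read_timecourse()` returns the time course with metadata attributes
#'   restored.
#' @export
write_timecourse <- function(tc, path) {
  meta <- c(model_id = attr(tc, "model_id") %||% "",
            condition_id = as.character(attr(tc, "condition_id") %||% ""),
            C_E = as.character(attr(tc, "C_E") %||% ""),
            seed = as.character(attr(tc, "seed") %||% ""))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.csv(as.data.frame(tc), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^# ([^:]+): ?(.*)$", lines[h]))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  tc <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr)])
  cls <- if ("sigma_C_AN_mM" %in% names(tc))
    c("noisy_timecourse", "timecourse", "data.frame")
  else c("timecourse", "data.frame")
  structure(tc, class = cls,
            model_id = if (nzchar(meta$model_id %||% "")) meta$model_id else NA,
            condition_id = if (nzchar(meta$condition_id %||% ""))
              as.integer(meta$condition_id) else NA_integer_,
            C_E = if (nzchar(meta$C_E %||% "")) as.numeric(meta$C_E) else NA,
            seed = if (nzchar(meta$seed %||% "")) as.integer(meta$seed) else NULL)
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse: %s, condition %s, %d time points over %g min>\n",
              attr(x, "model_id") %||% "?",
              attr(x, "condition_id") %||% "?",
              nrow(x), max(x$time_min)))
  print(utils::head(as.data.frame(x), 4L), ...)
  if (nrow(x) > 4L) cat("... ", nrow(x) - 4L, " more rows\n", sep = "")
  invisible(x)
}
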