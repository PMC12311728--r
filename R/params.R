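#' Parameter containers for the two amoxicillin synthesis models
#'
#' The package models the PGA-catalyzed condensation of 6-APA with POHPGME
#' using two competing kinetic formulations.  Model 1 is a Michaelis-Menten
#' rate-law model with competitive inhibition; Model 2 describes the
#' acyl-enzyme mechanism through elementary rate and equilibrium constants.
#' Each parameter set is stored as a named numeric vector with a class
#' attribute, in a fixed canonical order.
#'
#' Model 1 parameters (canonical order):
#' \describe{
#'   \item{KEN}{6-APA--enzyme adsorption constant (mM)}
#'   \item{Km1, Km2}{Michaelis constants of ester consumption and
#'     amoxicillin hydrolysis (mM)}
#'   \item{Tmax}{maximum enzymatic conversion (dimensionless, in (0, 1])}
#'   \item{kAB, kAN, kAOH, kNH}{competitive inhibition constants (mM)}
#'   \item{kcat1, kcat2}{catalytic rate constants (umol IU^-1 min^-1)}
#' }
#'
#' Model 2 parameters (canonical order):
#' \describe{
#'   \item{KN, KP, KS}{nucleophile, product and substrate equilibrium
#'     constants (mM)}
#'   \item{k_m4}{reverse rate constant of product release (min^-1),
#'     often written k-4}
#'   \item{k2, k3, k4, k5}{elementary rate constants (min^-1)}
#' }
#'
#' @param KEN,Km1,Km2,Tmax,kAB,kAN,kAOH,kNH,kcat1,kcat2 Model 1 values.
#' @return A named numeric vector of class `model1_params`.
#' @examples
#' p <- model1_params(KEN = 14.35, Km1 = 7.905, Km2 = 12.509, Tmax = 0.606,
#'                    kAB = 3.78, kAN = 9.174, kAOH = 10.907, kNH = 62.044,
#'                    kcat1 = 0.178, kcat2 = 0.327)
#' @export
model1_params <- function(KEN, Km1, Km2, Tmax, kAB, kAN, kAOH, kNH,
                          kcat1, kcat2) {
  p <- c(KEN = KEN, Km1 = Km1, Km2 = Km2, Tmax = Tmax, kAB = kAB,
         kAN = kAN, kAOH = kAOH, kNH = kNH, kcat1 = kcat1, kcat2 = kcat2)
  validate_params(p, "model1")
  structure(p, class = c("model1_params", "kinetic_params"))
}

#' @param KN,KP,KS,k_m4,k2,k3,k4,k5 Model 2 values.
#' @rdname model1_params
#' @return For `model2_params`, a named numeric vector of class
#'   `model2_params`.
#' @export
model2_params <- function(KN, KP, KS, k_m4, k2, k3, k4, k5) {
  p <- c(KN = KN, KP = KP, KS = KS, k_m4 = k_m4,
         k2 = k2, k3 = k3, k4 = k4, k5 = k5)
  validate_params(p, "model2")
  structure(p, class = c("model2_params", "kinetic_params"))
}

validate_params <- function(p, model_id) {
  if (anyNA(p) || any(!is.finite(p)))
    stop("kinetic parameters must be finite and non-missing", call. = FALSE)
  if (any(p <= 0))
    stop("all kinetic parameters must be strictly positive; offending: ",
         paste(names(p)[p <= 0], collapse = ", "), call. = FALSE)
  if (model_id == "model1" && p[["Tmax"]] > 1)
    stop("Tmax is a conversion fraction and must lie in (0, 1]",
         call. = FALSE)
  invisible(p)
}

#' Literature parameter values for both models
#'
#' Returns the published reference values for either kinetic model, used as
#' sensitivity-analysis centers, MCMC chain starting points, and defaults
#' throughout the package.
#'
#' @param model_id `"model1"` or `"model2"`.
#' @return A `model1_params` or `model2_params` object.
#' @export
literature_params <- function(model_id = c("model1", "model2")) {
  model_id <- match.arg(model_id)
  if (model_id == "model1") {
    model1_params(KEN = 14.350, Km1 = 7.905, Km2 = 12.509, Tmax = 0.606,
                  kAB = 3.780, kAN = 9.174, kAOH = 10.907, kNH = 62.044,
                  kcat1 = 0.178, kcat2 = 0.327)
  } else {
    model2_params(KN = 43.0, KP = 95.0, KS = 380.0, k_m4 = 3.617,
                  k2 = 3.117, k3 = 0.733, k4 = 3.917, k5 = 0.150)
  }
}

#' Enzyme activity load
#'
#' The enzyme enters both models as a constant multiplicative activity
#' concentration `C_E` (IU mL^-1); enzyme deactivation is not modeled, so
#' the load is constant over a batch.  Because the catalytic constants are
#' expressed per IU, the product (umol IU^-1 min^-1) x (IU mL^-1) gives all
#' rate laws units of mM min^-1.
#'
#' @param C_E Enzyme activity concentration (IU mL^-1), a positive scalar.
#' @return A numeric scalar of class `enzyme_load`.
#' @export
enzyme_load <- function(C_E) {
  if (!is.numeric(C_E) || length(C_E) != 1L || !is.finite(C_E) || C_E < 0)
    stop("C_E must be a single finite non-negative number", call. = FALSE)
  structure(c(C_E = C_E), class = "enzyme_load")
}

as_enzyme_load <- function(e) {
  if (inherits(e, "enzyme_load")) return(unname(e[["C_E"]]))
  if (is.numeric(e) && length(e) == 1L) return(unname(e))
  stop("expected an enzyme_load or a single number", call. = FALSE)
}

param_names <- function(model_id) {
  switch(model_id,
    model1 = c("KEN", "Km1", "Km2", "Tmax", "kAB", "kAN", "kAOH", "kNH",
               "kcat1", "kcat2"),
    model2 = c("KN", "KP", "KS", "k_m4", "k2", "k3", "k4", "k5"),
    stop("unknown model_id: ", model_id, call. = FALSE))
}

as_params <- function(x, model_id) {
  nm <- param_names(model_id)
  if (!all(nm %in% names(x)))
    stop("missing parameters: ", paste(setdiff(nm, names(x)), collapse = ", "),
         call. = FALSE)
  x <- as.numeric(x[nm])
  names(x) <- nm
  if (model_id == "model1") do.call(model1_params, as.list(x))
  else do.call(model2_params, as.list(x))
}

#' @export
print.kinetic_params <- function(x, ...) {
  model <- if (inherits(x, "model1_params")) "Model 1 (Michaelis-Menten)"
           else "Model 2 (acyl-enzyme equilibrium)"
  cat("<", model, " kinetic parameters>\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Read and write kinetic parameter sets
#'
#' Parameter sets serialize to a flat key-value mapping using the field's
#' symbol names (`kcat1`, `Km2`, `KS`, with k-4 spelled `k_m4`, ...).  The
#' format is chosen from the file extension: `.json` or `.yaml`/`.yml`.
#'
#' @param params A `model1_params` or `model2_params` object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns the parameter object.
#' @export
write_params <- function(params, path) {
  model_id <- if (inherits(params, "model1_params")) "model1" else "model2"
  obj <- c(list(model_id = model_id), as.list(unclass(params)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else stop("unsupported parameter file extension: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("unsupported parameter file extension: ", path, call. = FALSE)
  model_id <- obj$model_id
  if (is.null(model_id))
    stop("parameter file lacks a model_id field", call. = FALSE)
  as_params(unlist(obj[names(obj) != "model_id"]), model_id)
}
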