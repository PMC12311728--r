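#' Reaction state of the four-species system
#'
#' One time point of the batch reaction holds the concentrations (mM) of
#' amoxicillin (`C_AN`), the POHPG hydrolysis byproduct (`C_AOH`), the
#' 6-APA nucleophile (`C_NH`) and the POHPGME acyl-donor ester (`C_AB`).
#' The internal state ordering is fixed as `(C_AN, C_AOH, C_NH, C_AB)`.
#'
#' @param C_AN,C_AB,C_NH,C_AOH Species concentrations in mM.
#' @return A named numeric vector of class `reaction_state` in canonical
#'   order.
#' @export
reaction_state <- function(C_AN = 0, C_AB = 0, C_NH = 0, C_AOH = 0) {
  s <- c(C_AN = C_AN, C_AOH = C_AOH, C_NH = C_NH, C_AB = C_AB)
  check_state(s)
  structure(s, class = "reaction_state")
}

species_names <- function() c("C_AN", "C_AOH", "C_NH", "C_AB")

check_state <- function(s, allow_negative = FALSE) {
  if (anyNA(s) || any(!is.finite(s)))
    stop("concentrations must be finite and non-missing", call. = FALSE)
  if (!allow_negative && any(s < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  invisible(s)
}

#' Model 1 rate laws
#'
#' The Michaelis-Menten model resolves the network into three rates, all in
#' mM min^-1:
#' \describe{
#'   \item{`rate_ester_consumption()`}{total ester (POHPGME) consumption
#'     `v_AB`, Michaelis-Menten in `C_AB` with competitive inhibition by
#'     amoxicillin, 6-APA and POHPG.}
#'   \item{`rate_amox_hydrolysis()`}{secondary hydrolysis of amoxicillin
#'     `v_h2`, Michaelis-Menten in `C_AN` with competitive inhibition by
#'     ester, 6-APA and POHPG.}
#'   \item{`rate_amox_synthesis()`}{the fraction of ester consumption
#'     channeled into amoxicillin, `v_S = v_AB * C_NH * Tmax / (KEN + C_NH)`,
#'     saturating in the nucleophile via the enzyme adsorption constant.}
#' }
#'
#' As printed in the source rate law, the 6-APA term in the
#' ester-consumption denominator is scaled by `kAOH`, although the
#' narrative description of the mechanism assigns 6-APA inhibition to
#' `kNH`; `use_knh = TRUE` switches to the `kNH` variant.  The default
#' keeps the printed form.
#'
#' @param state A `reaction_state` (or named vector with the four species).
#' @param p A `model1_params` object.
#' @param e An `enzyme_load` or a single number (IU mL^-1).
#' @param use_knh Logical; divide the 6-APA inhibition term of `v_AB` by
#'   `kNH` instead of the printed `kAOH`.
#' @return A single rate in mM min^-1.
#' @export
rate_ester_consumption <- function(state, p, e, use_knh = FALSE) {
  s <- check_state(state); C_E <- as_enzyme_load(e)
  k_6apa <- if (use_knh) p[["kNH"]] else p[["kAOH"]]
  den <- p[["Km1"]] * (1 + s[["C_AN"]] / p[["kAN"]] + s[["C_NH"]] / k_6apa +
                         s[["C_AOH"]] / p[["kAOH"]]) + s[["C_AB"]]
  unname(p[["kcat1"]] * C_E * s[["C_AB"]] / den)
}

#' @rdname rate_ester_consumption
#' @export
rate_amox_hydrolysis <- function(state, p, e) {
  s <- check_state(state); C_E <- as_enzyme_load(e)
  den <- p[["Km2"]] * (1 + s[["C_AB"]] / p[["kAB"]] + s[["C_NH"]] / p[["kNH"]] +
                         s[["C_AOH"]] / p[["kAOH"]]) + s[["C_AN"]]
  unname(p[["kcat2"]] * C_E * s[["C_AN"]] / den)
}

#' @param v_AB The ester-consumption rate (mM min^-1), typically from
#'   `rate_ester_consumption()`.
#' @rdname rate_ester_consumption
#' @export
rate_amox_synthesis <- function(v_AB, state, p) {
  if (!is.finite(v_AB) || v_AB < 0)
    stop("v_AB must be a finite non-negative rate", call. = FALSE)
  s <- check_state(state)
  unname(v_AB * s[["C_NH"]] * p[["Tmax"]] / (p[["KEN"]] + s[["C_NH"]]))
}

#' ODE right-hand sides for both kinetic models
#'
#' Time derivatives of the state `(C_AN, C_AOH, C_NH, C_AB)` in mM min^-1.
#' For Model 1 the balance is built from the three rate laws:
#' `dC_AN/dt = v_S - v_h2`, `dC_AOH/dt = (v_AB - v_S) + v_h2`,
#' `dC_NH/dt = -(v_S - v_h2)`, `dC_AB/dt = -v_AB`.  For Model 2 the
#' amoxicillin and POHPG derivatives follow from the acyl-enzyme
#' quasi-equilibrium mechanism, with `dC_NH/dt = -dC_AN/dt` and
#' `dC_AB/dt = -(dC_AN/dt + dC_AOH/dt)`.
#'
#' Both systems conserve `C_AN + C_NH` (beta-lactam nucleus) and
#' `C_AB + C_AN + C_AOH` (acyl moiety) exactly in the algebra.  The rate
#' laws are evaluated as written even for (slightly) negative trial states,
#' as stiff integrators probe such states during error control;
#' non-negativity is enforced as a post-simulation check.
#'
#' These R implementations mirror the compiled versions used by
#' [simulate_batch()]; the two are cross-checked in the test suite.
#'
#' @param t Time (min); unused, the systems are autonomous.
#' @param state Named or canonically ordered concentration vector.
#' @param p `model1_params` / `model2_params`.
#' @param e Enzyme load (IU mL^-1).
#' @param use_knh See [rate_ester_consumption()].
#' @return A named numeric 4-vector of derivatives in canonical state
#'   order.
#' @export
rhs_model1 <- function(t, state, p, e, use_knh = FALSE) {
  s <- as_state_vector(state)
  C_E <- as_enzyme_load(e)
  k_6apa <- if (use_knh) p[["kNH"]] else p[["kAOH"]]
  v_AB <- p[["kcat1"]] * C_E * s[["C_AB"]] /
    (p[["Km1"]] * (1 + s[["C_AN"]] / p[["kAN"]] + s[["C_NH"]] / k_6apa +
                     s[["C_AOH"]] / p[["kAOH"]]) + s[["C_AB"]])
  v_h2 <- p[["kcat2"]] * C_E * s[["C_AN"]] /
    (p[["Km2"]] * (1 + s[["C_AB"]] / p[["kAB"]] + s[["C_NH"]] / p[["kNH"]] +
                     s[["C_AOH"]] / p[["kAOH"]]) + s[["C_AN"]])
  v_S <- v_AB * s[["C_NH"]] * p[["Tmax"]] / (p[["KEN"]] + s[["C_NH"]])
  c(C_AN = v_S - v_h2,
    C_AOH = (v_AB - v_S) + v_h2,
    C_NH = -(v_S - v_h2),
    C_AB = -v_AB)
}

#' @rdname rhs_model1
#' @export
rhs_model2 <- function(t, state, p, e) {
  s <- as_state_vector(state)
  C_E <- as_enzyme_load(e)
  den <- p[["k3"]] * p[["KN"]] + (p[["k4"]] + p[["k5"]]) * s[["C_NH"]]
  if (den <= 0)
    stop("model 2 denominator k3*KN + (k4+k5)*C_NH must be positive",
         call. = FALSE)
  dAN <- C_E / den *
    (p[["k2"]] * p[["k4"]] * s[["C_AB"]] * s[["C_NH"]] / p[["KS"]] -
       p[["k_m4"]] * s[["C_AN"]] *
         (p[["k3"]] * p[["KN"]] + p[["k5"]] * s[["C_NH"]]) / p[["KP"]])
  dAOH <- C_E * (p[["k3"]] * p[["KN"]] + p[["k5"]] * s[["C_NH"]]) / den *
    (p[["k2"]] * s[["C_AB"]] / p[["KS"]] - p[["k_m4"]] * s[["C_AN"]] / p[["KP"]])
  c(C_AN = dAN, C_AOH = dAOH, C_NH = -dAN, C_AB = -(dAN + dAOH))
}

# Accepts a reaction_state, a named vector in any order, or a bare numeric
# 4-vector assumed to be in canonical order. Negative entries are allowed
# here: integrator trial steps may probe them.
as_state_vector <- function(state) {
  nm <- species_names()
  if (is.numeric(state) && is.null(names(state))) {
    if (length(state) != 4L) stop("state must have 4 components", call. = FALSE)
    names(state) <- nm
    return(state)
  }
  if (!all(nm %in% names(state)))
    stop("state must name all of ", paste(nm, collapse = ", "), call. = FALSE)
  out <- as.numeric(state[nm]); names(out) <- nm
  check_state(out, allow_negative = TRUE)
  out
}
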