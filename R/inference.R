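#' Gaussian log-likelihood of a kinetic model against measured data
#'
#' Simulates the model at the data's sampling times and scores the fit
#' with an independent-Gaussian likelihood over all species and times:
#' `sum(-0.5 * log(2 * pi * sigma^2) - (obs - pred)^2 / (2 * sigma^2))`.
#' Measurement standard deviations come from `sigma_spec`: either the
#' per-observation `sigma_*` columns stored in a `noisy_timecourse`
#' (default), or a noise specification `list(rho, sigma0)` applied to the
#' observations, or a single numeric sd.
#'
#' A failed simulation (e.g. at pathological proposed parameters) returns
#' `-Inf`, which an MCMC caller treats as an automatic rejection.
#'
#' @param params Full parameter vector (named; canonical set for the
#'   model).
#' @param data A `noisy_timecourse` (or data frame with `time_min` and the
#'   four concentration columns).
#' @param model_id `"model1"` or `"model2"`.
#' @param sigma_spec `NULL` (use the data's sigma columns), a
#'   `list(rho, sigma0)`, or a positive scalar.
#' @param C_E Enzyme load; defaults to the data's recorded load.
#' @inheritParams simulate_batch
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(params, data, model_id, sigma_spec = NULL,
                           C_E = NULL, rel_tol = 1e-3, abs_tol = 1e-6) {
  if (nrow(data) < 1L) stop("data has no observations", call. = FALSE)
  conc_cols <- c("C_AN_mM", "C_AB_mM", "C_NH_mM", "C_AOH_mM")
  obs <- as.matrix(as.data.frame(data)[conc_cols])
  sigma <- resolve_sigma(data, sigma_spec, obs)
  if (any(sigma <= 0)) stop("measurement sd must be positive", call. = FALSE)
  if (is.null(C_E)) C_E <- attr(data, "C_E") %||% default_enzyme_load()
  p <- tryCatch(as_params(params, model_id), error = function(e) NULL)
  if (is.null(p)) return(-Inf)
  y0 <- c(C_AN = 0, C_AOH = 0,
          C_NH = data$C_NH_mM[data$time_min == 0][1],
          C_AB = data$C_AB_mM[data$time_min == 0][1])
  y0 <- attr(data, "y0") %||% y0
  sol <- integrate_model(model_id, p, y0, data$time_min, as_enzyme_load(C_E),
                         rel_tol = rel_tol, abs_tol = abs_tol)
  if (inherits(sol, "sim_failure")) return(-Inf)
  pred <- cbind(sol[, "C_AN"], sol[, "C_AB"], sol[, "C_NH"], sol[, "C_AOH"])
  sum(-0.5 * log(2 * pi * sigma^2) - (obs - pred)^2 / (2 * sigma^2))
}

resolve_sigma <- function(data, sigma_spec, obs) {
  conc_cols <- c("C_AN_mM", "C_AB_mM", "C_NH_mM", "C_AOH_mM")
  if (is.null(sigma_spec)) {
    sig_cols <- paste0("sigma_", conc_cols)
    if (all(sig_cols %in% names(data))) {
      s <- as.matrix(as.data.frame(data)[sig_cols])
      # zero sds can occur in noise-free data; floor at the default
      s[s <= 0] <- default_noise_spec()$sigma0
      return(s)
    }
    sigma_spec <- default_noise_spec()
  }
  if (is.numeric(sigma_spec) && length(sigma_spec) == 1L)
    return(matrix(sigma_spec, nrow(obs), ncol(obs)))
  if (is.list(sigma_spec))
    return(pmax(sigma_spec$rho * obs, sigma_spec$sigma0))
  stop("unrecognized sigma_spec", call. = FALSE)
}

#' Multiplicative random-walk proposal
#'
#' Candidate generation for the MH sampler: each component moves
#' multiplicatively, `P*_i = P_i * (1 + omega * eps_i)` with independent
#' standard-normal `eps_i` and relative step size `omega` (default
#' `6e-3`).  At this small `omega` the kernel is symmetric to excellent
#' approximation, so the plain Metropolis ratio applies; an exact
#' Hastings correction is available in [mh_step()].
#'
#' @param current Named numeric parameter vector.
#' @param omega Relative proposal standard deviation (> 0).
#' @return Candidate vector of the same names.
#' @export
propose <- function(current, omega = 6e-3) {
  if (omega <= 0) stop("omega must be positive", call. = FALSE)
  current * (1 + omega * stats::rnorm(length(current)))
}

# log q(to | from) for the multiplicative Gaussian kernel
log_proposal_density <- function(to, from, omega) {
  sum(stats::dnorm(to, mean = from, sd = omega * abs(from), log = TRUE))
}

#' One Metropolis-Hastings step
#'
#' Proposes a candidate with [propose()], evaluates its log-posterior via
#' `log_post_fn`, and accepts with probability
#' `min(1, exp(delta log-posterior))`.  On rejection the chain repeats the
#' current state.  Proposals with `-Inf` posterior (out of prior support,
#' failed simulation) are always rejected.
#'
#' @param current Named parameter vector (current state).
#' @param log_post_current Its log-posterior (finite).
#' @param log_post_fn Function: parameter vector -> log-posterior.
#' @param omega Relative proposal sd.
#' @param hastings Apply the exact asymmetry correction for the
#'   multiplicative kernel (default `FALSE`, matching the plain-MH
#'   formulation; negligible at `omega = 6e-3`).
#' @return List with `state`, `log_post`, `accepted`.
#' @export
mh_step <- function(current, log_post_current, log_post_fn,
                    omega = 6e-3, hastings = FALSE) {
  if (!is.finite(log_post_current))
    stop("current log-posterior must be finite", call. = FALSE)
  cand <- propose(current, omega)
  lp_cand <- log_post_fn(cand)
  log_alpha <- lp_cand - log_post_current
  if (hastings && is.finite(lp_cand))
    log_alpha <- log_alpha +
      log_proposal_density(current, cand, omega) -
      log_proposal_density(cand, current, omega)
  if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
    list(state = cand, log_post = lp_cand, accepted = TRUE)
  } else {
    list(state = current, log_post = log_post_current, accepted = FALSE)
  }
}

#' Uniform priors over the sensitivity bounds
#'
#' The default prior: independent uniforms over the same positivity-floored
#' +/-260% ranges used for the sensitivity analysis, which always contain
#' the literature values.  Returns a log-prior function.
#'
#' @param bounds Matrix from [build_bounds()].
#' @return Function: named parameter vector -> log-prior (`-Inf` outside
#'   the box, constant inside).
#' @export
uniform_prior <- function(bounds) {
  lo <- bounds[, "low"]; hi <- bounds[, "high"]
  lognorm <- -sum(log(hi - lo))
  nm <- rownames(bounds)
  function(p) {
    v <- p[nm]
    if (any(v < lo | v > hi)) -Inf else lognorm
  }
}

#' Run the Metropolis-Hastings sampler on one batch data set
#'
#' Estimates the screened-in (sensitive) parameters of a kinetic model by
#' MCMC, holding the screened-out parameters fixed at their literature
#' values.  The chain starts at the literature values, uses the
#' multiplicative proposal of [propose()] and uniform priors over the
#' sensitivity bounds by default, and is fully reproducible given `seed`.
#'
#' @inheritParams log_likelihood
#' @param estimated Character vector of parameter names to estimate; by
#'   default all parameters (screen first with [screen_parameters()]).
#' @param fixed_values Named vector of values for the non-estimated
#'   parameters (defaults to literature values).
#' @param init Starting point for the estimated parameters (defaults to
#'   literature values).
#' @param log_prior Log-prior function over the estimated parameters
#'   (default [uniform_prior()] on the sensitivity bounds).
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded from summaries (default 20% of
#'   `n_iter`).
#' @param omega Relative proposal sd (default `6e-3`).
#' @param seed Integer RNG seed.
#' @param hastings See [mh_step()].
#' @return An `mcmc_chain`: list with `samples` (iterations x estimated
#'   parameters), `log_post`, `accepted` (logical), `acceptance_rate`
#'   (post burn-in), `burn_in`, `estimated`, `fixed_values`, `model_id`,
#'   `seed`, `n_sim_failures`.
#' @export
run_mcmc <- function(data, model_id, estimated = NULL, fixed_values = NULL,
                     init = NULL, log_prior = NULL,
                     n_iter = 50000, burn_in = floor(0.2 * n_iter),
                     omega = 6e-3, seed = 1L, sigma_spec = NULL,
                     C_E = NULL, rel_tol = 1e-3, abs_tol = 1e-6,
                     hastings = FALSE) {
  model_id <- match.arg(model_id, c("model1", "model2"))
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  lit <- literature_params(model_id)
  all_names <- param_names(model_id)
  if (is.null(estimated)) estimated <- all_names
  if (!all(estimated %in% all_names))
    stop("unknown parameter(s): ",
         paste(setdiff(estimated, all_names), collapse = ", "), call. = FALSE)
  fixed_names <- setdiff(all_names, estimated)
  if (is.null(fixed_values)) fixed_values <- unclass(lit)[fixed_names]
  if (is.null(init)) init <- unclass(lit)[estimated]
  init <- init[estimated]
  if (is.null(log_prior)) {
    bounds <- build_bounds(lit)[estimated, , drop = FALSE]
    log_prior <- uniform_prior(bounds)
  }

  n_fail <- 0L
  assemble <- function(est) {
    full <- c(est, fixed_values)
    full[all_names]
  }
  log_post_fn <- function(est) {
    lp <- log_prior(est)
    if (!is.finite(lp)) return(-Inf)
    ll <- log_likelihood(assemble(est), data, model_id,
                         sigma_spec = sigma_spec, C_E = C_E,
                         rel_tol = rel_tol, abs_tol = abs_tol)
    if (!is.finite(ll)) n_fail <<- n_fail + 1L
    lp + ll
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  k <- length(estimated)
  samples <- matrix(NA_real_, n_iter, k,
                    dimnames = list(NULL, estimated))
  log_post <- numeric(n_iter)
  accepted <- logical(n_iter)
  cur <- init
  lp_cur <- log_post_fn(cur)
  if (!is.finite(lp_cur))
    stop("log-posterior is not finite at the starting point", call. = FALSE)
  for (it in seq_len(n_iter)) {
    st <- mh_step(cur, lp_cur, log_post_fn, omega = omega,
                  hastings = hastings)
    cur <- st$state; lp_cur <- st$log_post
    samples[it, ] <- cur
    log_post[it] <- lp_cur
    accepted[it] <- st$accepted
  }
  acc_post <- mean(accepted[(burn_in + 1):n_iter])
  if (acc_post == 0)
    warning("no proposals accepted after burn-in; consider retuning omega",
            call. = FALSE)
  structure(list(samples = samples, log_post = log_post, accepted = accepted,
                 acceptance_rate = acc_post, burn_in = as.integer(burn_in),
                 estimated = estimated, fixed_values = fixed_values,
                 model_id = model_id, seed = as.integer(seed),
                 omega = omega, n_sim_failures = n_fail),
            class = "mcmc_chain")
}

#' Posterior summaries in the reporting layout
#'
#' Post-burn-in mean, standard deviation and central credible interval per
#' estimated parameter; fixed parameters are echoed with a `fixed` flag
#' (the asterisk convention of the reporting tables) and never summarized
#' as estimated.
#'
#' @param chain An `mcmc_chain`.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `parameter`, `mean`, `sd`, `lo`, `hi`,
#'   `fixed`.
#' @export
summarize_posterior <- function(chain, level = 0.95) {
  post <- chain$samples[(chain$burn_in + 1):nrow(chain$samples), ,
                        drop = FALSE]
  if (nrow(post) < 100L)
    stop("need at least 100 post-burn-in samples", call. = FALSE)
  a <- (1 - level) / 2
  est <- data.frame(
    parameter = colnames(post),
    mean = colMeans(post),
    sd = apply(post, 2, stats::sd),
    lo = apply(post, 2, stats::quantile, probs = a, names = FALSE),
    hi = apply(post, 2, stats::quantile, probs = 1 - a, names = FALSE),
    fixed = FALSE, row.names = NULL)
  if (length(chain$fixed_values)) {
    fx <- data.frame(parameter = names(chain$fixed_values),
                     mean = unname(chain$fixed_values),
                     sd = 0, lo = unname(chain$fixed_values),
                     hi = unname(chain$fixed_values), fixed = TRUE)
    est <- rbind(est, fx)
  }
  nm <- param_names(chain$model_id)
  est[order(match(est$parameter, nm)), , drop = FALSE]
}

#' Posterior mean as a full parameter vector
#'
#' Convenience for downstream simulation: post-burn-in posterior means for
#' the estimated parameters merged with the fixed values, in canonical
#' order.
#' @param chain An `mcmc_chain`.
#' @return A `model1_params`/`model2_params` object.
#' @export
posterior_mean_params <- function(chain) {
  post <- chain$samples[(chain$burn_in + 1):nrow(chain$samples), ,
                        drop = FALSE]
  est <- colMeans(post)
  as_params(c(est, chain$fixed_values), chain$model_id)
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain: %s, %d iterations (burn-in %d), %d estimated>\n",
              x$model_id, nrow(x$samples), x$burn_in, length(x$estimated)))
  cat(sprintf("acceptance rate (post burn-in): %.3f; sim failures: %d\n",
              x$acceptance_rate, x$n_sim_failures))
  invisible(x)
}

#' Persist an MCMC chain
#'
#' Writes the iteration-level chain as CSV (iteration, parameters,
#' log-posterior, accepted) and, optionally, a JSON posterior summary in
#' the mean +/- sd layout with fixed parameters flagged.
#'
#' @param chain An `mcmc_chain`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the chain.
#' @export
write_chain <- function(chain, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.frame(iteration = seq_len(nrow(chain$samples)),
                     chain$samples,
                     log_post = chain$log_post,
                     accepted = chain$accepted)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    s <- summarize_posterior(chain)
    jsonlite::write_json(
      list(model_id = chain$model_id, seed = chain$seed,
           acceptance_rate = chain$acceptance_rate,
           summary = s),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(chain)
}
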