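#' Relative root-mean-square error
#'
#' `rrmse()` scores agreement between measured and predicted concentration
#' series as a percentage: `100 * sqrt(mean((obs - pred)^2)) /
#' (max(obs) - min(obs))` — the root of the mean squared error normalized
#' by the observed range.  It is invariant to common positive rescaling
#' and common translation of both series.  For matrix input (one column
#' per species) the error is computed per species and averaged.
#'
#' @param observed,predicted Numeric vectors of equal length, or matrices
#'   of equal shape (columns = species).
#' @return rRMSE as a percentage.
#' @export
rrmse <- function(observed, predicted) {
  if (is.matrix(observed) || is.data.frame(observed)) {
    observed <- as.matrix(observed); predicted <- as.matrix(predicted)
    if (!all(dim(observed) == dim(predicted)))
      stop("observed and predicted must have the same shape", call. = FALSE)
    return(mean(vapply(seq_len(ncol(observed)), function(j)
      rrmse(observed[, j], predicted[, j]), numeric(1))))
  }
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  rng <- max(observed) - min(observed)
  if (rng <= 0)
    stop("observed series is constant; range-normalized error is undefined",
         call. = FALSE)
  100 * sqrt(mean((observed - predicted)^2)) / rng
}

#' Information criteria for model comparison
#'
#' `aic(lnL, k) = -2 lnL + 2k`; `bic(lnL, k, n) = -2 lnL + k ln(n)`, where
#' `k` counts the estimated (non-fixed) parameters and `n` the total
#' scalar observations (all species x all times).
#'
#' @param log_likelihood Log-likelihood at the evaluated parameter point.
#' @param k Number of estimated parameters (>= 0).
#' @param n Number of scalar observations (>= 1).
#' @return A numeric scalar.
#' @export
aic <- function(log_likelihood, k) {
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  -2 * log_likelihood + 2 * k
}

#' @rdname aic
#' @export
bic <- function(log_likelihood, k, n) {
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  -2 * log_likelihood + k * log(n)
}

#' Fit metrics for one model on one data set
#'
#' Simulates the model at the data's sampling times from the given
#' parameter point (typically a posterior mean) and reports rRMSE (%),
#' AIC, BIC, the log-likelihood at that point, `n` (scalar observations)
#' and `k` (estimated parameters).
#'
#' @inheritParams log_likelihood
#' @param k Number of estimated parameters charged to AIC/BIC.
#' @return A one-row data frame of class `fit_metrics`.
#' @export
fit_metrics <- function(params, data, model_id, k, sigma_spec = NULL,
                        C_E = NULL, rel_tol = 1e-3, abs_tol = 1e-6) {
  conc_cols <- c("C_AN_mM", "C_AB_mM", "C_NH_mM", "C_AOH_mM")
  obs <- as.matrix(as.data.frame(data)[conc_cols])
  pred <- predict_timecourse(params, data, model_id, C_E,
                             rel_tol = rel_tol, abs_tol = abs_tol)
  ll <- log_likelihood(params, data, model_id, sigma_spec = sigma_spec,
                       C_E = C_E, rel_tol = rel_tol, abs_tol = abs_tol)
  n <- length(obs)
  structure(data.frame(rRMSE = rrmse(obs, pred), AIC = aic(ll, k),
                       BIC = bic(ll, k, n), logLik = ll, n = n, k = k),
            class = c("fit_metrics", "data.frame"))
}

predict_timecourse <- function(params, data, model_id, C_E = NULL,
                               rel_tol = 1e-3, abs_tol = 1e-6) {
  if (is.null(C_E)) C_E <- attr(data, "C_E") %||% default_enzyme_load()
  y0 <- attr(data, "y0") %||% c(C_AN = 0, C_AOH = 0,
                                C_NH = data$C_NH_mM[1], C_AB = data$C_AB_mM[1])
  p <- as_params(params, model_id)
  sol <- integrate_model(model_id, p, y0, data$time_min, as_enzyme_load(C_E),
                         rel_tol = rel_tol, abs_tol = abs_tol)
  if (inherits(sol, "sim_failure"))
    stop("prediction failed near t = ", signif(sol$t_fail, 4), call. = FALSE)
  cbind(sol[, "C_AN"], sol[, "C_AB"], sol[, "C_NH"], sol[, "C_AOH"])
}

#' Leave-one-experiment-out cross-validation
#'
#' For each calibration experiment i: fit the model to data set i by MCMC,
#' take the posterior mean, simulate every experiment from its initial
#' state, and fill row i of the matrix with per-experiment rRMSE values
#' (the diagonal is the in-sample fit).  Row means over the off-diagonal
#' entries rank the calibration experiments; the argmin row is the best
#' calibration experiment.
#'
#' @param datasets Named list of `noisy_timecourse` objects, one per
#'   condition (as from [generate_study()]).
#' @param model_id `"model1"` or `"model2"`.
#' @param estimated Parameter names to estimate (from
#'   [screen_parameters()]); `NULL` estimates all.
#' @param n_iter,burn_in,omega,seed MCMC settings (see [run_mcmc()]).
#' @param sigma_spec See [log_likelihood()].
#' @return A `crossval_matrix`: the rRMSE matrix (rows = calibration
#'   experiment, columns = evaluated experiment) with attributes
#'   `row_mean_offdiag`, `best_row`, `chains` (posterior mean vectors) and
#'   `failed_rows`.
#' @export
cross_validate <- function(datasets, model_id, estimated = NULL,
                           n_iter = 5000, burn_in = floor(0.2 * n_iter),
                           omega = 6e-3, seed = 1L, sigma_spec = NULL) {
  ids <- names(datasets)
  n <- length(datasets)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  post_means <- vector("list", n); names(post_means) <- ids
  failed <- character(0)
  for (i in seq_len(n)) {
    ch <- tryCatch(
      run_mcmc(datasets[[i]], model_id, estimated = estimated,
               n_iter = n_iter, burn_in = burn_in, omega = omega,
               seed = (as.integer(seed) * 131L + i) %% .Machine$integer.max,
               sigma_spec = sigma_spec),
      error = function(e) NULL)
    if (is.null(ch)) { failed <- c(failed, ids[i]); next }
    pm <- posterior_mean_params(ch)
    post_means[[i]] <- pm
    for (j in seq_len(n)) {
      obs <- as.matrix(as.data.frame(datasets[[j]])[
        c("C_AN_mM", "C_AB_mM", "C_NH_mM", "C_AOH_mM")])
      pred <- tryCatch(
        predict_timecourse(pm, datasets[[j]], model_id),
        error = function(e) NULL)
      if (!is.null(pred)) M[i, j] <- rrmse(obs, pred)
    }
  }
  offdiag <- M; diag(offdiag) <- NA
  row_mean <- rowMeans(offdiag, na.rm = TRUE)
  best <- if (all(is.na(row_mean))) NA_character_ else
    ids[which.min(row_mean)]
  structure(M, class = c("crossval_matrix", "matrix", "array"),
            row_mean_offdiag = row_mean, best_row = best,
            chains = post_means, failed_rows = failed)
}

#' @export
print.crossval_matrix <- function(x, ...) {
  cat("<crossval_matrix: rows = calibration experiment, cols = evaluated>\n")
  print(round(unclass(x), 2), ...)
  cat("best calibration row:", attr(x, "best_row"), "\n")
  invisible(x)
}

#' Write a cross-validation matrix to CSV
#'
#' Labeled rows/columns plus a trailing column of off-diagonal row means.
#' @param m A `crossval_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crossval <- function(m, path) {
  df <- data.frame(calibration = rownames(m), unclass(m),
                   mean_offdiag = attr(m, "row_mean_offdiag"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Model comparison table
#'
#' Collects `fit_metrics` rows for several (model, parameter source)
#' entries evaluated on the same data sets and declares a winner by lowest
#' rRMSE, with AIC/BIC as corroboration.  Identical metric rows are
#' reported as an explicit tie.
#'
#' @param entries Named list of `fit_metrics` (or one-row data frames with
#'   `rRMSE`, `AIC`, `BIC`, `n`).
#' @return A `model_comparison` data frame (rows = entries) with
#'   attributes `winner` (entry name, or `"tie"`) and `tie`.
#' @export
compare_models <- function(entries) {
  if (length(entries) < 2L)
    stop("need at least two entries to compare", call. = FALSE)
  ns <- vapply(entries, function(e) e$n[1], numeric(1))
  if (length(unique(ns)) != 1L)
    stop("entries were evaluated on different numbers of observations; ",
         "metrics are not comparable", call. = FALSE)
  tab <- do.call(rbind, lapply(entries, function(e)
    data.frame(rRMSE = e$rRMSE[1], AIC = e$AIC[1], BIC = e$BIC[1],
               n = e$n[1], k = e$k[1])))
  rownames(tab) <- names(entries)
  best <- which(tab$rRMSE == min(tab$rRMSE))
  tie <- length(best) > 1L
  structure(tab, class = c("model_comparison", "data.frame"),
            winner = if (tie) "tie" else rownames(tab)[best],
            tie = tie)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model comparison (winner by lowest rRMSE)>\n")
  print(as.data.frame(x), ...)
  cat("winner:", attr(x, "winner"), "\n")
  invisible(x)
}
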