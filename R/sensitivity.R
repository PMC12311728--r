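#' Sampling bounds for global sensitivity analysis
#'
#' Parameters are sampled within +/-260% of their literature values by
#' default (`span = 2.6`).  Because `v * (1 - 2.6)` is negative and all
#' kinetic constants must be positive, the lower bound is floored at
#' `floor_frac * v` (default `1e-3 * v`); the interpretation is
#' multiplicative around the literature value with a positivity floor.
#'
#' @param literature A `kinetic_params` object or named positive vector.
#' @param span Half-width of the relative sampling range (2.6 = +/-260%).
#' @param floor_frac Positivity floor as a fraction of the literature
#'   value.
#' @return A matrix with one row per parameter and columns `low`, `high`.
#' @export
build_bounds <- function(literature, span = 2.6, floor_frac = 1e-3) {
  v <- unclass(literature)
  if (span <= 0) stop("span must be positive", call. = FALSE)
  if (any(v <= 0) || any(!is.finite(v)))
    stop("literature values must be positive and finite", call. = FALSE)
  b <- cbind(low = pmax(v * (1 - span), floor_frac * v),
             high = v * (1 + span))
  rownames(b) <- names(v)
  b
}

#' Saltelli cross-sampling design
#'
#' Builds the cross-sampled design supporting estimation of first- and
#' total-order Sobol indices: two independent base matrices A and B of
#' `base_n` rows are drawn from a seeded maximin-free Latin hypercube over
#' the unit cube (columns then rescaled to `bounds`), and the radial blocks
#' `AB_i` (A with column i from B) — plus `BA_i` when `second_order = TRUE`
#' — are appended.  Total rows: `N * (2d + 2)` with second-order blocks on,
#' `N * (d + 2)` off.
#'
#' @param bounds Matrix from [build_bounds()] (rows = parameters, columns
#'   `low`, `high`).
#' @param base_n Base sample size N; a power of 2.
#' @param second_order Include the `BA_i` blocks (default `TRUE`).
#' @param seed RNG seed for the base sample.
#' @return A `saltelli_design`: the design matrix (rows x d) with
#'   attributes `base_n`, `second_order`, `bounds`, `seed` and the block
#'   layout used by the estimators.
#' @export
saltelli_sample <- function(bounds, base_n, second_order = TRUE, seed = 1L) {
  d <- nrow(bounds)
  if (d < 1L) stop("need at least one parameter", call. = FALSE)
  if (base_n < 1L) stop("base_n must be at least 1", call. = FALSE)
  if (bitwAnd(base_n, base_n - 1L) != 0L)
    stop("base_n must be a power of 2", call. = FALSE)
  if (any(bounds[, "high"] <= bounds[, "low"]))
    stop("each high bound must exceed its low bound", call. = FALSE)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  base <- lhs::randomLHS(base_n, 2L * d)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  A <- base[, seq_len(d), drop = FALSE]
  B <- base[, d + seq_len(d), drop = FALSE]
  blocks <- vector("list", if (second_order) 2L * d + 2L else d + 2L)
  blocks[[1]] <- A
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    blocks[[1L + i]] <- ABi
  }
  if (second_order) {
    for (i in seq_len(d)) {
      BAi <- B; BAi[, i] <- A[, i]
      blocks[[1L + d + i]] <- BAi
    }
  }
  blocks[[length(blocks)]] <- B
  design01 <- do.call(rbind, blocks)
  lo <- bounds[, "low"]; hi <- bounds[, "high"]
  design <- sweep(sweep(design01, 2L, hi - lo, "*"), 2L, lo, "+")
  colnames(design) <- rownames(bounds)
  structure(design, class = c("saltelli_design", "matrix", "array"),
            base_n = as.integer(base_n), second_order = second_order,
            bounds = bounds, seed = as.integer(seed))
}

# Row indices of the A, B and AB_i blocks within a saltelli_design.
design_blocks <- function(design) {
  N <- attr(design, "base_n")
  d <- ncol(design)
  n_blocks <- if (attr(design, "second_order")) 2L * d + 2L else d + 2L
  list(N = N, d = d,
       A = seq_len(N),
       AB = lapply(seq_len(d), function(i) N * i + seq_len(N)),
       B = N * (n_blocks - 1L) + seq_len(N))
}

#' Evaluate a model ensemble over a Saltelli design
#'
#' Simulates every design row under each selected batch condition on a
#' common output grid.  Failed integrations (step-size collapse,
#' non-finite states) are recorded and excluded from index estimation with
#' a logged count; more than `max_fail_frac` failures aborts, since that
#' signals pathological sampling bounds.
#'
#' In addition to outright integration failures, runs that leave the
#' model's physical domain are dropped: a trajectory is unphysical when any
#' concentration magnitude exceeds `phys_bound_factor` times the total
#' conserved mass `C_NH0 + C_AB0` of its condition.  Such runs arise under
#' the very wide sampling ranges when a species is driven negative (for
#' the equilibrium model the quasi-steady-state denominator
#' `k3*KN + (k4+k5)*C_NH` can then vanish, making the dynamics singular);
#' their near-arbitrary magnitudes would otherwise dominate the output
#' variance.  Both exclusion counts are logged.
#'
#' @inheritParams simulate_batch
#' @param design A `saltelli_design` whose columns are the model's
#'   parameters.
#' @param conditions A `condition_grid` (subset) of conditions to simulate.
#' @param max_fail_frac Maximum tolerated fraction of failed rows.
#' @param phys_bound_factor Physicality bound as a multiple of the total
#'   conserved mass (default 1).
#' @return A `sobol_ensemble`: list with `outputs` (one rows x
#'   (species*time) matrix per condition), `failed` and `unphysical`
#'   (logical per design row x condition), `design`, `times`,
#'   `conditions`, `model_id`, `species`.
#' @export
evaluate_ensemble <- function(model_id, design, conditions,
                              times = default_time_grid(),
                              C_E = default_enzyme_load(),
                              rel_tol = 1e-3, abs_tol = 1e-6,
                              max_fail_frac = 0.01,
                              phys_bound_factor = 1, use_knh = FALSE) {
  model_id <- match.arg(model_id, c("model1", "model2"))
  n_row <- nrow(design)
  n_cond <- nrow(conditions)
  species <- c("C_AN", "C_AOH", "C_NH", "C_AB")
  outputs <- vector("list", n_cond)
  failed <- matrix(FALSE, n_row, n_cond)
  unphysical <- matrix(FALSE, n_row, n_cond)
  for (ci in seq_len(n_cond)) {
    cond <- get_condition(conditions, conditions$experiment_id[ci])
    y0 <- c(C_AN = 0, C_AOH = 0, C_NH = cond$C_NH0, C_AB = cond$C_AB0)
    mass_bound <- phys_bound_factor * (cond$C_NH0 + cond$C_AB0) + 1e-6
    Y <- matrix(NA_real_, n_row, 4L * length(times))
    for (r in seq_len(n_row)) {
      # design rows bypass the physical-range validation (e.g. Tmax <= 1):
      # the +/-260% sampling deliberately explores beyond it, positivity is
      # guaranteed by the bounds
      p <- design[r, ]
      sol <- integrate_model(model_id, p, y0, times, C_E,
                             rel_tol = rel_tol, abs_tol = abs_tol,
                             use_knh = use_knh)
      if (inherits(sol, "sim_failure")) {
        failed[r, ci] <- TRUE
      } else if (max(abs(sol[, species])) > mass_bound) {
        unphysical[r, ci] <- TRUE
      } else {
        Y[r, ] <- as.vector(sol[, species])  # time fastest, species blocks
      }
    }
    outputs[[ci]] <- Y
  }
  fail_frac <- mean(failed)
  if (fail_frac > max_fail_frac)
    stop(sprintf("%.1f%% of ensemble runs failed (> %g%%); check bounds",
                 100 * fail_frac, 100 * max_fail_frac), call. = FALSE)
  if (any(failed) || any(unphysical))
    message(sum(failed), " failed and ", sum(unphysical),
            " unphysical runs of ", length(failed), " were excluded")
  names(outputs) <- paste0("exp", conditions$experiment_id)
  structure(list(outputs = outputs, failed = failed,
                 unphysical = unphysical, design = design,
                 times = times, conditions = conditions, model_id = model_id,
                 species = species, C_E = C_E),
            class = "sobol_ensemble")
}

# Core variance-based estimators on one output matrix (rows follow the
# design's block layout; columns are output coordinates).  Saltelli-2010
# first-order and Jansen total-order estimators.  Excluded runs (NA rows)
# are handled by pairwise deletion: the index for parameter i uses the
# base samples whose A, B and AB_i rows are all complete, so a dropped row
# does not discard the whole base block for every parameter.
sobol_estimate_matrix <- function(Y, design) {
  bl <- design_blocks(design)
  fA0 <- Y[bl$A, , drop = FALSE]
  fB0 <- Y[bl$B, , drop = FALSE]
  ok_ab <- stats::complete.cases(fA0) & stats::complete.cases(fB0)
  S1 <- matrix(0, bl$d, ncol(Y), dimnames = list(colnames(design), NULL))
  ST <- S1
  flagged <- rep(FALSE, ncol(Y))
  V_all <- rep(NA_real_, ncol(Y))
  ok_any <- rep(FALSE, bl$N)
  for (i in seq_len(bl$d)) {
    fABi <- Y[bl$AB[[i]], , drop = FALSE]
    ok <- ok_ab & stats::complete.cases(fABi)
    if (sum(ok) < 2L) stop("fewer than 2 usable base samples", call. = FALSE)
    ok_any <- ok_any | ok
    fA <- fA0[ok, , drop = FALSE]; fB <- fB0[ok, , drop = FALSE]
    fAB <- fABi[ok, , drop = FALSE]
    n <- sum(ok)
    mu <- (colMeans(fA) + colMeans(fB)) / 2
    V <- (colSums(sweep(fA, 2, mu)^2) + colSums(sweep(fB, 2, mu)^2)) /
      (2 * n - 1)
    fl <- V < 1e-10
    Vsafe <- ifelse(fl, 1, V)
    # center outputs before the first-order numerator (as the reference
    # implementations normalize Y): identical in expectation, but removes
    # the mean(fB)*mean(fAB - fA) noise term that dominates for
    # heavy-tailed outputs
    fAc <- sweep(fA, 2, mu); fBc <- sweep(fB, 2, mu)
    fABc <- sweep(fAB, 2, mu)
    S1[i, ] <- colMeans(fBc * (fABc - fAc)) / Vsafe
    ST[i, ] <- colMeans((fA - fAB)^2) / (2 * Vsafe)
    S1[i, fl] <- 0; ST[i, fl] <- 0
    flagged <- flagged | fl
    if (i == 1L) V_all <- V
  }
  list(S1 = S1, ST = ST, V = V_all, flagged = flagged,
       n_used = sum(ok_any), ok = ok_any)
}

#' Sobol first- and total-order indices
#'
#' Estimates S1 (direct variance share) and ST (total variance share,
#' including interactions) from model outputs evaluated on a Saltelli
#' design, using the standard Saltelli-2010 first-order and Jansen
#' total-order estimators on the radial blocks.  Output coordinates with
#' (numerically) zero variance get indices 0 and are flagged.
#'
#' `outputs` may be a numeric vector (scalar model output per design row),
#' a matrix (rows x coordinates), or a `sobol_ensemble`, in which case the
#' result is resolved per parameter, species, time and condition, and
#' aggregates are computed as the arithmetic mean over all time points,
#' species and conditions.
#'
#' @param outputs Vector, matrix or `sobol_ensemble`.
#' @param design The `saltelli_design` (ignored for a `sobol_ensemble`,
#'   which carries its own).
#' @return A `sobol_result` list: `S1`/`ST` (for ensembles, arrays
#'   `[parameter, species, time, condition]`; otherwise `d x m` matrices),
#'   `aggregate` (named mean S1/ST per parameter), `flagged_fraction`,
#'   `model_id`, `times`, `species`.
#' @export
sobol_indices <- function(outputs, design = NULL) {
  if (inherits(outputs, "sobol_ensemble")) {
    ens <- outputs
    design <- ens$design
    d <- ncol(design); nt <- length(ens$times); ns <- length(ens$species)
    n_cond <- length(ens$outputs)
    dn <- list(parameter = colnames(design), species = ens$species,
               time = NULL, condition = names(ens$outputs))
    S1 <- array(NA_real_, c(d, ns, nt, n_cond), dimnames = dn)
    ST <- S1
    flagged <- 0; total <- 0
    for (ci in seq_len(n_cond)) {
      est <- sobol_estimate_matrix(ens$outputs[[ci]], design)
      # estimator columns are (species block x time, time fastest)
      S1[, , , ci] <- aperm(array(est$S1, c(d, nt, ns)), c(1, 3, 2))
      ST[, , , ci] <- aperm(array(est$ST, c(d, nt, ns)), c(1, 3, 2))
      flagged <- flagged + sum(est$flagged); total <- total + length(est$flagged)
    }
    res <- list(S1 = S1, ST = ST,
                aggregate = list(S1 = apply(S1, 1, mean),
                                 ST = apply(ST, 1, mean)),
                flagged_fraction = flagged / total,
                model_id = ens$model_id, times = ens$times,
                species = ens$species, design = design)
    return(structure(res, class = "sobol_result"))
  }
  if (is.null(design)) stop("design is required", call. = FALSE)
  Y <- if (is.matrix(outputs)) outputs else matrix(outputs, ncol = 1L)
  est <- sobol_estimate_matrix(Y, design)
  structure(list(S1 = est$S1, ST = est$ST, V = est$V,
                 aggregate = list(S1 = rowMeans(est$S1),
                                  ST = rowMeans(est$ST)),
                 flagged_fraction = mean(est$flagged),
                 design = design),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result>\n")
  agg <- cbind(S1 = x$aggregate$S1, ST = x$aggregate$ST)
  print(round(agg[order(-agg[, "ST"]), , drop = FALSE], 4))
  invisible(x)
}

#' Bootstrap confidence intervals for Sobol indices
#'
#' Percentile confidence intervals obtained by resampling whole base-sample
#' blocks (a resampled index j carries its A, B and all AB_i rows
#' together), preserving the cross-sampling structure.  Intended for
#' scalar or modest-dimensional outputs; for full time-resolved ensembles
#' apply it to a thinned grid.
#'
#' @param outputs Numeric vector or matrix of model outputs (design rows x
#'   coordinates).
#' @param design The `saltelli_design`.
#' @param n_boot Number of bootstrap resamples (>= 2; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List with `S1_lo`, `S1_hi`, `ST_lo`, `ST_hi` (d x m matrices of
#'   percentile bounds) and `S1_ci`, `ST_ci` (half-widths).
#' @export
bootstrap_ci <- function(outputs, design, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  if (n_boot < 2L) stop("n_boot must be at least 2", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  Y <- if (is.matrix(outputs)) outputs else matrix(outputs, ncol = 1L)
  bl <- design_blocks(design)
  # bootstrap resampling requires fully complete base blocks
  ok <- stats::complete.cases(Y[bl$A, , drop = FALSE]) &
    stats::complete.cases(Y[bl$B, , drop = FALSE])
  for (i in seq_len(bl$d))
    ok <- ok & stats::complete.cases(Y[bl$AB[[i]], , drop = FALSE])
  ok_idx <- which(ok)
  n <- length(ok_idx)
  if (n < 2L) stop("fewer than 2 complete base samples", call. = FALSE)
  d <- bl$d; m <- ncol(Y)
  s1 <- array(NA_real_, c(n_boot, d, m)); st <- s1
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  fA0 <- Y[bl$A, , drop = FALSE]; fB0 <- Y[bl$B, , drop = FALSE]
  fAB0 <- lapply(seq_len(d), function(i) Y[bl$AB[[i]], , drop = FALSE])
  for (b in seq_len(n_boot)) {
    idx <- sample(ok_idx, n, replace = TRUE)
    fA <- fA0[idx, , drop = FALSE]; fB <- fB0[idx, , drop = FALSE]
    mu <- (colMeans(fA) + colMeans(fB)) / 2
    V <- (colSums(sweep(fA, 2, mu)^2) + colSums(sweep(fB, 2, mu)^2)) /
      (2 * n - 1)
    V <- pmax(V, 1e-300)
    fAc <- sweep(fA, 2, mu); fBc <- sweep(fB, 2, mu)
    for (i in seq_len(d)) {
      fAB <- fAB0[[i]][idx, , drop = FALSE]
      s1[b, i, ] <- colMeans(fBc * (sweep(fAB, 2, mu) - fAc)) / V
      st[b, i, ] <- colMeans((fA - fAB)^2) / (2 * V)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  a <- (1 - level) / 2
  qlo <- function(x) apply(x, c(2, 3), stats::quantile, probs = a, names = FALSE)
  qhi <- function(x) apply(x, c(2, 3), stats::quantile, probs = 1 - a, names = FALSE)
  S1_lo <- qlo(s1); S1_hi <- qhi(s1); ST_lo <- qlo(st); ST_hi <- qhi(st)
  rn <- colnames(design)
  dimnames(S1_lo) <- dimnames(S1_hi) <- dimnames(ST_lo) <- dimnames(ST_hi) <-
    list(rn, NULL)
  list(S1_lo = S1_lo, S1_hi = S1_hi, ST_lo = ST_lo, ST_hi = ST_hi,
       S1_ci = (S1_hi - S1_lo) / 2, ST_ci = (ST_hi - ST_lo) / 2,
       level = level, n_boot = n_boot)
}

#' Temporal gradients of sensitivity indices
#'
#' Differentiates index time series with central finite differences on the
#' interior (using local spacing, so non-uniform grids are handled) and
#' one-sided differences at the ends, and locates local extrema as sign
#' changes of the gradient.
#'
#' For a `sobol_result` from an ensemble, indices are first averaged over
#' conditions, giving `dST/dt` and `dS1/dt` arrays
#' `[parameter, species, time]` plus an extrema table.
#'
#' @param x A numeric index series or a `sobol_result`.
#' @param times Sampling times; taken from the result when available.
#' @param ... Unused.
#' @return For a series: list with `gradient` and `extrema` (times where
#'   the gradient changes sign).  For a `sobol_result`: list with
#'   `dST_dt`, `dS1_dt` arrays and an `extrema` data frame
#'   (parameter, species, index, time, type).
#' @export
temporal_gradient <- function(x, times = NULL, ...) UseMethod("temporal_gradient")

#' @export
temporal_gradient.default <- function(x, times = NULL, ...) {
  y <- as.numeric(x)
  if (is.null(times)) times <- seq_along(y)
  if (length(y) < 3L) stop("need at least 3 time points", call. = FALSE)
  g <- finite_diff(y, times)
  list(gradient = g, extrema = extrema_times(g, times))
}

#' @export
temporal_gradient.sobol_result <- function(x, times = NULL, ...) {
  if (is.null(times)) times <- x$times
  if (length(dim(x$ST)) != 4L)
    stop("temporal gradients need a time-resolved (ensemble) result",
         call. = FALSE)
  ST <- apply(x$ST, c(1, 2, 3), mean)  # average over conditions
  S1 <- apply(x$S1, c(1, 2, 3), mean)
  grad_arr <- function(A) {
    out <- A
    for (i in seq_len(dim(A)[1])) for (j in seq_len(dim(A)[2]))
      out[i, j, ] <- finite_diff(A[i, j, ], times)
    out
  }
  dST <- grad_arr(ST); dS1 <- grad_arr(S1)
  ex <- list()
  for (i in seq_len(dim(dST)[1])) for (j in seq_len(dim(dST)[2])) {
    et <- extrema_times(dST[i, j, ], times)
    if (nrow(et))
      ex[[length(ex) + 1L]] <- cbind(
        parameter = dimnames(x$ST)[[1]][i],
        species = dimnames(x$ST)[[2]][j], et)
  }
  extrema <- if (length(ex)) do.call(rbind, ex) else
    data.frame(parameter = character(), species = character(),
               time = numeric(), type = character())
  list(dST_dt = dST, dS1_dt = dS1, extrema = extrema)
}

finite_diff <- function(y, t) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  g
}

extrema_times <- function(g, times) {
  s <- sign(g)
  nz <- which(s != 0)
  out <- data.frame(time = numeric(), type = character())
  if (length(nz) < 2L) return(out)
  for (k in seq_len(length(nz) - 1L)) {
    i <- nz[k]; j <- nz[k + 1L]
    if (s[i] > 0 && s[j] < 0)
      out <- rbind(out, data.frame(time = (times[i] + times[j]) / 2,
                                   type = "maximum"))
    if (s[i] < 0 && s[j] > 0)
      out <- rbind(out, data.frame(time = (times[i] + times[j]) / 2,
                                   type = "minimum"))
  }
  out
}

#' Screen parameters by aggregate total-order index
#'
#' Parameters whose aggregate mean ST falls below the threshold (default
#' 0.1) are classified nonsignificant and fixed at their literature values
#' during estimation; the rest form the estimated set.
#'
#' @param result A `sobol_result` with aggregates.
#' @param threshold Screening threshold on mean ST, in (0, 1).
#' @return List with `fixed` and `estimated` (character vectors of
#'   parameter names) and `aggregate_ST`.
#' @export
screen_parameters <- function(result, threshold = 0.1) {
  if (threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)", call. = FALSE)
  st <- result$aggregate$ST
  list(fixed = names(st)[st < threshold],
       estimated = names(st)[st >= threshold],
       aggregate_ST = st, threshold = threshold)
}

#' Default conditions for the sensitivity analysis
#'
#' Six batch conditions spanning the extremes of the 13-experiment grid
#' (experiments 1, 2, 6, 7, 10, 13), used as the state-space coverage for
#' the time-resolved Sobol analysis.
#' @inheritParams make_condition_grid
#' @return A `condition_grid` with 6 rows.
#' @export
default_sensitivity_conditions <- function(C_E = default_enzyme_load()) {
  grid <- make_condition_grid(C_E = C_E)
  structure(grid[grid$experiment_id %in% c(1L, 2L, 6L, 7L, 10L, 13L), ],
            class = class(grid))
}

#' Run the full Sobol sensitivity workflow for one model
#'
#' Convenience wrapper: bounds at +/-`span` around the literature values,
#' Saltelli design, ensemble simulation over the sensitivity conditions at
#' 201 points over 500 min, and index estimation with aggregation over
#' time, species and conditions.
#'
#' @inheritParams evaluate_ensemble
#' @inheritParams build_bounds
#' @inheritParams saltelli_sample
#' @param params Center of the sampling ranges (literature values by
#'   default).
#' @param conditions Conditions to simulate
#'   ([default_sensitivity_conditions()] by default).
#' @return A `sobol_result` (see [sobol_indices()]), with the ensemble
#'   failure count attached as attribute `n_failed`.
#' @export
run_sobol_analysis <- function(model_id,
                               params = literature_params(model_id),
                               span = 2.6, base_n = 2048,
                               second_order = TRUE,
                               conditions = NULL,
                               times = default_time_grid(),
                               C_E = default_enzyme_load(),
                               seed = 1L, rel_tol = 1e-3, abs_tol = 1e-6,
                               use_knh = FALSE) {
  if (is.null(conditions)) conditions <- default_sensitivity_conditions(C_E)
  bounds <- build_bounds(params, span = span)
  design <- saltelli_sample(bounds, base_n = base_n,
                            second_order = second_order, seed = seed)
  ens <- evaluate_ensemble(model_id, design, conditions, times = times,
                           C_E = C_E, rel_tol = rel_tol, abs_tol = abs_tol,
                           use_knh = use_knh)
  res <- sobol_indices(ens)
  attr(res, "n_failed") <- sum(ens$failed)
  attr(res, "n_unphysical") <- sum(ens$unphysical)
  res
}

#' Export a Sobol result
#'
#' Writes the per-(parameter, species, time, condition) indices as a
#' long-format CSV and the aggregates plus fixed/estimated split as JSON.
#'
#' @param result A time-resolved `sobol_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param threshold Screening threshold used for the JSON split.
#' @return Invisibly, the long-format data frame.
#' @export
write_sobol_result <- function(result, csv_path = NULL, json_path = NULL,
                               threshold = 0.1) {
  dn <- dimnames(result$ST)
  long <- expand.grid(parameter = dn[[1]], species = dn[[2]],
                      time_index = seq_along(result$times),
                      condition = dn[[4]], stringsAsFactors = FALSE)
  long$time_min <- result$times[long$time_index]
  long$S1 <- as.vector(result$S1)
  long$ST <- as.vector(result$ST)
  long$time_index <- NULL
  if (!is.null(csv_path)) utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    scr <- screen_parameters(result, threshold)
    jsonlite::write_json(
      list(aggregate_S1 = as.list(result$aggregate$S1),
           aggregate_ST = as.list(result$aggregate$ST),
           fixed = scr$fixed, estimated = scr$estimated,
           threshold = threshold),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(long)
}
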