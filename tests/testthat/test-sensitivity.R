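test_that("sampling bounds follow the span rule with a positivity floor", {
  b <- build_bounds(c(a = 1), span = 0.5)
  expect_equal(unname(b), matrix(c(0.5, 1.5), 1))
  b <- build_bounds(c(a = 1), span = 2.6)
  expect_equal(unname(b), matrix(c(0.001, 3.6), 1))
  lit <- literature_params("model1")
  bb <- build_bounds(lit)
  expect_true(all(bb[, "low"] < unclass(lit) & unclass(lit) < bb[, "high"]))
  expect_true(all(bb[, "low"] > 0))
  expect_error(build_bounds(c(a = -1)), "positive")
})

test_that("Saltelli design row counts follow N(2d+2) / N(d+2)", {
  b8 <- build_bounds(literature_params("model2"))
  expect_equal(nrow(saltelli_sample(b8, 2048, second_order = TRUE)), 36864L)
  b10 <- build_bounds(literature_params("model1"))
  expect_equal(nrow(saltelli_sample(b10, 2048, second_order = TRUE)), 45056L)
  expect_equal(nrow(saltelli_sample(b10, 64, second_order = FALSE)),
               64L * 12L)
  b1 <- build_bounds(c(a = 1), span = 0.5)
  expect_equal(nrow(saltelli_sample(b1, 1, second_order = TRUE)), 4L)
  expect_error(saltelli_sample(b1, 0), "at least 1")
  expect_error(saltelli_sample(b1, 100), "power of 2")
  d <- saltelli_sample(b8, 16)
  expect_true(all(sweep(d, 2, attr(d, "bounds")[, "low"], ">=") &
                    sweep(d, 2, attr(d, "bounds")[, "high"], "<=")))
})

test_that("estimators recover analytic indices of an additive linear model", {
  a <- c(x1 = 1, x2 = 2, x3 = 3, dummy = 0)
  bounds <- cbind(low = rep(0, 4), high = rep(1, 4))
  rownames(bounds) <- names(a)
  design <- saltelli_sample(bounds, 1024, second_order = TRUE, seed = 2)
  y <- apply_rows(design, function(x) sum(a * x))
  res <- sobol_indices(y, design)
  truth <- a^2 / sum(a^2)
  expect_lt(max(abs(res$aggregate$S1 - truth)), 0.05)
  expect_lt(max(abs(res$aggregate$ST - truth)), 0.05)
  expect_equal(sum(res$aggregate$S1), 1, tolerance = 0.05)
  # the inert parameter is indistinguishable from zero
  expect_lt(abs(res$aggregate$S1[["dummy"]]), 0.02)
  expect_lt(res$aggregate$ST[["dummy"]], 0.02)
})

test_that("estimators match the analytic Ishigami indices within bootstrap CIs", {
  a <- 7; b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  truth_S1 <- c(V1, V2, 0) / V
  truth_ST <- c(V1 + V13, V2, V13) / V

  bounds <- cbind(low = rep(-pi, 3), high = rep(pi, 3))
  rownames(bounds) <- c("x1", "x2", "x3")
  design <- saltelli_sample(bounds, 1024, second_order = TRUE, seed = 3)
  y <- apply_rows(design, function(x)
    sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1]))
  ci <- bootstrap_ci(y, design, n_boot = 500, seed = 4)
  for (i in 1:3) {
    expect_true(truth_S1[i] >= ci$S1_lo[i, 1] && truth_S1[i] <= ci$S1_hi[i, 1],
                label = sprintf("S1[%d]=%.3f in [%.3f, %.3f]", i, truth_S1[i],
                                ci$S1_lo[i, 1], ci$S1_hi[i, 1]))
    expect_true(truth_ST[i] >= ci$ST_lo[i, 1] && truth_ST[i] <= ci$ST_hi[i, 1],
                label = sprintf("ST[%d]=%.3f in [%.3f, %.3f]", i, truth_ST[i],
                                ci$ST_lo[i, 1], ci$ST_hi[i, 1]))
  }
})

test_that("bootstrap CIs are seeded, validated, and shrink with base sample", {
  bounds <- cbind(low = rep(0, 3), high = rep(1, 3))
  rownames(bounds) <- c("x1", "x2", "x3")
  f <- function(x) x[1] + 2 * x[2] + 0.5 * x[3]^2
  width <- sapply(c(256, 1024), function(N) {
    design <- saltelli_sample(bounds, N, seed = 5)
    y <- apply_rows(design, f)
    ci <- bootstrap_ci(y, design, n_boot = 200, seed = 6)
    mean(ci$ST_ci)
  })
  expect_lt(width[2], 0.75 * width[1])  # ~1/sqrt(N) contraction

  design <- saltelli_sample(bounds, 64, seed = 5)
  y <- apply_rows(design, f)
  expect_error(bootstrap_ci(y, design, n_boot = 1), "at least 2")
  c1 <- bootstrap_ci(y, design, n_boot = 50, seed = 9)
  c2 <- bootstrap_ci(y, design, n_boot = 50, seed = 9)
  expect_identical(c1, c2)
})

test_that("temporal gradients use central differences and locate extrema", {
  t <- seq(0, 2 * pi, length.out = 200)
  g <- temporal_gradient(sin(t), t)
  expect_equal(g$gradient[100], cos(t[100]), tolerance = 1e-3)
  expect_equal(nrow(g$extrema), 2L)
  expect_equal(g$extrema$time, c(pi / 2, 3 * pi / 2), tolerance = 0.05)
  expect_equal(g$extrema$type, c("maximum", "minimum"))

  cg <- temporal_gradient(rep(2, 10), 1:10)
  expect_true(all(cg$gradient == 0) && nrow(cg$extrema) == 0)

  lg <- temporal_gradient(3 * (1:50), 1:50)
  expect_true(all(abs(lg$gradient - 3) < 1e-12))

  expect_error(temporal_gradient(c(1, 2), 1:2), "at least 3")
})

test_that("screening splits parameters at the aggregate ST threshold", {
  res <- structure(list(aggregate = list(
    ST = c(a = 0.5, b = 0.09, c = 0.11, d = 0.02),
    S1 = c(a = 0.4, b = 0.05, c = 0.08, d = 0.01))),
    class = "sobol_result")
  s <- screen_parameters(res, 0.1)
  expect_setequal(s$fixed, c("b", "d"))
  expect_setequal(s$estimated, c("a", "c"))
  s0 <- screen_parameters(res, 0)
  expect_length(s0$fixed, 0L)
  expect_error(screen_parameters(res, 1.2), "threshold")
})

test_that("ensemble evaluation drops failed and unphysical runs with a log", {
  # tiny ensemble: identical rows give identical trajectories
  bounds <- build_bounds(literature_params("model2"), span = 0.2)
  design <- saltelli_sample(bounds, 2, second_order = FALSE, seed = 1)
  grid <- make_condition_grid()
  conds <- structure(grid[grid$experiment_id == 13, ], class = class(grid))
  ens <- evaluate_ensemble("model2", design, conds,
                           times = seq(0, 500, length.out = 21))
  expect_equal(dim(ens$outputs[[1]]), c(nrow(design), 4L * 21L))
  expect_true(all(!ens$failed))
  # a duplicated design row yields a bit-identical trajectory
  d2 <- design; d2[2, ] <- d2[1, ]
  attr(d2, "base_n") <- attr(design, "base_n")
  attr(d2, "second_order") <- attr(design, "second_order")
  ens2 <- evaluate_ensemble("model2", d2, conds,
                            times = seq(0, 500, length.out = 21))
  expect_identical(ens2$outputs[[1]][1, ], ens2$outputs[[1]][2, ])
})

test_that("S1 does not exceed ST beyond bootstrap uncertainty for both models", {
  for (m in c("model1", "model2")) {
    bounds <- build_bounds(literature_params(m))
    design <- saltelli_sample(bounds, 64, second_order = FALSE, seed = 7)
    grid <- make_condition_grid()
    conds <- structure(grid[grid$experiment_id %in% c(1L, 13L), ],
                       class = class(grid))
    ens <- suppressMessages(
      evaluate_ensemble(m, design, conds,
                        times = seq(0, 500, length.out = 11)))
    for (ci_ in seq_along(ens$outputs)) {
      Y <- ens$outputs[[ci_]]
      ci <- bootstrap_ci(Y, design, n_boot = 100, seed = 8)
      # 95% intervals: allow the nominal miss rate across coordinates
      expect_gte(mean(ci$S1_lo <= ci$ST_hi + 1e-8), 0.95)
      expect_gte(mean(ci$S1_hi >= 0), 0.9)
      expect_true(all(ci$ST_lo >= 0))  # Jansen estimator is non-negative
    }
  }
})
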