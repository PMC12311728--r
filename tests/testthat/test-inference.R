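test_that("the multiplicative proposal has the stated relative spread", {
  expect_error(propose(c(a = 1), omega = 0), "positive")
  set.seed(1)
  p0 <- c(a = 1, b = 2)
  draws <- replicate(1e5, propose(p0, omega = 6e-3))
  rel <- draws / p0 - 1
  expect_lt(abs(sd(rel[1, ]) - 6e-3) / 6e-3, 0.01)
  expect_lt(abs(sd(rel[2, ]) - 6e-3) / 6e-3, 0.01)
  expect_lt(abs(mean(rel)), 1e-4)
  # one canonical draw: unit epsilon on a unit parameter moves it to 1.006
  expect_equal(unname(c(a = 1) * (1 + 6e-3 * 1)), 1.006)
})

test_that("MH accepts everything on a flat posterior and rejects out-of-support", {
  set.seed(2)
  flat <- function(p) 0
  acc <- replicate(200, mh_step(c(a = 1), 0, flat, omega = 0.1)$accepted)
  expect_true(all(acc))

  none <- function(p) -Inf
  st <- mh_step(c(a = 1), 0, none, omega = 0.1)
  expect_false(st$accepted)
  expect_identical(st$state, c(a = 1))
  expect_error(mh_step(c(a = 1), -Inf, flat), "finite")
})

test_that("the sampler reproduces a known positive-support target", {
  # Exponential(1): mean and variance 1.  The multiplicative kernel needs
  # its exact Hastings correction at this large omega.
  set.seed(3)
  lp <- function(p) if (p[1] <= 0) -Inf else -p[1]
  cur <- c(x = 1); lpc <- lp(cur)
  xs <- numeric(2e4)
  for (i in seq_along(xs)) {
    st <- mh_step(cur, lpc, lp, omega = 0.9, hastings = TRUE)
    cur <- st$state; lpc <- st$log_post
    xs[i] <- cur
  }
  xs <- xs[-(1:2000)]
  expect_equal(mean(xs), 1, tolerance = 0.1)
  expect_equal(var(xs), 1, tolerance = 0.25)
})

test_that("visit frequencies on a two-level density match the target ratio", {
  # pi(x) = 1 on (0,1], 3 on (1,2]: P(upper)/P(lower) = 3
  set.seed(4)
  lp <- function(p) {
    x <- p[1]
    if (x <= 0 || x > 2) -Inf else if (x > 1) log(3) else 0
  }
  cur <- c(x = 0.5); lpc <- lp(cur)
  up <- logical(3e4)
  for (i in seq_along(up)) {
    st <- mh_step(cur, lpc, lp, omega = 0.8, hastings = TRUE)
    cur <- st$state; lpc <- st$log_post
    up[i] <- cur > 1
  }
  ratio <- mean(up[-(1:3000)]) / mean(!up[-(1:3000)])
  expect_equal(ratio, 3, tolerance = 0.2)
})

test_that("log-likelihood is exact on self-generated data", {
  data <- noise_free_data("model1", 3)
  p1 <- literature_params("model1")
  n <- 4 * nrow(data)
  # zero residuals: only the normalization remains
  ll0 <- log_likelihood(p1, data, "model1", sigma_spec = 1)
  expect_equal(ll0, -n / 2 * log(2 * pi), tolerance = 1e-8)

  # shifting every observation by sigma costs exactly n/2
  shifted <- data
  cols <- c("C_AN_mM", "C_AB_mM", "C_NH_mM", "C_AOH_mM")
  shifted[cols] <- shifted[cols] + 1
  ll1 <- log_likelihood(p1, shifted, "model1", sigma_spec = 1)
  expect_equal(ll0 - ll1, n / 2, tolerance = 1e-8)
})

test_that("perturbing a sensitive parameter lowers the likelihood of clean data", {
  data <- noise_free_data("model1", 3)
  p1 <- unclass(literature_params("model1"))
  ll_truth <- log_likelihood(p1, data, "model1")
  for (nm in c("kcat1", "Km1", "Tmax")) {
    for (f in c(0.9, 1.1)) {
      p <- p1; p[nm] <- p[nm] * f
      expect_lt(log_likelihood(p, data, "model1"), ll_truth)
    }
  }
  # simulation failure surfaces as -Inf, not an error
  bad <- p1; bad["Km1"] <- -1
  expect_identical(log_likelihood(bad, data, "model1"), -Inf)
})

test_that("chains are reproducible and respect the fixed set", {
  data <- noise_free_data("model1", 3)
  est <- c("kcat1", "Km1")
  ch1 <- run_mcmc(data, "model1", estimated = est, n_iter = 300,
                  burn_in = 100, seed = 42)
  ch2 <- run_mcmc(data, "model1", estimated = est, n_iter = 300,
                  burn_in = 100, seed = 42)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$accepted, ch2$accepted)
  ch3 <- run_mcmc(data, "model1", estimated = est, n_iter = 300,
                  burn_in = 100, seed = 43)
  expect_false(identical(ch1$samples, ch3$samples))

  expect_setequal(colnames(ch1$samples), est)
  expect_setequal(names(ch1$fixed_values),
                  setdiff(param_names <- c("KEN", "Km1", "Km2", "Tmax", "kAB",
                                           "kAN", "kAOH", "kNH", "kcat1",
                                           "kcat2"), est))
  expect_gt(ch1$acceptance_rate, 0)
  expect_lt(ch1$acceptance_rate, 1)
  expect_error(run_mcmc(data, "model1", n_iter = 100, burn_in = 100),
               "exceed")
})

test_that("posterior summaries separate estimated from fixed parameters", {
  data <- noise_free_data("model1", 3)
  ch <- run_mcmc(data, "model1", estimated = c("kcat1", "Km1"),
                 n_iter = 400, burn_in = 150, seed = 1)
  s <- summarize_posterior(ch)
  expect_setequal(s$parameter[!s$fixed], c("kcat1", "Km1"))
  expect_true(all(s$sd[s$fixed] == 0))
  expect_true(all(s$lo <= s$mean & s$mean <= s$hi))
  pm <- posterior_mean_params(ch)
  expect_s3_class(pm, "model1_params")
  expect_identical(unname(pm[["kNH"]]), 62.044)

  # iid-normal chain: known mean and central interval
  fake <- structure(list(
    samples = matrix(rnorm(20000), ncol = 1,
                     dimnames = list(NULL, "z")),
    burn_in = 0L, fixed_values = numeric(0), model_id = "model1"),
    class = "mcmc_chain")
  set.seed(10)
  fake$samples[, 1] <- rnorm(20000)
  sf <- summarize_posterior(fake)
  expect_equal(sf$mean, 0, tolerance = 0.05)
  expect_equal(sf$lo, -1.96, tolerance = 0.1)
  expect_equal(sf$hi, 1.96, tolerance = 0.1)

  const <- fake
  const$samples[, 1] <- 5
  sc <- summarize_posterior(const)
  expect_identical(c(sc$sd, sc$lo, sc$hi), c(0, 5, 5))
})

test_that("chains persist to CSV and JSON", {
  data <- noise_free_data("model1", 3)
  ch <- run_mcmc(data, "model1", estimated = c("kcat1", "Km1"),
                 n_iter = 300, burn_in = 100, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_chain(ch, csv, json)
  df <- read.csv(csv)
  expect_equal(nrow(df), 300L)
  expect_true(all(c("iteration", "kcat1", "Km1", "log_post", "accepted")
                  %in% names(df)))
  j <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(j$model_id, "model1")
  expect_setequal(j$summary$parameter[j$summary$fixed],
                  c("KEN", "Km2", "Tmax", "kAB", "kAN", "kAOH", "kNH",
                    "kcat2"))
})
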