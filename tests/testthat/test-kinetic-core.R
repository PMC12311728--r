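p1 <- literature_params("model1")
p2 <- literature_params("model2")

test_that("parameter constructors enforce positivity and Tmax range", {
  expect_error(model1_params(KEN = -1, Km1 = 1, Km2 = 1, Tmax = 0.5,
                             kAB = 1, kAN = 1, kAOH = 1, kNH = 1,
                             kcat1 = 1, kcat2 = 1), "positive")
  expect_error(model1_params(KEN = 1, Km1 = 1, Km2 = 1, Tmax = 1.5,
                             kAB = 1, kAN = 1, kAOH = 1, kNH = 1,
                             kcat1 = 1, kcat2 = 1), "Tmax")
  expect_error(model2_params(KN = 1, KP = 1, KS = 0, k_m4 = 1,
                             k2 = 1, k3 = 1, k4 = 1, k5 = 1), "positive")
  expect_s3_class(p1, "model1_params")
  expect_named(unclass(p2),
               c("KN", "KP", "KS", "k_m4", "k2", "k3", "k4", "k5"))
})

test_that("parameter sets round-trip through JSON and YAML", {
  for (ext in c("json", "yaml")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(p1, f)
    expect_equal(unclass(read_params(f)), unclass(p1), tolerance = 1e-12)
  }
  f <- withr::local_tempfile(fileext = ".json")
  write_params(p2, f)
  expect_s3_class(read_params(f), "model2_params")
})

test_that("ester consumption rate matches direct evaluation of the rate law", {
  # experiment-3 start: 80 mM 6-APA, 40 mM ester, C_E = 1 IU/mL
  s <- reaction_state(C_AN = 0, C_AB = 40, C_NH = 80, C_AOH = 0)
  # independent hand evaluation of the printed law (6-APA term over kAOH)
  expected <- 0.178 * 1 * 40 / (7.905 * (1 + 0 / 9.174 + 80 / 10.907 + 0 / 10.907) + 40)
  expect_equal(rate_ester_consumption(s, p1, 1), expected, tolerance = 1e-12)

  # kNH variant moves the 6-APA inhibition to kNH
  expected_knh <- 0.178 * 1 * 40 / (7.905 * (1 + 0 + 80 / 62.044 + 0) + 40)
  expect_equal(rate_ester_consumption(s, p1, 1, use_knh = TRUE),
               expected_knh, tolerance = 1e-12)

  # zero substrate, saturation asymptote
  expect_identical(rate_ester_consumption(
    reaction_state(C_AN = 5, C_AB = 0, C_NH = 10, C_AOH = 2), p1, 1), 0)
  sat <- rate_ester_consumption(
    reaction_state(C_AN = 5, C_AB = 1e9, C_NH = 10, C_AOH = 2), p1, 2)
  expect_equal(sat, 0.178 * 2, tolerance = 1e-6)
})

test_that("amoxicillin hydrolysis rate matches direct evaluation", {
  s <- reaction_state(C_AN = 10, C_AB = 20, C_NH = 50, C_AOH = 5)
  expected <- 0.327 * 1 * 10 /
    (12.509 * (1 + 20 / 3.78 + 50 / 62.044 + 5 / 10.907) + 10)
  expect_equal(rate_amox_hydrolysis(s, p1, 1), expected, tolerance = 1e-12)

  expect_identical(rate_amox_hydrolysis(
    reaction_state(C_AN = 0, C_AB = 20, C_NH = 50, C_AOH = 5), p1, 1), 0)

  # Michaelis-Menten half-max: no inhibitors, C_AN = Km2
  s_half <- reaction_state(C_AN = p1[["Km2"]], C_AB = 0, C_NH = 0, C_AOH = 0)
  expect_equal(rate_amox_hydrolysis(s_half, p1, 1), 0.327 / 2,
               tolerance = 1e-12)
})

test_that("synthesis rate saturates in the nucleophile", {
  s0 <- reaction_state(C_AN = 0, C_AB = 40, C_NH = 0, C_AOH = 0)
  expect_identical(rate_amox_synthesis(1, s0, p1), 0)
  s_half <- reaction_state(C_AN = 0, C_AB = 40, C_NH = p1[["KEN"]], C_AOH = 0)
  expect_equal(rate_amox_synthesis(2, s_half, p1), 2 * p1[["Tmax"]] / 2,
               tolerance = 1e-12)
  s_big <- reaction_state(C_AN = 0, C_AB = 40, C_NH = 1e9, C_AOH = 0)
  expect_equal(rate_amox_synthesis(2, s_big, p1), 2 * p1[["Tmax"]],
               tolerance = 1e-6)
})

test_that("rate laws reject invalid inputs", {
  s <- reaction_state(C_AN = 1, C_AB = 1, C_NH = 1, C_AOH = 1)
  expect_error(rate_ester_consumption(c(C_AN = -1, C_AOH = 0, C_NH = 1,
                                        C_AB = 1), p1, 1), "non-negative")
  expect_error(rate_ester_consumption(c(C_AN = NaN, C_AOH = 0, C_NH = 1,
                                        C_AB = 1), p1, 1), "finite")
  expect_error(rate_amox_synthesis(-1, s, p1), "non-negative")
  expect_error(enzyme_load(-1), "non-negative")
})

test_that("model 1 RHS assembles the rate laws with the right stoichiometry", {
  s <- reaction_state(C_AN = 0, C_AB = 40, C_NH = 80, C_AOH = 0)
  v_ab <- rate_ester_consumption(s, p1, 1)
  v_h2 <- rate_amox_hydrolysis(s, p1, 1)
  v_s <- rate_amox_synthesis(v_ab, s, p1)
  d <- rhs_model1(0, s, p1, 1)
  expect_equal(unname(d),
               c(v_s - v_h2, (v_ab - v_s) + v_h2, -(v_s - v_h2), -v_ab),
               tolerance = 1e-14)
  expect_equal(unname(rhs_model1(0, reaction_state(), p1, 1)), rep(0, 4))
})

test_that("model 2 RHS matches direct evaluation at the experiment-13 start", {
  s <- reaction_state(C_AN = 0, C_AB = 5, C_NH = 30, C_AOH = 0)
  den <- 0.733 * 43 + (3.917 + 0.150) * 30
  dAN <- 1 / den * (3.117 * 3.917 * 5 * 30 / 380 - 0)
  dAOH <- (0.733 * 43 + 0.150 * 30) / den * (3.117 * 5 / 380 - 0)
  d <- rhs_model2(0, s, p2, 1)
  expect_equal(unname(d), c(dAN, dAOH, -dAN, -(dAN + dAOH)),
               tolerance = 1e-12)
  expect_equal(unname(rhs_model2(0, reaction_state(), p2, 1)), rep(0, 4))
})

test_that("model 2 byproduct derivative vanishes when its bracket balances", {
  # choose C_AN so that k2*C_AB/KS = k_m4*C_AN/KP exactly
  C_AB <- 20
  C_AN <- p2[["k2"]] * C_AB / p2[["KS"]] * p2[["KP"]] / p2[["k_m4"]]
  s <- c(C_AN = C_AN, C_AOH = 3, C_NH = 40, C_AB = C_AB)
  expect_equal(rhs_model2(0, s, p2, 1.7)[["C_AOH"]], 0, tolerance = 1e-15)
})

test_that("both RHS conserve nucleus and acyl totals to machine precision", {
  set.seed(42)
  for (i in 1:25) {
    s <- c(C_AN = runif(1, 0, 80), C_AOH = runif(1, 0, 80),
           C_NH = runif(1, 0, 80), C_AB = runif(1, 0, 100))
    ce <- runif(1, 0.1, 5)
    for (d in list(rhs_model1(0, s, p1, ce), rhs_model2(0, s, p2, ce))) {
      expect_equal(d[["C_AN"]] + d[["C_NH"]], 0, tolerance = 1e-15)
      expect_equal(d[["C_AB"]] + d[["C_AN"]] + d[["C_AOH"]], 0,
                   tolerance = 1e-15)
    }
  }
})

test_that("model 1 rates are non-negative and monotone in their substrate", {
  set.seed(7)
  for (i in 1:10) {
    s <- c(C_AN = runif(1, 0, 50), C_AOH = runif(1, 0, 50),
           C_NH = runif(1, 0, 80), C_AB = runif(1, 0, 100))
    expect_gte(rate_ester_consumption(s, p1, 1), 0)
    expect_gte(rate_amox_hydrolysis(s, p1, 1), 0)
    s_up <- s; s_up[["C_AB"]] <- s[["C_AB"]] + 5
    expect_gt(rate_ester_consumption(s_up, p1, 1),
              rate_ester_consumption(s, p1, 1))
    s_up <- s; s_up[["C_AN"]] <- s[["C_AN"]] + 5
    expect_gt(rate_amox_hydrolysis(s_up, p1, 1),
              rate_amox_hydrolysis(s, p1, 1))
  }
})

test_that("RHS evaluation is deterministic", {
  s <- c(C_AN = 3, C_AOH = 1, C_NH = 20, C_AB = 15)
  expect_identical(rhs_model1(0, s, p1, 1.3), rhs_model1(100, s, p1, 1.3))
  expect_identical(rhs_model2(0, s, p2, 1.3), rhs_model2(100, s, p2, 1.3))
})
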