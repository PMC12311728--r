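# amoxkin

Kinetic modeling of the enzymatic synthesis of amoxicillin in a batch
reactor, for biochemical engineers and modelers studying kinetically
controlled β-lactam synthesis by penicillin G acylase (PGA).

PGA condenses 6-aminopenicillanic acid (6-APA, the nucleophile C_NH) with
p-hydroxyphenylglycine methyl ester (POHPGME, the activated acyl donor
C_AB) into amoxicillin (C_AN), while also hydrolyzing both the ester and
the antibiotic to p-hydroxyphenylglycine (POHPG, C_AOH). Yield is set by
the race between synthesis and hydrolysis, so quantitative kinetic models
matter for process design. `amoxkin` implements, as one tested pipeline:

* **Two competing kinetic models.** Model 1, Michaelis–Menten with
  competitive inhibition — rates v_AB (ester consumption), v_h2
  (amoxicillin hydrolysis) and the synthesis channel
  v_S = v_AB·C_NH·T_max/(K_EN + C_NH), with mass balances
  dC_AN/dt = v_S − v_h2, dC_AOH/dt = (v_AB − v_S) + v_h2,
  dC_NH/dt = −(v_S − v_h2), dC_AB/dt = −v_AB.
  Model 2, a quasi-steady-state acyl-enzyme mechanism in equilibrium
  (K_S, K_P, K_N) and elementary rate constants (k_2, k_3, k_4, k_−4,
  k_5), sharing the denominator k_3·K_N + (k_4 + k_5)·C_NH.
* **Stiff batch simulation** (BDF via deSolve, compiled right-hand
  sides), 201 points over 500 min by default, with conservation audits
  of C_AN + C_NH and C_AB + C_AN + C_AOH.
* **Global sensitivity analysis**: Saltelli cross-sampling within ±260%
  (positivity-floored) of the literature parameter values, time-resolved
  Sobol S1/ST indices (Saltelli-2010/Jansen estimators), block-bootstrap
  CIs, temporal gradients dS_T/dt, and screening at mean S_T < 0.1.
* **Bayesian estimation**: Metropolis–Hastings with the multiplicative
  proposal P* = P(1 + ωε), ω = 6×10⁻³, uniform priors over the
  sensitivity bounds, Gaussian likelihood.
* **Validation**: rRMSE (range-normalized, in %), AIC/BIC,
  leave-one-experiment-out cross-validation over the 13-condition grid,
  and a model-comparison table.
* **Synthetic study generator** emulating the 13 batch experiments
  (25 °C, pH 6.5; 6-APA 30–80 mM, POHPGME 5–100 mM) with heteroscedastic
  HPLC-like noise, since the original measurements are unpublished.

See `vignettes/amoxkin-methods.Rmd` for the models, assumptions, and
numerical choices.

## Worked example

```r
library(amoxkin)

# simulate experiment 1 (30 mM 6-APA, 30 mM POHPGME) under Model 1
tc <- simulate_batch("model1", literature_params("model1"),
                     get_condition(make_condition_grid(), 1))
tc
#> <timecourse: model1, condition 1, 201 time points over 500 min>
#>   time_min   C_AN_mM  C_AB_mM  C_NH_mM  C_AOH_mM
#> 1      0.0 0.0000000 30.00000 30.00000 0.0000000
#> 2      2.5 0.1465170 29.64027 29.85348 0.2132119
#> 3      5.0 0.2898426 29.28376 29.71016 0.4263956
#> 4      7.5 0.4299967 28.93047 29.57000 0.6395336
#> ... 197 more rows
max(check_mass_balance(tc)$drift)
#> [1] 5.45e-15
```

Amoxicillin accumulates early, then secondary hydrolysis erodes it —
the signature of kinetic control. Both conserved totals drift only at
machine precision.

```r
# fit three parameters to a noisy synthetic data set of the same batch
data <- generate_experiment("model1", literature_params("model1"),
                            get_condition(make_condition_grid(), 1), seed = 1)
ch <- run_mcmc(data, "model1", estimated = c("kcat1", "kcat2", "Tmax"),
               n_iter = 5000, burn_in = 1000, seed = 1)
summarize_posterior(ch)[c(1, 2, 4), ]
#>    parameter  mean      sd    lo    hi fixed
#>        kcat1 0.177 0.00311 0.171 0.184 FALSE
#>        kcat2 0.304 0.02447 0.266 0.356 FALSE
#>         Tmax 0.594 0.03292 0.525 0.652 FALSE
fit_metrics(posterior_mean_params(ch), data, "model1", k = 3)
#>   rRMSE AIC   BIC logLik  n k
#> 1  8.25 111 116.9 -52.51 52 3
```

The generating values (k_cat1 = 0.178, k_cat2 = 0.327, T_max = 0.606)
sit inside or at the edge of the 95% credible intervals; the remaining
parameters are held at their literature values (`fixed = TRUE` rows,
the asterisk convention of kinetic parameter tables). An rRMSE of 8.25%
against 5%-noise data reflects the noise floor of the measurements.

The same stages are scriptable end to end (`pipeline_simulate()`,
`pipeline_generate()`, `pipeline_sensitivity()`, `pipeline_fit()`,
`pipeline_crossval()`, `pipeline_report()`, or the thin CLI in
`inst/cli/amoxkin.R`), each writing CSV/JSON artifacts plus a manifest
with the configuration hash and seed.

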