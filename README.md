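# cpradapt

Adaptive harvest dynamics in common-pool resource (CPR) systems.

Groups harvesting a shared renewable resource face a running trade-off:
extracting aggressively now, or restraining themselves so the stock keeps
producing. `cpradapt` implements a group-level adaptive model of this
trade-off, the round-wise calibration of its key behavioral parameter to
observed resource time series, the derived behavioral statistics, and the
between-round feedback analysis that locates the *sustainability threshold*
separating self-reinforcing cooperation from a downward spiral of
overexploitation. Because the laboratory data this kind of analysis targets
are typically not redistributable, the package ships a synthetic-experiment
generator that reproduces the full study structure (6 sessions x 6 rounds,
treatment switch after round 3, harvest-to-expectation feedback between
rounds), so the whole pipeline is testable end to end.

## The model

Three coupled ODEs for the resource R, cumulated harvest H, and a
behavioral trait θ ∈ [0, 1] (harvesting restraint), for n users over a
round of length T:

    dR/dt = g(R) − G(R, θ)          g(R) = r R (1 − R/K)
    dH/dt = G(R, θ) − P(θ)          G    = n h_max R / (k(θ) + R)
    dθ/dt = δ ∂W/∂θ                 k(θ) = k_min + k_var θ^q_k

The trait adapts along the gradient of the fitness

    W = G(R, θ) + φ(θ, t) g(R) − P(θ),
    φ(θ, t) = φ_max θ^q_φ / (1 + exp(a (t/T − b))),

the sum of the current harvest, the discounted future resource
productivity, and an optional punishment cost (a Gaussian kernel in θ,
active only in punishment treatments). The maximum discount factor φ_max
encodes how much weight on future pay-offs the social environment
(communication, punishment, experience) sustains; it is the single
parameter calibrated per round. Under exponential discounting a fitted
φ_max maps to a discount rate ρ via (1 − e^(−ρT))/ρ = φ_max.

## Worked example

```r
library(cpradapt)

# one round in each discount regime: myopia collapses immediately and
# harvests poorly; valuing the future delays collapse and pays
for (phi in c(0, 16.5, 32.5)) {
  tr <- integrate_round(cpr_params(phi_max = phi))
  cat(sprintf("phi_max = %4.1f: H_T = %6.1f, collapse at t = %s\n",
              phi, total_harvest(tr), tr$t[which(tr$R < 1)[1]]))
}
#> phi_max =  0.0: H_T =   58.8, collapse at t = 21
#> phi_max = 16.5: H_T =  199.6, collapse at t = 218
#> phi_max = 32.5: H_T =  207.6, collapse at t = 230

# synthetic 36-round study -> per-round calibration -> feedback analysis
study  <- generate_study(study_design(), seed = 42)
report <- calibrate_study(study)
fb     <- analyze_feedback(report)
fb$threshold$threshold   # estimated sustainability threshold phi*
#> [1] 9.117787
induced_fixed_point()    # the generating fixed point of the feedback map
#> [1] 8.499238
fb$logistic$par[["m"]]   # sigmoid midpoint: reference harvest level
#> [1] 179.5083
```

The threshold estimate means: groups whose calibrated φ_max exceeded ~9 in
a round tended to enter the next same-treatment round with an even higher
φ_max (expectations ratcheting up), while groups below it deteriorated —
the generator's true tipping point is 8.5.

A command-line surface wraps the same stages:

```sh
Rscript -e 'quit(status = cpradapt::cli_main(commandArgs(TRUE)))' \
  synth --out study_dir --seed 42
Rscript -e 'quit(status = cpradapt::cli_main(commandArgs(TRUE)))' \
  calibrate --manifest study_dir/manifest.csv --out report.csv
Rscript -e 'quit(status = cpradapt::cli_main(commandArgs(TRUE)))' \
  analyze-feedback --report report.csv --out feedback.csv
```

Configuration is a JSON file overlaying documented defaults
(`default_config()`); unknown keys are rejected by name.

## Documentation

The methods vignette (`vignettes/cpradapt-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and default,
what the synthetic generator does and does not emulate, the numerical
choices, and known limitations.
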