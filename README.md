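# thermostates

Bayesian assignment of resting metabolic rate measurements to **torpor**,
**euthermic rest** below the thermoneutral zone (TNZ), or **rest within the
TNZ**, with joint estimation of the thermoregulatory curve of the extended
Scholander–Irving model.

## Who this is for

Physiologists analysing respirometry data from endotherms measured at
varying ambient temperature ($T_a$).  Separating torpid from euthermic
measurements is easy in deep hibernators and hard everywhere else — daily
heterotherms, thermolabile species, measurements taken just below the TNZ.
`thermostates` replaces ad hoc thresholds with a probabilistic assignment
under an explicit thermoregulatory model, and tells you per measurement how
confident that assignment is and per parameter whether your data can
identify it at all.

## The model and method

Resting metabolic rate $M$ follows three state-specific curves: a flat
segment $M_{TNZ}$ above the lower critical temperature $T_{lc}$; a
euthermic line below it, anchored at $(T_{lc}, M_{TNZ})$ and reaching zero
at $T_{be}$; and a two-piece torpor curve — a "regulated torpor" line
sharing the euthermic slope and reaching zero at $T_{bt}$, meeting an
exponential "conforming torpor" branch at the threshold $T_t$, where the
minimal torpid rate $TMR$ occurs.  The torpid rate at $T_{lc}$, $M_r$, may
sit below $M_{TNZ}$ (additional metabolic inhibition).

The analysis runs in three steps: (1) a rolling-regression search (OLS
slope + Breusch–Pagan heteroscedasticity tests) finds a conservative
boundary `tlc_low`, then a Bayesian mixture run with $T_{lc}$ free
estimates $T_{lc}$ and $M_{TNZ}$; (2) a fixed-$T_{lc}$ mixture run
pre-assigns each below-TNZ measurement to torpor or euthermy by posterior
state-indicator frequencies, with automatic overrides outside the
predicted curves; (3) a final run with the automatic assignments clamped
produces parameter posteriors, per-record predictions with 95% credible
intervals, assignment confidence (membership probability times the
$T_{lc}$-side probability) and a binomial validity test at threshold 0.8.
Prior–posterior overlap (PPO) above 75% flags unidentifiable parameters.
Sampling: 3 chains x 50,000 iterations, 30,000 burn-in, thinning 10, via
the package's JAGS model code.

See `vignettes/thermostates-methods.Rmd` for the full account.

## Worked example

```r
library(thermostates)

# A synthetic deep hibernator with known ground truth
# (T_lc = 30, T_be = 38, T_bt = 2, TMR = 0.05, M_r = 0.7, M_TNZ = 1):
cfg <- default_fixtures(n = 120, seed = 7)$deep_hibernator
d   <- generate_dataset(cfg)

fit <- fit_thermo(d, mcmc_config(seed = 11))
print(fit)
#> Three-step Bayesian state assignment
#>   n = 120 records; tlc_low = 29.41 C
#>   T_lc = 30.15 C [29.90, 30.41]   M_TNZ = 1.003
#>   TMR = 0.04884   M_r = 0.7244   T_be = 38.25 C   T_bt = 1.79 C   T_t = 1.40 C
#>   states: tnz 21 / euthermy 57 / torpor 42; valid 120/120
#>   max R-hat: 1.006 (converged)

evaluate_fit(fit)
#> Corroboration index: 1.000 over 120 valid records
#> Valid-assignment proportion: 1.000
#> Inhibition fraction M_r/M_TNZ: 0.722 (identifiable)
```

Every estimated parameter lands on its generating value: $T_{lc}$ within
0.2 °C, $TMR$ and $M_r$ within a few percent, and all 120 records recover
their true state with valid confidence.  On a homeotherm dataset the same
pipeline assigns no valid torpor and reports a $TMR$ PPO near 100% — the
unidentifiability signature that tells you the data contain no torpor
information.

`write_fit(fit, "out/")` writes the assignment table (CSV), the parameter
summary with credible intervals, R-hat and PPO (JSON, including the full
run configuration and seed), and the step-1 window diagnostics.  A thin
command-line wrapper lives at `inst/cli/thermostates.R`
(`simulate` / `fit` / `evaluate`).

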