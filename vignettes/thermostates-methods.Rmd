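---
title: "Assigning metabolic rate measurements to torpor, euthermy and thermoneutral rest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning metabolic rate measurements to torpor, euthermy and thermoneutral rest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Respirometry on heterothermic endotherms produces pairs of ambient
temperature $T_a$ and resting metabolic rate $M$.  Below the thermoneutral
zone (TNZ) an animal may be either in euthermic rest or in torpor, and when
the torpid and euthermic rates are close — daily heterotherms, thermolabile
species, measurements taken just below the TNZ — assigning each measurement
to a state by eye or by an ad hoc threshold is arbitrary.  `thermostates`
implements a three-step Bayesian mixture analysis that estimates the lower
critical temperature $T_{lc}$, assigns every measurement to one of three
states (rest within the TNZ, euthermic rest below it, torpor), quantifies
the confidence of each assignment, and reports the thermoregulatory-curve
parameters with an identifiability diagnostic.

## The model

The extended Scholander–Irving model describes resting $M$ as a function of
$T_a$ through three state-specific curves:

* **Thermoneutral rest**: $M = M_{TNZ}$, independent of $T_a$, for
  $T_a > T_{lc}$, with Gaussian scatter $SD_{TNZ}$.
* **Euthermic rest** below the TNZ: $M_e = \alpha_e + \beta_e T_a$.  The
  line is anchored at $(T_{lc}, M_{TNZ})$ and at $(T_{be}, 0)$, where
  $T_{be}$ is the extrapolated ambient temperature of zero euthermic
  metabolism (a proxy for euthermic body temperature under constant
  conductance).  Hence $\beta_e = -M_{TNZ}/(T_{be}-T_{lc})$ and
  $\alpha_e = M_{TNZ} - \beta_e T_{lc}$.  Scatter $SD_r$.
* **Torpor**, two branches meeting at the threshold temperature $T_t$:
  below $T_t$ ("regulated torpor") a line with the *same slope* as the
  euthermic one ($\beta_r = \beta_e$) through $(T_{bt}, 0)$, so
  $\alpha_r = -\beta_r T_{bt}$, with scatter $SD_r$; between $T_t$ and
  $T_{lc}$ ("conforming torpor") an exponential
  $M_t = \alpha_c e^{\beta_c T_a}$ through $(T_t, TMR)$ and
  $(T_{lc}, M_r)$, so $\beta_c = \ln(M_r/TMR)/(T_{lc}-T_t)$ and
  $\alpha_c = M_r e^{-\beta_c T_{lc}}$, with scatter $SD_c$.

$TMR$ is the minimal torpid rate, reached at
$T_t = T_{bt} + TMR/\beta_r$; $M_r$ is the torpid rate at $T_{lc}$, and
$M_r < M_{TNZ}$ indicates metabolic inhibition beyond the suspension of
thermogenesis.  The two torpor branches are continuous at $T_t$ by
construction, and `thermo_params()` enforces every admissibility
constraint: $T_{be} > T_{lc}$, $T_{bt} \ge -5\,°C$,
$0 < TMR \le 0.8\,M_{TNZ}$, $TMR \le M_r \le M_{TNZ}$, $T_t < T_{lc}$, and
a conforming $Q_{10} = e^{10\beta_c} \le 5$.

Measurements below $T_{lc}$ follow a two-component mixture of the euthermic
and torpor curves with dataset-level fractions $(p_t, p_e)$; each record
carries a latent categorical state indicator.

## The three steps

**Step 1a — conservative boundary.**  Starting from the ten records at the
highest $T_a$, OLS regressions of $M$ on $T_a$ run on windows growing one
record (one tie group) at a time towards colder temperatures.  A window
that shows a significantly negative slope (one-sided $t$-test, level 0.01)
or significant heteroscedasticity (studentized Breusch–Pagan test, level
0.05) has grown past the TNZ; `tlc_low` is the smallest $T_a$ of the last
window passing both tests, so it still underestimates $T_{lc}$.  A
significantly positive slope (level 0.01) means the dataset lacks euthermic
measurements below the TNZ and aborts the analysis.  We take the *last
passing* rather than the first failing window because the bound must stay
conservative.

**Step 1b — $T_{lc}$ and $M_{TNZ}$.**  The mixture model runs on the
records at $T_a \le$ `tlc_low` with $T_{lc}$ as a free parameter truncated
to $[\,$`tlc_low`$, \max T_a]$.  The $M_{TNZ}$ supplied to this run is the
mean (mean-normalised) rate above `tlc_low`; after sampling, $M_{TNZ}$ is
recalculated as the mean rate above the posterior median $T_{lc}$.

**Step 2 — pre-assignment.**  With $T_{lc}$ fixed at its posterior median,
records above it are assigned to thermoneutral rest with membership
probability one; records below receive torpor/euthermy membership
probabilities equal to the relative frequency of their state indicator
across retained draws.  If at least one record was assigned to torpor, two
automatic overrides apply: records above the posterior-median euthermic
curve are fixed to euthermy and records below the posterior-median torpor
curve are fixed to torpor (membership one).  We use the posterior-median
curves, i.e. the central predictor, as the override boundary.  Ties in
membership (exactly 0.5/0.5) resolve to euthermy, the conservative
non-torpor reading.

**Step 3 — final run.**  The mixture model runs again with the
automatically assigned indicators clamped as observed data; only records
lying between the predicted curves keep free indicators.  This run yields
the reported curve-parameter posteriors, per-record predicted rates with
95% credible intervals, and the final memberships.

## Priors and sampling

Except where noted, priors are Gaussian with mean 0 and precision 0.001,
truncated to biologically motivated supports: $T_{be} \in (T_{lc}, 50]$,
$TMR \in (0, 0.8\,M_{TNZ}]$, $M_r \in [TMR, M_{TNZ}]$,
$T_{bt} \in [-5, U]$.  The upper bound $U$ enforces two conditions at the
current parameter values: $T_t$ must fall below the lower 95% credible
limit of $T_{lc}$, and the conforming $Q_{10}$ may not exceed 5, giving
$U = \min\!\big(L_{95} + TMR/|\beta_r|,\;
T_{lc} - 10\ln(M_r/TMR)/\ln 5 + TMR/|\beta_r|\big)$.  State fractions get
a flat Dirichlet(1, 1); $SD_r \sim U(0, 3)$ on the normalised scale,
$SD_c \sim U(SD_r/5, SD_r)$, $SD_{TNZ} \sim U(SD_r/2, SD_r)$.  Euthermic
rest shares $SD_r$ with regulated torpor: both are the linear branches,
and the parameter set names only three scatter parameters.

Numerical choices worth stating:

* In step 1 no $T_{lc}$ posterior exists yet, so the *current* $T_{lc}$
  draw stands in for $L_{95}$ in the $T_{bt}$ bound.
* In step 1 we truncate $T_{be}$ at the current $T_{lc}$ (not at
  `tlc_low`): allowing $T_{be} < T_{lc}$ would flip the euthermic slope
  positive and break the curve geometry the other bounds are built on.
* $U$ is clamped below at $-4.999\,°C$ inside the sampler so the
  conditional support of $T_{bt}$ never empties mid-run; parameter
  combinations that would invert the bound are thereby confined to
  $T_{bt} \approx -5$ and carry no appreciable posterior mass.  The joint
  prior sampler used for overlap diagnostics instead *rejects* such
  combinations, so every prior draw satisfies the $Q_{10}$ and
  threshold-temperature constraints exactly.
* All likelihood computation happens on $M$ divided by its dataset mean;
  rates are rescaled to input units for reporting.

Sampling uses JAGS (via `rjags`) with the package's own model code: three
chains of 50,000 iterations, the first 30,000 dropped (the 1,000
adaptation iterations are counted inside this budget), thinned by 10 —
2,000 retained draws per chain.  Convergence is assessed with the
Brooks–Gelman–Rubin $\hat{R}$ against a 1.1 threshold; non-convergence
yields a warning-carrying result, never an error.  Every entry point takes
an explicit integer seed, and chain RNGs are derived from it, so runs are
exactly reproducible.

**Initialisation.**  Chains start in the torpor-free configuration: every
free state indicator at euthermy and the torpor curve low in its support
(small $TMR$, $T_{bt}$ near the cold end).  This choice matters.  On
single-cloud data — a homeotherm, or any dataset without a separated
torpid cluster — the regulated-torpor line, which shares the euthermic
slope, can fit the euthermic cloud exactly as well as the euthermic line,
so the posterior is bimodal and chains do not hop between modes at this
run length.  Starting from the parsimonious no-torpor mode lets the
likelihood introduce torpor only where measurements actually demand it;
on datasets with genuine torpor the torpid cluster pulls the torpor
component onto itself within the burn-in.

## Identifiability and confidence

The prior–posterior overlap (PPO) of a parameter is the percent overlap of
Gaussian kernel density estimates of its joint-prior draws and its
posterior draws on a shared 512-point grid (bandwidth `bw.nrd0`,
trapezoidal integration of the pointwise minimum).  A PPO at or above 75%
marks a parameter the data cannot identify; in practice $TMR$, $M_r$ and
$T_{bt}$ are unidentifiable exactly when the dataset contains no (or too
few) torpid measurements, and the PPOs of $T_{lc}$ and $T_{be}$ are not
useful for this purpose because their priors are data-dependent.
$M_r/M_{TNZ}$, the additional-inhibition fraction, is reported with a
reliability flag tied to the $M_r$ PPO.

Each record's assignment confidence is the product of its highest
membership probability and the probability that its $T_a$ lies on the
assigned side of $T_{lc}$, read off the empirical CDF of the $T_{lc}$
posterior draws.  Validity treats the retained draws as Bernoulli trials
(successes `round(confidence * n_draws)`) and applies a one-sided exact
binomial test of $H_0\!: p \le 0.8$ at level 0.05, so a confidence at or
below the threshold can never be valid, and raising the threshold can only
shrink the valid set.  The Bernoulli construction is our reading of the
named test; the method's published description fixes the test, its
sidedness and the 0.8 threshold but not the trial counts.

## The synthetic-data generator

`generate_dataset()` draws $T_a$ uniformly over
$[T_{bt} - 5, T_{lc} + 8]$ by default (wide enough that the TNZ segment
holds the ten records step 1 needs), assigns below-$T_{lc}$ records to
torpor or euthermy by the configured fractions, and adds Gaussian scatter
around the state's curve with the state's SD, redrawing any non-positive
rate.  Redrawing (rather than truncating) keeps the generating density
essentially identical to the fitted likelihood at realistic scatter
levels.  Four reference fixtures span the regimes the method must handle:
a deep hibernator ($T_{bt} = 2\,°C$, large separation), a shallow daily
heterotherm ($T_{bt} = 25\,°C$, the hard case), a homeotherm (torpor
fraction zero), and a strongly inhibited heterotherm
($M_r/M_{TNZ} = 0.35$).  Scatter defaults ($SD_r = 0.06\,M_{TNZ}$) sit in
the range typical of resting respirometry.  The generator emulates
independent steady-state measurements only: no torpor-bout time series,
no transitions, no circadian structure, no body-mass covariates — so
passing recovery tests demonstrates correctness of the estimator under
the model's own assumptions, not robustness to violations of them.

The test suite runs the full pipeline at its reference protocol on two
fixtures of $n = 120$ records (a deep hibernator and a homeotherm) and
checks parameter recovery, label recovery, convergence, truncation
soundness and the identifiability signature; curve algebra and the
confidence/validity mechanics are checked exactly on thousands of random
admissible parameter sets.

## Limitations

Everything the underlying model excludes applies here: no states above the
upper critical temperature (callers must remove such records), a strictly
linear euthermic branch, identical slopes for euthermy and regulated
torpor, no hypometabolic state within the TNZ, no individual-level
effects.  On datasets without torpor the torpor-curve parameters are
reported but unidentifiable — that is what the PPO diagnostic is for — and
$T_{lc}$ can be overestimated when strong metabolic inhibition depresses
$M_r$ far below $M_{TNZ}$.
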