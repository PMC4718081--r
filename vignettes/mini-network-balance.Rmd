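---
title: "Methods: mini network balance modelling of AD progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mini network balance modelling of AD progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

Alzheimer's disease perturbs three core CSF biomarkers in concert: amyloid
beta 1-42 (lowered), total tau and phosphorylated tau-181 (raised).  Their
mutual biochemistry — P-tau raising AChE activity and hence presenilin-1 and
amyloid production; amyloid activating GSK-3beta and calcium-dependent
kinases that hyperphosphorylate tau — forms a small crosstalk network.  The
package treats disease progression as *loss of balance* of this network and
quantifies it in three complementary ways: geometric disruption parameters,
a Monte Carlo disruption probability, and a triangle "balance map".

## Network structure

`build_network()` represents each marker as a node with first-order
turnover, and each indirect biochemical route as a transit-compartment
chain.  A chain from source S to target X with `n` stages of mean transit
time `tau` obeys

    dC1/dt = (S - C1) / tau,    dCi/dt = (C(i-1) - Ci) / tau,

and its last compartment multiplies the target's production:

    dX/dt = prod_X * (1 + sum_c gain_c * Clast_c / S_baseline_c) - clear_X * X.

Chain outputs are normalized by the source baseline so gains are
dimensionless; at steady state each chain contributes exactly its gain.
Production rates are then *solved* so that a requested baseline is a fixed
point (`prod_X = clear_X * baseline_X / (1 + sum of incoming gains)`) — a
calibration, not a fit, and verified to 1e-8 in the tests.

This ODE form is the standard transit-compartment formalism for delayed
indirect effects.  The precise chain lengths, transit times and gains of the
underlying biology are unknown at this level of abstraction; the defaults
(3 compartments, tau = 0.5 months, gains 0.2–0.3) are package choices, made
once, with two requirements: the system is linearly stable (verified by a
Jacobian eigenvalue test) and perturbations relax well within one
inter-visit interval of 12 months.  All are configurable.  The four default
edges are the two amyloid-to-P-tau routes (kinase and calcium), the
P-tau-to-amyloid route, and tau-to-P-tau phosphorylation; total tau receives
no incoming chain, matching the topology in which tau pathology feeds
forward into P-tau but not conversely.

## Disruption parameters

With `Va` the marker vector in a pathological state and `Vb` the normal
state,

    K   = |Va| / |Vb|                      (modulus ratio)
    phi = arccos( Va.Vb / (|Va| |Vb|) )    (angle, radians)
    U   = (Va - Vb)(Va - Vb)^T             (squared distance)

`K` responds to consistent co-movement of all markers, `phi` to
inconsistent (direction-changing) variation, `U` to total variation.  At
the normal state (U, K, phi) = (0, 1, 0).

Two reporting conventions matter:

* Markers are normalized by the Normal-group means before the formulas
  (`cohort_disruption(..., normalize = TRUE)`, the default), so
  `Vb = (1, 1, 1)`.  The three raw marker scales differ by an order of
  magnitude; without normalization `U` and `phi` would be dominated by
  amyloid alone, and the balance map's normal state would not be an
  equilateral triangle.  Raw-scale computation remains available.
* `K` is reported as `|K - 1| x 100` ("K percent"), the deviation from its
  normal-state value: a uniform increase of all markers by a gradient g
  then yields exactly g x 100, as `run_gradient_experiment()` demonstrates
  (10% -> 10.00, 20% -> 20.00, 50% -> 50.00, with phi = 0 throughout).
  `phi` is reported in radians plus a x100 display column; `U` in squared
  normalized units.  Alternative percentage conventions for phi and U that
  would make the inconsistent-variation scenarios print specific values
  are not derivable from first principles and are deliberately not
  emulated; the uniform-increase scenario, which is analytically forced,
  is the only numeric anchor.

The gradient experiment's three scenarios (one marker moving; all moving
together; one up, two down) reproduce the parameters' physiological
reading: U responds to everything, K to consistent variation, phi to
inconsistent variation.

## Disruption probability

`estimate_disruption_probability()` asks: if a subject's markers are
randomly perturbed, how often does the network leave its normal operating
region?

* **Perturbation.** Multiplicative lognormal around the observed level,
  `exp(Z)` with `Z ~ N(-sigma^2/2, sigma^2)` so the factor has mean 1;
  default sigma 0.25.  A multiplicative, positivity-preserving distribution
  is the natural choice for concentration data; sigma is per-marker
  configurable.
* **Operating region.** Thresholds calibrated from the Normal group as the
  Tukey upper whisker (largest observation within Q3 + 1.5 IQR) of each of
  U, |K - 1| and phi (`calibrate_thresholds()`).  A perturbed state is
  disrupted when *any* parameter exceeds its whisker (OR rule); an AND
  variant is available since the criterion could also be read
  conjunctively.
* **Estimator.** Plain Monte Carlo, pf = d / D, in batches (default 100)
  with the adaptive stopping rule: terminate once the relative error

      eps_p = t(alpha/2, D-1) * sqrt(pf (1 - pf)) / (pf sqrt(D))

  falls below 5%.  This is the relative half-width of the binomial
  confidence interval.  The rule is evaluated at the *current* iteration
  count D — with a fixed predefined count the rule could not adapt — and
  the t quantile uses D - 1 degrees of freedom, converging to the normal
  quantile.  When no disruption is ever observed the estimator reports
  pf = 0 with an explicit no-disruption status instead of a relative error,
  which is undefined at pf = 0.
* **Two operating modes.** In `static` mode the perturbed vector itself is
  scored.  In `coupled` mode the perturbation is first propagated through
  the transit-compartment network for a configurable horizon (default 1
  month), so crosstalk can amplify or buffer it before scoring.  Static is
  the default: it is what makes the uniform-increase gradient scenario
  exact, and it is orders of magnitude faster.  Coupled mode is where the
  network topology matters, e.g. in the contribution analysis below.

The static single-marker case has a closed form — the disruption region in
the perturbation factor is `|m * s - r| > sqrt(u_max)` with lognormal m —
and the estimator is tested against deterministic integration of that
density within three binomial standard errors.

## Marker contributions

`marker_contributions()` perturbs one marker (or a group) while holding the
others at their observed levels, and reports each subset's pf as a
percentage of the sum over evaluated subsets.  Two regimes deserve note:

* at a state already far outside the Normal whiskers (e.g. the synthetic
  AD group mean) every subset's pf saturates at 1 and contributions
  equalize — the network is already disrupted, so no marker is pivotal;
* near the disruption boundary, and especially in coupled mode, the
  topology differentiates the subsets; joint subsets dominate their
  members (a guaranteed monotonicity under the OR rule, tested by coupling
  the random draws).

## Downstream evaluation

`regress_pf_vs_mmse()` fits ordinary least squares of pf on MMSE (or on
1/MMSE, since a disruption probability bounded in [0, 1] tracking a
declining score is naturally reciprocal).  `crossvalidate()` runs
stratified 10-fold cross-validation of an RBF-kernel SVM (e1071, default
hyperparameters; no kernel or tuning is prescribed at this level), pooling
fold predictions into one confusion matrix — pooling is stable with a
disease group as small as 18 subjects, where per-fold averages would be
noisy.  The disease class is the positive class for sensitivity.
Classification is per subject by default, averaging each subject's visit
features; per-visit classification is available
(`build_features(unit = "visit")`).  Feature standardization uses
training-fold statistics only.  `compare_feature_sets()` contrasts the
model features (U, K, phi, pf) with raw markers (tau, P-tau, abeta) and
with the three leave-one-parameter-out ablations, on identical folds.

# The synthetic cohort

`generate_cohort()` emulates the published demographic frame of the
longitudinal ADNI-1 CSF subset: 135 Normal / 155 MCI / 18 AD subjects,
four visits at months 12/24/36/48, group MMSE 29±1 / 27±2 / 24±2, and the
published sex ratios and ages.  What it cannot take from the publication
are the raw per-group CSF means, which are not public for that subset; the
defaults (Normal means 205 / 70 / 25 pg/mL; AD multipliers 0.66 / 1.75 /
1.85; MCI intermediate; mild annual drift in the disease groups) are
package choices at typical CSF immunoassay magnitudes and effect sizes,
stated in the configuration and documented as such, not as ADNI values.

Generative structure per subject: lognormal between-subject effect
(cv 0.10), group multiplier, compounding annual drift, multiplicative
lognormal measurement noise (cv 0.15) — all mean-1 so configured means are
recovered in expectation (verified to 2% at n = 5000).  The latent severity
of a subject-visit is the Euclidean distance of the *noise-free* normalized
marker vector from (1, 1, 1); MMSE is the group mean minus 1.5 points per
standard deviation of severity plus residual noise, rounded and clipped to
[0, 30].  Severity is stored with each record for parameter-recovery tests
but never used by the analysis functions, and `write_cohort()` drops it.

What the generator does **not** emulate: the empirical covariance of real
CSF assays, diagnosis conversion, attrition patterns (dropout is a plain
per-visit Bernoulli, default 0 because the emulated study excluded
incomplete subjects), imaging or genetic covariates, and assay batch
effects.  Consequently, passing tests demonstrate that the *method* is
implemented correctly and recovers built-in signal; they do not certify
clinical performance.  In particular the default synthetic effect sizes
separate the groups strongly, so cross-validated accuracies near 100% on
synthetic cohorts say nothing about accuracy on real data, and the
published headline classification figures are not reproduction targets
here.

# Numerical choices

* Integration: deSolve's `lsoda`, atol 1e-9, rtol 1e-6, fixed output grid.
  Negative levels beyond -1e-8 abort; smaller undershoots are clamped to 0.
* Steady states are solved algebraically (at a fixed point every chain
  compartment equals its source), giving an independent check on the
  calibration.
* `acos` arguments are clipped to [-1, 1]; parallel vectors can otherwise
  overshoot by ~1e-16 and phi prints as ~1e-8 rather than 0.
* Tukey whiskers use R's default type-7 quantiles.
* Every stochastic routine takes an explicit integer seed and restores the
  caller's RNG state; identical (input, seed) pairs give identical output,
  including the Monte Carlo (d, D, pf) bookkeeping.
* Test problem sizes are chosen to keep the full suite fast while leaving
  no estimator untested at convergence: cohorts of 30–100 subjects per
  group in unit tests, the full 308-subject design for the end-to-end
  regression check, Monte Carlo caps of 10⁴–5x10⁴ draws, and coupled-mode
  runs of a few hundred draws (each draw costs one ODE solve).

# Known limitations

* The ODE reconstruction is structural, not mechanistic: AChE, GSK-3beta,
  PS1 and calcium are collapsed into linear transit chains, and no rate is
  estimated from data.
* Static-mode contribution analysis is symmetric by construction when the
  subject sits at the reference; discriminating marker contributions
  requires coupled mode or an off-reference state.
* The relative-error stopping rule is undefined when pf = 0 and slow for
  pf near 0 (D grows like 1/pf); runs that hit the iteration cap are
  flagged unconverged rather than silently accepted.
* phi and U "percent" scales beyond the x100 display convention are not
  modelled (see the disruption-parameters section).
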