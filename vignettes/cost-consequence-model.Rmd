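---
title: "An early cost-consequence model for computer-vision-based skin prick tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An early cost-consequence model for computer-vision-based skin prick tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptcca)
```

## The decision problem

Skin prick tests (SPTs) are the usual first-line investigation for suspected
IgE-mediated allergy: allergen extracts are pricked into the forearm skin and
a wheal at least 3 mm larger than the negative control indicates
sensitization. Reading and recording the wheals by hand takes staff time and
is error-prone; a camera-based device ("digital SPT", DSPT) can locate and
measure wheals automatically, cutting the hands-on reading time but --- on
current evidence --- with somewhat lower diagnostic accuracy than the manual
gold standard.

`sptcca` implements an early cost-consequence model, from the perspective of
a hospital allergology department over a one-year horizon (no discounting,
all amounts in CHF at a fixed CHF 1 = EUR 1), that asks: *per referred
patient tested, does reading SPTs with the camera system save money once its
lower accuracy is accounted for?*

The model is deliberately narrow, as early cost-consequence models are: it
tracks only direct SPT-related hospital costs. No health outcomes, patient
or GP costs, quality-of-life effects, or multi-year dynamics are modelled.

## Model structure

The model is a two-arm decision tree. A decision node selects the strategy
(fully manual vs computer-vision SPT). Within an arm, a referred patient is
truly sensitized with probability $p$ (the prevalence in the referred
population); the test then comes back positive with probability equal to the
arm's sensitivity $se$ if sensitized, and negative with probability equal to
its specificity $sp$ otherwise. That yields four mutually exclusive
terminal pathways per arm with probabilities

$$\Pr(TP) = p\,se,\quad \Pr(FN) = p\,(1-se),\quad
\Pr(FP) = (1-p)(1-sp),\quad \Pr(TN) = (1-p)\,sp.$$

Costs attach to terminals as follows:

* **TP, TN, FP** --- one test's cost $C_{arm}$. A false positive has no
  *direct* further hospital cost: an SPT is not a standalone diagnosis, so a
  false positive is assumed to be caught when the result is combined with
  the clinical history.
* **FN** --- the patient is assumed to return via a second GP referral and
  be retested. With $f$ the *total* number of tests accrued by a
  false-negative patient (default mean 2), the terminal pays
  $C_{arm} + (f - 1)\,C_{retest}$.

The expected cost per strategy is the probability-weighted sum over the four
pathways (expected-value rollback), and the headline quantity is

$$\Delta = E[\text{cost}\mid\text{digital}] - E[\text{cost}\mid\text{manual}],$$

negative when the digital arm saves money; `savings = -incremental` is
reported alongside.

### The retest strategy

Which price does the FN retest carry? The package's default,
`manual_retest`, prices it at the *manual* per-test cost in both arms: a
patient whose camera-read test missed a real sensitization plausibly returns
to the reference (manual) pathway. This is also the only reading under which
higher prevalence *dis*favours the less accurate digital arm --- the
direction the sensitivity analysis is expected to show, since more
sensitized patients mean more of the digital arm's extra false negatives
generating expensive manual retests. The alternative `same_arm_retest`
(retest priced at the arm's own cost) is retained as a configurable option;
under it the comparison becomes symmetric and savings negate exactly when
the two arms' parameters are swapped.

With the default mean of $f = 2$ the FN surcharge is exactly one repeat
test, so the two readings coincide for the manual arm.

## Parameters

All inputs are carried with their provenance, not just their point value.

| Parameter | Definition | Default | One-way range |
|---|---|---|---|
| prevalence | grass-pollen sensitization among referred adults, 1061/8357 | 0.127 | 0.10--0.20 |
| manual sensitivity | 3 mm cut-off, 1485/2289 | 0.649 | 0.64--0.66 |
| manual specificity | 9366/9627 | 0.973 | 0.97--0.98 |
| digital sensitivity | manual minus 2.5 points, 1448/2289 | 0.633 | 0.62--0.64 |
| digital specificity | 9132/9627 | 0.948 | 0.94--0.96 |
| manual cost/test | materials 19.41 + staff 19.96 (5.5 min) | CHF 39.37 | 31.5--47.2 |
| digital cost/test | materials 19.41 + staff 10.89 (3 min) + device 0.40 | CHF 30.70 | 24.6--36.9 |
| further tests $f$ | total tests for an FN patient | 2 | 1.6--2.4 |

Probability parameters are defined by a positive count $r$ out of a sample
$n$ and receive the conjugate specification $\mathrm{Beta}(r,\,n-r)$, whose
mean is exactly $r/n$; that keeps the probabilistic analysis centred on the
deterministic point estimates. Cost parameters receive method-of-moments
Gamma distributions, $shape = (\mu/\sigma)^2$, $scale = \sigma^2/\mu$, with
$\sigma$ defaulting to $0.2\mu$ (the same 20% rule as the one-way ranges).

Two derivation notes:

* The device contributes CHF 0.40/test: straight-line depreciation of a
  CHF 10,400 capital value over 10 years plus CHF 1,040/year service,
  spread over 5,200 tests/year (`device_cost_per_test()`).
* The staff rate is back-derived from the printed per-test salary costs
  (19.96/5.5 min = 10.89/3 min ≈ CHF 3.63/min); the per-test costs are
  treated as authoritative because they, not an hourly wage, enter the
  model.
* The further-tests multiplier is continuous (Gamma-distributed), not an
  integer; draws below 1 are possible in principle but vanishingly rare
  under Gamma(25, 0.08), and are flagged with a warning rather than
  truncated.

```{r basecase}
inputs <- spt_default_inputs()
expected_incremental(inputs)
```

## One-way sensitivity analysis

`one_way_dsa()` re-evaluates the tree with each of the eight parameters at
its lower then upper bound, everything else fixed. Each parameter enters
the model in exactly one place, so varying the manual cost also reprices
the FN retest (under `manual_retest`) --- a deliberate design choice that
keeps the excursion internally consistent rather than freezing a shadow
copy of the same price.

```{r dsa}
rank_by_width(one_way_dsa(inputs))[, c("parameter", "incremental_at_low",
                                       "incremental_at_high", "bar_width")]
```

The two arm costs dominate the tornado; accuracy and prevalence move the
result by fractions of a franc over their plausible ranges, and no excursion
changes the sign of the incremental.

## Probabilistic sensitivity analysis

`run_psa()` samples all eight parameters independently from their
Beta/Gamma specifications --- the model states no correlation structure, and
independence is the simplest assumption consistent with that (a known
limitation: materials costs, for instance, are shared between arms in
reality). Draws happen in a fixed parameter order from one seeded
generator, so a seed fully determines the result. Each draw is a plug-in
re-evaluation of the same deterministic tree engine; because the
incremental cost is multilinear in the independently sampled parameters,
the Monte Carlo mean converges to the deterministic base case, which the
test suite checks at 50,000 draws.

```{r psa}
psa <- run_psa(inputs, n_simulations = 2000, seed = 1)
psa
convergence_trace(psa$incremental, block = 500, tolerance = 0.01)
```

Convergence is assessed on the running mean at block boundaries (default
block 500 draws): the simulation is declared stable at the first boundary
where the running mean moves by less than 1% relative to the previous
boundary. The default of 10,000 draws is comfortably past stabilisation for
this model. `distribution_summary()` reports moment-based skewness and
excess kurtosis; the incremental-cost draws are close to normal in shape
(|skewness| well under 0.5), being a smooth combination of eight
independent, mostly additive sources of noise.

## The microsimulation oracle

Because the rollback is a closed-form computation, it is validated against
an implementation that shares none of its code path:
`simulate_cohort()` pushes individual synthetic patients through the
modelled pathway --- Bernoulli sensitization at the prevalence, a Bernoulli
test result governed by the arm's accuracy, per-patient cost accrual with
the FN retest rule --- and compares cohort mean costs with the analytic
expected values.

```{r microsim}
coh <- simulate_cohort(inputs, n_patients = 50000, seed = 2)
coh
classification_check(coh, inputs)
```

What the generator emulates is exactly the tree's stochastic structure:
conditionally independent Bernoulli events and a two-valued cost
distribution per arm. What it does *not* emulate is everything the tree
itself omits --- patient covariates, within-patient correlation of repeat
tests, the possibility that the retest is itself falsely negative (the
surcharge is charged once, matching the tree), or downstream non-SPT costs.
Agreement between simulator and rollback therefore validates the engine,
not the model's fidelity to real patients.

`random_scenario()` generates valid random parameter sets (counts with
binomial provenance, right-skewed positive costs, multiplier ≥ 1) for
property-based testing; the suite sweeps 100 such scenarios at 10^5
patients each. Since a two-sided 3-standard-error criterion across 200
scenario-arm comparisons flags roughly half a comparison by pure chance,
the suite uses a two-stage rule: a flagged comparison is re-simulated once
at 10^6 patients and must then fall within 3 SE. A genuine engine error
grows like $\sqrt{n}$ under escalation, so the retest increases, rather
than dilutes, the sweep's power. Degenerate scenarios (prevalence 0 or 1,
sensitivity 0 or 1, multiplier 1) produce zero-variance cohorts and are
required to match exactly.

## Numerical conventions and problem sizes

* Probability sums at chance nodes are checked to 1e-9; payoffs are kept as
  exact decimals of the inputs, with rounding (2 decimals for CHF, printed
  output only) applied at the reporting edge.
* Tornado tie-breaks: equal bar widths rank alphabetically by parameter
  label, making exports deterministic.
* The checked-in analyses use 10,000 PSA draws (the default), 10^5--10^6
  microsimulated patients, and 100 random validation scenarios; these sizes
  put Monte Carlo noise one to two orders of magnitude below the effects
  being tested.
* A single integer seed determines every stochastic result
  (`run_psa()`, `simulate_cohort()`, `random_scenario()`).

## Known limitations

The package reproduces an *early* model and inherits its scope: hospital
perspective only, one year, no discounting, no health outcomes, accuracy
assumptions for the digital device resting on limited unpublished evidence,
and a referred-population prevalence taken from a 1995 national survey.
The closed-form rollback of the tree yields a base-case saving of about
CHF 8.6 per test. Headline figures for this comparison are often quoted
more conservatively, at roughly CHF 7 per test; the package's acceptance
checks therefore treat CHF 7 as a lower bound the reconstruction must
clear, and report the model's own rollback transparently rather than
calibrating toward any external figure.
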