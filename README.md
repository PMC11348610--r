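# sptcca

An early cost-consequence model comparing **computer-vision-based skin prick
tests (SPTs)** with the standard fully manual technique, from the perspective
of a hospital allergology department.

SPTs are the usual first-line allergy investigation: allergen extracts are
pricked into the skin, and a wheal ≥ 3 mm over the negative control indicates
sensitization. A camera-assisted reader cuts the hands-on reading time per
test (3 min vs 5.5 min of staff time) at the price of somewhat lower
diagnostic accuracy, plus a small amortised device cost. For health
economists and hospital decision-makers, `sptcca` answers: *per referred
patient tested, which reading technique costs less once misclassification is
priced in?*

## The model

A two-arm decision tree over a referred patient population. Within each arm,
a patient is truly sensitized with probability *p* and the test result
follows the arm's sensitivity *se* / specificity *sp*, giving four terminal
pathways:

    Pr(TP) = p·se        Pr(FN) = p·(1−se)
    Pr(FP) = (1−p)(1−sp) Pr(TN) = (1−p)·sp

Every terminal costs one test `C_arm`; a **false negative** additionally
accrues `(f − 1)` repeat tests (default *f* = 2 total tests, priced at the
manual cost — the reference pathway a missed patient returns to); a false
positive has no further direct hospital cost. The expected cost per strategy
is the probability-weighted pathway sum (rollback), and the headline result
is the incremental cost `Δ = E[cost|digital] − E[cost|manual]` (negative =
the camera arm saves money).

Around this deterministic core the package provides:

* **Parameter construction** — probabilities as positive-count/sample-size
  pairs with conjugate `Beta(r, n−r)` specifications; costs as mean/SD with
  method-of-moments Gamma specifications and a 20% default uncertainty rule;
  device amortisation (straight-line depreciation + service over annual
  volume).
* **One-way sensitivity analysis** — tornado entries and plot over all eight
  parameter ranges.
* **Probabilistic sensitivity analysis** — seeded Monte Carlo over all
  Beta/Gamma distributions with convergence and distribution-shape
  diagnostics.
* **A microsimulation oracle** — patient-level simulation of the same
  pathway, used to validate the analytic engine.
* **A file-driven pipeline** — YAML/JSON model specifications,
  `run_all()` result bundles, and a command-line wrapper in
  `inst/scripts/run_spt_cca.R`.

## Worked example

```r
library(sptcca)

inputs <- spt_default_inputs()   # reference counts and costs
expected_incremental(inputs)
#> Incremental cost, digital vs manual SPT (CHF per test)
#>   E[cost | manual]  :    41.13
#>   E[cost | digital] :    32.54
#>   incremental (digital - manual):    -8.59
#>   savings per test  :     8.59
```

Reading: a manual SPT costs CHF 39.37, but the expected cost per referred
patient is CHF 41.13 once false-negative retests are priced in; the digital
arm's cheaper test (CHF 30.70) more than offsets its extra false negatives,
for an expected saving of **CHF 8.59 per test**.

```r
rank_by_width(one_way_dsa(inputs))[1:3, c("parameter", "bar_width")]
#>     parameter bar_width
#> 1 manual_cost 15.667780
#> 2   dspt_cost 12.300000
#> 3 dspt_sensitivity 0.09996786

psa <- run_psa(inputs, n_simulations = 10000, seed = 1)
psa
#> PSA: 10000 Monte Carlo draws (seed 1)
#>   incremental (digital - manual), CHF/test: mean -8.67, sd 9.86
#>   95% interval: [-28.26, 10.36]
#>   P(digital arm cost-saving) = 0.8118
```

The two per-test cost parameters dominate the tornado; no one-way excursion
makes the digital arm cost-increasing. Under full parameter uncertainty the
digital arm is cost-saving in 81% of simulations.

```r
simulate_cohort(inputs, n_patients = 1e6, seed = 2)$arms[, 1:3]
#>     arm mean_cost          se
#>  manual  41.13980 0.008157505
#>    dspt  32.55696 0.008346284
```

The independent patient-level simulation reproduces the rollback values
within Monte Carlo error.

See `vignette("cost-consequence-model")` for the model's assumptions,
parameter provenance, and validation design.

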