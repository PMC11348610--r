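# Closed-form oracle for the two-arm pathway model, written directly from
# the pathway algebra and independent of the tree engine:
#   E[cost | arm] = C_arm + prev * (1 - sens) * (further - 1) * C_retest
# with C_retest = manual cost under manual_retest, the arm's own cost
# otherwise. Used to check rollback / expected_incremental / one_way_dsa.
oracle_arm_ev <- function(prev, sens, arm_cost, retest_cost, further) {
  arm_cost + prev * (1 - sens) * (further - 1) * retest_cost
}

oracle_incremental <- function(inputs) {
  p <- inputs$prevalence$point_estimate
  cm <- inputs$manual_cost$mean
  cd <- inputs$dspt_cost$mean
  ft <- inputs$further_tests$mean
  retest_d <- if (inputs$retest_strategy == "manual_retest") cm else cd
  ev_m <- oracle_arm_ev(p, inputs$manual_sensitivity$point_estimate, cm, cm, ft)
  ev_d <- oracle_arm_ev(p, inputs$dspt_sensitivity$point_estimate, cd, retest_d, ft)
  list(ev_manual = ev_m, ev_dspt = ev_d, incremental = ev_d - ev_m)
}

# Default inputs with selected parameters overridden on the evaluation
# scale (probability for proportions, mean for costs).
inputs_with <- function(..., base = spt_default_inputs()) {
  overrides <- list(...)
  for (nm in names(overrides)) {
    p <- base[[nm]]
    if (inherits(p, "proportion_parameter")) {
      v <- overrides[[nm]]
      # exact point estimate via counts on a large denominator
      base[[nm]] <- proportion_parameter(p$label, v * 1e6, 1e6,
                                         dsa_low = max(0, min(v, p$dsa_low)),
                                         dsa_high = min(1, max(v, p$dsa_high)))
    } else {
      base[[nm]] <- cost_parameter(p$label, overrides[[nm]])
    }
  }
  base
}
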