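test_that("validate_tree flags structural violations and passes the model tree", {
  tree <- build_spt_tree(spt_default_inputs())
  report <- validate_tree(tree)
  expect_true(report$valid)
  expect_length(report$violations, 0)

  bad_probs <- decision_tree(decision_node("root", list(
    a = chance_node("c", list(
      list(prob = 0.6, node = terminal_node("t1", 1)),
      list(prob = 0.3, node = terminal_node("t2", 2)))))))
  rep1 <- validate_tree(bad_probs)
  expect_false(rep1$valid)
  expect_match(rep1$violations, "sum", all = FALSE)

  bad_payoff <- decision_tree(decision_node("root", list(
    a = chance_node("c", list(
      list(prob = 1, node = terminal_node("t", -1)))))))
  rep2 <- validate_tree(bad_payoff)
  expect_false(rep2$valid)
  expect_match(rep2$violations, "non-negative", all = FALSE)

  nested_decision <- decision_tree(decision_node("root", list(
    a = decision_node("inner", list(b = terminal_node("t", 1))))))
  rep3 <- validate_tree(nested_decision)
  expect_false(rep3$valid)
  expect_match(rep3$violations, "below the root", all = FALSE)

  expect_error(rollback(bad_probs), "invalid tree")
})

test_that("rollback is the probability-weighted pathway sum", {
  single <- decision_tree(decision_node("root", list(
    only = terminal_node("t", 42))))
  expect_equal(rollback(single), c(only = 42))

  even <- decision_tree(decision_node("root", list(
    s = chance_node("c", list(
      list(prob = 0.5, node = terminal_node("lo", 0)),
      list(prob = 0.5, node = terminal_node("hi", 10)))))))
  expect_equal(rollback(even), c(s = 5))

  # default inputs against the closed-form pathway oracle (~41.13 / ~32.54)
  ev <- rollback(build_spt_tree(spt_default_inputs()))
  oracle <- oracle_incremental(spt_default_inputs())
  expect_equal(unname(ev["manual"]), oracle$ev_manual)
  expect_equal(unname(ev["dspt"]), oracle$ev_dspt)
  expect_equal(unname(ev["manual"]), 41.13, tolerance = 1e-3)
})

test_that("the built tree carries the four classification pathways per arm", {
  inp <- spt_default_inputs()
  po <- pathway_outcomes(inp)
  expect_equal(nrow(po), 8)
  for (arm in c("manual", "dspt")) {
    expect_equal(sum(po$probability[po$strategy == arm]), 1, tolerance = 1e-9)
  }
  p <- inp$prevalence$point_estimate
  sens <- inp$manual_sensitivity$point_estimate
  spec <- inp$manual_specificity$point_estimate
  man <- po[po$strategy == "manual", ]
  expect_equal(man$probability[man$classification == "TP"], p * sens)
  expect_equal(man$probability[man$classification == "FN"], p * (1 - sens))
  expect_equal(man$probability[man$classification == "FP"], (1 - p) * (1 - spec))
  expect_equal(man$probability[man$classification == "TN"], (1 - p) * spec)
  # only the FN terminal carries the retest surcharge
  expect_equal(man$payoff[man$classification == "FN"],
               39.37 + (2 - 1) * 39.37)
  expect_equal(man$payoff[man$classification != "FN"], rep(39.37, 3))

  # degenerate prevalence removes the sensitized pathways
  po0 <- pathway_outcomes(inputs_with(prevalence = 0))
  expect_equal(po0$probability[po0$classification %in% c("TP", "FN")],
               rep(0, 4))

  # further_tests = 1 removes the FN surcharge
  po1 <- pathway_outcomes(inputs_with(further_tests = 1))
  expect_equal(po1$payoff[po1$strategy == "manual"], rep(39.37, 4))
})

test_that("expected_incremental matches the closed-form oracle and sign conventions", {
  inp <- spt_default_inputs()
  res <- expected_incremental(inp)
  oracle <- oracle_incremental(inp)
  expect_equal(res$ev_manual, oracle$ev_manual)
  expect_equal(res$ev_dspt, oracle$ev_dspt)
  expect_equal(res$incremental, oracle$incremental)
  expect_identical(res$savings, res$ev_manual - res$ev_dspt)

  # identical arms cancel exactly
  equal_arms <- inputs_with(dspt_cost = 39.37)
  equal_arms$dspt_sensitivity <- equal_arms$manual_sensitivity
  equal_arms$dspt_specificity <- equal_arms$manual_specificity
  expect_equal(expected_incremental(equal_arms)$incremental, 0)

  # no sensitized patients: saving is the pure per-test cost difference
  expect_equal(expected_incremental(inputs_with(prevalence = 0))$savings,
               39.37 - 30.70)
})

test_that("pathway probabilities and EV bounds hold over random scenarios", {
  for (s in 1:25) {
    inp <- random_scenario(s)
    po <- pathway_outcomes(inp)
    for (arm in c("manual", "dspt")) {
      sub <- po[po$strategy == arm, ]
      expect_equal(sum(sub$probability), 1, tolerance = 1e-9)
      ev <- if (arm == "manual") expected_incremental(inp)$ev_manual
            else expected_incremental(inp)$ev_dspt
      expect_gte(ev, min(sub$payoff) - 1e-9)
      expect_lte(ev, max(sub$payoff) + 1e-9)
    }
    # engine agrees with the closed-form oracle on every scenario
    expect_equal(expected_incremental(inp)$incremental,
                 oracle_incremental(inp)$incremental)
  }
})

test_that("EV is monotone in prevalence and further tests", {
  evm <- function(p) expected_incremental(inputs_with(prevalence = p))$ev_manual
  grid <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(grid, evm, numeric(1))) >= 0))

  evf <- function(ft) expected_incremental(inputs_with(further_tests = ft))$ev_dspt
  fts <- c(1, 1.5, 2, 3, 5)
  expect_true(all(diff(vapply(fts, evf, numeric(1))) > 0))
})

test_that("savings negate when the arms are swapped under same_arm_retest", {
  for (s in 1:10) {
    inp <- random_scenario(s)
    inp$retest_strategy <- "same_arm_retest"
    swapped <- inp
    swapped$manual_sensitivity <- inp$dspt_sensitivity
    swapped$dspt_sensitivity <- inp$manual_sensitivity
    swapped$manual_specificity <- inp$dspt_specificity
    swapped$dspt_specificity <- inp$manual_specificity
    swapped$manual_cost <- inp$dspt_cost
    swapped$dspt_cost <- inp$manual_cost
    expect_equal(expected_incremental(swapped)$savings,
                 -expected_incremental(inp)$savings)
  }
})

test_that("tree JSON export and base-case CSV round-trip the structure", {
  tree <- build_spt_tree(spt_default_inputs())
  json <- tree_to_json(tree)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(parsed$kind, "decision")
  expect_length(parsed$children, 2)
  expect_equal(parsed$children[[1]]$children[[1]]$probability,
               1061 / 8357)

  path <- withr::local_tempfile(fileext = ".csv")
  res <- expected_incremental(spt_default_inputs())
  basecase_export(res, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 4)
  expect_equal(df$chf_per_test[df$quantity == "savings_per_test"], res$savings)
})
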