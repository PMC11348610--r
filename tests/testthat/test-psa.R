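test_that("draw_inputs samples the assigned distributions reproducibly", {
  inp <- spt_default_inputs()
  set.seed(11)
  d1 <- suppressWarnings(draw_inputs(inp, 2000))
  set.seed(11)
  d2 <- suppressWarnings(draw_inputs(inp, 2000))
  expect_identical(d1, d2)

  expect_equal(names(d1),
               c("prevalence", "manual_sensitivity", "manual_specificity",
                 "dspt_sensitivity", "dspt_specificity",
                 "manual_cost", "dspt_cost", "further_tests"))
  probs <- as.matrix(d1[, 1:5])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(d1$manual_cost > 0 & d1$dspt_cost > 0 & d1$further_tests > 0))

  # prevalence draws centre on r/n: Beta(1061, 7296) has known moments
  set.seed(3)
  n <- 10000
  prev <- suppressWarnings(draw_inputs(inp, n))$prevalence
  p <- 1061 / 8357
  se <- sqrt(p * (1 - p) / (8357 + 1)) / sqrt(n)
  expect_lt(abs(mean(prev) - p), 3 * se)

  # improper Beta (no positives) is refused for sampling
  degen <- inp
  degen$prevalence <- proportion_parameter("prevalence", 0, 100)
  expect_error(draw_inputs(degen, 10), "improper")
})

test_that("run_psa is reproducible and consistent with the deterministic engine", {
  inp <- spt_default_inputs()
  r1 <- suppressWarnings(run_psa(inp, 500, seed = 9))
  r2 <- suppressWarnings(run_psa(inp, 500, seed = 9))
  expect_identical(r1$incremental, r2$incremental)
  expect_identical(r1$prob_cost_saving, r2$prob_cost_saving)

  # each draw is a plug-in evaluation of the same engine (pick a draw whose
  # further-tests value is a valid multiplier for the public constructor)
  i <- which.max(r1$draws$further_tests)
  row <- r1$draws[i, ]
  check <- do.call(inputs_with, as.list(row[names(row) != "incremental"]))
  expect_equal(r1$incremental[i], expected_incremental(check)$incremental,
               tolerance = 1e-9)

  one <- suppressWarnings(run_psa(inp, 1, seed = 4))
  expect_equal(one$mean, one$incremental[1])
  expect_true(is.na(one$sd))
  expect_error(run_psa(inp, 0), "invalid argument")
})

test_that("the PSA mean converges to the deterministic incremental", {
  # incremental cost is multilinear in independently sampled parameters, so
  # its Monte Carlo expectation equals the plug-in value
  inp <- spt_default_inputs()
  res <- suppressWarnings(run_psa(inp, 50000, seed = 21))
  base <- expected_incremental(inp)$incremental
  mc_se <- res$sd / sqrt(res$n_simulations)
  expect_lt(abs(res$mean - base), 3 * mc_se)
})

test_that("shifting both arms' cost draws moves the incremental by the exact affine term", {
  inp <- spt_default_inputs()
  res <- suppressWarnings(run_psa(inp, 300, seed = 14))
  shift <- 5
  shifted <- res$draws
  shifted$manual_cost <- shifted$manual_cost + shift
  shifted$dspt_cost <- shifted$dspt_cost + shift
  eval_rows <- function(d) {
    vapply(seq_len(nrow(d)), function(i) {
      sptcca:::.incremental_values(
        prev = d$prevalence[i], sens_m = d$manual_sensitivity[i],
        spec_m = d$manual_specificity[i], sens_d = d$dspt_sensitivity[i],
        spec_d = d$dspt_specificity[i], cost_m = d$manual_cost[i],
        cost_d = d$dspt_cost[i], further = d$further_tests[i],
        retest_strategy = "manual_retest")$incremental
    }, numeric(1))
  }
  inc_shifted <- eval_rows(shifted)
  # under manual_retest the FN retest is priced from the (shifted) manual
  # cost, so the per-draw change is prev * (sens_m - sens_d) * (ft - 1) * shift
  delta <- with(res$draws,
                prevalence * (manual_sensitivity - dspt_sensitivity) *
                  (further_tests - 1) * shift)
  expect_equal(inc_shifted, res$incremental + delta, tolerance = 1e-8)

  # with identical sensitivities the affine term vanishes and the
  # cost-saving probability is exactly shift-invariant
  same_sens <- res$draws
  same_sens$dspt_sensitivity <- same_sens$manual_sensitivity
  inc0 <- eval_rows(same_sens)
  same_sens$manual_cost <- same_sens$manual_cost + shift
  same_sens$dspt_cost <- same_sens$dspt_cost + shift
  inc1 <- eval_rows(same_sens)
  expect_equal(inc1, inc0, tolerance = 1e-8)
  expect_identical(mean(inc1 < 0), mean(inc0 < 0))
})

test_that("convergence_trace finds the first stable running-mean block", {
  expect_equal(convergence_trace(rep(3.7, 2000), block = 500), 500L)
  # an oscillating sequence never stabilises at a tight tolerance
  alternating <- rep(c(1e6, -1e6), 500)
  expect_true(is.na(convergence_trace(alternating, block = 1, tolerance = 1e-6)))
  expect_error(convergence_trace(numeric(0)), "empty")
  # fewer draws than one block: no block boundary to assess
  expect_true(is.na(convergence_trace(rnorm(100), block = 500)))
})

test_that("distribution_summary computes moment-based shape statistics", {
  sym <- distribution_summary(c(-1, 0, 1))
  expect_equal(sym$skewness, 0)
  x <- rnorm(500, mean = 4, sd = 2)
  s1 <- distribution_summary(x)
  s2 <- distribution_summary(x + 100)  # translation invariance
  expect_equal(s1$skewness, s2$skewness)
  expect_equal(s1$excess_kurtosis, s2$excess_kurtosis)
  expect_error(distribution_summary(c(1, 2)), "at least 3")
  skip_if_not_installed("e1071")
  expect_equal(s1$skewness, e1071::skewness(x, type = 1))
  expect_equal(s1$excess_kurtosis, e1071::kurtosis(x, type = 1))
})

test_that("PSA exports carry the draws, the summary and a unit-mass histogram", {
  res <- suppressWarnings(run_psa(spt_default_inputs(), 400, seed = 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  psa_export_draws(res, csv)
  draws <- utils::read.csv(csv)
  expect_equal(nrow(draws), 400)
  expect_true("incremental" %in% names(draws))

  js <- withr::local_tempfile(fileext = ".json")
  psa_export_summary(res, js)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n_simulations, 400)
  expect_equal(summ$prob_cost_saving, res$prob_cost_saving)
  expect_equal(summ$mean_savings_chf, -summ$mean_incremental_chf)

  h <- ggplot2::ggplot_build(plot_psa_histogram(res))$data[[1]]
  expect_equal(sum(h$density * (h$xmax - h$xmin)), 1, tolerance = 1e-9)
  expect_s3_class(plot_psa_convergence(res), "ggplot")
})
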