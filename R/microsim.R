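#' Patient-level microsimulation of the SPT pathway
#'
#' Simulates individual referred patients through each arm of the modelled
#' pathway: true sensitization is Bernoulli at the prevalence; the test
#' outcome is Bernoulli at the arm's sensitivity for sensitized patients and
#' at one minus its specificity otherwise; every patient accrues one test's
#' cost, and a false negative additionally accrues `(further_tests - 1)`
#' repeat tests priced by the retest strategy. The cohort mean cost per arm
#' is an independent estimate of the analytic rollback, which is the
#' module's purpose as a validation oracle.
#'
#' By default the two arms draw independent randomness (the model compares
#' population strategies, not paired within-patient results); `paired = TRUE`
#' reuses one sensitization draw per patient across arms to reduce the
#' variance of the between-arm comparison.
#'
#' @param inputs An `spt_model_inputs` object.
#' @param n_patients Cohort size per arm (>= 1).
#' @param seed Integer seed.
#' @param paired Share the sensitization draw between arms (default `FALSE`).
#' @param keep_patients Attach the per-patient records (`patient_id`, `arm`,
#'   `sensitized`, `test_positive`, `classification`, `accrued_cost`).
#' @return An object of class `cohort_result`: `n_patients`, `arms` (a
#'   data.frame with one row per arm: `mean_cost`, `se`, and TP/FN/FP/TN
#'   counts), and optionally `patients`.
#' @examples
#' simulate_cohort(spt_default_inputs(), n_patients = 1000, seed = 7)
#' @export
simulate_cohort <- function(inputs, n_patients, seed = 1L, paired = FALSE,
                            keep_patients = FALSE) {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  if (!is.numeric(n_patients) || n_patients < 1L) {
    stop("invalid argument: 'n_patients' must be >= 1")
  }
  n_patients <- as.integer(n_patients)
  v <- .values_from_inputs(inputs)
  set.seed(seed)
  shared_sens <- if (paired) stats::runif(n_patients) < v$prev else NULL

  sim_arm <- function(arm) {
    if (arm == "manual") {
      sens <- v$sens_m; spec <- v$spec_m; arm_cost <- v$cost_m
    } else {
      sens <- v$sens_d; spec <- v$spec_d; arm_cost <- v$cost_d
    }
    retest <- if (v$retest_strategy == "manual_retest") v$cost_m else arm_cost
    sensitized <- if (paired) shared_sens else stats::runif(n_patients) < v$prev
    u <- stats::runif(n_patients)
    positive <- ifelse(sensitized, u < sens, u < 1 - spec)
    classification <- ifelse(sensitized,
                             ifelse(positive, "TP", "FN"),
                             ifelse(positive, "FP", "TN"))
    cost <- arm_cost + (classification == "FN") * (v$further - 1) * retest
    counts <- vapply(c("TP", "FN", "FP", "TN"),
                     function(k) sum(classification == k), integer(1))
    list(summary = data.frame(
           arm = arm, mean_cost = mean(cost),
           se = stats::sd(cost) / sqrt(n_patients),
           TP = counts[["TP"]], FN = counts[["FN"]],
           FP = counts[["FP"]], TN = counts[["TN"]],
           stringsAsFactors = FALSE),
         patients = if (keep_patients) data.frame(
           patient_id = seq_len(n_patients), arm = arm,
           sensitized = sensitized, test_positive = positive,
           classification = classification, accrued_cost = cost,
           stringsAsFactors = FALSE) else NULL)
  }

  manual <- sim_arm("manual")
  dspt <- sim_arm("dspt")
  structure(
    list(n_patients = n_patients,
         arms = rbind(manual$summary, dspt$summary),
         patients = if (keep_patients) rbind(manual$patients, dspt$patients)
                    else NULL,
         seed = seed, paired = paired),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Microsimulated cohort: %d patients per arm (seed %d%s)\n",
              x$n_patients, x$seed, if (x$paired) ", paired" else ""))
  print(x$arms, row.names = FALSE)
  invisible(x)
}

#' Random valid model scenario
#'
#' Generates a complete, valid input set for property-based testing:
#' proportion parameters with binomial provenance (counts `1 <= r <= n - 1`
#' so the Beta specification is proper), positive right-skewed costs, and a
#' further-tests multiplier of at least 1. Sensitivity ranges are set to
#' +/-20% of each value (clamped to the unit interval for probabilities).
#'
#' @param seed Integer seed; the same seed always yields the same scenario.
#' @return An `spt_model_inputs` object.
#' @export
random_scenario <- function(seed) {
  set.seed(seed)
  rprop <- function(label) {
    n <- sample(50:10000, 1L)
    # target probability anywhere in (0.05, 0.95); resample the count into
    # the proper-Beta interior
    r <- stats::rbinom(1L, n, stats::runif(1, 0.05, 0.95))
    r <- min(max(r, 1L), n - 1L)
    p <- r / n
    proportion_parameter(label, r, n,
                         dsa_low = max(0, 0.8 * p), dsa_high = min(1, 1.2 * p))
  }
  rcost <- function(label, meanlog, sdlog) {
    m <- stats::rlnorm(1L, meanlog, sdlog)
    cost_parameter(label, m)
  }
  ft_mean <- 1 + stats::rgamma(1L, shape = 2, scale = 0.5)
  model_inputs(
    prevalence = rprop("prevalence"),
    manual_sensitivity = rprop("manual_sensitivity"),
    manual_specificity = rprop("manual_specificity"),
    dspt_sensitivity = rprop("dspt_sensitivity"),
    dspt_specificity = rprop("dspt_specificity"),
    manual_cost = rcost("manual_cost", log(35), 0.4),
    dspt_cost = rcost("dspt_cost", log(30), 0.4),
    further_tests = cost_parameter("further_tests", ft_mean),
    retest_strategy = sample(c("manual_retest", "same_arm_retest"), 1L)
  )
}

#' Check simulated classification counts against the tree's probabilities
#'
#' Chi-square goodness-of-fit of the observed 4-way TP/FN/FP/TN counts in
#' each arm against the pathway probabilities of the analytic tree. A cell
#' with zero pathway probability but a nonzero observed count is a hard
#' failure (the simulator produced an impossible outcome).
#'
#' @param cohort A `cohort_result` simulated under `inputs`.
#' @param inputs The `spt_model_inputs` the cohort was simulated under.
#' @param alpha Significance level (default 0.001, chosen to keep repeated
#'   property tests stable).
#' @return A data.frame with one row per arm: `statistic`, `df`, `p_value`,
#'   `pass`.
#' @export
classification_check <- function(cohort, inputs, alpha = 0.001) {
  stopifnot(inherits(cohort, "cohort_result"),
            inherits(inputs, "spt_model_inputs"))
  paths <- pathway_outcomes(inputs)
  rows <- lapply(c("manual", "dspt"), function(arm) {
    obs <- as.numeric(cohort$arms[cohort$arms$arm == arm,
                                  c("TP", "FN", "FP", "TN")])
    expd <- paths$probability[paths$strategy == arm][
      match(c("TP", "FN", "FP", "TN"),
            as.character(paths$classification[paths$strategy == arm]))]
    if (any(expd == 0 & obs > 0)) {
      stop(sprintf("arm '%s': observed count in a zero-probability pathway", arm))
    }
    keep <- expd > 0
    if (sum(keep) < 2L) {
      # degenerate model: a single possible pathway; counts match by
      # construction, statistic 0
      return(data.frame(arm = arm, statistic = 0, df = 0L, p_value = 1,
                        pass = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::chisq.test(obs[keep], p = expd[keep] / sum(expd[keep]))
    data.frame(arm = arm, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = ct$p.value,
               pass = ct$p.value >= alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export per-patient microsimulation records
#'
#' @param cohort A `cohort_result` simulated with `keep_patients = TRUE`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
cohort_export <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_result"))
  if (is.null(cohort$patients)) {
    stop("cohort carries no per-patient records; rerun with keep_patients = TRUE")
  }
  utils::write.csv(cohort$patients, path, row.names = FALSE)
  invisible(path)
}
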