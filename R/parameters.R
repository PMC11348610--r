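#' Beta distribution specification from a positive count and sample size
#'
#' A probability parameter observed as `count_r` positives out of `sample_n`
#' subjects is given the conjugate specification `Beta(count_r, sample_n -
#' count_r)`, whose mean equals the point estimate `count_r / sample_n`.
#'
#' @param count_r Number of positives (non-negative integer).
#' @param sample_n Sample size (positive integer, `>= count_r`).
#'
#' @return A list with elements `alpha`, `beta` and `mean`.
#' @examples
#' beta_from_counts(1061, 8357) # prevalence of grass-pollen sensitization
#' @export
beta_from_counts <- function(count_r, sample_n) {
  if (length(count_r) != 1L || length(sample_n) != 1L ||
      !is.finite(count_r) || !is.finite(sample_n)) {
    stop("invalid counts: 'count_r' and 'sample_n' must be single finite numbers")
  }
  if (sample_n <= 0) {
    stop("invalid counts: 'sample_n' must be positive")
  }
  if (count_r < 0 || count_r > sample_n) {
    stop("invalid counts: need 0 <= count_r <= sample_n")
  }
  list(alpha = count_r, beta = sample_n - count_r, mean = count_r / sample_n)
}

#' Gamma distribution specification from a mean and standard deviation
#'
#' Method-of-moments parameterisation of the Gamma distribution used for
#' cost parameters: `shape = (mean/sd)^2`, `scale = sd^2/mean`, so that
#' `shape * scale` recovers the mean and `shape * scale^2` the variance.
#'
#' @param mean Positive mean (CHF per test, or dimensionless).
#' @param sd Positive standard deviation, same units as `mean`.
#'
#' @return A list with elements `shape` and `scale`.
#' @examples
#' gamma_from_mean_sd(2, 0.4) # shape 25, scale 0.08
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (length(mean) != 1L || length(sd) != 1L ||
      !is.finite(mean) || !is.finite(sd) || mean <= 0 || sd <= 0) {
    stop("invalid moments: 'mean' and 'sd' must be single positive numbers")
  }
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Default standard deviation for a cost parameter
#'
#' Cost uncertainty defaults to 20% of the mean, matching the +/-20% ranges
#' used for all cost inputs.
#'
#' @param mean Non-negative mean.
#' @return `0.20 * mean`.
#' @export
default_sd <- function(mean) {
  stopifnot(is.numeric(mean), all(mean >= 0))
  0.20 * mean
}

#' Annual straight-line depreciation of a capital item
#'
#' @param capital_value Purchase cost (CHF, non-negative).
#' @param useful_life Useful life in years (positive).
#' @return Annual depreciation in CHF/year.
#' @examples
#' straight_line_depreciation(10400, 10)
#' @export
straight_line_depreciation <- function(capital_value, useful_life) {
  if (!is.numeric(useful_life) || length(useful_life) != 1L || useful_life <= 0) {
    stop("invalid life: 'useful_life' must be a positive number of years")
  }
  stopifnot(is.numeric(capital_value), capital_value >= 0)
  capital_value / useful_life
}

#' Device cost inputs
#'
#' Bundle of the capital figures needed to spread an imaging device's annual
#' cost (straight-line depreciation plus service fees) over the yearly test
#' volume.
#'
#' @param capital_value Purchase cost, CHF.
#' @param useful_life Useful life, years.
#' @param annual_service Annual service fee, CHF/year.
#' @param tests_per_year Annual number of tests performed with the device.
#' @return An object of class `device_cost_inputs`.
#' @export
device_cost_inputs <- function(capital_value, useful_life, annual_service,
                               tests_per_year) {
  vals <- as.numeric(c(capital_value = capital_value, useful_life = useful_life,
                       annual_service = annual_service,
                       tests_per_year = tests_per_year))
  names(vals) <- c("capital_value", "useful_life", "annual_service",
                   "tests_per_year")
  if (!all(is.finite(vals)) || any(vals[c("useful_life", "tests_per_year")] <= 0) ||
      any(vals[c("capital_value", "annual_service")] < 0)) {
    stop("device cost inputs must be finite; life and volume strictly positive")
  }
  structure(as.list(vals), class = "device_cost_inputs")
}

#' Device cost per test
#'
#' Annual device cost (depreciation + service) divided by the annual test
#' volume.
#'
#' @param inputs A [device_cost_inputs()] object.
#' @return CHF per test.
#' @examples
#' device_cost_per_test(device_cost_inputs(10400, 10, 1040, 5200)) # 0.40
#' @export
device_cost_per_test <- function(inputs) {
  stopifnot(inherits(inputs, "device_cost_inputs"))
  if (inputs$tests_per_year <= 0) stop("invalid volume: 'tests_per_year' must be positive")
  annual <- straight_line_depreciation(inputs$capital_value, inputs$useful_life) +
    inputs$annual_service
  annual / inputs$tests_per_year
}

#' Staff cost per test
#'
#' Hands-on time multiplied by the per-minute staff rate, reported to two
#' decimals (the resolution at which per-test salary costs are carried).
#'
#' @param minutes Hands-on minutes per test (non-negative).
#' @param rate Staff rate, CHF per minute (non-negative).
#' @return CHF per test, rounded to 2 decimals.
#' @export
staff_cost_per_test <- function(minutes, rate) {
  if (!is.numeric(minutes) || !is.numeric(rate) || any(minutes < 0) || any(rate < 0)) {
    stop("invalid input: 'minutes' and 'rate' must be non-negative")
  }
  round(minutes * rate, 2)
}

#' Per-arm cost breakdown
#'
#' Decomposition of one test's cost into materials, staff time and (for the
#' camera-assisted arm) the amortised device cost. The manual arm has no
#' device component.
#'
#' @param materials Materials cost, CHF/test.
#' @param staff_time Hands-on staff time, minutes/test.
#' @param staff_rate Staff rate, CHF/minute.
#' @param device_per_test Amortised device cost, CHF/test (0 for manual).
#' @return An object of class `arm_cost_breakdown` with fields `materials`,
#'   `staff_time`, `staff_rate`, `staff_cost`, `device_per_test`, `total`.
#' @examples
#' arm_cost_breakdown(19.41, 5.5, 3.6291)        # manual arm, total 39.37
#' arm_cost_breakdown(19.41, 3, 3.6291, 0.40)    # digital arm, total 30.70
#' @export
arm_cost_breakdown <- function(materials, staff_time, staff_rate,
                               device_per_test = 0) {
  stopifnot(materials >= 0, staff_time >= 0, staff_rate >= 0, device_per_test >= 0)
  staff_cost <- staff_cost_per_test(staff_time, staff_rate)
  structure(
    list(materials = materials, staff_time = staff_time, staff_rate = staff_rate,
         staff_cost = staff_cost, device_per_test = device_per_test,
         total = materials + staff_cost + device_per_test),
    class = "arm_cost_breakdown"
  )
}

#' Total per-test cost of an arm
#'
#' @param breakdown An [arm_cost_breakdown()] object.
#' @return Materials + staff cost + device cost, CHF/test.
#' @export
arm_total <- function(breakdown) {
  stopifnot(inherits(breakdown, "arm_cost_breakdown"))
  breakdown$materials + breakdown$staff_cost + breakdown$device_per_test
}

#' Probability parameter from counts
#'
#' A probability model input defined by the number of positives `count_r` in a
#' sample of size `sample_n`, carrying a one-way sensitivity range and the
#' Beta specification used in probabilistic sensitivity analysis.
#'
#' @param label Parameter name.
#' @param count_r Positives.
#' @param sample_n Sample size.
#' @param dsa_low,dsa_high One-way sensitivity bounds on the probability
#'   scale. Default to the point estimate (a degenerate range).
#' @return An object of class `proportion_parameter`.
#' @export
proportion_parameter <- function(label, count_r, sample_n,
                                 dsa_low = NULL, dsa_high = NULL) {
  count_r <- as.numeric(count_r)
  sample_n <- as.numeric(sample_n)
  spec <- beta_from_counts(count_r, sample_n)
  dsa_low <- if (is.null(dsa_low)) spec$mean else as.numeric(dsa_low)
  dsa_high <- if (is.null(dsa_high)) spec$mean else as.numeric(dsa_high)
  if (dsa_low > dsa_high || dsa_low < 0 || dsa_high > 1) {
    stop(sprintf("'%s': DSA range must satisfy 0 <= low <= high <= 1", label))
  }
  structure(
    list(label = as.character(label), count_r = count_r, sample_n = sample_n,
         point_estimate = spec$mean, dsa_low = dsa_low, dsa_high = dsa_high,
         beta_alpha = spec$alpha, beta_beta = spec$beta),
    class = "proportion_parameter"
  )
}

#' Cost (or multiplier) parameter
#'
#' A positive-valued model input defined by its mean and standard deviation,
#' carrying a one-way sensitivity range and a method-of-moments Gamma
#' specification. When `sd` or the range are omitted they default to the 20%
#' rule: `sd = 0.2 * mean`, range `[0.8, 1.2] * mean`.
#'
#' @param label Parameter name.
#' @param mean Mean value (CHF per test, or dimensionless for the further-tests
#'   multiplier).
#' @param sd Standard deviation; defaults to [default_sd()].
#' @param dsa_low,dsa_high One-way sensitivity bounds; default +/-20%.
#' @return An object of class `cost_parameter`.
#' @export
cost_parameter <- function(label, mean, sd = NULL,
                           dsa_low = NULL, dsa_high = NULL) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0) {
    stop(sprintf("'%s': cost mean must be a single positive number", label))
  }
  mean <- as.numeric(mean)
  sd <- if (is.null(sd)) default_sd(mean) else as.numeric(sd)
  dsa_low <- if (is.null(dsa_low)) 0.8 * mean else as.numeric(dsa_low)
  dsa_high <- if (is.null(dsa_high)) 1.2 * mean else as.numeric(dsa_high)
  if (sd <= 0) stop(sprintf("'%s': sd must be positive", label))
  if (dsa_low > dsa_high || dsa_low < 0) {
    stop(sprintf("'%s': DSA range must satisfy 0 <= low <= high", label))
  }
  spec <- gamma_from_mean_sd(mean, sd)
  structure(
    list(label = as.character(label), mean = mean, sd = sd,
         dsa_low = dsa_low, dsa_high = dsa_high,
         gamma_shape = spec$shape, gamma_scale = spec$scale),
    class = "cost_parameter"
  )
}

#' Complete model input set
#'
#' Everything one evaluation of the two-arm SPT cost model needs: the
#' sensitization prevalence in the referred population, per-arm diagnostic
#' accuracy, per-arm per-test cost, the further-tests multiplier (total tests
#' accrued by a false-negative patient), and the retest costing strategy.
#'
#' `retest_strategy` controls which arm's cost prices the repeat test that a
#' false-negative patient returns for: `"manual_retest"` (default) prices it
#' at the manual per-test cost in both arms; `"same_arm_retest"` prices it at
#' the cost of the arm the patient is in.
#'
#' @param prevalence,manual_sensitivity,manual_specificity,dspt_sensitivity,dspt_specificity
#'   [proportion_parameter()] objects.
#' @param manual_cost,dspt_cost,further_tests [cost_parameter()] objects;
#'   `further_tests` is dimensionless with mean `>= 1`.
#' @param retest_strategy `"manual_retest"` or `"same_arm_retest"`.
#' @return An object of class `spt_model_inputs`.
#' @seealso [spt_default_inputs()] for the reference input set.
#' @export
model_inputs <- function(prevalence, manual_sensitivity, manual_specificity,
                         dspt_sensitivity, dspt_specificity,
                         manual_cost, dspt_cost, further_tests,
                         retest_strategy = c("manual_retest", "same_arm_retest")) {
  retest_strategy <- match.arg(retest_strategy)
  props <- list(prevalence = prevalence,
                manual_sensitivity = manual_sensitivity,
                manual_specificity = manual_specificity,
                dspt_sensitivity = dspt_sensitivity,
                dspt_specificity = dspt_specificity)
  for (nm in names(props)) {
    if (!inherits(props[[nm]], "proportion_parameter")) {
      stop(sprintf("'%s' must be a proportion_parameter", nm))
    }
  }
  costs <- list(manual_cost = manual_cost, dspt_cost = dspt_cost,
                further_tests = further_tests)
  for (nm in names(costs)) {
    if (!inherits(costs[[nm]], "cost_parameter")) {
      stop(sprintf("'%s' must be a cost_parameter", nm))
    }
  }
  if (further_tests$mean < 1) {
    stop("'further_tests' mean must be >= 1 (total tests for a false-negative patient)")
  }
  structure(c(props, costs, list(retest_strategy = retest_strategy)),
            class = "spt_model_inputs")
}

#' Reference input set for the two-arm SPT model
#'
#' The default parameterisation of the model: grass-pollen sensitization
#' prevalence 1061/8357 in the referred adult population, manual-arm
#' sensitivity 1485/2289 and specificity 9366/9627 at the 3 mm wheal cut-off,
#' camera-assisted (DSPT) arm accuracy 2.5 percentage points lower
#' (1448/2289, 9132/9627), per-test costs of CHF 39.37 (manual) and CHF 30.70
#' (digital, including CHF 0.40/test device amortisation and service), and an
#' average of 2 total tests for a false-negative patient.
#'
#' @param retest_strategy Retest costing rule, see [model_inputs()].
#' @return An `spt_model_inputs` object.
#' @examples
#' inp <- spt_default_inputs()
#' inp$prevalence$point_estimate # 0.127
#' @export
spt_default_inputs <- function(retest_strategy = "manual_retest") {
  model_inputs(
    prevalence          = proportion_parameter("prevalence", 1061, 8357, 0.10, 0.20),
    manual_sensitivity  = proportion_parameter("manual_sensitivity", 1485, 2289, 0.64, 0.66),
    manual_specificity  = proportion_parameter("manual_specificity", 9366, 9627, 0.97, 0.98),
    dspt_sensitivity    = proportion_parameter("dspt_sensitivity", 1448, 2289, 0.62, 0.64),
    dspt_specificity    = proportion_parameter("dspt_specificity", 9132, 9627, 0.94, 0.96),
    manual_cost         = cost_parameter("manual_cost", 39.37, 7.87, 31.5, 47.2),
    dspt_cost           = cost_parameter("dspt_cost", 30.70, 6.14, 24.6, 36.9),
    further_tests       = cost_parameter("further_tests", 2, 0.4, 1.6, 2.4),
    retest_strategy     = retest_strategy
  )
}

#' The reference device cost inputs
#'
#' Capital value CHF 10,400, 10-year useful life, CHF 1,040/year service,
#' 5,200 tests/year -- yielding CHF 0.40 per test.
#'
#' @return A [device_cost_inputs()] object.
#' @export
spt_default_device <- function() {
  device_cost_inputs(capital_value = 10400, useful_life = 10,
                     annual_service = 1040, tests_per_year = 5200)
}

.proportion_names <- c("prevalence", "manual_sensitivity", "manual_specificity",
                       "dspt_sensitivity", "dspt_specificity")
.cost_names <- c("manual_cost", "dspt_cost", "further_tests")

#' Parameter table
#'
#' One row per model parameter with its point estimate, one-way sensitivity
#' range and probabilistic distribution specification.
#'
#' @param inputs An `spt_model_inputs` object.
#' @param source Optional character vector of source annotations, recycled.
#' @return A data.frame with columns `label`, `point_estimate`, `dsa_low`,
#'   `dsa_high`, `distribution`, `dist_param_1`, `dist_param_2`, `source`.
#' @export
parameter_table <- function(inputs, source = "") {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  rows <- lapply(c(.proportion_names, .cost_names), function(nm) {
    p <- inputs[[nm]]
    if (inherits(p, "proportion_parameter")) {
      data.frame(label = p$label, point_estimate = p$point_estimate,
                 dsa_low = p$dsa_low, dsa_high = p$dsa_high,
                 distribution = "beta", dist_param_1 = p$beta_alpha,
                 dist_param_2 = p$beta_beta, stringsAsFactors = FALSE)
    } else {
      data.frame(label = p$label, point_estimate = p$mean,
                 dsa_low = p$dsa_low, dsa_high = p$dsa_high,
                 distribution = "gamma", dist_param_1 = p$gamma_shape,
                 dist_param_2 = p$gamma_scale, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$source <- rep_len(source, nrow(out))
  out
}

#' @export
print.spt_model_inputs <- function(x, ...) {
  cat("Two-arm SPT cost-consequence model inputs\n")
  cat(sprintf("  retest strategy: %s\n", x$retest_strategy))
  tab <- parameter_table(x)
  tab$point_estimate <- signif(tab$point_estimate, 6)
  print(tab[, c("label", "point_estimate", "dsa_low", "dsa_high", "distribution")],
        row.names = FALSE)
  invisible(x)
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("Incremental cost, digital vs manual SPT (CHF per test)\n")
  cat(sprintf("  E[cost | manual]  : %8.2f\n", x$ev_manual))
  cat(sprintf("  E[cost | digital] : %8.2f\n", x$ev_dspt))
  cat(sprintf("  incremental (digital - manual): %8.2f\n", x$incremental))
  cat(sprintf("  savings per test  : %8.2f\n", x$savings))
  invisible(x)
}
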