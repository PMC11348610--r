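# Column order is part of the contract: parameters are sampled column-wise
# in this order, so a given seed yields the same draw matrix in any run.
.psa_order <- c("prevalence", "manual_sensitivity", "manual_specificity",
                "dspt_sensitivity", "dspt_specificity",
                "manual_cost", "dspt_cost", "further_tests")

#' Sample parameter values for probabilistic sensitivity analysis
#'
#' Draws all model parameters independently from their assigned
#' distributions: Beta(`r`, `n - r`) for the five probabilities, Gamma (by
#' method of moments) for the two arm costs and the further-tests
#' multiplier. Parameters are sampled in a fixed order (prevalence, manual
#' sensitivity, manual specificity, digital sensitivity, digital
#' specificity, manual cost, digital cost, further tests) so a seeded run is
#' reproducible. Uses the current RNG state; call `set.seed()` beforehand
#' for reproducibility.
#'
#' @param inputs An `spt_model_inputs` object.
#' @param n Number of draws.
#' @return A data.frame with `n` rows and one column per parameter. A
#'   warning is emitted if any further-tests draw falls below 1 (the Gamma
#'   spec makes this vanishingly rare; draws are not truncated).
#' @export
draw_inputs <- function(inputs, n = 1L) {
  stopifnot(inherits(inputs, "spt_model_inputs"), n >= 1L)
  cols <- lapply(.psa_order, function(nm) {
    p <- inputs[[nm]]
    if (inherits(p, "proportion_parameter")) {
      if (p$beta_alpha <= 0 || p$beta_beta <= 0) {
        stop(sprintf("'%s': Beta(%g, %g) is improper; PSA needs r >= 1 and r <= n - 1",
                     nm, p$beta_alpha, p$beta_beta))
      }
      stats::rbeta(n, p$beta_alpha, p$beta_beta)
    } else {
      stats::rgamma(n, shape = p$gamma_shape, scale = p$gamma_scale)
    }
  })
  names(cols) <- .psa_order
  out <- as.data.frame(cols)
  if (any(out$further_tests < 1)) {
    warning(sprintf("%d further-tests draw(s) below 1 (FN patients sampled as accruing fewer total tests than one)",
                    sum(out$further_tests < 1)))
  }
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples `n_simulations` full parameter sets with [draw_inputs()] and
#' re-evaluates the deterministic decision tree on each draw (a plug-in
#' evaluation: distributions sit around a deterministic engine). Summaries
#' are computed on the vector of per-draw incremental costs.
#'
#' @param inputs An `spt_model_inputs` object.
#' @param n_simulations Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed for the single generator driving all draws.
#' @return An object of class `psa_result`: `draws` (data.frame of sampled
#'   values plus the per-draw `incremental`), `incremental` (numeric
#'   vector), `mean`, `sd` (`NA` for a single draw), `percentile_2_5`,
#'   `percentile_97_5`, `prob_cost_saving` (fraction of draws with
#'   incremental < 0), `seed`, `n_simulations`.
#' @examples
#' res <- run_psa(spt_default_inputs(), n_simulations = 200, seed = 1)
#' res$prob_cost_saving
#' @export
run_psa <- function(inputs, n_simulations = 10000L, seed = 1L) {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  if (!is.numeric(n_simulations) || n_simulations < 1L) {
    stop("invalid argument: 'n_simulations' must be >= 1")
  }
  n_simulations <- as.integer(n_simulations)
  set.seed(seed)
  draws <- draw_inputs(inputs, n_simulations)
  strategy <- inputs$retest_strategy
  incremental <- vapply(seq_len(n_simulations), function(i) {
    .incremental_values(prev = draws$prevalence[i],
                        sens_m = draws$manual_sensitivity[i],
                        spec_m = draws$manual_specificity[i],
                        sens_d = draws$dspt_sensitivity[i],
                        spec_d = draws$dspt_specificity[i],
                        cost_m = draws$manual_cost[i],
                        cost_d = draws$dspt_cost[i],
                        further = draws$further_tests[i],
                        retest_strategy = strategy)$incremental
  }, numeric(1))
  draws$incremental <- incremental
  structure(
    list(draws = draws, incremental = incremental,
         mean = mean(incremental),
         sd = if (n_simulations > 1L) stats::sd(incremental) else NA_real_,
         percentile_2_5 = unname(stats::quantile(incremental, 0.025)),
         percentile_97_5 = unname(stats::quantile(incremental, 0.975)),
         prob_cost_saving = mean(incremental < 0),
         seed = seed, n_simulations = n_simulations),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo draws (seed %d)\n", x$n_simulations, x$seed))
  cat(sprintf("  incremental (digital - manual), CHF/test: mean %.2f, sd %s\n",
              x$mean, ifelse(is.na(x$sd), "NA", sprintf("%.2f", x$sd))))
  cat(sprintf("  95%% interval: [%.2f, %.2f]\n",
              x$percentile_2_5, x$percentile_97_5))
  cat(sprintf("  P(digital arm cost-saving) = %.4f\n", x$prob_cost_saving))
  invisible(x)
}

#' Running-mean convergence of a Monte Carlo sequence
#'
#' Tracks the running mean at the end of consecutive blocks of draws and
#' returns the first draw index at which it changes by less than a relative
#' tolerance from one block end to the previous (the end of block one is
#' compared against the first draw). `NA` if the sequence never stabilises.
#'
#' @param draws Numeric vector of per-draw results.
#' @param block Block size in draws (default 500).
#' @param tolerance Relative tolerance on the running-mean change (default
#'   0.01, i.e. 1%).
#' @return The stabilisation draw index (a multiple of `block`), or
#'   `NA_integer_`.
#' @export
convergence_trace <- function(draws, block = 500L, tolerance = 0.01) {
  if (length(draws) == 0L) stop("invalid argument: 'draws' is empty")
  stopifnot(block >= 1L, tolerance > 0)
  n_blocks <- length(draws) %/% block
  if (n_blocks < 1L) return(NA_integer_)
  prev_mean <- draws[1]
  csum <- cumsum(draws)
  for (b in seq_len(n_blocks)) {
    idx <- b * block
    m <- csum[idx] / idx
    if (idx > 1L) {  # a one-draw prefix gives no comparison window
      denom <- max(abs(prev_mean), .Machine$double.eps)
      if (abs(m - prev_mean) / denom < tolerance) return(as.integer(idx))
    }
    prev_mean <- m
  }
  NA_integer_
}

#' Shape summary of the simulated incremental-cost distribution
#'
#' Moment-based sample skewness `m3 / m2^(3/2)` and excess kurtosis
#' `m4 / m2^2 - 3`, where `m_k` are central sample moments. Used to check
#' that the Monte Carlo output is close to normal in shape.
#'
#' @param draws Numeric vector with at least 3 values.
#' @return A list with `skewness` and `excess_kurtosis`.
#' @export
distribution_summary <- function(draws) {
  if (length(draws) < 3L) stop("invalid argument: need at least 3 draws")
  x <- draws - mean(draws)
  m2 <- mean(x^2)
  list(skewness = mean(x^3) / m2^1.5,
       excess_kurtosis = mean(x^4) / m2^2 - 3)
}

#' Histogram of PSA incremental-cost draws
#'
#' Density-normalised histogram (it integrates to 1), with reference lines
#' at zero and at the PSA mean. Both sign conventions are reported in the
#' subtitle: digital minus manual (plotted) and manual minus digital.
#'
#' @param result A `psa_result`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_psa_histogram <- function(result, bins = 50L) {
  stopifnot(inherits(result, "psa_result"))
  df <- data.frame(incremental = result$incremental)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$incremental)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "#4477AA", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = result$mean, colour = "#CC3311") +
    ggplot2::labs(
      x = "Incremental cost, digital - manual (CHF per test)", y = "Density",
      title = "Monte Carlo distribution of the incremental cost",
      subtitle = sprintf("mean %.2f CHF/test (equivalently %.2f saved per test); P(cost-saving) = %.3f",
                         result$mean, -result$mean, result$prob_cost_saving)) +
    ggplot2::theme_minimal()
}

#' Running-mean convergence plot
#'
#' @param result A `psa_result`.
#' @return A ggplot object showing the running mean of the incremental cost
#'   against the draw index.
#' @export
plot_psa_convergence <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  n <- result$n_simulations
  df <- data.frame(draw = seq_len(n),
                   running_mean = cumsum(result$incremental) / seq_len(n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$running_mean)) +
    ggplot2::geom_line(colour = "#4477AA") +
    ggplot2::geom_hline(yintercept = result$mean, linetype = "dashed") +
    ggplot2::labs(x = "Monte Carlo draw", y = "Running mean incremental cost (CHF)",
                  title = "Convergence of the Monte Carlo simulation") +
    ggplot2::theme_minimal()
}

#' Export PSA draws and summary
#'
#' `psa_export_draws()` writes one CSV row per draw (all sampled parameter
#' values plus the incremental cost, digital minus manual);
#' `psa_export_summary()` writes a JSON summary (mean, sd, percentiles,
#' probability of cost saving, seed, n).
#'
#' @param result A `psa_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @name psa-export
NULL

#' @rdname psa-export
#' @export
psa_export_draws <- function(result, path) {
  stopifnot(inherits(result, "psa_result"))
  utils::write.csv(result$draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname psa-export
#' @export
psa_export_summary <- function(result, path) {
  stopifnot(inherits(result, "psa_result"))
  summary <- list(
    mean_incremental_chf = result$mean,
    sd_chf = result$sd,
    percentile_2_5_chf = result$percentile_2_5,
    percentile_97_5_chf = result$percentile_97_5,
    prob_cost_saving = result$prob_cost_saving,
    mean_savings_chf = -result$mean,
    sign_convention = "incremental = E[cost|digital] - E[cost|manual]; negative favours digital",
    seed = result$seed,
    n_simulations = result$n_simulations
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
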