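# Map from parameter label to the slot it occupies in the plain-value
# evaluation; each parameter enters the model in exactly one place, so a
# one-way excursion replaces exactly one value (the manual-cost excursion
# also reprices the FN retest under manual_retest, because the retest is
# costed from the same parameter).
.param_slots <- c(prevalence = "prev",
                  manual_sensitivity = "sens_m",
                  manual_specificity = "spec_m",
                  dspt_sensitivity = "sens_d",
                  dspt_specificity = "spec_d",
                  manual_cost = "cost_m",
                  dspt_cost = "cost_d",
                  further_tests = "further")

.incremental_at <- function(values, slot, x) {
  values[[slot]] <- x
  do.call(.incremental_values, values)$incremental
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the incremental cost with each parameter set to its lower
#' then upper one-way bound, all other parameters held at their point
#' estimates. Bounds are evaluated exactly (no interior sampling).
#'
#' @param inputs An `spt_model_inputs` object; every parameter must carry a
#'   sensitivity range.
#' @return A data.frame of class `tornado_entries` with one row per
#'   parameter: `parameter`, `dsa_low`, `dsa_high`, `incremental_at_low`,
#'   `incremental_at_high`, `bar_width` (absolute difference) and
#'   `base_incremental` (identical across rows). All monetary columns are
#'   CHF per test with the digital-minus-manual sign convention.
#' @export
one_way_dsa <- function(inputs) {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  values <- .values_from_inputs(inputs)
  base <- do.call(.incremental_values, values)$incremental
  rows <- lapply(names(.param_slots), function(nm) {
    p <- inputs[[nm]]
    bounds <- c(p$dsa_low, p$dsa_high)
    if (any(!is.finite(bounds))) {
      stop(sprintf("parameter '%s' carries no usable sensitivity range", nm))
    }
    slot <- .param_slots[[nm]]
    inc_low <- .incremental_at(values, slot, bounds[1])
    inc_high <- .incremental_at(values, slot, bounds[2])
    data.frame(parameter = nm, dsa_low = bounds[1], dsa_high = bounds[2],
               incremental_at_low = inc_low, incremental_at_high = inc_high,
               bar_width = abs(inc_high - inc_low), base_incremental = base,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("tornado_entries", "data.frame"))
}

#' Rank tornado entries by influence
#'
#' Sorts entries by bar width (absolute swing of the incremental cost over
#' the parameter's range) in decreasing order; ties are broken by parameter
#' label, alphabetically.
#'
#' @param entries A `tornado_entries` data.frame from [one_way_dsa()].
#' @return The same data.frame, reordered; empty input yields an empty
#'   result.
#' @export
rank_by_width <- function(entries) {
  stopifnot(is.data.frame(entries))
  if (nrow(entries) == 0L) return(entries)
  ord <- order(-entries$bar_width, entries$parameter)
  out <- entries[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tornado diagram
#'
#' Horizontal-bar plot of the one-way sensitivity analysis: one bar per
#' parameter spanning the incremental cost at its low and high bound, widest
#' bars on top, with a vertical reference line at the base-case incremental.
#'
#' @param entries A `tornado_entries` data.frame.
#' @return A ggplot object.
#' @export
plot_tornado <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1L)
  ranked <- rank_by_width(entries)
  ranked$parameter <- factor(ranked$parameter, levels = rev(ranked$parameter))
  long <- rbind(
    data.frame(parameter = ranked$parameter, bound = "low",
               incremental = ranked$incremental_at_low,
               base = ranked$base_incremental),
    data.frame(parameter = ranked$parameter, bound = "high",
               incremental = ranked$incremental_at_high,
               base = ranked$base_incremental)
  )
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$base, xend = .data$incremental,
                   y = .data$parameter, yend = .data$parameter,
                   colour = .data$bound),
      linewidth = 6) +
    ggplot2::geom_vline(xintercept = long$base[1], linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(low = "#4477AA", high = "#CC3311")) +
    ggplot2::labs(x = "Incremental cost, digital - manual (CHF per test)",
                  y = NULL, colour = "Parameter bound",
                  title = "One-way sensitivity of the incremental cost") +
    ggplot2::theme_minimal()
}

#' Export the tornado analysis
#'
#' Writes `<basename>.csv` (columns `parameter`, `low`, `high`,
#' `incremental_at_low`, `incremental_at_high`, `width`; ranked by width)
#' and `<basename>.png` (the bar chart) into `dir`.
#'
#' @param entries A `tornado_entries` data.frame.
#' @param dir Output directory (created if missing).
#' @param basename File stem, default `"tornado"`.
#' @return Character vector of the files written, invisibly.
#' @export
tornado_export <- function(entries, dir, basename = "tornado") {
  stopifnot(is.data.frame(entries))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, paste0(basename, ".csv"))
  ranked <- rank_by_width(entries)
  out <- data.frame(parameter = character(0), low = numeric(0), high = numeric(0),
                    incremental_at_low = numeric(0),
                    incremental_at_high = numeric(0), width = numeric(0))
  if (nrow(ranked) > 0L) {
    out <- data.frame(parameter = ranked$parameter, low = ranked$dsa_low,
                      high = ranked$dsa_high,
                      incremental_at_low = ranked$incremental_at_low,
                      incremental_at_high = ranked$incremental_at_high,
                      width = ranked$bar_width)
  }
  utils::write.csv(out, csv_path, row.names = FALSE)
  files <- csv_path
  if (nrow(ranked) > 0L) {
    png_path <- file.path(dir, paste0(basename, ".png"))
    ggplot2::ggsave(png_path, plot_tornado(entries),
                    width = 7, height = 4.5, dpi = 150)
    files <- c(files, png_path)
  }
  invisible(files)
}
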