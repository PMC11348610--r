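.required_settings <- function(settings) {
  defaults <- list(retest_strategy = "manual_retest",
                   n_simulations = 10000L, seed = 1L,
                   microsim_patients = 100000L)
  for (nm in names(defaults)) {
    if (is.null(settings[[nm]])) settings[[nm]] <- defaults[[nm]]
  }
  if (settings$n_simulations < 1L) stop("settings: 'n_simulations' must be >= 1")
  if (!settings$retest_strategy %in% c("manual_retest", "same_arm_retest")) {
    stop("settings: 'retest_strategy' must be 'manual_retest' or 'same_arm_retest'")
  }
  settings
}

.parse_block <- function(doc, block) {
  entries <- doc[[block]]
  if (is.null(entries)) stop(sprintf("model specification: missing '%s' block", block))
  # tolerate both a list of records and a data.frame-ish structure
  if (is.data.frame(entries)) entries <- split(entries, seq_len(nrow(entries)))
  # YAML 1.1 parses a bare key `n` as boolean FALSE; map it back
  entries <- lapply(entries, function(e) {
    names(e)[names(e) %in% c("FALSE", "false")] <- "n"
    e
  })
  stats::setNames(entries, vapply(entries, function(e) as.character(e$label),
                                  character(1)))
}

#' Load a model specification file
#'
#' Reads a YAML or JSON model specification with blocks `proportions`
#' (label, r, n, dsa_low, dsa_high), `costs` (label, mean, and optionally
#' sd / dsa_low / dsa_high, which default to the 20% rule), an optional
#' `device` block (capital, life_years, annual_service, tests_per_year) and
#' an optional `settings` block (retest_strategy, n_simulations, seed,
#' microsim_patients). The five proportion labels and three cost labels of
#' [model_inputs()] must each appear exactly once.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `spt_run_config`: `inputs` (an
#'   `spt_model_inputs`), `device` (a [device_cost_inputs()] or `NULL`) and
#'   `settings` (a list with defaults applied).
#' @examples
#' cfg <- load_config(system.file("extdata", "spt_model.yaml", package = "sptcca"))
#' cfg$inputs$prevalence$point_estimate
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("model specification not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  props <- .parse_block(doc, "proportions")
  costs <- .parse_block(doc, "costs")
  missing_p <- setdiff(.proportion_names, names(props))
  if (length(missing_p)) {
    stop("model specification: 'proportions' block is missing ",
         paste(missing_p, collapse = ", "))
  }
  missing_c <- setdiff(.cost_names, names(costs))
  if (length(missing_c)) {
    stop("model specification: 'costs' block is missing ",
         paste(missing_c, collapse = ", "))
  }
  settings <- .required_settings(doc$settings)
  prop_params <- lapply(.proportion_names, function(nm) {
    e <- props[[nm]]
    if (is.null(e$r) || is.null(e$n)) {
      stop(sprintf("model specification: proportion '%s' needs fields 'r' and 'n'", nm))
    }
    proportion_parameter(nm, e$r, e$n, e$dsa_low, e$dsa_high)
  })
  names(prop_params) <- .proportion_names
  cost_params <- lapply(.cost_names, function(nm) {
    e <- costs[[nm]]
    if (is.null(e$mean)) {
      stop(sprintf("model specification: cost '%s' needs field 'mean'", nm))
    }
    cost_parameter(nm, e$mean, e$sd, e$dsa_low, e$dsa_high)
  })
  names(cost_params) <- .cost_names
  inputs <- do.call(model_inputs,
                    c(prop_params, cost_params,
                      list(retest_strategy = settings$retest_strategy)))
  device <- NULL
  if (!is.null(doc$device)) {
    d <- doc$device
    device <- device_cost_inputs(d$capital, d$life_years, d$annual_service,
                                 d$tests_per_year)
  }
  structure(list(inputs = inputs, device = device, settings = settings),
            class = "spt_run_config")
}

#' Write a model specification file
#'
#' Serialises an input set (and optional device block and settings) to the
#' schema read by [load_config()]; a written file re-loads to an identical
#' input set.
#'
#' @param inputs An `spt_model_inputs` object.
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @param device Optional [device_cost_inputs()].
#' @param settings Optional settings list (retest_strategy is taken from
#'   `inputs` when absent).
#' @return The path, invisibly.
#' @export
write_model_spec <- function(inputs, path, device = NULL, settings = list()) {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  if (is.null(settings$retest_strategy)) {
    settings$retest_strategy <- inputs$retest_strategy
  }
  doc <- list(
    proportions = lapply(.proportion_names, function(nm) {
      p <- inputs[[nm]]
      list(label = p$label, r = p$count_r, n = p$sample_n,
           dsa_low = p$dsa_low, dsa_high = p$dsa_high)
    }),
    costs = lapply(.cost_names, function(nm) {
      p <- inputs[[nm]]
      list(label = p$label, mean = p$mean, sd = p$sd,
           dsa_low = p$dsa_low, dsa_high = p$dsa_high)
    }),
    settings = settings
  )
  if (!is.null(device)) {
    doc$device <- list(capital = device$capital_value,
                       life_years = device$useful_life,
                       annual_service = device$annual_service,
                       tests_per_year = device$tests_per_year)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

.log_stage <- function(...) message(sprintf("[sptcca] %s", sprintf(...)))

#' Run the full analysis bundle
#'
#' Executes every stage of the analysis on one configuration and writes the
#' result bundle into `out_dir`: the parameter table
#' (`parameter_table.csv`), the base case (`basecase.csv`), the one-way
#' sensitivity analysis (`tornado.csv`, `tornado.png`), the probabilistic
#' sensitivity analysis (`psa_draws.csv`, `psa_summary.json`,
#' `psa_histogram.png`, `psa_convergence.png`), the microsimulation
#' validation (`microsim_check.json`) and a run manifest
#' (`manifest.json`) recording every input value, seed and stage timing
#' actually used. All monetary columns are CHF per test; incremental values
#' use the digital-minus-manual sign convention.
#'
#' @param config An `spt_run_config` from [load_config()], or an
#'   `spt_model_inputs` (default settings are then applied).
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list with the key results (`basecase`, `tornado`,
#'   `psa`, `microsim`) and the manifest.
#' @export
run_all <- function(config, out_dir) {
  if (inherits(config, "spt_model_inputs")) {
    config <- structure(list(inputs = config, device = NULL,
                             settings = .required_settings(NULL)),
                        class = "spt_run_config")
  }
  stopifnot(inherits(config, "spt_run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inputs <- config$inputs
  settings <- config$settings
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    .log_stage("stage '%s' done in %.2fs", stage, timings[[stage]])
    value
  }

  .log_stage("seed %d, %d PSA draws, retest strategy '%s'",
             settings$seed, settings$n_simulations, settings$retest_strategy)
  clock("parameters", {
    utils::write.csv(parameter_table(inputs),
                     file.path(out_dir, "parameter_table.csv"),
                     row.names = FALSE)
  })
  basecase <- clock("basecase", {
    res <- expected_incremental(inputs)
    basecase_export(res, file.path(out_dir, "basecase.csv"))
    res
  })
  tornado <- clock("dsa", {
    entries <- one_way_dsa(inputs)
    tornado_export(entries, out_dir)
    entries
  })
  psa <- clock("psa", {
    res <- run_psa(inputs, n_simulations = settings$n_simulations,
                   seed = settings$seed)
    psa_export_draws(res, file.path(out_dir, "psa_draws.csv"))
    psa_export_summary(res, file.path(out_dir, "psa_summary.json"))
    ggplot2::ggsave(file.path(out_dir, "psa_histogram.png"),
                    plot_psa_histogram(res), width = 7, height = 4.5, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "psa_convergence.png"),
                    plot_psa_convergence(res), width = 7, height = 4.5, dpi = 150)
    res
  })
  microsim <- clock("microsim", {
    cohort <- simulate_cohort(inputs, n_patients = settings$microsim_patients,
                              seed = settings$seed)
    check <- classification_check(cohort, inputs)
    ev <- c(manual = basecase$ev_manual, dspt = basecase$ev_dspt)
    agreement <- lapply(c("manual", "dspt"), function(arm) {
      row <- cohort$arms[cohort$arms$arm == arm, ]
      list(arm = arm, microsim_mean_chf = row$mean_cost,
           rollback_ev_chf = unname(ev[[arm]]),
           abs_diff_in_se = if (row$se > 0)
             abs(row$mean_cost - ev[[arm]]) / row$se else 0)
    })
    jsonlite::write_json(
      list(n_patients = cohort$n_patients, seed = settings$seed,
           classification_check = check, rollback_agreement = agreement),
      file.path(out_dir, "microsim_check.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    list(cohort = cohort, check = check)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("sptcca")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = settings$seed,
    settings = settings,
    inputs = parameter_table(inputs),
    retest_strategy = inputs$retest_strategy,
    stage_timings_s = timings,
    sign_convention = "incremental = E[cost|digital] - E[cost|manual]; CHF per test"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  .log_stage("bundle written to %s", normalizePath(out_dir))
  invisible(list(basecase = basecase, tornado = tornado, psa = psa,
                 microsim = microsim, manifest = manifest))
}
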