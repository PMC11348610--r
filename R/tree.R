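#' Decision-tree node constructors
#'
#' Trees are nested lists of three node kinds: a single decision node at the
#' root (one child per strategy), chance nodes whose branches carry
#' probabilities summing to one, and terminal nodes carrying a cost payoff.
#'
#' @param label Node label.
#' @param strategies Named list of child nodes, one per strategy.
#' @return A node (list with class `tree_node`).
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
decision_node <- function(label, strategies) {
  stopifnot(is.list(strategies), length(strategies) >= 1L,
            !is.null(names(strategies)))
  structure(list(kind = "decision", label = label, children = strategies),
            class = "tree_node")
}

#' @rdname tree-nodes
#' @param branches List of `list(prob = , node = )` pairs.
#' @export
chance_node <- function(label, branches) {
  stopifnot(is.list(branches), length(branches) >= 1L)
  structure(list(kind = "chance", label = label, children = branches),
            class = "tree_node")
}

#' @rdname tree-nodes
#' @param payoff Terminal cost payoff in CHF (finite, non-negative).
#' @export
terminal_node <- function(label, payoff) {
  structure(list(kind = "terminal", label = label, payoff = payoff),
            class = "tree_node")
}

#' Decision tree container
#'
#' @param root A decision node.
#' @return An object of class `decision_tree` with fields `root` and
#'   `strategy_labels`.
#' @export
decision_tree <- function(root) {
  stopifnot(inherits(root, "tree_node"), identical(root$kind, "decision"))
  structure(list(root = root, strategy_labels = names(root$children)),
            class = "decision_tree")
}

#' Validate a decision tree
#'
#' Checks structural soundness: branch probabilities of every chance node lie
#' in \[0, 1\] and sum to 1 within `1e-9`; terminal payoffs are finite and
#' non-negative; the decision node occurs only at the root; every path ends
#' at a terminal.
#'
#' @param tree A [decision_tree()].
#' @return A list with `valid` (logical) and `violations` (character vector).
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  violations <- character()
  walk <- function(node, at_root) {
    if (node$kind == "decision") {
      if (!at_root) {
        violations <<- c(violations,
                         sprintf("decision node '%s' below the root", node$label))
      }
      for (child in node$children) walk(child, FALSE)
    } else if (node$kind == "chance") {
      probs <- vapply(node$children, function(b) b$prob, numeric(1))
      if (any(probs < 0 | probs > 1)) {
        violations <<- c(violations,
                         sprintf("chance node '%s': branch probability outside [0, 1]",
                                 node$label))
      }
      if (abs(sum(probs) - 1) > 1e-9) {
        violations <<- c(violations,
                         sprintf("chance node '%s': branch probabilities sum to %.12f",
                                 node$label, sum(probs)))
      }
      for (b in node$children) walk(b$node, FALSE)
    } else if (node$kind == "terminal") {
      if (!is.null(node$children)) {
        violations <<- c(violations,
                         sprintf("terminal '%s' has children", node$label))
      }
      if (!is.finite(node$payoff) || node$payoff < 0) {
        violations <<- c(violations,
                         sprintf("terminal '%s': payoff must be finite and non-negative",
                                 node$label))
      }
    } else {
      violations <<- c(violations, sprintf("unknown node kind '%s'", node$kind))
    }
  }
  walk(tree$root, TRUE)
  list(valid = length(violations) == 0L, violations = violations)
}

# Plain-value core used by both the user-facing constructor and the PSA loop:
# builds one strategy's chance subtree from scalar probabilities and costs.
.arm_subtree <- function(arm, prev, sens, spec, arm_cost, retest_cost, further) {
  fn_payoff <- arm_cost + (further - 1) * retest_cost
  chance_node(
    paste0(arm, ": sensitization"),
    list(
      list(prob = prev, node = chance_node(
        paste0(arm, ": test | sensitized"),
        list(
          list(prob = sens,     node = terminal_node(paste0(arm, ": TP"), arm_cost)),
          list(prob = 1 - sens, node = terminal_node(paste0(arm, ": FN"), fn_payoff))
        ))),
      list(prob = 1 - prev, node = chance_node(
        paste0(arm, ": test | not sensitized"),
        list(
          list(prob = 1 - spec, node = terminal_node(paste0(arm, ": FP"), arm_cost)),
          list(prob = spec,     node = terminal_node(paste0(arm, ": TN"), arm_cost))
        )))
    ))
}

.build_tree_values <- function(prev, sens_m, spec_m, sens_d, spec_d,
                               cost_m, cost_d, further, retest_strategy) {
  retest_m <- cost_m
  retest_d <- if (retest_strategy == "manual_retest") cost_m else cost_d
  decision_tree(decision_node("SPT technique", list(
    manual = .arm_subtree("manual", prev, sens_m, spec_m, cost_m, retest_m, further),
    dspt   = .arm_subtree("dspt",   prev, sens_d, spec_d, cost_d, retest_d, further)
  )))
}

.values_from_inputs <- function(inputs) {
  list(prev   = inputs$prevalence$point_estimate,
       sens_m = inputs$manual_sensitivity$point_estimate,
       spec_m = inputs$manual_specificity$point_estimate,
       sens_d = inputs$dspt_sensitivity$point_estimate,
       spec_d = inputs$dspt_specificity$point_estimate,
       cost_m = inputs$manual_cost$mean,
       cost_d = inputs$dspt_cost$mean,
       further = inputs$further_tests$mean,
       retest_strategy = inputs$retest_strategy)
}

#' Build the two-arm SPT decision tree
#'
#' Each arm is a chance subtree over true sensitization status (Bernoulli at
#' the prevalence) followed by the test outcome (sensitivity for sensitized
#' patients, specificity otherwise), giving four terminals per arm:
#' true positive, false negative, false positive, true negative. All
#' terminals cost one test in that arm; a false negative additionally accrues
#' `(further_tests - 1)` repeat tests, priced by the retest strategy (a false
#' positive carries no downstream hospital cost).
#'
#' @param inputs An `spt_model_inputs` object.
#' @return A validated [decision_tree()].
#' @export
build_spt_tree <- function(inputs) {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  v <- .values_from_inputs(inputs)
  tree <- do.call(.build_tree_values, v)
  report <- validate_tree(tree)
  if (!report$valid) {
    stop("constructed tree failed validation: ",
         paste(report$violations, collapse = "; "))
  }
  tree
}

.rollback_node <- function(node) {
  switch(node$kind,
         terminal = node$payoff,
         chance = sum(vapply(node$children,
                             function(b) b$prob * .rollback_node(b$node),
                             numeric(1))),
         stop("rollback reached a decision node below the root"))
}

#' Expected-value rollback
#'
#' Computes, for each strategy at the root, the probability-weighted sum of
#' terminal payoffs over all root-to-terminal pathways.
#'
#' @param tree A [decision_tree()]; it is re-validated before evaluation.
#' @return Named numeric vector of expected payoffs, one per strategy.
#' @export
rollback <- function(tree) {
  report <- validate_tree(tree)
  if (!report$valid) {
    stop("invalid tree: ", paste(report$violations, collapse = "; "))
  }
  vapply(tree$root$children, .rollback_node, numeric(1))
}

#' Pathway outcomes
#'
#' Enumerates the four mutually exclusive classification pathways per
#' strategy with their probabilities and terminal payoffs, by walking the
#' built tree.
#'
#' @param inputs An `spt_model_inputs` object.
#' @return A data.frame with columns `strategy`, `classification`
#'   (TP/FN/FP/TN), `probability`, `payoff`.
#' @export
pathway_outcomes <- function(inputs) {
  tree <- build_spt_tree(inputs)
  rows <- list()
  walk <- function(node, strategy, prob) {
    if (node$kind == "terminal") {
      cls <- sub(".*: ", "", node$label)
      rows[[length(rows) + 1L]] <<- data.frame(
        strategy = strategy, classification = cls,
        probability = prob, payoff = node$payoff, stringsAsFactors = FALSE)
    } else if (node$kind == "chance") {
      for (b in node$children) walk(b$node, strategy, prob * b$prob)
    }
  }
  for (s in tree$strategy_labels) walk(tree$root$children[[s]], s, 1)
  out <- do.call(rbind, rows)
  out$classification <- factor(out$classification, levels = c("TP", "FN", "FP", "TN"))
  out[order(out$strategy, out$classification), , drop = FALSE]
}

# Single deterministic evaluation on plain values; the engine behind both
# expected_incremental() and the per-draw PSA loop.
.incremental_values <- function(prev, sens_m, spec_m, sens_d, spec_d,
                                cost_m, cost_d, further, retest_strategy) {
  tree <- .build_tree_values(prev, sens_m, spec_m, sens_d, spec_d,
                             cost_m, cost_d, further, retest_strategy)
  ev <- vapply(tree$root$children, .rollback_node, numeric(1))
  structure(
    list(ev_manual = ev[["manual"]], ev_dspt = ev[["dspt"]],
         incremental = ev[["dspt"]] - ev[["manual"]],
         savings = ev[["manual"]] - ev[["dspt"]]),
    class = "incremental_result"
  )
}

#' Expected incremental cost of the digital arm
#'
#' Builds the tree from the point estimates, validates it, rolls it back and
#' returns both arms' expected costs. The sign convention is
#' `incremental = E[cost | digital] - E[cost | manual]`, so negative values
#' favour the camera-assisted arm; `savings = -incremental` is reported
#' alongside.
#'
#' @param inputs An `spt_model_inputs` object.
#' @return An object of class `incremental_result` with fields `ev_manual`,
#'   `ev_dspt`, `incremental`, `savings` (all CHF per test).
#' @examples
#' expected_incremental(spt_default_inputs())
#' @export
expected_incremental <- function(inputs) {
  stopifnot(inherits(inputs, "spt_model_inputs"))
  tree <- build_spt_tree(inputs)  # validates
  ev <- rollback(tree)
  structure(
    list(ev_manual = ev[["manual"]], ev_dspt = ev[["dspt"]],
         incremental = ev[["dspt"]] - ev[["manual"]],
         savings = ev[["manual"]] - ev[["dspt"]]),
    class = "incremental_result"
  )
}

.node_to_list <- function(node) {
  if (node$kind == "terminal") {
    list(kind = "terminal", label = node$label, payoff = node$payoff)
  } else if (node$kind == "chance") {
    list(kind = "chance", label = node$label,
         children = lapply(node$children, function(b) {
           c(list(probability = b$prob), .node_to_list(b$node))
         }))
  } else {
    list(kind = "decision", label = node$label,
         children = lapply(node$children, .node_to_list))
  }
}

#' Export a decision tree as JSON
#'
#' Serialises the node structure (kind, label, branch probability, payoff,
#' children) for inspection or regression fixtures.
#'
#' @param tree A [decision_tree()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  json <- jsonlite::toJSON(.node_to_list(tree$root), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export the base-case report
#'
#' Writes a CSV with one row per strategy (expected cost, CHF per test) plus
#' an incremental row (digital minus manual).
#'
#' @param result An `incremental_result`.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
basecase_export <- function(result, path) {
  stopifnot(inherits(result, "incremental_result"))
  df <- data.frame(
    quantity = c("expected_cost_manual", "expected_cost_dspt",
                 "incremental_dspt_minus_manual", "savings_per_test"),
    chf_per_test = c(result$ev_manual, result$ev_dspt,
                     result$incremental, result$savings)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
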