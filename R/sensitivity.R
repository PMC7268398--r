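#' Select resource items for a sensitivity scenario
#'
#' A selector names the subset of a project's inventory that a one-way
#' sensitivity scenario perturbs: by activity step, by cost type, and/or by
#' a regular-expression pattern on item labels. Criteria combine with AND.
#' Selecting step `"library_prep_and_sequencing"` matches items in either
#' of the two underlying steps, whether or not the project reports them
#' merged.
#'
#' @param step Optional step label (or the combined
#'   `"library_prep_and_sequencing"` key).
#' @param cost_type Optional cost type label.
#' @param label_pattern Optional regular expression matched against item
#'   labels.
#' @return An object of class `item_selector`.
#' @export
#' @examples
#' item_selector(cost_type = "labour")
#' item_selector(step = "library_prep_and_sequencing")
item_selector <- function(step = NULL, cost_type = NULL,
                          label_pattern = NULL) {
  if (is.null(step) && is.null(cost_type) && is.null(label_pattern)) {
    stop(
      "empty selector: give at least one of step, cost_type, label_pattern",
      call. = FALSE
    )
  }
  if (!is.null(step)) step <- .normalize_step(step)
  if (!is.null(cost_type)) cost_type <- .normalize_cost_type(cost_type)
  structure(
    list(step = step, cost_type = cost_type, label_pattern = label_pattern),
    class = "item_selector"
  )
}

.describe_selector <- function(selector) {
  parts <- c(
    if (!is.null(selector$step)) paste0("step=", selector$step),
    if (!is.null(selector$cost_type)) {
      paste0("cost_type=", selector$cost_type)
    },
    if (!is.null(selector$label_pattern)) {
      paste0("label~'", selector$label_pattern, "'")
    }
  )
  paste(parts, collapse = ", ")
}

.match_items <- function(items, selector) {
  keep <- rep(TRUE, nrow(items))
  if (!is.null(selector$step)) {
    steps <- selector$step
    if (steps == .merged_step) {
      steps <- c("library_preparation", "sequencing")
    }
    keep <- keep & items$step %in% steps
  }
  if (!is.null(selector$cost_type)) {
    keep <- keep & items$cost_type == selector$cost_type
  }
  if (!is.null(selector$label_pattern)) {
    keep <- keep & grepl(selector$label_pattern, items$label)
  }
  keep
}

#' Apply a one-way perturbation to a project
#'
#' Returns a modified copy of the project in which the per-patient cost of
#' every item matched by the selector is multiplied by `factor` (or, with
#' `replace`, set to an absolute AUD value). The original project is never
#' modified. When the selector targets `data_storage` and the project
#' carries a [storage_spec()] instead of an explicit storage item, the
#' spec's monthly price is scaled instead.
#'
#' @param project A [seq_project()].
#' @param selector An [item_selector()].
#' @param factor Positive multiplicative factor.
#' @param replace Optional absolute replacement cost (AUD per patient) for
#'   each matched item; overrides `factor`.
#' @return A modified [seq_project()].
#' @export
#' @examples
#' p <- load_fixture("oesophageal_genome")
#' cheaper <- apply_scenario(
#'   p, item_selector(step = "library_prep_and_sequencing"), 0.9
#' )
apply_scenario <- function(project, selector, factor = 1, replace = NULL) {
  if (!inherits(project, "seq_project")) {
    stop("project must be a seq_project object", call. = FALSE)
  }
  if (!inherits(selector, "item_selector")) {
    stop("selector must be an item_selector object", call. = FALSE)
  }
  if (is.null(replace) && (!is.finite(factor) || factor <= 0)) {
    stop("perturbation factor must be positive and finite", call. = FALSE)
  }
  items <- project$items
  keep <- .match_items(items, selector)

  storage_hit <- FALSE
  if (!any(keep) && !is.null(project$storage) &&
    identical(selector$step, "data_storage") && is.null(replace)) {
    project$storage$usd_per_gb_month <-
      project$storage$usd_per_gb_month * factor
    storage_hit <- TRUE
  }
  if (!any(keep) && !storage_hit) {
    stop(
      "selector (", .describe_selector(selector),
      ") matched no items in project '", project$name, "'",
      call. = FALSE
    )
  }
  if (any(keep)) {
    if (!is.null(replace)) {
      if (replace < 0) stop("replacement cost must be >= 0", call. = FALSE)
      items$per_patient_cost[keep] <- replace
      items$quantity[keep] <- NA_real_
      items$unit_price[keep] <- NA_real_
    } else {
      resolved <- component_cost(items[keep, , drop = FALSE])
      items$per_patient_cost[keep] <- resolved * factor
      items$quantity[keep] <- NA_real_
      items$unit_price[keep] <- NA_real_
    }
    project$items <- items
  }
  project
}

#' Relative change in the capital-inclusive total under a scenario
#'
#' Applies the perturbation and reports the percentage change of the
#' per-patient total *including* capital (the convention for sensitivity
#' results, in contrast to step shares which use the operating total).
#'
#' @inheritParams apply_scenario
#' @return Signed percentage change of the capital-inclusive total.
#' @export
#' @examples
#' relative_total_change(
#'   load_fixture("oesophageal_genome"),
#'   item_selector(step = "data_storage"), 2.5
#' ) # ~ +6.6
relative_total_change <- function(project, selector, factor = 1,
                                  replace = NULL) {
  baseline <- per_patient_breakdown(project)$total_incl_capital
  if (!is.finite(baseline) || baseline <= 0) {
    stop(
      "relative change undefined: baseline total is not positive",
      call. = FALSE
    )
  }
  perturbed <- per_patient_breakdown(
    apply_scenario(project, selector, factor, replace)
  )$total_incl_capital
  100 * (perturbed - baseline) / baseline
}

#' Cross-project summary of a one-way scenario
#'
#' Applies the same perturbation to every project and summarises the
#' unrounded per-project relative changes with an unweighted arithmetic
#' mean and min-max range.
#'
#' @param projects List of [seq_project()] objects (at least one).
#' @inheritParams apply_scenario
#' @return List with `mean`, `min`, `max` and the named `per_project`
#'   vector of percentage changes.
#' @export
#' @examples
#' cross_project_sensitivity(
#'   load_fixtures(),
#'   item_selector(step = "library_prep_and_sequencing"), 0.9
#' )$mean # ~ -7.2
cross_project_sensitivity <- function(projects, selector, factor = 1,
                                      replace = NULL) {
  if (inherits(projects, "seq_project")) projects <- list(projects)
  if (!length(projects)) {
    stop("at least one project is required", call. = FALSE)
  }
  changes <- vapply(
    projects, relative_total_change, numeric(1),
    selector = selector, factor = factor, replace = replace
  )
  names(changes) <- vapply(projects, `[[`, character(1), "name")
  list(
    mean = mean(changes), min = min(changes), max = max(changes),
    per_project = changes
  )
}

#' Define a named low/high sensitivity scenario
#'
#' @param name Scenario name used in tornado tables.
#' @param selector An [item_selector()].
#' @param low,high Multiplicative factors for the low and high arms; a
#'   single one-sided scenario may set both to the same value.
#' @return An object of class `sens_scenario`.
#' @export
#' @examples
#' scenario(
#'   "labour wages +/-20%", item_selector(cost_type = "labour"), 0.8, 1.2
#' )
scenario <- function(name, selector, low, high = low) {
  if (!inherits(selector, "item_selector")) {
    stop("selector must be an item_selector object", call. = FALSE)
  }
  if (low <= 0 || high <= 0) {
    stop("scenario factors must be positive", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name), selector = selector,
      low = as.numeric(low), high = as.numeric(high)
    ),
    class = "sens_scenario"
  )
}

#' Default one-way scenario set
#'
#' The scenario set explored in the base analysis: combined library
#' preparation + sequencing price +/-10%, scientist wages +/-20% (applied
#' to all labour-typed items), and the storage tier moved from nearline to
#' the coldline / regional price points.
#'
#' @return List of [scenario()] objects.
#' @export
default_scenarios <- function() {
  nearline <- storage_tier_price("nearline")
  list(
    scenario(
      "library preparation + sequencing price +/-10%",
      item_selector(step = "library_prep_and_sequencing"), 0.9, 1.1
    ),
    scenario(
      "scientist wages +/-20%",
      item_selector(cost_type = "labour"), 0.8, 1.2
    ),
    scenario(
      "storage tier (coldline / regional)",
      item_selector(step = "data_storage"),
      storage_tier_price("coldline") / nearline,
      storage_tier_price("regional") / nearline
    )
  )
}

#' One-way sensitivity (tornado) table for a project
#'
#' Evaluates each scenario's low and high arm against the project baseline
#' and returns one row per scenario, sorted by swing (|high - low|)
#' descending; ties are broken by scenario name so the output is fully
#' deterministic.
#'
#' @param project A [seq_project()].
#' @param scenarios List of [scenario()] objects (at least one); default
#'   [default_scenarios()].
#' @return Data frame of class `tornado_table` with columns `parameter`,
#'   `baseline_total`, `total_low`, `total_high`, `swing`,
#'   `relative_change_low`, `relative_change_high` (totals in AUD, changes
#'   in percent, all capital-inclusive and unrounded).
#' @export
#' @examples
#' tornado(load_fixture("oesophageal_genome"))
tornado <- function(project, scenarios = default_scenarios()) {
  if (inherits(scenarios, "sens_scenario")) scenarios <- list(scenarios)
  if (!length(scenarios)) {
    stop("at least one scenario is required", call. = FALSE)
  }
  baseline <- per_patient_breakdown(project)$total_incl_capital
  rows <- lapply(scenarios, function(sc) {
    total_low <- per_patient_breakdown(
      apply_scenario(project, sc$selector, sc$low)
    )$total_incl_capital
    total_high <- per_patient_breakdown(
      apply_scenario(project, sc$selector, sc$high)
    )$total_incl_capital
    data.frame(
      parameter = sc$name,
      baseline_total = baseline,
      total_low = total_low,
      total_high = total_high,
      swing = abs(total_high - total_low),
      relative_change_low = 100 * (total_low - baseline) / baseline,
      relative_change_high = 100 * (total_high - baseline) / baseline,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_table", class(out))
  attr(out, "project") <- project$name
  out
}
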