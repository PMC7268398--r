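#' Run the accounting invariants for one project
#'
#' Checks, without raising on failure, that: the step costs sum to the
#' operating total; the capital-inclusive total equals operating total plus
#' capital; the cost-type totals sum to the capital-inclusive total; step
#' shares sum to 100 (within 0.2 for rounding slack); and all component
#' costs are non-negative.
#'
#' @param project A [seq_project()].
#' @param tol Absolute tolerance in AUD for the conservation checks.
#' @return Data frame with columns `check`, `pass`, `detail`.
#' @export
#' @examples
#' validate_breakdown(load_fixture("breast_panel"))
validate_breakdown <- function(project, tol = 0.05) {
  bd <- per_patient_breakdown(project)
  items <- .effective_items(project)
  costs <- if (nrow(items)) component_cost(items) else numeric(0)

  checks <- list(
    list(
      check = "step costs sum to operating total",
      pass = abs(sum(bd$per_step) - bd$total_excl_capital) <= tol,
      detail = sprintf(
        "sum(steps) = %.4f, total = %.4f",
        sum(bd$per_step), bd$total_excl_capital
      )
    ),
    list(
      check = "capital-inclusive total = operating + capital",
      pass = abs(bd$total_excl_capital + bd$capital_per_patient -
        bd$total_incl_capital) <= tol,
      detail = sprintf(
        "%.4f + %.4f vs %.4f",
        bd$total_excl_capital, bd$capital_per_patient,
        bd$total_incl_capital
      )
    ),
    list(
      check = "type costs sum to capital-inclusive total",
      pass = abs(sum(bd$per_type) - bd$total_incl_capital) <= tol,
      detail = sprintf(
        "sum(types) = %.4f, total = %.4f",
        sum(bd$per_type), bd$total_incl_capital
      )
    ),
    list(
      check = "step shares sum to 100",
      pass = is.finite(sum(bd$step_shares)) &&
        abs(sum(bd$step_shares) - 100) <= 0.2,
      detail = sprintf("sum(shares) = %.4f", sum(bd$step_shares))
    ),
    list(
      check = "all component costs non-negative",
      pass = all(costs >= 0),
      detail = sprintf("min component = %.4f", if (length(costs)) min(costs) else 0)
    )
  )
  out <- do.call(rbind, lapply(checks, as.data.frame))
  out$project <- project$name
  out[, c("project", "check", "pass", "detail")]
}

#' Validate a set of projects
#'
#' @param projects List of [seq_project()] objects.
#' @inheritParams validate_breakdown
#' @return Combined check table over all projects.
#' @export
validation_report <- function(projects, tol = 0.05) {
  if (inherits(projects, "seq_project")) projects <- list(projects)
  do.call(rbind, lapply(projects, validate_breakdown, tol = tol))
}
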