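#' Per-patient cloud storage cost in AUD
#'
#' Accumulates the monthly USD storage charge over the storage duration and
#' converts it to AUD: `gb_per_patient * usd_per_gb_month * months /
#' usd_per_aud`.
#'
#' @param spec A [storage_spec()].
#' @return Storage cost in AUD per patient.
#' @export
#' @examples
#' storage_cost_per_patient(storage_spec(100, 0.01, 60, 0.6929))
storage_cost_per_patient <- function(spec) {
  if (!inherits(spec, "storage_spec")) {
    stop("spec must be a storage_spec object", call. = FALSE)
  }
  spec$gb_per_patient * spec$usd_per_gb_month * spec$months / spec$usd_per_aud
}

#' Convert AUD amounts to USD
#'
#' @param amount Amount(s) in AUD.
#' @param usd_per_aud Exchange rate, USD per 1 AUD (> 0).
#' @return Amount(s) in USD, unrounded; round to whole dollars when
#'   rendering.
#' @export
#' @examples
#' aud_to_usd(2895.19) # ~2006 USD
aud_to_usd <- function(amount, usd_per_aud = 0.6929) {
  if (!is.numeric(usd_per_aud) || usd_per_aud <= 0) {
    stop("usd_per_aud exchange rate must be positive", call. = FALSE)
  }
  amount * usd_per_aud
}

# items actually costed for a project: the inventory plus, when a storage
# spec is given and no data_storage item exists, a computed storage item
.effective_items <- function(project) {
  items <- project$items
  if (!is.null(project$storage) && !any(items$step == "data_storage")) {
    storage_item <- data.frame(
      label = "data storage",
      step = "data_storage",
      cost_type = "other",
      per_patient_cost = storage_cost_per_patient(project$storage),
      quantity = NA_real_,
      unit_price = NA_real_,
      note = "computed from storage_spec",
      stringsAsFactors = FALSE
    )
    items <- rbind(items, storage_item)
  }
  items
}

# step labels used for reporting: six rows when steps 3+4 are merged
.report_steps <- function(merged) {
  if (merged) {
    c(
      "sampling", "dna_extraction", .merged_step,
      "analysis", "data_storage", "clinician_reporting"
    )
  } else {
    .step_labels()
  }
}

#' Per-patient cost breakdown of a project
#'
#' Aggregates the project inventory into per-patient costs by activity step
#' and by cost type, computes the operating total (excluding capital), the
#' annuitized capital charge, the capital-inclusive total, each step's
#' share of the operating total, and the capital add-on percentage.
#'
#' When the project's library preparation and sequencing were outsourced as
#' one service (`merge_lib_seq = TRUE`), the two steps are reported as a
#' single combined row keyed `"library_prep_and_sequencing"`.
#'
#' Steps with no items contribute zero and are flagged as absent so that
#' renderers can distinguish "not applicable" from a true zero cost.
#'
#' @param project A [seq_project()].
#' @return An object of class `cost_breakdown`: a list with elements
#'   `per_step`, `steps_present`, `per_type`, `total_excl_capital`,
#'   `machine_per_patient`, `maintenance_per_patient`,
#'   `capital_per_patient`, `total_incl_capital`, `step_shares`,
#'   `capital_addon_percent`, `merged`, `project` and `n_patients`.
#' @export
#' @examples
#' bd <- per_patient_breakdown(load_fixture("melanoma_exome"))
#' bd$total_excl_capital # 870.63
per_patient_breakdown <- function(project) {
  if (!inherits(project, "seq_project")) {
    stop("project must be a seq_project object", call. = FALSE)
  }
  items <- .effective_items(project)
  costs <- if (nrow(items)) component_cost(items) else numeric(0)

  steps <- .report_steps(project$merge_lib_seq)
  item_steps <- items$step
  if (project$merge_lib_seq) {
    item_steps[item_steps %in% c("library_preparation", "sequencing")] <-
      .merged_step
  }
  per_step <- vapply(
    steps,
    function(s) sum(costs[item_steps == s]),
    numeric(1)
  )
  steps_present <- vapply(steps, function(s) any(item_steps == s), logical(1))

  capital <- .project_capital(project)
  total_excl <- sum(per_step)
  total_incl <- total_excl + capital$capital_per_patient

  per_type <- vapply(
    cost_types(),
    function(ct) sum(costs[items$cost_type == ct]),
    numeric(1)
  )
  # capital machine + maintenance joins the equipment row of the type table
  per_type[["equipment"]] <- per_type[["equipment"]] +
    capital$capital_per_patient

  shares <- if (total_excl > 0) 100 * per_step / total_excl else
    rep(NA_real_, length(per_step))
  names(shares) <- steps

  structure(
    list(
      project = project$name,
      n_patients = project$n_patients,
      technology = project$technology,
      merged = project$merge_lib_seq,
      per_step = per_step,
      steps_present = steps_present,
      per_type = per_type,
      total_excl_capital = total_excl,
      machine_per_patient = capital$machine_per_patient,
      maintenance_per_patient = capital$maintenance_per_patient,
      capital_per_patient = capital$capital_per_patient,
      total_incl_capital = total_incl,
      step_shares = shares,
      capital_addon_percent = if (total_excl > 0) {
        100 * capital$capital_per_patient / total_excl
      } else {
        NA_real_
      }
    ),
    class = "cost_breakdown"
  )
}

#' Step shares of the operating total
#'
#' Each step's percentage of the per-patient total excluding capital
#' equipment (the convention used for workflow-step shares). Values are
#' unrounded; renderers round to one decimal.
#'
#' @param breakdown A `cost_breakdown` (or a [seq_project()], which is
#'   broken down first).
#' @return Named numeric vector of percentages.
#' @export
step_shares <- function(breakdown) {
  if (inherits(breakdown, "seq_project")) {
    breakdown <- per_patient_breakdown(breakdown)
  }
  if (!inherits(breakdown, "cost_breakdown")) {
    stop("breakdown must be a cost_breakdown or seq_project", call. = FALSE)
  }
  if (!is.finite(breakdown$total_excl_capital) ||
    breakdown$total_excl_capital <= 0) {
    stop(
      "step shares are undefined: operating total is not positive",
      call. = FALSE
    )
  }
  100 * breakdown$per_step / breakdown$total_excl_capital
}

#' Per-patient costs by cost type
#'
#' Aggregates the inventory by the labour / consumables / testing /
#' equipment / other classification. The equipment row includes the
#' annuitized capital charge (machine + maintenance), so the type totals
#' sum to the capital-inclusive per-patient total.
#'
#' @param project A [seq_project()] or a `cost_breakdown`.
#' @return Named numeric vector over [cost_types()], AUD per patient.
#' @export
#' @examples
#' type_breakdown(load_fixture("melanoma_exome"))
type_breakdown <- function(project) {
  if (inherits(project, "seq_project")) {
    project <- per_patient_breakdown(project)
  }
  if (!inherits(project, "cost_breakdown")) {
    stop("project must be a seq_project or cost_breakdown", call. = FALSE)
  }
  project$per_type
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> ", x$project, " (n = ", x$n_patients, ")\n",
    sep = ""
  )
  step_df <- data.frame(
    step = names(x$per_step),
    aud_per_patient = round(x$per_step, 2),
    pct_of_total = ifelse(
      x$steps_present,
      sprintf("%.1f%%", x$step_shares),
      "n/a"
    ),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  print(step_df, row.names = FALSE)
  cat(
    sprintf("  TOTAL per person (excl. capital): AUD %.2f\n", x$total_excl_capital),
    sprintf(
      "  capital (machine + maintenance):  AUD %.2f (+%.1f%%)\n",
      x$capital_per_patient, x$capital_addon_percent
    ),
    sprintf("  TOTAL per person incl. capital:   AUD %.2f\n", x$total_incl_capital),
    sep = ""
  )
  invisible(x)
}

#' Cross-project summary of step shares and capital add-ons
#'
#' Computes, for each activity step (with library preparation and
#' sequencing always combined so that merged and unmerged projects are
#' comparable), the arithmetic mean and min-max range of the unrounded step
#' shares across projects, plus the range of capital add-on percentages.
#' The mean is unweighted: each project counts equally regardless of its
#' patient numbers. Steps absent from a project contribute a zero share.
#'
#' @param projects List of [seq_project()] objects (at least one).
#' @return A list with `shares` (data frame: step, mean, min, max,
#'   n_present) and `capital_addon` (mean, min, max).
#' @export
#' @examples
#' cross_project_summary(load_fixtures())$shares
cross_project_summary <- function(projects) {
  if (inherits(projects, "seq_project")) projects <- list(projects)
  if (!length(projects)) {
    stop("at least one project is required", call. = FALSE)
  }
  breakdowns <- lapply(projects, per_patient_breakdown)
  steps <- .report_steps(merged = TRUE)

  share_of <- function(bd, step) {
    shares <- bd$step_shares
    if (step == .merged_step && !bd$merged) {
      return(sum(shares[c("library_preparation", "sequencing")]))
    }
    if (step %in% names(shares)) shares[[step]] else 0
  }
  present <- function(bd, step) {
    if (step == .merged_step && !bd$merged) {
      return(any(bd$steps_present[c("library_preparation", "sequencing")]))
    }
    isTRUE(bd$steps_present[[step]])
  }

  share_mat <- sapply(steps, function(s) {
    vapply(breakdowns, share_of, numeric(1), step = s)
  })
  share_mat <- matrix(share_mat,
    nrow = length(breakdowns),
    dimnames = list(NULL, steps)
  )
  shares <- data.frame(
    step = steps,
    mean = colMeans(share_mat),
    min = apply(share_mat, 2, min),
    max = apply(share_mat, 2, max),
    n_present = vapply(steps, function(s) {
      sum(vapply(breakdowns, present, logical(1), step = s))
    }, numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  addons <- vapply(breakdowns, `[[`, numeric(1), "capital_addon_percent")
  list(
    shares = shares,
    capital_addon = c(
      mean = mean(addons), min = min(addons), max = max(addons)
    )
  )
}
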