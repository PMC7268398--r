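#' Canonical activity steps of a sequencing workflow
#'
#' The costing model organises every resource line item into one of seven
#' workflow steps: sampling, DNA extraction, library preparation, sequencing,
#' analysis (including report generation), data storage, and reporting to
#' clinicians. When library preparation and sequencing are outsourced as a
#' single commercial service the two steps are reported as one combined row
#' (see [per_patient_breakdown()]).
#'
#' @return A data frame with columns `ordinal` (1-7) and `label`.
#' @export
#' @examples
#' activity_steps()
activity_steps <- function() {
  data.frame(
    ordinal = 1:7,
    label = c(
      "sampling", "dna_extraction", "library_preparation", "sequencing",
      "analysis", "data_storage", "clinician_reporting"
    ),
    stringsAsFactors = FALSE
  )
}

# internal constants -----------------------------------------------------

.step_labels <- function() activity_steps()$label

# key used when steps 3 and 4 are reported as one combined row
.merged_step <- "library_prep_and_sequencing"

#' Cost type categories
#'
#' The orthogonal classification of the same line items by resource type.
#'
#' @return Character vector of the five categories.
#' @export
cost_types <- function() {
  c("labour", "consumables", "testing", "equipment", "other")
}

#' Cloud storage price tiers
#'
#' Monthly cloud-storage list prices in USD per gigabyte for three access
#' tiers: `coldline` (very infrequent access, 0.007), `nearline` (infrequent,
#' 0.010; the base-case tier) and `regional` (frequent, 0.025).
#'
#' @param tier Optional tier name; when given, returns that tier's price.
#' @return Named numeric vector of prices, or a single price.
#' @export
#' @examples
#' storage_tiers()
#' storage_tier_price("regional")
storage_tiers <- function(tier = NULL) {
  tiers <- c(coldline = 0.007, nearline = 0.010, regional = 0.025)
  if (is.null(tier)) {
    return(tiers)
  }
  tier <- match.arg(tolower(tier), names(tiers))
  unname(tiers[[tier]])
}

#' @rdname storage_tiers
#' @export
storage_tier_price <- function(tier) storage_tiers(tier)

# 2018 market exchange rate used throughout as the default; always a
# configurable input, never hard-wired into arithmetic.
.default_usd_per_aud <- 0.6929

# -- label normalisation -------------------------------------------------

.normalize_step <- function(step) {
  step <- tolower(trimws(as.character(step)))
  valid <- c(.step_labels(), .merged_step)
  bad <- !step %in% valid
  if (any(bad)) {
    stop(
      "unknown activity step label(s): ",
      paste(unique(step[bad]), collapse = ", "),
      "; valid labels are: ", paste(valid, collapse = ", "),
      call. = FALSE
    )
  }
  step
}

.normalize_cost_type <- function(cost_type) {
  cost_type <- tolower(trimws(as.character(cost_type)))
  bad <- !cost_type %in% cost_types()
  if (any(bad)) {
    stop(
      "unknown cost type label(s): ",
      paste(unique(cost_type[bad]), collapse = ", "),
      "; valid labels are: ", paste(cost_types(), collapse = ", "),
      call. = FALSE
    )
  }
  cost_type
}
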