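#' Capital equipment specification
#'
#' Inputs for annuitizing a sequencing instrument into a per-patient charge:
#' the acquisition price is converted to an equivalent annual cost over the
#' instrument's useful life at the given interest rate, divided by annual
#' patient throughput, and topped up with maintenance expressed as a
#' fraction of the machine charge.
#'
#' @param acquisition_price Instrument purchase price, AUD (> 0).
#' @param useful_life_years Amortisation horizon in whole years (default 5).
#' @param interest_rate Annual interest rate as a fraction (default 0.03).
#' @param annual_patients Patients processed per year (> 0).
#' @param maintenance_ratio Annual maintenance as a fraction of the
#'   per-patient machine charge (default 0.5).
#' @return An object of class `equipment_spec`.
#' @seealso [per_patient_capital()], [annuity_factor()]
#' @export
equipment_spec <- function(acquisition_price, useful_life_years = 5L,
                           interest_rate = 0.03, annual_patients,
                           maintenance_ratio = 0.5) {
  stopifnot(
    is.numeric(acquisition_price), length(acquisition_price) == 1,
    is.numeric(annual_patients), length(annual_patients) == 1
  )
  if (!is.finite(acquisition_price) || acquisition_price <= 0) {
    stop("acquisition_price must be positive and finite", call. = FALSE)
  }
  if (useful_life_years < 1 || useful_life_years != round(useful_life_years)) {
    stop("useful_life_years must be a whole number >= 1", call. = FALSE)
  }
  if (interest_rate < 0) stop("interest_rate must be >= 0", call. = FALSE)
  if (annual_patients <= 0) {
    stop("annual_patients must be positive", call. = FALSE)
  }
  if (maintenance_ratio < 0) {
    stop("maintenance_ratio must be >= 0", call. = FALSE)
  }
  structure(
    list(
      acquisition_price = as.numeric(acquisition_price),
      useful_life_years = as.integer(useful_life_years),
      interest_rate = as.numeric(interest_rate),
      annual_patients = as.numeric(annual_patients),
      maintenance_ratio = as.numeric(maintenance_ratio)
    ),
    class = "equipment_spec"
  )
}

#' Directly-specified per-patient capital charges
#'
#' Alternative to [equipment_spec()] when the per-patient machine and
#' maintenance charges are already known (e.g. copied from a published
#' costing table) rather than derived from acquisition price and
#' throughput.
#'
#' @param machine_per_patient Machine charge, AUD per patient (>= 0).
#' @param maintenance_per_patient Maintenance charge, AUD per patient; by
#'   default half the machine charge.
#' @return An object of class `capital_costs`.
#' @export
capital_costs <- function(machine_per_patient,
                          maintenance_per_patient = 0.5 * machine_per_patient) {
  stopifnot(machine_per_patient >= 0, maintenance_per_patient >= 0)
  structure(
    list(
      machine_per_patient = as.numeric(machine_per_patient),
      maintenance_per_patient = as.numeric(maintenance_per_patient)
    ),
    class = "capital_costs"
  )
}

#' Cloud storage specification
#'
#' Short-term (typically 5-year) storage of sequencing output, priced at a
#' monthly USD rate per gigabyte and converted to AUD.
#'
#' @param gb_per_patient Gigabytes stored per patient (>= 0); for matched
#'   tumour/germline pairs, the combined footprint of both samples.
#' @param usd_per_gb_month Price in USD per GB per month (> 0); see
#'   [storage_tiers()] for tier presets. Default is the nearline tier.
#' @param months Storage duration in months (default 60, i.e. 5 years).
#' @param usd_per_aud Exchange rate, USD per 1 AUD (> 0).
#' @return An object of class `storage_spec`.
#' @export
storage_spec <- function(gb_per_patient,
                         usd_per_gb_month = storage_tier_price("nearline"),
                         months = 60L, usd_per_aud = 0.6929) {
  if (gb_per_patient < 0) stop("gb_per_patient must be >= 0", call. = FALSE)
  if (usd_per_gb_month <= 0) {
    stop("usd_per_gb_month must be positive", call. = FALSE)
  }
  if (months < 0 || months != round(months)) {
    stop("months must be a whole number >= 0", call. = FALSE)
  }
  if (!is.finite(usd_per_aud) || usd_per_aud <= 0) {
    stop("usd_per_aud exchange rate must be positive", call. = FALSE)
  }
  structure(
    list(
      gb_per_patient = as.numeric(gb_per_patient),
      usd_per_gb_month = as.numeric(usd_per_gb_month),
      months = as.integer(months),
      usd_per_aud = as.numeric(usd_per_aud)
    ),
    class = "storage_spec"
  )
}

#' Construct a sequencing project
#'
#' A project bundles the metadata and per-patient resource inventory of one
#' sequencing application: its technology tier (targeted panel, exome or
#' whole genome), sample design (germline only, tumour only, or matched
#' tumour/germline pairs), resource items, and optional capital-equipment
#' and storage specifications.
#'
#' @param name Project name.
#' @param n_patients Number of patients costed (> 0).
#' @param technology One of `"panel"`, `"exome"`, `"genome"`.
#' @param sample_design One of `"germline_only"`, `"tumour_only"`,
#'   `"tumour_germline_pair"`. Item costs are per patient in all designs;
#'   pair designs already include both samples.
#' @param items Resource item table (see [resource_item()]).
#' @param equipment Optional [equipment_spec()] or [capital_costs()];
#'   `NULL` means no capital charge.
#' @param storage Optional [storage_spec()]. Used only when the inventory
#'   has no `data_storage` item of its own.
#' @param merge_lib_seq Logical; `TRUE` when library preparation and
#'   sequencing were purchased as one outsourced service and must be
#'   reported as a single combined step.
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class `seq_project`.
#' @export
seq_project <- function(name, n_patients, technology, sample_design, items,
                        equipment = NULL, storage = NULL,
                        merge_lib_seq = FALSE, metadata = list()) {
  technology <- match.arg(tolower(technology), c("panel", "exome", "genome"))
  sample_design <- match.arg(
    tolower(sample_design),
    c("germline_only", "tumour_only", "tumour_germline_pair")
  )
  if (!is.numeric(n_patients) || n_patients <= 0 ||
    n_patients != round(n_patients)) {
    stop("n_patients must be a positive whole number", call. = FALSE)
  }
  items <- validate_items(items)
  if (!is.null(equipment) &&
    !inherits(equipment, c("equipment_spec", "capital_costs"))) {
    stop(
      "equipment must be an equipment_spec or capital_costs object",
      call. = FALSE
    )
  }
  if (!is.null(storage) && !inherits(storage, "storage_spec")) {
    stop("storage must be a storage_spec object", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      n_patients = as.integer(n_patients),
      technology = technology,
      sample_design = sample_design,
      items = items,
      equipment = equipment,
      storage = storage,
      merge_lib_seq = isTRUE(merge_lib_seq),
      metadata = metadata
    ),
    class = "seq_project"
  )
}

#' @export
print.seq_project <- function(x, ...) {
  cat(
    "<seq_project> ", x$name, "\n",
    "  technology:    ", x$technology, "\n",
    "  sample design: ", x$sample_design, "\n",
    "  patients:      ", x$n_patients, "\n",
    "  items:         ", nrow(x$items), " line item(s)",
    if (x$merge_lib_seq) " (library prep + sequencing merged)" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.equipment_spec <- function(x, ...) {
  cat(
    "<equipment_spec> acquisition AUD ", format(x$acquisition_price),
    ", life ", x$useful_life_years, " y at ",
    100 * x$interest_rate, "%, ", format(x$annual_patients),
    " patients/y, maintenance ratio ", x$maintenance_ratio, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.storage_spec <- function(x, ...) {
  cat(
    "<storage_spec> ", format(x$gb_per_patient), " GB/patient at USD ",
    format(x$usd_per_gb_month), "/GB-month for ", x$months,
    " months (rate ", format(x$usd_per_aud), " USD/AUD)\n",
    sep = ""
  )
  invisible(x)
}
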