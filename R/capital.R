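#' Annuity factor
#'
#' Present value of an annuity of 1 per year for `n` years at annual rate
#' `r`: `(1 - (1 + r)^(-n)) / r`, with the zero-interest limit `n`.
#' Dividing an acquisition price by this factor gives the equivalent annual
#' cost of owning the asset over its useful life.
#'
#' @param r Annual interest rate as a fraction (>= 0).
#' @param n Useful life in whole years (>= 1).
#' @return Dimensionless annuity factor.
#' @export
#' @examples
#' annuity_factor(0.03, 5)
annuity_factor <- function(r, n) {
  if (n < 1 || n != round(n)) {
    stop("useful life n must be a whole number >= 1", call. = FALSE)
  }
  if (r < 0) stop("interest rate r must be >= 0", call. = FALSE)
  if (r == 0) {
    return(as.numeric(n))
  }
  (1 - (1 + r)^(-n)) / r
}

#' Per-patient capital charge from an equipment specification
#'
#' Annuitizes the instrument acquisition price into an equivalent annual
#' cost (acquisition / annuity factor), allocates it across the annual
#' patient throughput, and adds maintenance as a fixed fraction of the
#' machine charge.
#'
#' @param spec An [equipment_spec()], or a [capital_costs()] object whose
#'   directly-specified charges are passed through unchanged.
#' @return A list of class `capital_result` with elements `annuity_factor`,
#'   `equivalent_annual_cost`, `machine_per_patient`,
#'   `maintenance_per_patient` and `capital_per_patient`.
#' @export
#' @examples
#' per_patient_capital(equipment_spec(
#'   acquisition_price = 100000, annual_patients = 972
#' ))
per_patient_capital <- function(spec) {
  if (inherits(spec, "capital_costs")) {
    return(structure(
      list(
        annuity_factor = NA_real_,
        equivalent_annual_cost = NA_real_,
        machine_per_patient = spec$machine_per_patient,
        maintenance_per_patient = spec$maintenance_per_patient,
        capital_per_patient = spec$machine_per_patient +
          spec$maintenance_per_patient
      ),
      class = "capital_result"
    ))
  }
  if (!inherits(spec, "equipment_spec")) {
    stop("spec must be an equipment_spec or capital_costs object",
      call. = FALSE
    )
  }
  if (spec$annual_patients <= 0) {
    stop("annual_patients must be positive", call. = FALSE)
  }
  af <- annuity_factor(spec$interest_rate, spec$useful_life_years)
  aec <- spec$acquisition_price / af
  machine <- aec / spec$annual_patients
  maintenance <- spec$maintenance_ratio * machine
  structure(
    list(
      annuity_factor = af,
      equivalent_annual_cost = aec,
      machine_per_patient = machine,
      maintenance_per_patient = maintenance,
      capital_per_patient = machine + maintenance
    ),
    class = "capital_result"
  )
}

#' @export
print.capital_result <- function(x, ...) {
  cat("<capital_result>\n")
  if (!is.na(x$annuity_factor)) {
    cat(
      "  annuity factor:          ", format(x$annuity_factor), "\n",
      "  equivalent annual cost:  AUD ",
      format(round(x$equivalent_annual_cost, 2)), "\n",
      sep = ""
    )
  }
  cat(
    "  machine per patient:     AUD ",
    format(round(x$machine_per_patient, 2)), "\n",
    "  maintenance per patient: AUD ",
    format(round(x$maintenance_per_patient, 2)), "\n",
    "  capital per patient:     AUD ",
    format(round(x$capital_per_patient, 2)), "\n",
    sep = ""
  )
  invisible(x)
}

# capital charge for a project, zero when no equipment is specified
.project_capital <- function(project) {
  if (is.null(project$equipment)) {
    return(structure(
      list(
        annuity_factor = NA_real_, equivalent_annual_cost = NA_real_,
        machine_per_patient = 0, maintenance_per_patient = 0,
        capital_per_patient = 0
      ),
      class = "capital_result"
    ))
  }
  per_patient_capital(project$equipment)
}
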