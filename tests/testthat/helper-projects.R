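# shared helpers for building tiny projects in tests

tiny_items <- function(...) {
  validate_items(do.call(rbind, list(...)))
}

tiny_item <- function(label, step, cost_type, cost = NA_real_,
                      quantity = NA_real_, unit_price = NA_real_) {
  data.frame(
    label = label, step = step, cost_type = cost_type,
    per_patient_cost = cost, quantity = quantity, unit_price = unit_price,
    note = "", stringsAsFactors = FALSE
  )
}

tiny_project <- function(items, name = "tiny", n_patients = 10,
                         technology = "panel",
                         sample_design = "germline_only", ...) {
  seq_project(
    name = name, n_patients = n_patients, technology = technology,
    sample_design = sample_design, items = items, ...
  )
}

# printed per-patient totals excluding capital, by fixture, 2018 AUD
published_totals <- c(
  lung_melanoma_panel = 428.56,
  breast_panel = 347.08,
  melanoma_exome = 870.63,
  lung_exome = 2787.53,
  oesophageal_genome = 4829.76,
  mesothelioma_genome = 2895.19
)

# printed "% of total" cells by fixture and (possibly merged) step
published_shares <- list(
  lung_melanoma_panel = c(
    sampling = 0.0, dna_extraction = 6.6,
    library_prep_and_sequencing = 76.8, analysis = 14.3,
    data_storage = 0.5, clinician_reporting = 1.8
  ),
  breast_panel = c(
    sampling = 7.2, dna_extraction = 13.1, library_preparation = 45.1,
    sequencing = 24.1, analysis = 7.8, data_storage = 0.6,
    clinician_reporting = 2.2
  ),
  melanoma_exome = c(
    sampling = 3.2, dna_extraction = 7.6,
    library_prep_and_sequencing = 86.1, analysis = 2.0, data_storage = 1.1
  ),
  lung_exome = c(
    sampling = 0.9, dna_extraction = 6.6, library_preparation = 43.1,
    sequencing = 42.4, analysis = 2.1, data_storage = 1.4
  ),
  oesophageal_genome = c(
    sampling = 0.5, dna_extraction = 6.2,
    library_prep_and_sequencing = 86.7, analysis = 2.0, data_storage = 4.5
  ),
  mesothelioma_genome = c(
    sampling = 0.9, dna_extraction = 8.4,
    library_prep_and_sequencing = 56.3, analysis = 26.9, data_storage = 7.5
  )
)

# brute-force per-patient total: direct sum over the raw item list plus an
# independently computed capital charge; deliberately bypasses
# per_patient_breakdown()
brute_force_total <- function(project, include_capital = TRUE) {
  items <- project$items
  cost <- ifelse(
    !is.na(items$per_patient_cost),
    items$per_patient_cost,
    items$quantity * items$unit_price
  )
  total <- sum(cost)
  if (!is.null(project$storage) && !any(items$step == "data_storage")) {
    st <- project$storage
    total <- total + st$gb_per_patient * st$usd_per_gb_month * st$months /
      st$usd_per_aud
  }
  if (include_capital && !is.null(project$equipment)) {
    eq <- project$equipment
    capital <- if (inherits(eq, "capital_costs")) {
      eq$machine_per_patient + eq$maintenance_per_patient
    } else {
      r <- eq$interest_rate
      n <- eq$useful_life_years
      af <- if (r == 0) n else (1 - (1 + r)^(-n)) / r
      (eq$acquisition_price / af / eq$annual_patients) *
        (1 + eq$maintenance_ratio)
    }
    total <- total + capital
  }
  total
}
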