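# Packaged fixtures: six Australian cancer sequencing projects (2017/2018,
# Brisbane), with per-patient component costs in 2018 AUD. Items carry the
# published per-patient values directly; raw resource quantities were never
# deposited. Labour items are annotated with the implied hours at the two
# scientific wage levels (46.57 / 51.86 AUD/h incl. 20% overheads) where
# that is the natural unit, as notes only.

.fixture_builders <- function() {
  mdt_note <- "multidisciplinary team meeting, 10% of cases"

  list(
    lung_melanoma_panel = function() {
      items <- validate_items(data.frame(
        label = c(
          "tumour sample (biopsied in routine care)",
          "extraction consumables",
          "extraction validation / quality control",
          "extraction labour",
          "library preparation consumables",
          "pre-sequencing quality control",
          "library preparation labour",
          "computing software",
          "analysis labour",
          "data storage (2 GB/sample, nearline)",
          "multidisciplinary team meeting"
        ),
        step = c(
          "sampling", "dna_extraction", "dna_extraction", "dna_extraction",
          "library_preparation", "library_preparation",
          "library_preparation", "analysis", "analysis", "data_storage",
          "clinician_reporting"
        ),
        cost_type = c(
          "other", "consumables", "testing", "labour", "consumables",
          "testing", "labour", "equipment", "labour", "other", "labour"
        ),
        per_patient_cost = c(
          0.00, 22.13, 5.34, 0.78, 322.23, 0.78, 6.31, 1.74, 59.74,
          1.96, 7.56
        ),
        note = c(
          "no cost: biopsy stored in the normal course of diagnosis",
          "", "", "", "", "", "", "", "", "", mdt_note
        ),
        stringsAsFactors = FALSE
      ))
      seq_project(
        name = "Lung cancer/melanoma (panel)",
        n_patients = 745,
        technology = "panel",
        sample_design = "tumour_only",
        items = items,
        equipment = capital_costs(22.46, 11.23),
        merge_lib_seq = TRUE,
        metadata = list(
          setting = "statewide health service",
          platform = "Illumina MiSeq/NextSeq, TruSeq 26-gene panel"
        )
      )
    },

    breast_panel = function() {
      items <- validate_items(data.frame(
        label = c(
          "blood sample collection",
          "extraction consumables",
          "extraction validation / quality control",
          "extraction labour",
          "library preparation consumables",
          "library preparation labour",
          "sequencing (incl. MLPA)",
          "sequencing labour",
          "computing software",
          "analysis labour",
          "data storage (2 GB/sample, nearline)",
          "multidisciplinary team meeting"
        ),
        step = c(
          "sampling", "dna_extraction", "dna_extraction", "dna_extraction",
          "library_preparation", "library_preparation", "sequencing",
          "sequencing", "analysis", "analysis", "data_storage",
          "clinician_reporting"
        ),
        cost_type = c(
          "other", "consumables", "testing", "labour", "consumables",
          "labour", "testing", "labour", "equipment", "labour", "other",
          "labour"
        ),
        per_patient_cost = c(
          25.05, 39.37, 5.34, 0.78, 149.67, 6.79, 79.67, 3.88, 3.20,
          23.82, 1.96, 7.56
        ),
        note = c(
          "", "", "", "", "", "",
          "MLPA folded into the sequencing step", "", "", "", "", mdt_note
        ),
        stringsAsFactors = FALSE
      ))
      seq_project(
        name = "Breast cancer (panel)",
        n_patients = 192,
        technology = "panel",
        sample_design = "germline_only",
        items = items,
        equipment = capital_costs(22.46, 11.23),
        metadata = list(
          setting = "statewide health service",
          platform = "Illumina MiSeq/NextSeq, in-house panel + MLPA"
        )
      )
    },

    melanoma_exome = function() {
      items <- validate_items(data.frame(
        label = c(
          "saliva self-collection kit",
          "extraction consumables",
          "extraction validation / quality control",
          "extraction labour",
          "outsourced library preparation and sequencing",
          "analysis labour",
          "data storage (10 GB/sample, nearline)"
        ),
        step = c(
          "sampling", "dna_extraction", "dna_extraction", "dna_extraction",
          "sequencing", "analysis", "data_storage"
        ),
        cost_type = c(
          "other", "consumables", "testing", "labour", "testing",
          "labour", "other"
        ),
        per_patient_cost = c(
          27.50, 19.28, 32.91, 13.86, 750.00, 17.29, 9.79
        ),
        note = c(
          "", "", "", "",
          "commercial service; library prep not separable", "", ""
        ),
        stringsAsFactors = FALSE
      ))
      seq_project(
        name = "Melanoma (exome)",
        n_patients = 383,
        technology = "exome",
        sample_design = "germline_only",
        items = items,
        equipment = capital_costs(61.58, 30.79),
        merge_lib_seq = TRUE,
        metadata = list(
          setting = "clinical research",
          reporting = "n/a, pre-clinical project"
        )
      )
    },

    lung_exome = function() {
      items <- validate_items(data.frame(
        label = c(
          "blood sample collection",
          "extraction consumables (blood and tumour)",
          "extraction validation / quality control",
          "extraction labour",
          "library preparation consumables",
          "pre-sequencing quality control",
          "library preparation labour",
          "sequencing",
          "sequencing labour",
          "computing software",
          "analysis labour",
          "data storage (20 GB/sample, nearline)",
          "multidisciplinary team preparation"
        ),
        step = c(
          "sampling", "dna_extraction", "dna_extraction", "dna_extraction",
          "library_preparation", "library_preparation",
          "library_preparation", "sequencing", "sequencing", "analysis",
          "analysis", "data_storage", "clinician_reporting"
        ),
        cost_type = c(
          "other", "consumables", "testing", "labour", "consumables",
          "testing", "labour", "testing", "labour", "equipment", "labour",
          "other", "labour"
        ),
        per_patient_cost = c(
          25.05, 39.99, 81.50, 63.86, 1050.21, 11.54, 139.72, 1111.75,
          69.86, 0.73, 57.63, 39.15, 96.54
        ),
        stringsAsFactors = FALSE
      ))
      seq_project(
        name = "Lung cancer (exome)",
        n_patients = 10,
        technology = "exome",
        sample_design = "tumour_germline_pair",
        items = items,
        equipment = capital_costs(131.01, 65.51),
        metadata = list(
          setting = "clinical research",
          platform = "Illumina NovaSeq / NextSeq"
        )
      )
    },

    oesophageal_genome = function() {
      items <- validate_items(data.frame(
        label = c(
          "blood sample collection",
          "extraction consumables (tumour and blood kits)",
          "extraction validation / quality control",
          "extraction labour",
          "outsourced library preparation and sequencing",
          "analysis labour",
          "data storage (150 GB tumour + 72 GB blood, nearline)"
        ),
        step = c(
          "sampling", "dna_extraction", "dna_extraction", "dna_extraction",
          "sequencing", "analysis", "data_storage"
        ),
        cost_type = c(
          "other", "consumables", "testing", "labour", "testing",
          "labour", "other"
        ),
        per_patient_cost = c(
          25.05, 84.19, 180.70, 35.39, 4188.60, 98.54, 217.28
        ),
        note = c(
          "", "includes re-extraction for low tumour-content biopsies",
          "", "", "commercial service; library prep not separable", "", ""
        ),
        stringsAsFactors = FALSE
      ))
      seq_project(
        name = "Oesophageal cancer (genome)",
        n_patients = 100,
        technology = "genome",
        sample_design = "tumour_germline_pair",
        items = items,
        equipment = capital_costs(62.45, 31.22),
        merge_lib_seq = TRUE,
        metadata = list(
          setting = "research",
          platform = "Illumina HiSeq X Ten",
          reporting = "n/a, pre-clinical project"
        )
      )
    },

    mesothelioma_genome = function() {
      items <- validate_items(data.frame(
        label = c(
          "blood sample collection",
          "extraction consumables",
          "extraction validation / quality control",
          "extraction labour",
          "outsourced library preparation and sequencing",
          "analysis labour",
          "data storage (150 GB tumour + 72 GB blood, nearline)"
        ),
        step = c(
          "sampling", "dna_extraction", "dna_extraction", "dna_extraction",
          "sequencing", "analysis", "data_storage"
        ),
        cost_type = c(
          "other", "consumables", "testing", "labour", "testing",
          "labour", "other"
        ),
        per_patient_cost = c(
          25.05, 72.69, 139.90, 31.05, 1631.26, 777.96, 217.28
        ),
        note = c(
          "", "", "", "",
          "USD 600 per sample converted at 1.29038 AUD/USD", "", ""
        ),
        stringsAsFactors = FALSE
      ))
      seq_project(
        name = "Mesothelioma (genome)",
        n_patients = 3,
        technology = "genome",
        sample_design = "tumour_germline_pair",
        items = items,
        equipment = capital_costs(74.24, 37.12),
        merge_lib_seq = TRUE,
        metadata = list(
          setting = "research",
          platform = "BGISEQ-500",
          reporting = "n/a, pre-clinical project"
        )
      )
    }
  )
}

#' Names of the packaged project fixtures
#'
#' @return Character vector of valid fixture names.
#' @export
fixture_names <- function() names(.fixture_builders())

#' Load a packaged sequencing project fixture
#'
#' Returns one of six cancer sequencing projects (two targeted panels, two
#' exomes, two whole genomes) with per-patient component costs in 2018 AUD.
#'
#' @param name One of [fixture_names()].
#' @return A [seq_project()].
#' @export
#' @examples
#' load_fixture("oesophageal_genome")
load_fixture <- function(name) {
  builders <- .fixture_builders()
  if (length(name) != 1 || !name %in% names(builders)) {
    stop(
      "unknown fixture '", paste(name, collapse = ", "),
      "'; valid names are: ", paste(names(builders), collapse = ", "),
      call. = FALSE
    )
  }
  builders[[name]]()
}

#' Load all six packaged fixtures
#'
#' @return Named list of [seq_project()] objects.
#' @export
load_fixtures <- function() {
  lapply(.fixture_builders(), function(f) f())
}
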