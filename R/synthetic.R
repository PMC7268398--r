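# evaluate code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Parameters for the synthetic project generator
#'
#' Defines the statistical shape of randomly generated sequencing projects:
#' a technology mix over panel / exome / genome tiers, a probability of a
#' matched tumour/germline sample design, lognormal per-step cost
#' components (location on the log scale, common log-scale spread), a
#' technology-dependent storage footprint, wage rates for labour items, a
#' capital-equipment distribution, and a rework rate inflating DNA
#' extraction and quality-control costs for failed samples that must be
#' re-extracted.
#'
#' Defaults are centred on the magnitudes of the six packaged fixtures
#' (see the methods vignette for the rationale).
#'
#' @param n_projects Number of projects a cohort draw produces.
#' @param technology_mix Named probabilities over `panel`, `exome`,
#'   `genome`; must sum to 1.
#' @param pair_probability Probability of a tumour/germline pair design.
#' @param reporting_probability Probability the project is clinical and
#'   incurs a clinician-reporting step.
#' @param cost_location Named list of log-scale locations for the lognormal
#'   cost components; `libseq` is a named vector over the three
#'   technologies.
#' @param cost_scale Common log-scale standard deviation (> 0).
#' @param storage_gb_range Named list of `c(min, max)` gigabyte intervals
#'   per technology; pair designs add a second germline footprint drawn
#'   from the same interval scaled by `pair_storage_fraction`.
#' @param pair_storage_fraction Germline share of the tumour footprint for
#'   pair designs (default 0.48, i.e. 72/150).
#' @param storage_tier Storage price tier name (see [storage_tiers()]).
#' @param storage_months Storage duration, months.
#' @param usd_per_aud Exchange rate used for storage conversion.
#' @param wage_rates Hourly wage levels (AUD, incl. overheads) sampled for
#'   labour items.
#' @param equipment_acquisition_location,equipment_scale Lognormal
#'   parameters for the instrument acquisition price.
#' @param annual_patients_range `c(min, max)` interval for annual
#'   instrument throughput (log-uniform).
#' @param n_patients_range `c(min, max)` interval for project size
#'   (log-uniform, rounded).
#' @param rework_rate Fraction of samples needing re-extraction, in
#'   \[0, 0.5\]; inflates every DNA-extraction item by `1 + rework_rate`.
#' @param seed Base seed; each generated project is deterministic given
#'   `(seed, index)`.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_projects = 6,
                             technology_mix = c(
                               panel = 1 / 3, exome = 1 / 3, genome = 1 / 3
                             ),
                             pair_probability = 0.5,
                             reporting_probability = 0.5,
                             cost_location = list(
                               sampling = log(25),
                               extraction_consumables = log(45),
                               extraction_qc = log(35),
                               extraction_hours = log(0.75),
                               libseq = c(
                                 panel = log(320), exome = log(1400),
                                 genome = log(3200)
                               ),
                               analysis_hours = log(2),
                               software = log(2),
                               reporting = log(30)
                             ),
                             cost_scale = 0.4,
                             storage_gb_range = list(
                               panel = c(2, 4), exome = c(10, 40),
                               genome = c(150, 250)
                             ),
                             pair_storage_fraction = 0.48,
                             storage_tier = "nearline",
                             storage_months = 60L,
                             usd_per_aud = 0.6929,
                             wage_rates = c(46.57, 51.86),
                             equipment_acquisition_location = log(4e5),
                             equipment_scale = 0.5,
                             annual_patients_range = c(100, 2000),
                             n_patients_range = c(3, 745),
                             rework_rate = 0.3,
                             seed = 1L) {
  technology_mix <- technology_mix[c("panel", "exome", "genome")]
  if (anyNA(technology_mix) ||
    abs(sum(technology_mix) - 1) > 1e-8 || any(technology_mix < 0)) {
    stop(
      "technology_mix must be non-negative probabilities over ",
      "panel/exome/genome summing to 1",
      call. = FALSE
    )
  }
  if (pair_probability < 0 || pair_probability > 1) {
    stop("pair_probability must be in [0, 1]", call. = FALSE)
  }
  if (cost_scale <= 0) stop("cost_scale must be positive", call. = FALSE)
  if (rework_rate < 0 || rework_rate > 0.5) {
    stop("rework_rate must be in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(
      n_projects = as.integer(n_projects),
      technology_mix = technology_mix,
      pair_probability = pair_probability,
      reporting_probability = reporting_probability,
      cost_location = cost_location,
      cost_scale = cost_scale,
      storage_gb_range = storage_gb_range,
      pair_storage_fraction = pair_storage_fraction,
      storage_tier = storage_tier,
      storage_months = as.integer(storage_months),
      usd_per_aud = usd_per_aud,
      wage_rates = wage_rates,
      equipment_acquisition_location = equipment_acquisition_location,
      equipment_scale = equipment_scale,
      annual_patients_range = annual_patients_range,
      n_patients_range = n_patients_range,
      rework_rate = rework_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_params"
  )
}

.runif_log <- function(range) exp(stats::runif(1, log(range[1]), log(range[2])))

#' Generate one synthetic sequencing project
#'
#' Draws a project deterministically from `(params$seed, index)`: a
#' technology tier, sample design and patient count, lognormal per-step
#' cost components (labour items are expressed as hours at a sampled wage
#' rate), a technology-dependent storage footprint priced through
#' [storage_cost_per_patient()], and a capital-equipment specification.
#' All DNA-extraction items (consumables, quality control, labour hours)
#' are inflated by `1 + rework_rate` to account for failed samples that
#' must be re-extracted and re-checked.
#'
#' @param params A [synthetic_params()] object.
#' @param index Project index (>= 1); the pair `(seed, index)` fully
#'   determines the output.
#' @return A [seq_project()].
#' @export
#' @examples
#' generate_project(synthetic_params(seed = 42), 1)
generate_project <- function(params, index = 1) {
  if (!inherits(params, "synthetic_params")) {
    stop("params must be a synthetic_params object", call. = FALSE)
  }
  if (index < 1 || index != round(index)) {
    stop("index must be a whole number >= 1", call. = FALSE)
  }
  seed_i <- (params$seed + 77003 * as.integer(index)) %% 2147483647L
  .with_seed(seed_i, .generate_project_impl(params, index, seed_i))
}

.generate_project_impl <- function(params, index, seed_i) {
  loc <- params$cost_location
  s <- params$cost_scale

  technology <- sample(
    c("panel", "exome", "genome"), 1,
    prob = params$technology_mix
  )
  pair <- stats::runif(1) < params$pair_probability
  clinical <- stats::runif(1) < params$reporting_probability
  n_patients <- max(1, round(.runif_log(params$n_patients_range)))
  wage <- sample(params$wage_rates, 1)

  draw <- function(meanlog) stats::rlnorm(1, meanlog, s)
  rework <- 1 + params$rework_rate

  sampling_cost <- draw(loc$sampling)
  second_sample_cost <- draw(loc$sampling) # consumed even when unused
  extraction_cons <- draw(loc$extraction_consumables) * rework
  extraction_qc <- draw(loc$extraction_qc) * rework
  extraction_hours <- draw(loc$extraction_hours) * rework
  libseq_cost <- draw(loc$libseq[[technology]])
  analysis_hours <- draw(loc$analysis_hours)
  software_cost <- draw(loc$software)
  reporting_cost <- draw(loc$reporting)

  gb_range <- params$storage_gb_range[[technology]]
  gb <- stats::runif(1, gb_range[1], gb_range[2])
  if (pair) gb <- gb * (1 + params$pair_storage_fraction)
  storage <- storage_spec(
    gb_per_patient = gb,
    usd_per_gb_month = storage_tier_price(params$storage_tier),
    months = params$storage_months,
    usd_per_aud = params$usd_per_aud
  )

  equipment <- equipment_spec(
    acquisition_price = stats::rlnorm(
      1, params$equipment_acquisition_location, params$equipment_scale
    ),
    annual_patients = .runif_log(params$annual_patients_range)
  )

  item <- function(label, step, cost_type, cost = NA_real_,
                   quantity = NA_real_, unit_price = NA_real_) {
    data.frame(
      label = label, step = step, cost_type = cost_type,
      per_patient_cost = cost, quantity = quantity,
      unit_price = unit_price, note = "", stringsAsFactors = FALSE
    )
  }
  rows <- list(
    item("sample collection", "sampling", "other", sampling_cost),
    if (pair) {
      item(
        "second sample collection (matched pair)", "sampling", "other",
        second_sample_cost
      )
    },
    item(
      "extraction consumables", "dna_extraction", "consumables",
      extraction_cons
    ),
    item(
      "extraction validation / quality control", "dna_extraction",
      "testing", extraction_qc
    ),
    item(
      "extraction labour", "dna_extraction", "labour",
      quantity = extraction_hours, unit_price = wage
    ),
    item(
      "library preparation and sequencing", "sequencing", "testing",
      libseq_cost
    ),
    item(
      "analysis labour", "analysis", "labour",
      quantity = analysis_hours, unit_price = wage
    ),
    item("computing software", "analysis", "equipment", software_cost),
    item(
      "data storage", "data_storage", "other",
      storage_cost_per_patient(storage)
    ),
    if (clinical) {
      item(
        "multidisciplinary team meeting", "clinician_reporting", "labour",
        reporting_cost
      )
    }
  )
  items <- validate_items(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))

  seq_project(
    name = sprintf("synthetic-%d-%d", params$seed, index),
    n_patients = n_patients,
    technology = technology,
    sample_design = if (pair) "tumour_germline_pair" else "germline_only",
    items = items,
    equipment = equipment,
    storage = storage,
    merge_lib_seq = TRUE,
    metadata = list(synthetic = TRUE, seed = seed_i, index = index)
  )
}

#' Generate a cohort of synthetic projects
#'
#' @param params A [synthetic_params()] object.
#' @return List of `params$n_projects` projects, deterministic in the seed.
#' @export
generate_projects <- function(params) {
  lapply(seq_len(params$n_projects), function(i) generate_project(params, i))
}
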