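test_that("fixture loading exposes the published component costs", {
  mel <- load_fixture("melanoma_exome")
  expect_equal(mel$n_patients, 383)
  expect_equal(
    mel$items$per_patient_cost[mel$items$step == "sampling"], 27.50
  )

  meso <- load_fixture("mesothelioma_genome")
  analysis_labour <- meso$items$per_patient_cost[
    meso$items$step == "analysis" & meso$items$cost_type == "labour"
  ]
  expect_equal(analysis_labour, 777.96)

  breast <- load_fixture("breast_panel")
  seq_testing <- breast$items$per_patient_cost[
    breast$items$step == "sequencing" & breast$items$cost_type == "testing"
  ]
  expect_equal(seq_testing, 79.67)

  expect_equal(
    unname(vapply(load_fixtures(), `[[`, numeric(1), "n_patients")),
    c(745, 192, 383, 10, 100, 3)
  )
  expect_error(load_fixture("colon_panel"), "valid names")
})

test_that("generation is deterministic in (seed, index)", {
  params <- synthetic_params(seed = 11)
  expect_identical(generate_project(params, 3), generate_project(params, 3))
  p1 <- generate_project(params, 1)
  p2 <- generate_project(params, 2)
  expect_false(identical(p1$items, p2$items))
  other_seed <- generate_project(synthetic_params(seed = 12), 1)
  expect_false(identical(p1$items, other_seed$items))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- stats::runif(1)
  set.seed(99)
  invisible(generate_project(synthetic_params(seed = 5), 1))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("the rework rate inflates extraction costs multiplicatively", {
  base <- synthetic_params(seed = 7, rework_rate = 0)
  reworked <- synthetic_params(seed = 7, rework_rate = 0.3)
  for (i in 1:5) {
    p0 <- generate_project(base, i)
    p3 <- generate_project(reworked, i)
    extraction <- function(p) {
      per_patient_breakdown(p)$per_step[["dna_extraction"]]
    }
    expect_equal(extraction(p3) / extraction(p0), 1.3, tolerance = 1e-12)
    # other steps unaffected
    expect_equal(
      per_patient_breakdown(p3)$per_step[["analysis"]],
      per_patient_breakdown(p0)$per_step[["analysis"]]
    )
  }
})

test_that("generated projects validate and round-trip through CSV", {
  params <- synthetic_params(seed = 21)
  for (i in 1:10) {
    p <- generate_project(params, i)
    report <- validate_breakdown(p)
    expect_true(all(report$pass), info = paste("project", i))
    shares <- step_shares(p)
    expect_true(all(per_patient_breakdown(p)$per_step >= 0))
    expect_equal(sum(shares), 100, tolerance = 0.2)

    path <- withr::local_tempfile(fileext = ".csv")
    write_inventory(p, path)
    back <- read_inventory(path)
    expect_equal(back, p$items, tolerance = 1e-12)
  }
})

test_that("pair designs carry a second sampling component", {
  params <- synthetic_params(seed = 31, pair_probability = 1)
  p <- generate_project(params, 1)
  expect_equal(p$sample_design, "tumour_germline_pair")
  expect_equal(sum(p$items$step == "sampling"), 2)
  none <- generate_project(
    synthetic_params(seed = 31, pair_probability = 0), 1
  )
  expect_equal(sum(none$items$step == "sampling"), 1)
})

test_that("technology tiers order the storage footprint", {
  mean_storage <- function(tech) {
    params <- synthetic_params(
      seed = 41,
      technology_mix = stats::setNames(
        as.numeric(c("panel", "exome", "genome") == tech),
        c("panel", "exome", "genome")
      ),
      pair_probability = 0
    )
    mean(vapply(1:40, function(i) {
      per_patient_breakdown(
        generate_project(params, i)
      )$per_step[["data_storage"]]
    }, numeric(1)))
  }
  expect_lt(mean_storage("panel"), mean_storage("exome"))
  expect_lt(mean_storage("exome"), mean_storage("genome"))
})

test_that("cohort means agree with the generator's closed-form expectation", {
  # single-technology, no pairs, no reporting or rework: the expected
  # operating total is a sum of independent lognormal means plus the
  # expected (uniform) storage cost
  params <- synthetic_params(
    seed = 51,
    technology_mix = c(panel = 0, exome = 1, genome = 0),
    pair_probability = 0, reporting_probability = 0, rework_rate = 0
  )
  totals <- vapply(1:1000, function(i) {
    per_patient_breakdown(generate_project(params, i))$total_excl_capital
  }, numeric(1))

  loc <- params$cost_location
  s2 <- params$cost_scale^2 / 2
  mean_wage <- mean(params$wage_rates)
  gb_mid <- mean(params$storage_gb_range$exome)
  expected <- exp(loc$sampling + s2) +
    exp(loc$extraction_consumables + s2) +
    exp(loc$extraction_qc + s2) +
    exp(loc$extraction_hours + s2) * mean_wage +
    exp(loc$libseq[["exome"]] + s2) +
    exp(loc$analysis_hours + s2) * mean_wage +
    exp(loc$software + s2) +
    gb_mid * storage_tier_price(params$storage_tier) *
      params$storage_months / params$usd_per_aud

  se <- stats::sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("synthetic parameter validation rejects degenerate settings", {
  expect_error(
    synthetic_params(technology_mix = c(panel = 0.5, exome = 0.2, genome = 0.2)),
    "summing to 1"
  )
  expect_error(synthetic_params(rework_rate = 0.9), "0.5")
  expect_error(synthetic_params(pair_probability = 2), "0, 1")
  expect_error(synthetic_params(cost_scale = 0), "positive")
  expect_error(generate_project(synthetic_params(), 0), "whole number")
})
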