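test_that("component_cost resolves both costing forms", {
  expect_equal(
    component_cost(resource_item("seq", "sequencing", "testing",
      per_patient_cost = 750
    )),
    750
  )
  expect_equal(
    component_cost(resource_item("idle", "analysis", "labour",
      quantity = 0, unit_price = 51.86
    )),
    0
  )
  expect_equal(
    component_cost(resource_item("extraction labour", "dna_extraction",
      "labour",
      quantity = 1.5, unit_price = 46.57
    )),
    1.5 * 46.57
  )
})

test_that("item validation rejects malformed line items", {
  expect_error(
    resource_item("bad", "dna_extraction", "labour"),
    "per_patient_cost or both"
  )
  expect_error(
    resource_item("neg", "sampling", "other", per_patient_cost = -1),
    "non-negative"
  )
  expect_error(
    resource_item("mismatch", "sampling", "other",
      per_patient_cost = 100, quantity = 2, unit_price = 10
    ),
    "disagrees"
  )
  expect_error(
    resource_item("x", "shipping", "other", per_patient_cost = 1),
    "unknown activity step"
  )
  expect_error(
    resource_item("x", "sampling", "overheads", per_patient_cost = 1),
    "unknown cost type"
  )
  # both forms allowed when they agree within 0.005 AUD
  expect_silent(
    resource_item("ok", "analysis", "labour",
      per_patient_cost = 69.855, quantity = 1.5, unit_price = 46.57
    )
  )
})

test_that("step and type labels are case-insensitive", {
  it <- resource_item("x", "Sampling", "Other", per_patient_cost = 1)
  expect_equal(it$step, "sampling")
  expect_equal(it$cost_type, "other")
})

test_that("fixture breakdowns reproduce the published per-patient totals", {
  for (nm in fixture_names()) {
    bd <- per_patient_breakdown(load_fixture(nm))
    expect_equal(
      bd$total_excl_capital, published_totals[[nm]],
      tolerance = 0.011, info = nm
    )
    # step conservation holds exactly on the encoded components
    expect_equal(sum(bd$per_step), bd$total_excl_capital, info = nm)
    expect_equal(
      bd$total_incl_capital,
      bd$total_excl_capital + bd$capital_per_patient,
      info = nm
    )
  }
})

test_that("merged projects report one combined library prep + sequencing row", {
  bd <- per_patient_breakdown(load_fixture("melanoma_exome"))
  expect_true("library_prep_and_sequencing" %in% names(bd$per_step))
  expect_false("sequencing" %in% names(bd$per_step))
  expect_equal(bd$per_step[["library_prep_and_sequencing"]], 750)

  unmerged <- per_patient_breakdown(load_fixture("breast_panel"))
  expect_true(all(c("library_preparation", "sequencing") %in%
    names(unmerged$per_step)))
  expect_equal(length(unmerged$per_step), 7)
})

test_that("absent steps are flagged distinctly from zero-cost steps", {
  bd <- per_patient_breakdown(load_fixture("melanoma_exome"))
  expect_false(bd$steps_present[["clinician_reporting"]])
  expect_equal(bd$per_step[["clinician_reporting"]], 0)
  # the lung/melanoma sampling item is present but costs zero
  bd2 <- per_patient_breakdown(load_fixture("lung_melanoma_panel"))
  expect_true(bd2$steps_present[["sampling"]])
  expect_equal(bd2$per_step[["sampling"]], 0)
})

test_that("an empty project yields an all-zero breakdown", {
  p <- tiny_project(tiny_item("void", "sampling", "other", 0))
  p$items <- p$items[0, ]
  bd <- per_patient_breakdown(p)
  expect_equal(bd$total_excl_capital, 0)
  expect_equal(bd$total_incl_capital, 0)
  expect_true(all(bd$per_step == 0))
  expect_error(step_shares(bd), "undefined")
})

test_that("step shares use the operating total and match printed cells", {
  for (nm in names(published_shares)) {
    shares <- step_shares(per_patient_breakdown(load_fixture(nm)))
    for (step in names(published_shares[[nm]])) {
      expect_lt(
        abs(unname(shares[[step]]) - published_shares[[nm]][[step]]),
        0.1,
        label = paste(nm, step, "share deviation")
      )
    }
    expect_equal(sum(shares), 100, tolerance = 1e-9, info = nm)
  }
})

test_that("a single-item project has a 100% share", {
  p <- tiny_project(tiny_item("only", "sequencing", "testing", 123.45))
  expect_equal(unname(step_shares(p)[["sequencing"]]), 100)
})

test_that("type breakdown reproduces the published type table", {
  types <- type_breakdown(load_fixture("melanoma_exome"))
  expect_equal(types[["testing"]], 782.91)
  expect_equal(types[["labour"]], 31.15)
  expect_equal(types[["consumables"]], 19.28)
  # equipment row carries capital; type totals sum to the capital-inclusive
  # total
  bd <- per_patient_breakdown(load_fixture("melanoma_exome"))
  expect_equal(sum(types), bd$total_incl_capital, tolerance = 1e-9)

  solo <- tiny_project(tiny_item("kit", "dna_extraction", "consumables", 42))
  tt <- type_breakdown(solo)
  expect_equal(tt[["consumables"]], 42)
  expect_equal(sum(tt[setdiff(names(tt), "consumables")]), 0)
})

test_that("storage cost accumulates monthly USD charges and converts to AUD", {
  expect_equal(
    storage_cost_per_patient(storage_spec(0, 0.01, 60, 0.6929)), 0
  )
  expect_equal(
    storage_cost_per_patient(storage_spec(100, 0.01, 60, 0.6929)),
    100 * 0.01 * 60 / 0.6929
  )
  base <- storage_cost_per_patient(storage_spec(50, 0.01, 60, 0.6929))
  regional <- storage_cost_per_patient(storage_spec(50, 0.025, 60, 0.6929))
  expect_equal(regional / base, 2.5)
  expect_error(storage_spec(10, 0.01, 60, 0), "exchange rate")
})

test_that("currency conversion matches the published parentheticals", {
  expect_equal(aud_to_usd(0), 0)
  expect_equal(round(aud_to_usd(4829.76, 0.6929)), 3347)
  expect_equal(round(aud_to_usd(2895.19, 0.6929)), 2006)
  expect_error(aud_to_usd(10, -1), "positive")
})

test_that("cross-project summary reproduces the published mean shares", {
  s <- cross_project_summary(load_fixtures())$shares
  row <- function(step) s[s$step == step, ]
  expect_equal(round(row("library_prep_and_sequencing")$mean, 1), 76.8)
  expect_equal(round(row("library_prep_and_sequencing")$min, 1), 56.3)
  expect_equal(round(row("library_prep_and_sequencing")$max, 1), 86.7)
  expect_equal(round(row("dna_extraction")$mean, 1), 8.1)
  expect_equal(round(row("analysis")$mean, 1), 9.2)

  single <- cross_project_summary(list(load_fixture("breast_panel")))
  expect_equal(
    single$shares$min, single$shares$max,
    info = "degenerate range for one project"
  )
  expect_error(cross_project_summary(list()), "at least one")
})

test_that("scaling every item cost by k scales totals and preserves shares", {
  p <- load_fixture("lung_exome")
  k <- 3.7
  scaled <- p
  scaled$items$per_patient_cost <- scaled$items$per_patient_cost * k
  bd <- per_patient_breakdown(p)
  bd_k <- per_patient_breakdown(scaled)
  expect_equal(bd_k$total_excl_capital, k * bd$total_excl_capital)
  expect_equal(bd_k$step_shares, bd$step_shares)
})
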