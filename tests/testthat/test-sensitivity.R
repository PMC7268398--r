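test_that("apply_scenario perturbs only the selected components", {
  p <- load_fixture("breast_panel")
  p2 <- apply_scenario(p, item_selector(step = "data_storage"), 2.5)
  expect_equal(
    per_patient_breakdown(p2)$per_step[["data_storage"]], 1.96 * 2.5
  )
  # everything else untouched, original unmodified
  expect_equal(
    per_patient_breakdown(p2)$per_step[["sampling"]],
    per_patient_breakdown(p)$per_step[["sampling"]]
  )
  expect_equal(per_patient_breakdown(p)$per_step[["data_storage"]], 1.96)

  oes <- apply_scenario(
    load_fixture("oesophageal_genome"),
    item_selector(step = "library_prep_and_sequencing"), 0.9
  )
  expect_equal(
    per_patient_breakdown(oes)$per_step[["library_prep_and_sequencing"]],
    4188.60 * 0.9
  )
})

test_that("identity and invalid scenarios behave as specified", {
  p <- load_fixture("melanoma_exome")
  same <- apply_scenario(p, item_selector(cost_type = "labour"), 1.0)
  expect_equal(
    per_patient_breakdown(same)$total_incl_capital,
    per_patient_breakdown(p)$total_incl_capital
  )
  expect_equal(
    relative_total_change(p, item_selector(cost_type = "labour"), 1.0), 0
  )
  expect_error(
    apply_scenario(p, item_selector(step = "clinician_reporting"), 1.1),
    "matched no items"
  )
  expect_error(
    apply_scenario(p, item_selector(cost_type = "labour"), -2),
    "positive"
  )
  expect_error(item_selector(), "empty selector")
})

test_that("absolute replacement overrides the matched item cost", {
  p <- load_fixture("breast_panel")
  p2 <- apply_scenario(
    p, item_selector(step = "data_storage"),
    replace = 10
  )
  expect_equal(per_patient_breakdown(p2)$per_step[["data_storage"]], 10)
})

test_that("relative changes use the capital-inclusive total", {
  p <- load_fixture("lung_melanoma_panel")
  bd <- per_patient_breakdown(p)
  libseq <- bd$per_step[["library_prep_and_sequencing"]]
  expect_equal(
    relative_total_change(
      p, item_selector(step = "library_prep_and_sequencing"), 0.9
    ),
    -100 * 0.1 * libseq / bd$total_incl_capital
  )
  expect_equal(
    relative_total_change(
      load_fixture("oesophageal_genome"),
      item_selector(step = "data_storage"), 2.5
    ),
    6.6,
    tolerance = 0.05 / 6.6
  )
})

test_that("cross-project sensitivity summarises unweighted changes", {
  fx <- load_fixtures()
  sel <- item_selector(step = "library_prep_and_sequencing")
  res <- cross_project_sensitivity(fx, sel, 0.9)
  expect_equal(length(res$per_project), 6)
  expect_equal(res$mean, mean(res$per_project))
  expect_equal(round(res$mean, 1), -7.2)

  lab <- cross_project_sensitivity(fx, item_selector(cost_type = "labour"), 1.2)
  expect_equal(round(lab$min, 1), 0.5)
  expect_equal(round(lab$max, 1), 5.4)

  one <- cross_project_sensitivity(fx[1], sel, 0.9)
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  expect_error(cross_project_sensitivity(list(), sel, 0.9), "at least one")
})

test_that("multiplicative perturbations are linear in the component share", {
  params <- synthetic_params(seed = 404)
  for (i in 1:25) {
    p <- generate_project(params, i)
    bd <- per_patient_breakdown(p)
    sel <- item_selector(step = "dna_extraction")
    share <- bd$per_step[["dna_extraction"]] / bd$total_incl_capital
    for (f in c(0.7, 0.9, 1.3)) {
      expect_equal(
        relative_total_change(p, sel, f),
        100 * (f - 1) * share,
        tolerance = 1e-9
      )
    }
  }
})

test_that("symmetric perturbations give equal and opposite changes", {
  params <- synthetic_params(seed = 405)
  sel <- item_selector(cost_type = "labour")
  for (i in 1:25) {
    p <- generate_project(params, i)
    up <- relative_total_change(p, sel, 1.2)
    down <- relative_total_change(p, sel, 0.8)
    expect_equal(up, -down, tolerance = 1e-9)
  }
})

test_that("tornado rows are sorted by swing with deterministic tie-breaks", {
  p <- load_fixture("oesophageal_genome")
  tt <- tornado(p)
  expect_s3_class(tt, "tornado_table")
  expect_true(all(diff(tt$swing) <= 0))
  # the combined library prep + sequencing price dominates
  expect_match(tt$parameter[1], "library preparation")
  expect_equal(tt$swing, abs(tt$total_high - tt$total_low))
  # baseline lies between the arms for monotone perturbations
  expect_true(all(
    tt$baseline_total >= pmin(tt$total_low, tt$total_high) - 1e-9 &
      tt$baseline_total <= pmax(tt$total_low, tt$total_high) + 1e-9
  ))
  # byte-identical on repeat runs
  expect_identical(tt, tornado(p))

  single <- tornado(p, list(
    scenario("only", item_selector(cost_type = "labour"), 0.8, 1.2)
  ))
  expect_equal(nrow(single), 1)
  expect_equal(single$swing, abs(single$total_high - single$total_low))

  ties <- tornado(p, list(
    scenario("b-identity", item_selector(cost_type = "labour"), 1, 1),
    scenario("a-identity", item_selector(step = "data_storage"), 1, 1)
  ))
  expect_equal(ties$swing, c(0, 0))
  expect_equal(ties$parameter, c("a-identity", "b-identity"))
})

test_that("storage-tier scenarios scale a storage_spec when no item exists", {
  p <- tiny_project(
    tiny_item("seq", "sequencing", "testing", 100),
    technology = "genome"
  )
  p$storage <- storage_spec(100, 0.01, 60, 0.6929)
  base <- per_patient_breakdown(p)$per_step[["data_storage"]]
  p2 <- apply_scenario(p, item_selector(step = "data_storage"), 2.5)
  expect_equal(
    per_patient_breakdown(p2)$per_step[["data_storage"]], base * 2.5
  )
})
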