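#' Read a project inventory CSV
#'
#' The inventory dialect is a UTF-8 comma-separated table with a header
#' row and columns `label`, `step`, `cost_type`, and either
#' `per_patient_cost` or `quantity` + `unit_price` (an optional `note`
#' column is kept). Column names and step/type labels are
#' case-insensitive.
#'
#' @param path Path to the CSV file.
#' @return A validated item table (see [validate_items()]).
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) {
    stop("inventory file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(
    path,
    stringsAsFactors = FALSE, encoding = "UTF-8",
    colClasses = NA
  )
  names(raw) <- tolower(names(raw))
  if (!nrow(raw)) {
    stop("inventory file is empty: ", path, call. = FALSE)
  }
  validate_items(raw)
}

#' Write a project inventory CSV
#'
#' @param items Item table (or a [seq_project()], whose items are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(items, path) {
  if (inherits(items, "seq_project")) items <- items$items
  items <- validate_items(items)
  utils::write.csv(items, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a project configuration document
#'
#' A YAML document describing one project: metadata (`name`, `n_patients`,
#' `technology`, `sample_design`, `merge_lib_seq`), its items (inline under
#' `items:` or in a CSV referenced by `inventory:`, resolved relative to
#' the config file), and optional `equipment` and `storage` blocks. The
#' equipment block gives either directly-specified per-patient charges
#' (`machine_per_patient`, `maintenance_per_patient`) or the full
#' annuitization inputs (`acquisition_price`, `useful_life_years`,
#' `interest_rate`, `annual_patients`, `maintenance_ratio`).
#'
#' @param path Path to the YAML file.
#' @return A [seq_project()].
#' @export
read_project_config <- function(path) {
  if (!file.exists(path)) {
    stop("project config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "n_patients", "technology", "sample_design")) {
    if (is.null(cfg[[field]])) {
      stop(
        "project config ", path, " is missing required field '", field, "'",
        call. = FALSE
      )
    }
  }
  if (!is.null(cfg$items)) {
    items <- do.call(rbind, lapply(cfg$items, function(it) {
      data.frame(
        label = it$label %||% stop(
          "config item without a label in ", path,
          call. = FALSE
        ),
        step = it$step,
        cost_type = it$cost_type,
        per_patient_cost = as.numeric(it$per_patient_cost %||% NA),
        quantity = as.numeric(it$quantity %||% NA),
        unit_price = as.numeric(it$unit_price %||% NA),
        note = it$note %||% "",
        stringsAsFactors = FALSE
      )
    }))
  } else if (!is.null(cfg$inventory)) {
    inv_path <- cfg$inventory
    if (!file.exists(inv_path)) {
      inv_path <- file.path(dirname(path), cfg$inventory)
    }
    items <- read_inventory(inv_path)
  } else {
    stop(
      "project config ", path, " must provide 'items' or 'inventory'",
      call. = FALSE
    )
  }

  equipment <- NULL
  if (!is.null(cfg$equipment)) {
    eq <- cfg$equipment
    if (!is.null(eq$machine_per_patient)) {
      equipment <- capital_costs(
        machine_per_patient = eq$machine_per_patient,
        maintenance_per_patient = eq$maintenance_per_patient %||%
          (0.5 * eq$machine_per_patient)
      )
    } else if (!is.null(eq$acquisition_price)) {
      equipment <- equipment_spec(
        acquisition_price = eq$acquisition_price,
        useful_life_years = eq$useful_life_years %||% 5L,
        interest_rate = eq$interest_rate %||% 0.03,
        annual_patients = eq$annual_patients %||% stop(
          "equipment block needs annual_patients when given an ",
          "acquisition_price",
          call. = FALSE
        ),
        maintenance_ratio = eq$maintenance_ratio %||% 0.5
      )
    } else {
      stop(
        "equipment block in ", path, " needs machine_per_patient or ",
        "acquisition_price",
        call. = FALSE
      )
    }
  }

  storage <- NULL
  if (!is.null(cfg$storage)) {
    st <- cfg$storage
    price <- st$usd_per_gb_month %||%
      storage_tier_price(st$tier %||% "nearline")
    storage <- storage_spec(
      gb_per_patient = st$gb_per_patient %||% stop(
        "storage block in ", path, " needs gb_per_patient",
        call. = FALSE
      ),
      usd_per_gb_month = price,
      months = st$months %||% 60L,
      usd_per_aud = st$usd_per_aud %||% cfg$currency$usd_per_aud %||% 0.6929
    )
  }

  seq_project(
    name = cfg$name,
    n_patients = cfg$n_patients,
    technology = cfg$technology,
    sample_design = cfg$sample_design,
    items = items,
    equipment = equipment,
    storage = storage,
    merge_lib_seq = isTRUE(cfg$merge_lib_seq),
    metadata = cfg$metadata %||% list()
  )
}

#' Write a project configuration document
#'
#' Serialises a project to the YAML dialect read by
#' [read_project_config()], with items inline.
#'
#' @param project A [seq_project()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_project_config <- function(project, path) {
  stopifnot(inherits(project, "seq_project"))
  items <- lapply(seq_len(nrow(project$items)), function(i) {
    row <- as.list(project$items[i, ])
    row <- row[!vapply(row, function(v) is.na(v) || identical(v, ""), logical(1))]
    row
  })
  cfg <- list(
    name = project$name,
    n_patients = project$n_patients,
    technology = project$technology,
    sample_design = project$sample_design,
    merge_lib_seq = project$merge_lib_seq,
    items = items
  )
  if (inherits(project$equipment, "capital_costs")) {
    cfg$equipment <- unclass(project$equipment)
  } else if (inherits(project$equipment, "equipment_spec")) {
    cfg$equipment <- unclass(project$equipment)
  }
  if (inherits(project$storage, "storage_spec")) {
    cfg$storage <- unclass(project$storage)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a sensitivity scenario file
#'
#' YAML list of scenarios, each with `name`, a `selector` block (`step`,
#' `cost_type`, `label_pattern`) and `low` / `high` factors.
#'
#' @param path Path to the YAML file.
#' @return List of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) {
    stop("scenario file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("scenario file ", path, " is empty", call. = FALSE)
  lapply(raw, function(sc) {
    if (is.null(sc$name)) {
      stop("scenario without a 'name' in ", path, call. = FALSE)
    }
    if (is.null(sc$selector)) {
      stop(
        "scenario '", sc$name, "' is missing its 'selector' block",
        call. = FALSE
      )
    }
    if (is.null(sc$low)) {
      stop(
        "scenario '", sc$name, "' is missing its 'low' factor",
        call. = FALSE
      )
    }
    scenario(
      name = sc$name,
      selector = item_selector(
        step = sc$selector$step,
        cost_type = sc$selector$cost_type,
        label_pattern = sc$selector$label_pattern
      ),
      low = sc$low,
      high = sc$high %||% sc$low
    )
  })
}

#' Export the packaged fixtures as inventory CSVs
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
export_fixture_inventories <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(fixture_names(), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_inventory(load_fixture(nm), p)
    p
  }, character(1))
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
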