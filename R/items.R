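#' Construct a resource line item
#'
#' A resource item is one costed line of a project inventory: a label, the
#' workflow step it belongs to, its cost type, and either a direct
#' per-patient cost or a quantity with a unit price (e.g. hours of staff
#' time at an hourly wage). Costs are in AUD per patient; for matched
#' tumour/germline designs the per-patient value already covers both
#' samples and is never doubled downstream.
#'
#' @param label Free-text description of the item.
#' @param step Activity step label (see [activity_steps()]); case-insensitive.
#' @param cost_type One of [cost_types()]; case-insensitive.
#' @param per_patient_cost Direct cost in AUD per patient (>= 0).
#' @param quantity Units consumed per patient (e.g. hours), >= 0.
#' @param unit_price Price in AUD per unit, >= 0.
#' @param note Optional free-text annotation.
#' @return A one-row data frame of class `resource_item`.
#' @export
#' @examples
#' resource_item("extraction labour", "dna_extraction", "labour",
#'   quantity = 1.5, unit_price = 46.57
#' )
resource_item <- function(label, step, cost_type, per_patient_cost = NA_real_,
                          quantity = NA_real_, unit_price = NA_real_,
                          note = "") {
  item <- data.frame(
    label = as.character(label),
    step = .normalize_step(step),
    cost_type = .normalize_cost_type(cost_type),
    per_patient_cost = as.numeric(per_patient_cost),
    quantity = as.numeric(quantity),
    unit_price = as.numeric(unit_price),
    note = as.character(note),
    stringsAsFactors = FALSE
  )
  class(item) <- c("resource_item", class(item))
  validate_items(item)
  item
}

.item_columns <- c(
  "label", "step", "cost_type", "per_patient_cost", "quantity",
  "unit_price", "note"
)

#' Assemble an item table from individual items
#'
#' @param ... `resource_item` rows or data frames with item columns.
#' @return A data frame with one row per item.
#' @export
resource_items <- function(...) {
  items <- do.call(rbind, lapply(list(...), as.data.frame))
  validate_items(items)
}

#' Validate an item table
#'
#' Checks that every row names a canonical step and cost type, that exactly
#' one costing form is populated (direct per-patient cost, or quantity with
#' unit price) or that both forms agree within 0.005 AUD, and that all
#' monetary values are finite and non-negative.
#'
#' @param items Data frame of resource items.
#' @return The validated item table, with normalised labels, invisibly
#'   usable downstream.
#' @export
validate_items <- function(items) {
  if (!is.data.frame(items)) {
    stop("items must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(c("label", "step", "cost_type"), names(items))
  if (length(missing_cols)) {
    stop(
      "item table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in setdiff(.item_columns, names(items))) {
    items[[col]] <- if (col == "note") "" else NA_real_
  }
  items <- items[, .item_columns]
  for (col in c("per_patient_cost", "quantity", "unit_price")) {
    items[[col]] <- as.numeric(items[[col]])
  }
  items$step <- .normalize_step(items$step)
  items$cost_type <- .normalize_cost_type(items$cost_type)
  items$note[is.na(items$note)] <- ""

  for (i in seq_len(nrow(items))) {
    row <- items[i, ]
    has_direct <- !is.na(row$per_patient_cost)
    has_qty <- !is.na(row$quantity) && !is.na(row$unit_price)
    if (!has_direct && !has_qty) {
      stop(
        "item '", row$label, "': provide per_patient_cost or both ",
        "quantity and unit_price",
        call. = FALSE
      )
    }
    vals <- c(row$per_patient_cost, row$quantity, row$unit_price)
    vals <- vals[!is.na(vals)]
    if (any(!is.finite(vals)) || any(vals < 0)) {
      stop(
        "item '", row$label, "': costs and quantities must be finite ",
        "and non-negative",
        call. = FALSE
      )
    }
    if (has_direct && has_qty) {
      implied <- row$quantity * row$unit_price
      if (abs(implied - row$per_patient_cost) > 0.005) {
        stop(
          "item '", row$label, "': per_patient_cost (",
          format(row$per_patient_cost), ") disagrees with quantity x ",
          "unit_price (", format(implied), ") by more than 0.005 AUD",
          call. = FALSE
        )
      }
    }
  }
  items
}

#' Per-patient cost of one resource item
#'
#' Returns the direct per-patient cost when given, otherwise
#' `quantity * unit_price`. All arithmetic is kept at full floating
#' precision; rounding happens only when rendering tables.
#'
#' @param item A `resource_item` (or any one-row data frame / list with the
#'   item fields).
#' @return Cost in AUD per patient (never negative).
#' @export
#' @examples
#' component_cost(resource_item("sequencing", "sequencing", "testing",
#'   per_patient_cost = 750
#' ))
component_cost <- function(item) {
  if (is.data.frame(item)) {
    if (nrow(item) != 1) {
      return(vapply(seq_len(nrow(item)), function(i) {
        component_cost(item[i, ])
      }, numeric(1)))
    }
    item <- as.list(item)
  }
  direct <- item$per_patient_cost
  if (!is.null(direct) && !is.na(direct)) {
    if (!is.finite(direct) || direct < 0) {
      stop(
        "item '", item$label, "': per_patient_cost must be finite and ",
        "non-negative",
        call. = FALSE
      )
    }
    return(as.numeric(direct))
  }
  qty <- item$quantity
  price <- item$unit_price
  if (is.null(qty) || is.null(price) || is.na(qty) || is.na(price)) {
    stop(
      "item '", item$label, "': provide per_patient_cost or both ",
      "quantity and unit_price",
      call. = FALSE
    )
  }
  if (qty < 0 || price < 0 || !is.finite(qty) || !is.finite(price)) {
    stop(
      "item '", item$label, "': quantity and unit_price must be finite ",
      "and non-negative",
      call. = FALSE
    )
  }
  as.numeric(qty) * as.numeric(price)
}
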