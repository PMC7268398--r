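# rendering helpers: all arithmetic upstream is full precision; these are
# the only places values are rounded (2 dp AUD, whole USD, 1 dp percents)

.fmt_aud <- function(x) sprintf("%.2f", x)
.fmt_usd <- function(x) sprintf("%d", round(x))
.fmt_pct <- function(x) sprintf("%.1f%%", x)

#' Step-level cost table for one project
#'
#' One row per activity step (merged projects get a combined library
#' preparation + sequencing row): per-patient AUD cost, USD equivalent,
#' and the step's share of the operating total. Steps with no items render
#' as `"n/a"` rather than `0.0%`.
#'
#' @param breakdown A `cost_breakdown` or [seq_project()].
#' @param usd_per_aud Exchange rate for the USD column.
#' @return Data frame with columns `step`, `aud_per_patient`,
#'   `usd_per_patient`, `pct_of_total` (character; `"n/a"` for absent
#'   steps).
#' @export
step_table <- function(breakdown, usd_per_aud = 0.6929) {
  if (inherits(breakdown, "seq_project")) {
    breakdown <- per_patient_breakdown(breakdown)
  }
  data.frame(
    step = names(breakdown$per_step),
    aud_per_patient = round(breakdown$per_step, 2),
    usd_per_patient = round(aud_to_usd(breakdown$per_step, usd_per_aud)),
    pct_of_total = ifelse(
      breakdown$steps_present,
      .fmt_pct(breakdown$step_shares),
      "n/a"
    ),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Cost-type table for one project
#'
#' One row per cost type (labour, consumables, testing, equipment, other);
#' the equipment row includes the annuitized capital charge so the column
#' sums to the capital-inclusive total.
#'
#' @inheritParams step_table
#' @return Data frame with columns `cost_type`, `aud_per_patient`,
#'   `usd_per_patient`, `pct_of_total`.
#' @export
type_table <- function(breakdown, usd_per_aud = 0.6929) {
  if (inherits(breakdown, "seq_project")) {
    breakdown <- per_patient_breakdown(breakdown)
  }
  per_type <- breakdown$per_type
  total <- breakdown$total_incl_capital
  data.frame(
    cost_type = names(per_type),
    aud_per_patient = round(per_type, 2),
    usd_per_patient = round(aud_to_usd(per_type, usd_per_aud)),
    pct_of_total = .fmt_pct(100 * per_type / total),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Render a data frame as a markdown pipe table
#'
#' @param df A data frame.
#' @return Character vector of markdown lines.
#' @export
render_markdown <- function(df) {
  cells <- vapply(df, function(col) format(col, trim = TRUE), FUN.VALUE = character(nrow(df)))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  header <- names(df)
  widths <- pmax(
    nchar(header),
    if (nrow(df)) apply(nchar(cells), 2, max) else 0
  )
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  line <- function(row) {
    paste0("| ", paste(mapply(pad, row, widths), collapse = " | "), " |")
  }
  c(
    line(header),
    line(vapply(widths, function(w) strrep("-", w), character(1))),
    if (nrow(df)) apply(cells, 1, line)
  )
}

#' Full per-project cost report as text lines
#'
#' Mirrors the published layout: the step table, the capital block
#' (machine, maintenance, add-on percentage) and per-person totals with
#' and without capital, in AUD with USD parentheticals.
#'
#' @inheritParams step_table
#' @return Character vector of markdown lines.
#' @export
breakdown_report <- function(breakdown, usd_per_aud = 0.6929) {
  if (inherits(breakdown, "seq_project")) {
    breakdown <- per_patient_breakdown(breakdown)
  }
  both <- function(aud) {
    paste0(
      "AU$", .fmt_aud(aud),
      " (US$", .fmt_usd(aud_to_usd(aud, usd_per_aud)), ")"
    )
  }
  c(
    paste0("## ", breakdown$project, " (n = ", breakdown$n_patients, ")"),
    "",
    render_markdown(step_table(breakdown, usd_per_aud)),
    "",
    paste0(
      "TOTAL per person: ", both(breakdown$total_excl_capital)
    ),
    "",
    "Capital costs:",
    paste0("  - sequencing machine: AU$", .fmt_aud(breakdown$machine_per_patient)),
    paste0("  - maintenance:        AU$", .fmt_aud(breakdown$maintenance_per_patient)),
    paste0(
      "  - total: AU$", .fmt_aud(breakdown$capital_per_patient),
      " (", .fmt_pct(breakdown$capital_addon_percent),
      " extra from total per person)"
    ),
    "",
    paste0(
      "TOTAL per person including capital: ",
      both(breakdown$total_incl_capital)
    ),
    "",
    render_markdown(type_table(breakdown, usd_per_aud)),
    paste0("(exchange rate: ", format(usd_per_aud), " USD per AUD)")
  )
}

#' Write a project's breakdown tables to files
#'
#' Writes `<name>_steps.csv` / `<name>_types.csv` and/or `<name>.md` under
#' `dir`. CSV and markdown are rendered from the same numeric tables.
#'
#' @inheritParams step_table
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
write_breakdown <- function(breakdown, dir, formats = c("csv", "markdown"),
                            usd_per_aud = 0.6929) {
  if (inherits(breakdown, "seq_project")) {
    breakdown <- per_patient_breakdown(breakdown)
  }
  formats <- match.arg(formats, c("csv", "markdown"), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slug <- gsub("[^a-z0-9]+", "_", tolower(breakdown$project))
  written <- character(0)
  if ("csv" %in% formats) {
    p1 <- file.path(dir, paste0(slug, "_steps.csv"))
    utils::write.csv(step_table(breakdown, usd_per_aud), p1, row.names = FALSE)
    p2 <- file.path(dir, paste0(slug, "_types.csv"))
    utils::write.csv(type_table(breakdown, usd_per_aud), p2, row.names = FALSE)
    written <- c(written, p1, p2)
  }
  if ("markdown" %in% formats) {
    p3 <- file.path(dir, paste0(slug, ".md"))
    writeLines(breakdown_report(breakdown, usd_per_aud), p3)
    written <- c(written, p3)
  }
  invisible(written)
}

#' @export
print.tornado_table <- function(x, ...) {
  cat("<tornado_table> ", attr(x, "project") %||% "", "\n", sep = "")
  df <- as.data.frame(x)
  df$baseline_total <- round(df$baseline_total, 2)
  df$total_low <- round(df$total_low, 2)
  df$total_high <- round(df$total_high, 2)
  df$swing <- round(df$swing, 2)
  df$relative_change_low <- round(df$relative_change_low, 1)
  df$relative_change_high <- round(df$relative_change_high, 1)
  print(df, row.names = FALSE)
  invisible(x)
}
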