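# Report rendering: published-table-shaped comparisons and machine outputs.
# Whole-SEK half-up rounding is applied here and only here; machine CSV/JSON
# outputs keep full precision.

REPORT_ROWS <- list(
  contacts = "Contacts/Visits/Sessions",
  administration = "Administration",
  training = "Training of providers",
  transportation = "Transportation",
  direct_fees = "Direct costs",
  emissions = "CO2 emissions"
)

# Sum a breakdown's items into presentation rows: technical support is
# displayed inside Administration, matching the published table layout.
presentation_lines <- function(b) {
  it <- b$items
  it$category[it$category == "technical_support"] <- "administration"
  lines <- list()
  for (d in COST_DOMAINS) {
    for (cat in names(REPORT_ROWS)) {
      tot <- sum(it$total[it$domain == d & it$category == cat])
      rows_exist <- any(it$domain == d & it$category == cat)
      if (rows_exist) {
        lines[[paste(d, cat, sep = ".")]] <- tot
      }
    }
    lines[[paste(d, "subtotal", sep = ".")]] <- get_subtotal(b, d)
  }
  lines[["total"]] <- b$total
  lines
}

#' Render a published-table-shaped cost comparison
#'
#' Builds a comparison table of one or more cost breakdowns with per-domain
#' line items, domain subtotals, a grand total, and (for exactly two models)
#' a difference row. All values are presentation-rounded to whole SEK
#' (half-up). Optionally written to CSV.
#'
#' @param breakdowns A single `cost_breakdown` or a list of them.
#' @param path Optional CSV output path.
#' @return A tibble with columns `domain`, `item`, one column per model, and
#'   (two models) `difference`.
#' @examples
#' ctx <- read_valuation_context(oacost_example("valuation.yaml"))
#' boa <- cost_model(read_care_model(oacost_example("boa.yaml")), ctx)
#' ja <- cost_model(read_care_model(oacost_example("ja.yaml")), ctx)
#' render_breakdown_report(list(boa, ja))
#' @export
render_breakdown_report <- function(breakdowns, path = NULL) {
  if (inherits(breakdowns, "cost_breakdown")) breakdowns <- list(breakdowns)
  if (length(breakdowns) < 1) abort_validation("need at least one breakdown")
  stopifnot(all(vapply(breakdowns, inherits, TRUE, "cost_breakdown")))
  all_lines <- lapply(breakdowns, presentation_lines)
  keys <- unique(unlist(lapply(all_lines, names)))
  split_key <- strsplit(keys, ".", fixed = TRUE)
  tab <- tibble::tibble(
    domain = vapply(split_key, function(k) if (length(k) == 2) k[1] else "", ""),
    item = vapply(split_key, function(k) {
      if (length(k) == 1) {
        "Total"
      } else if (k[2] == "subtotal") {
        "Sub-total"
      } else {
        REPORT_ROWS[[k[2]]]
      }
    }, "")
  )
  for (i in seq_along(breakdowns)) {
    vals <- vapply(keys, function(k) {
      v <- all_lines[[i]][[k]]
      if (is.null(v)) NA_real_ else round_half_up(v)
    }, numeric(1))
    tab[[breakdowns[[i]]$model_name]] <- unname(vals)
  }
  if (length(breakdowns) == 2L) {
    tab$difference <- tab[[3]] - tab[[4]]
  }
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  tab
}

#' Write a cost breakdown as machine-readable CSV
#'
#' Items at full precision (columns `domain`, `category`, `quantity_hours`,
#' `unit_value`, `total`) followed by subtotal and total summary rows.
#'
#' @param breakdown A `cost_breakdown`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_breakdown_csv <- function(breakdown, path) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  it <- as.data.frame(breakdown$items)
  summary_rows <- data.frame(
    domain = c(COST_DOMAINS, "all"),
    category = c(rep("subtotal", 3), "total"),
    quantity_hours = NA_real_, unit_value = NA_real_,
    total = c(breakdown$subtotal_system, breakdown$subtotal_patient,
              breakdown$subtotal_other, breakdown$total)
  )
  utils::write.csv(rbind(it, summary_rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a cost breakdown as JSON
#'
#' The JSON record embeds the full resolved valuation parameter set alongside
#' the items and totals, so a report is self-describing (no hidden defaults).
#'
#' @param breakdown A `cost_breakdown`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_breakdown_json <- function(breakdown, path) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  out <- list(
    model_name = breakdown$model_name,
    items = breakdown$items,
    subtotals = list(system = breakdown$subtotal_system,
                     patient = breakdown$subtotal_patient,
                     other = breakdown$subtotal_other),
    total = breakdown$total,
    parameters = if (!is.null(breakdown$context)) unclass(breakdown$context)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a scenario grid as CSV
#'
#' @param grid A [scenario_grid()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort as CSV
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert SEK to USD or EUR at the context's report rates
#'
#' @param sek Amount in SEK.
#' @param ctx A [valuation_context()].
#' @param to `"USD"` or `"EUR"`.
#' @return Converted amount.
#' @export
convert_sek <- function(sek, ctx, to = c("USD", "EUR")) {
  to <- match.arg(to)
  stopifnot(inherits(ctx, "valuation_context"))
  rate <- switch(to, USD = ctx$fx_usd_per_100_sek, EUR = ctx$fx_eur_per_100_sek)
  sek * rate / 100
}
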