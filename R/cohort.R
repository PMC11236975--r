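# Cohort aggregation: per-criterion counts over many study verdicts, and the
# survey-table renderer.

#' Round half-up at a given number of decimals
#'
#' Plain half-up rounding (34.45 -> 34.5), as used for the printed survey
#' percentages, rather than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Aggregate study verdicts into a cohort summary
#'
#' Counts, for every criterion of the registry, how many studies it applied
#' to and how many passed. Indeterminate verdicts (applicable but
#' undecidable) are excluded from all three counts, mirroring survey tables
#' whose denominators vary by criterion. Verdicts computed under different
#' configurations are refused.
#'
#' @param verdicts A list of `study_verdict` objects (or a single one).
#' @return A `cohort_summary` tibble: `criterion_id`, `label`, `table_ref`,
#'   `n_pass`, `n_fail`, `n_applicable`, `pct_pass` (half-up, one decimal;
#'   `NA` when no study was applicable).
#' @export
aggregate_verdicts <- function(verdicts) {
  if (inherits(verdicts, "study_verdict")) verdicts <- list(verdicts)
  stopifnot(length(verdicts) > 0, all(map_lgl(verdicts, inherits, "study_verdict")))
  fps <- unique(map_chr(verdicts, function(v) attr(v, "config_fingerprint")))
  if (length(fps) > 1) {
    stop_adnaudit(
      sprintf("cannot aggregate verdicts from %d different audit configurations",
              length(fps)),
      "adnaudit_fingerprint_error")
  }
  combined <- bind_rows(map(verdicts, function(v) {
    tibble(study = attr(v, "study_accession"), criterion_id = v$criterion_id,
           applicable = v$applicable, passed = v$passed)
  }))
  registry <- list_criteria()
  counts <- combined |>
    filter(.data$applicable & !is.na(.data$passed)) |>
    group_by(.data$criterion_id) |>
    summarise(n_pass = sum(.data$passed), n_fail = sum(!.data$passed),
              .groups = "drop")
  out <- registry[, c("criterion_id", "label", "table_ref")] |>
    left_join(counts, by = "criterion_id") |>
    mutate(
      n_pass = dplyr::coalesce(.data$n_pass, 0L),
      n_fail = dplyr::coalesce(.data$n_fail, 0L),
      n_applicable = .data$n_pass + .data$n_fail,
      pct_pass = ifelse(.data$n_applicable > 0,
                        round_half_up(100 * .data$n_pass / .data$n_applicable, 1),
                        NA_real_)
    )
  structure(out, class = c("cohort_summary", class(out)),
            config_fingerprint = fps, n_studies = length(verdicts))
}

format_pct <- function(pct) {
  ifelse(is.na(pct), "-",
         paste0(ifelse(pct == floor(pct), sprintf("%d", as.integer(pct)),
                       sprintf("%.1f", pct)), "%"))
}

#' Render a cohort summary as a survey table
#'
#' Produces the familiar survey layout: one row per criterion, with
#' "meeting" and "not meeting" cells formatted as `count (percentage)`.
#' Percentages carry one decimal, with a trailing `.0` dropped (45.0 prints
#' as `45%`).
#'
#' @param summary A `cohort_summary` from [aggregate_verdicts()].
#' @param table Optional selector (`"Table 1"` ... `"Table 5"`) restricting
#'   the rows; `NULL` renders the whole registry.
#' @param format `"text"` for an aligned table, `"tsv"` for tab-separated
#'   columns `criterion_id`, `label`, `n_pass`, `n_fail`, `n_applicable`,
#'   `pct_pass`.
#' @return A character vector of lines.
#' @export
render_table <- function(summary, table = NULL, format = c("text", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "cohort_summary"))
  rows <- if (is.null(table)) summary else summary[summary$table_ref == table, ]
  if (format == "tsv") {
    header <- paste(c("criterion_id", "label", "n_pass", "n_fail",
                      "n_applicable", "pct_pass"), collapse = "\t")
    body <- sprintf("%s\t%s\t%d\t%d\t%d\t%s", rows$criterion_id, rows$label,
                    rows$n_pass, rows$n_fail, rows$n_applicable,
                    ifelse(is.na(rows$pct_pass), "NA", as.character(rows$pct_pass)))
    return(c(header, body))
  }
  meeting <- sprintf("%d (%s)", rows$n_pass, format_pct(rows$pct_pass))
  not_meeting <- sprintf("%d (%s)", rows$n_fail,
                         format_pct(ifelse(rows$n_applicable > 0,
                                           round_half_up(100 - rows$pct_pass, 1),
                                           NA_real_)))
  meeting[rows$n_applicable == 0] <- "-"
  not_meeting[rows$n_applicable == 0] <- "-"
  cells <- rbind(
    c("Criterion", "Meeting", "Not meeting", "Applicable"),
    cbind(rows$label, meeting, not_meeting, as.character(rows$n_applicable)))
  widths <- apply(nchar(cells), 2, max)
  apply(cells, 1, function(r) {
    paste(sprintf(paste0("%-", widths, "s"), r), collapse = "  ")
  })
}

#' Parse a rendered TSV summary back into counts
#'
#' @param lines Lines produced by `render_table(..., format = "tsv")`.
#' @return A tibble with the numeric columns restored.
#' @export
parse_table_tsv <- function(lines) {
  readr::read_tsv(I(paste(lines, collapse = "\n")),
                  col_types = "cciiid", progress = FALSE)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d studies (config %s)\n",
              attr(x, "n_studies"), substr(attr(x, "config_fingerprint"), 1, 8)))
  writeLines(render_table(x))
  invisible(x)
}
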