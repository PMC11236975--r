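# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a study verdict
#'
#' @param x A `study_verdict`.
#' @param ... Unused.
#' @return A tibble with one row per criterion: `study_accession`,
#'   `criterion_id`, `table_ref`, `applicable`, `passed`, `status`.
#' @export
tidy.study_verdict <- function(x, ...) {
  tibble(
    study_accession = attr(x, "study_accession"),
    criterion_id = x$criterion_id,
    table_ref = x$table_ref,
    applicable = x$applicable,
    passed = x$passed,
    status = dplyr::case_when(
      !x$applicable ~ "not_applicable",
      is.na(x$passed) ~ "indeterminate",
      x$passed ~ "pass",
      TRUE ~ "fail")
  )
}

#' One-row summary of a study verdict
#'
#' @param x A `study_verdict`.
#' @param ... Unused.
#' @return A one-row tibble: `study_accession`, `n_criteria`, `n_applicable`,
#'   `n_pass`, `n_fail`, `n_indeterminate`, `config_fingerprint`.
#' @export
glance.study_verdict <- function(x, ...) {
  tibble(
    study_accession = attr(x, "study_accession"),
    n_criteria = nrow(x),
    n_applicable = sum(x$applicable),
    n_pass = sum(x$applicable & !is.na(x$passed) & x$passed),
    n_fail = sum(x$applicable & !is.na(x$passed) & !x$passed),
    n_indeterminate = sum(x$applicable & is.na(x$passed)),
    config_fingerprint = attr(x, "config_fingerprint")
  )
}

#' Tidy a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return The summary as a plain tibble.
#' @export
tidy.cohort_summary <- function(x, ...) {
  as_tibble(x)
}

#' Plot a cohort summary
#'
#' Horizontal bars of the per-criterion pass percentage, faceted by survey
#' table, annotated with the pass/applicable counts.
#'
#' @param object A `cohort_summary` from [aggregate_verdicts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$n_applicable > 0) |>
    mutate(criterion_id = factor(.data$criterion_id, levels = rev(.data$criterion_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct_pass, y = .data$criterion_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_pass,
                                                    .data$n_applicable)),
                       hjust = -0.1, size = 3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$table_ref), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_x_continuous(limits = c(0, 110), breaks = seq(0, 100, 25)) +
    ggplot2::labs(x = "studies meeting criterion (%)", y = NULL,
                  title = "Archiving-practice survey",
                  subtitle = sprintf("%d studies", attr(object, "n_studies"))) +
    ggplot2::theme_minimal()
}

#' Plot a study verdict
#'
#' Tile chart of per-criterion status for one study.
#'
#' @param object A `study_verdict`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_verdict <- function(object, ...) {
  df <- tidy(object) |>
    mutate(criterion_id = factor(.data$criterion_id, levels = rev(.data$criterion_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$table_ref, y = .data$criterion_id,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(
      pass = "#2e7d32", fail = "#c62828", indeterminate = "#f9a825",
      not_applicable = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Archiving audit: %s",
                                  attr(object, "study_accession"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
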