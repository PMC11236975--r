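# Submission preflight: the eight-step archiving checklist, each step backed
# by the registry criteria that operationalise it.

lint_steps <- function() {
  tibble(
    step = 1:8,
    description = c(
      "Register samples; reuse existing sample accessions for previously published samples",
      "Provide informative sample metadata (geography, coordinates, dating, lab codes, tissue, voucher)",
      "Prepare raw read files: demultiplexed, adapters trimmed, no length/quality filtering",
      "Deposit raw reads, one file per sample/library/run, linked to the right sample accession",
      "Provide experimental metadata on library preparation for each run",
      "Prepare alignment files: read groups set and matching metadata, validated, no hard filtering",
      "Deposit read alignments as analysis files, not as primary run files",
      "Document archiving choices (what was archived, for which samples, with what filtering) in the paper"
    ),
    criteria = list(
      c("accession_reuse", "libraries_linked_single_sample", "sample_count_match"),
      c("geo_any", "geo_coords", "date_any", "date_c14", "tissue_any", "voucher_present"),
      c("adapters_trimmed"),
      c("raw_reads_archived", "capture_raw"),
      c("library_metadata_present"),
      c("bam_has_rg", "bam_sm_present", "bam_sm_matches", "bam_single_sm",
        "bam_lb_present", "bam_lb_matches", "bam_valid", "no_any_hardfilter"),
      c("alignments_as_analysis"),
      c("total_reported", "all_samples_archived")
    )
  )
}

#' Preflight a submission against the archiving checklist
#'
#' Renders a [study_verdict] as a step-by-step checklist: each of the eight
#' archiving steps is `ok` when all its contributing applicable criteria
#' pass, `action_needed` when any fails, and `not_checked` when none could be
#' decided (inputs missing or not applicable).
#'
#' @param bundle A [study_bundle()] or bundle path.
#' @param config An [audit_config()].
#' @param data_dir,file_checks Passed to [audit_study()].
#' @param verdict Optionally, an already computed `study_verdict` (skips
#'   re-auditing).
#' @return A `lint_report` tibble: `step`, `description`, `status`,
#'   `failing_criteria` (list-column), `criteria` (list-column of the
#'   contributing verdict slices).
#' @export
lint_submission <- function(bundle, config = audit_config(), data_dir = NULL,
                            file_checks = TRUE, verdict = NULL) {
  if (is.null(verdict)) {
    verdict <- audit_study(bundle, config, data_dir, file_checks)
  }
  steps <- lint_steps()
  rows <- map(seq_len(nrow(steps)), function(i) {
    ids <- steps$criteria[[i]]
    slice <- verdict[verdict$criterion_id %in% ids, ]
    decided <- slice$applicable & !is.na(slice$passed)
    status <- if (any(decided & !slice$passed)) "action_needed"
              else if (any(decided)) "ok"
              else "not_checked"
    tibble(
      step = steps$step[i],
      description = steps$description[i],
      status = status,
      failing_criteria = list(slice$criterion_id[decided & !slice$passed]),
      criteria = list(as_tibble(slice)[, c("criterion_id", "applicable", "passed")])
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("lint_report", class(out)),
            study_accession = attr(verdict, "study_accession"),
            config_fingerprint = attr(verdict, "config_fingerprint"))
}

#' @export
print.lint_report <- function(x, ...) {
  cat(sprintf("<lint_report> %s\n", attr(x, "study_accession")))
  marks <- c(ok = "ok", action_needed = "ACTION NEEDED", not_checked = "not checked")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  step %d [%s] %s\n", x$step[i], marks[[x$status[i]]],
                x$description[i]))
    fails <- x$failing_criteria[[i]]
    if (length(fails) > 0) cat("      failing:", paste(fails, collapse = ", "), "\n")
  }
  invisible(x)
}
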