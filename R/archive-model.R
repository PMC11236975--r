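# Domain model for an INSDC-style study bundle: one study record, its samples
# (free-form tag/value attributes, as in BioSample), its sequencing runs and
# its analysis records, plus the facts the accompanying paper declares.
# Attribute tags are stored verbatim; matching elsewhere is case-insensitive.

#' Construct a study bundle
#'
#' A study bundle gathers everything the auditor needs to know about one
#' archived study: the study record itself, the registered samples with their
#' tag/value attributes, the sequencing runs, any analysis records (secondary
#' products such as read alignments), and optionally the facts declared in the
#' accompanying paper (sample counts, capture usage, previously published
#' samples).
#'
#' @param study A list with elements `accession`, `title`, `description`.
#' @param samples A data frame with columns `accession`, `alias`, `title` and a
#'   list-column `attributes` of tibbles with columns `tag`, `value`, `units`.
#' @param runs A data frame with columns `accession`, `sample_accession`,
#'   `library_name`, `library_construction_protocol`, `instrument_platform`,
#'   `submitted_format` and a list-column `files` of tibbles with columns
#'   `path`, `declared_format`.
#' @param analyses A data frame with columns `accession`, `analysis_type`,
#'   list-columns `linked_run_accessions`, `linked_sample_accessions`, and a
#'   `files` list-column as for runs.
#' @param paper_report Optional list of paper-declared facts; see
#'   [paper_report()].
#' @return An object of class `study_bundle`.
#' @seealso [load_bundle()], [write_bundle()], [validate_bundle()]
#' @export
study_bundle <- function(study,
                         samples = empty_samples(),
                         runs = empty_runs(),
                         analyses = empty_analyses(),
                         paper_report = NULL) {
  bundle <- structure(
    list(
      study = normalise_study(study),
      samples = normalise_samples(samples),
      runs = normalise_runs(runs),
      analyses = normalise_analyses(analyses),
      paper_report = if (!is.null(paper_report)) normalise_paper_report(paper_report)
    ),
    class = "study_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Paper-declared facts about a study
#'
#' Captures what the publication itself states about the dataset, used by the
#' criteria that compare the archive against the paper: how many samples were
#' analysed, how many were studied in total (including negative or screening
#' experiments), whether target-capture was used, and which samples had been
#' published before (and under which existing accessions).
#'
#' @param n_samples_analysed,n_samples_studied_total Optional non-negative
#'   counts; when both are given the total must be at least the analysed count.
#' @param used_capture Did the study use capture/target enrichment?
#' @param previously_published_samples A data frame with columns `alias` and
#'   `existing_accession`, or `NULL`.
#' @param total_reported_in_paper Does the paper state the total number of
#'   studied samples?
#' @return A list of class `paper_report`.
#' @export
paper_report <- function(n_samples_analysed = NULL,
                         n_samples_studied_total = NULL,
                         used_capture = FALSE,
                         previously_published_samples = NULL,
                         total_reported_in_paper = FALSE) {
  normalise_paper_report(list(
    n_samples_analysed = n_samples_analysed,
    n_samples_studied_total = n_samples_studied_total,
    used_capture = used_capture,
    previously_published_samples = previously_published_samples,
    total_reported_in_paper = total_reported_in_paper
  ))
}

empty_attributes <- function() {
  tibble(tag = character(), value = character(), units = character())
}

empty_samples <- function() {
  tibble(accession = character(), alias = character(), title = character(),
         attributes = list())
}

empty_runs <- function() {
  tibble(accession = character(), sample_accession = character(),
         library_name = character(), library_construction_protocol = character(),
         instrument_platform = character(), submitted_format = character(),
         files = list())
}

empty_analyses <- function() {
  tibble(accession = character(), analysis_type = character(),
         linked_run_accessions = list(), linked_sample_accessions = list(),
         files = list())
}

empty_files <- function() {
  tibble(path = character(), declared_format = character())
}

chr1 <- function(x, default = NA_character_) {
  if (is.null(x) || length(x) == 0) return(default)
  as.character(x)[[1]]
}

normalise_study <- function(study) {
  list(
    accession = chr1(study$accession),
    title = chr1(study$title, ""),
    description = chr1(study$description, "")
  )
}

normalise_attributes <- function(attrs) {
  if (is.null(attrs)) return(empty_attributes())
  attrs <- as_tibble(attrs)
  if (nrow(attrs) == 0) return(empty_attributes())
  if (!"units" %in% names(attrs)) attrs$units <- NA_character_
  tibble(tag = as.character(attrs$tag), value = as.character(attrs$value),
         units = as.character(attrs$units))
}

normalise_samples <- function(samples) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) return(empty_samples())
  if (!"title" %in% names(samples)) samples$title <- NA_character_
  if (!"alias" %in% names(samples)) samples$alias <- samples$accession
  if (!"attributes" %in% names(samples)) samples$attributes <- list(empty_attributes())
  samples$attributes <- map(samples$attributes, normalise_attributes)
  samples[, c("accession", "alias", "title", "attributes")]
}

normalise_files <- function(files) {
  if (is.null(files)) return(empty_files())
  files <- as_tibble(files)
  if (nrow(files) == 0) return(empty_files())
  if (!"declared_format" %in% names(files)) {
    files$declared_format <- guess_format(files$path)
  }
  fmt <- tolower(as.character(files$declared_format))
  bad <- !fmt %in% c("fastq", "bam", "cram", "sam", "other")
  if (any(bad)) {
    stop_adnaudit(
      sprintf("Unknown declared_format value(s): %s",
              paste(unique(fmt[bad]), collapse = ", ")),
      "adnaudit_parse_error")
  }
  tibble(path = as.character(files$path), declared_format = fmt)
}

guess_format <- function(path) {
  base <- sub("\\.gz$", "", tolower(path))
  dplyr::case_when(
    grepl("\\.(fastq|fq)$", base) ~ "fastq",
    grepl("\\.bam$", base) ~ "bam",
    grepl("\\.cram$", base) ~ "cram",
    grepl("\\.sam$", base) ~ "sam",
    TRUE ~ "other"
  )
}

normalise_runs <- function(runs) {
  runs <- as_tibble(runs)
  if (nrow(runs) == 0) return(empty_runs())
  for (col in c("library_name", "library_construction_protocol",
                "instrument_platform", "submitted_format")) {
    if (!col %in% names(runs)) runs[[col]] <- NA_character_
  }
  if (!"files" %in% names(runs)) runs$files <- list(empty_files())
  runs$files <- map(runs$files, normalise_files)
  runs[, c("accession", "sample_accession", "library_name",
           "library_construction_protocol", "instrument_platform",
           "submitted_format", "files")]
}

normalise_analyses <- function(analyses) {
  analyses <- as_tibble(analyses)
  if (nrow(analyses) == 0) return(empty_analyses())
  if (!"analysis_type" %in% names(analyses)) analyses$analysis_type <- "SEQUENCE_ASSEMBLY"
  if (!"linked_run_accessions" %in% names(analyses)) analyses$linked_run_accessions <- list(character())
  if (!"linked_sample_accessions" %in% names(analyses)) analyses$linked_sample_accessions <- list(character())
  analyses$linked_run_accessions <- map(analyses$linked_run_accessions, as.character)
  analyses$linked_sample_accessions <- map(analyses$linked_sample_accessions, as.character)
  if (!"files" %in% names(analyses)) analyses$files <- list(empty_files())
  analyses$files <- map(analyses$files, normalise_files)
  analyses[, c("accession", "analysis_type", "linked_run_accessions",
               "linked_sample_accessions", "files")]
}

normalise_paper_report <- function(pr) {
  if (is.null(pr)) return(NULL)
  pps <- pr$previously_published_samples
  if (is.list(pps) && !is.data.frame(pps)) {   # JSON form: list of records
    pps <- if (length(pps) == 0) NULL else bind_rows(map(pps, function(x) {
      tibble(alias = chr1(x$alias), existing_accession = chr1(x$existing_accession))
    }))
  }
  if (is.null(pps) || (is.data.frame(pps) && nrow(pps) == 0)) {
    pps <- tibble(alias = character(), existing_accession = character())
  } else {
    pps <- as_tibble(pps)[, c("alias", "existing_accession")]
    pps$alias <- as.character(pps$alias)
    pps$existing_accession <- as.character(pps$existing_accession)
  }
  out <- list(
    n_samples_analysed = if (!is.null(pr$n_samples_analysed)) as.integer(pr$n_samples_analysed),
    n_samples_studied_total = if (!is.null(pr$n_samples_studied_total)) as.integer(pr$n_samples_studied_total),
    used_capture = isTRUE(pr$used_capture),
    previously_published_samples = pps,
    total_reported_in_paper = isTRUE(pr$total_reported_in_paper)
  )
  for (fld in c("n_samples_analysed", "n_samples_studied_total")) {
    if (!is.null(out[[fld]]) && out[[fld]] < 0) {
      stop_adnaudit(sprintf("paper_report$%s must be non-negative", fld),
                    "adnaudit_parse_error")
    }
  }
  if (!is.null(out$n_samples_analysed) && !is.null(out$n_samples_studied_total) &&
      out$n_samples_studied_total < out$n_samples_analysed) {
    stop_adnaudit(
      "paper_report: n_samples_studied_total must be >= n_samples_analysed",
      "adnaudit_parse_error")
  }
  class(out) <- "paper_report"
  out
}

#' Validate the referential integrity of a study bundle
#'
#' Checks the invariants every bundle must satisfy: a non-empty study
#' accession, unique sample/run/analysis accessions, every run pointing at a
#' registered sample, and every analysis link resolving within the bundle.
#' Violations raise an error rather than being silently repaired.
#'
#' @param bundle A [study_bundle()].
#' @return The bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (is.na(bundle$study$accession) || !nzchar(bundle$study$accession)) {
    stop_adnaudit("study accession must be non-empty", "adnaudit_integrity_error")
  }
  for (tbl in c("samples", "runs", "analyses")) {
    acc <- bundle[[tbl]]$accession
    if (anyDuplicated(acc)) {
      stop_adnaudit(sprintf("duplicate accession in %s: %s", tbl,
                            paste(unique(acc[duplicated(acc)]), collapse = ", ")),
                    "adnaudit_integrity_error")
    }
  }
  dangling <- setdiff(bundle$runs$sample_accession, bundle$samples$accession)
  if (length(dangling) > 0) {
    stop_adnaudit(
      sprintf("run(s) reference unknown sample accession(s): %s",
              paste(dangling, collapse = ", ")),
      "adnaudit_integrity_error")
  }
  bad_runs <- setdiff(unlist(bundle$analyses$linked_run_accessions), bundle$runs$accession)
  if (length(bad_runs) > 0) {
    stop_adnaudit(
      sprintf("analysis link(s) reference unknown run accession(s): %s",
              paste(bad_runs, collapse = ", ")),
      "adnaudit_integrity_error")
  }
  bad_samp <- setdiff(unlist(bundle$analyses$linked_sample_accessions),
                      bundle$samples$accession)
  if (length(bad_samp) > 0) {
    stop_adnaudit(
      sprintf("analysis link(s) reference unknown sample accession(s): %s",
              paste(bad_samp, collapse = ", ")),
      "adnaudit_integrity_error")
  }
  invisible(bundle)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %s\n", x$study$accession))
  cat(sprintf("  %d sample(s), %d run(s), %d analysis record(s)%s\n",
              nrow(x$samples), nrow(x$runs), nrow(x$analyses),
              if (is.null(x$paper_report)) "" else ", paper report attached"))
  invisible(x)
}

# ---- canonical JSON serialization -------------------------------------------

attrs_to_json <- function(attrs) {
  pmap(attrs, function(tag, value, units) {
    out <- list(tag = tag, value = value)
    if (!is.na(units)) out$units <- units
    out
  })
}

files_to_json <- function(files) {
  pmap(files, function(path, declared_format) {
    list(path = path, declared_format = declared_format)
  })
}

json_scalar <- function(x) if (is.null(x) || is.na(x)) NULL else x

bundle_to_list <- function(bundle) {
  pr <- bundle$paper_report
  list(
    study = list(
      accession = bundle$study$accession,
      title = json_scalar(bundle$study$title) %||% "",
      description = json_scalar(bundle$study$description) %||% ""
    ),
    samples = pmap(bundle$samples, function(accession, alias, title, attributes) {
      out <- list(accession = accession, alias = alias)
      if (!is.na(title)) out$title <- title
      out$attributes <- attrs_to_json(attributes)
      out
    }),
    runs = pmap(bundle$runs, function(accession, sample_accession, library_name,
                                      library_construction_protocol,
                                      instrument_platform, submitted_format, files) {
      out <- list(accession = accession, sample_accession = sample_accession)
      if (!is.na(library_name)) out$library_name <- library_name
      if (!is.na(library_construction_protocol)) {
        out$library_construction_protocol <- library_construction_protocol
      }
      if (!is.na(instrument_platform)) out$instrument_platform <- instrument_platform
      if (!is.na(submitted_format)) out$submitted_format <- submitted_format
      out$files <- files_to_json(files)
      out
    }),
    analyses = pmap(bundle$analyses, function(accession, analysis_type,
                                              linked_run_accessions,
                                              linked_sample_accessions, files) {
      list(accession = accession, analysis_type = analysis_type,
           linked_run_accessions = as.list(linked_run_accessions),
           linked_sample_accessions = as.list(linked_sample_accessions),
           files = files_to_json(files))
    }),
    paper_report = if (!is.null(pr)) {
      out <- list()
      if (!is.null(pr$n_samples_analysed)) out$n_samples_analysed <- pr$n_samples_analysed
      if (!is.null(pr$n_samples_studied_total)) out$n_samples_studied_total <- pr$n_samples_studied_total
      out$used_capture <- pr$used_capture
      out$previously_published_samples <- pmap(pr$previously_published_samples,
        function(alias, existing_accession) {
          list(alias = alias, existing_accession = existing_accession)
        })
      out$total_reported_in_paper <- pr$total_reported_in_paper
      out
    }
  )
}

#' Write a study bundle to its canonical JSON form
#'
#' The serialization is canonical and deterministic (fixed key order, no
#' timestamps), so writing the same bundle twice produces byte-identical
#' files. Bundles violating their invariants are refused.
#'
#' @param bundle A [study_bundle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  json <- jsonlite::toJSON(bundle_to_list(bundle), auto_unbox = TRUE,
                           pretty = TRUE, null = "null", digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a study bundle from its canonical JSON form
#'
#' @param path Path to a bundle JSON file, as written by [write_bundle()] or
#'   produced by the adapters ([from_ena_filereport()]).
#' @return A [study_bundle()]; referential integrity is validated on load.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) {
    stop_adnaudit(sprintf("bundle file not found: %s", path), "adnaudit_io_error")
  }
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_adnaudit(sprintf("cannot parse bundle JSON %s: %s",
                                          path, conditionMessage(e)),
                                  "adnaudit_parse_error")
                  })
  if (is.null(raw$study) || is.null(raw$study$accession)) {
    stop_adnaudit("bundle JSON missing required field: study.accession",
                  "adnaudit_parse_error")
  }
  list_to_tbl <- function(items, fields, list_fields = character()) {
    if (length(items) == 0) return(NULL)
    rows <- map(items, function(item) {
      row <- lapply(fields, function(f) chr1(item[[f]]))
      names(row) <- fields
      as_tibble(row)
    })
    tbl <- bind_rows(rows)
    for (lf in list_fields) {
      tbl[[lf]] <- map(items, function(item) {
        as.character(unlist(item[[lf]]) %||% character())
      })
    }
    tbl
  }
  samples <- list_to_tbl(raw$samples, c("accession", "alias", "title"))
  if (!is.null(samples)) {
    samples$attributes <- map(raw$samples, function(s) {
      if (length(s$attributes) == 0) return(empty_attributes())
      bind_rows(map(s$attributes, function(a) {
        tibble(tag = chr1(a$tag), value = chr1(a$value), units = chr1(a$units))
      }))
    })
  }
  parse_files <- function(item) {
    if (length(item$files) == 0) return(empty_files())
    bind_rows(map(item$files, function(f) {
      tibble(path = chr1(f$path), declared_format = chr1(f$declared_format))
    }))
  }
  runs <- list_to_tbl(raw$runs, c("accession", "sample_accession", "library_name",
                                  "library_construction_protocol",
                                  "instrument_platform", "submitted_format"))
  if (!is.null(runs)) runs$files <- map(raw$runs, parse_files)
  analyses <- list_to_tbl(raw$analyses, c("accession", "analysis_type"),
                          c("linked_run_accessions", "linked_sample_accessions"))
  if (!is.null(analyses)) analyses$files <- map(raw$analyses, parse_files)
  study_bundle(
    study = raw$study,
    samples = samples %||% empty_samples(),
    runs = runs %||% empty_runs(),
    analyses = analyses %||% empty_analyses(),
    paper_report = raw$paper_report
  )
}

# ---- archive-export adapters ------------------------------------------------

#' Build a study bundle from an ENA filereport and BioSample attributes
#'
#' Converts the tabular per-run metadata export of the European Nucleotide
#' Archive (the "filereport" TSV) plus an optional BioSample attribute dump
#' into the canonical bundle. One run record is created per table row; file
#' references are recorded but never fetched.
#'
#' @param report_path Path to a tab-separated filereport with a header row.
#'   Columns `run_accession` and `sample_accession` are mandatory;
#'   `library_name`, `library_construction_protocol`, `instrument_platform`,
#'   `submitted_format` and `fastq_ftp`/`submitted_ftp` are used when present.
#' @param attributes_path Optional path to a BioSample attribute table (TSV
#'   with columns `sample_accession`, `tag`, `value`, `units`) or an
#'   equivalent JSON array of `{sample_accession, tag, value, units}` objects.
#' @param study_accession,study_title Study-level fields; the accession
#'   defaults to the value of a `study_accession` column when present.
#' @return A [study_bundle()].
#' @export
from_ena_filereport <- function(report_path, attributes_path = NULL,
                                study_accession = NULL, study_title = "") {
  if (!file.exists(report_path)) {
    stop_adnaudit(sprintf("filereport not found: %s", report_path), "adnaudit_io_error")
  }
  tbl <- readr::read_tsv(report_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("run_accession", "sample_accession")
  missing <- setdiff(mandatory, names(tbl))
  if (length(missing) > 0) {
    stop_adnaudit(
      sprintf("filereport is missing mandatory column(s) %s; expected at least: %s",
              paste(missing, collapse = ", "), paste(mandatory, collapse = ", ")),
      "adnaudit_parse_error")
  }
  study_accession <- study_accession %||%
    (if ("study_accession" %in% names(tbl) && nrow(tbl) > 0) tbl$study_accession[[1]] else "UNKNOWN_STUDY")

  col_or_na <- function(col) if (col %in% names(tbl)) tbl[[col]] else rep(NA_character_, nrow(tbl))
  ftp <- dplyr::coalesce(col_or_na("submitted_ftp"), col_or_na("fastq_ftp"))
  files <- map(seq_len(nrow(tbl)), function(i) {
    if (is.na(ftp[[i]]) || !nzchar(ftp[[i]])) return(empty_files())
    paths <- strsplit(ftp[[i]], ";", fixed = TRUE)[[1]]
    tibble(path = paths, declared_format = guess_format(paths))
  })
  known <- c("run_accession", "sample_accession", "library_name",
             "library_construction_protocol", "instrument_platform",
             "submitted_format", "fastq_ftp", "submitted_ftp", "study_accession")
  extra_cols <- setdiff(names(tbl), known)

  runs <- tibble(
    accession = tbl$run_accession,
    sample_accession = tbl$sample_accession,
    library_name = col_or_na("library_name"),
    library_construction_protocol = col_or_na("library_construction_protocol"),
    instrument_platform = col_or_na("instrument_platform"),
    submitted_format = col_or_na("submitted_format"),
    files = if (nrow(tbl) > 0) files else list()
  )

  sample_acc <- unique(tbl$sample_accession)
  attrs_by_sample <- read_biosample_attributes(attributes_path)
  # Unknown filereport columns are preserved as per-run attributes on the
  # sample they belong to would be wrong; keep them on the run via attr.
  samples <- tibble(
    accession = sample_acc,
    alias = sample_acc,
    title = rep(NA_character_, length(sample_acc)),
    attributes = map(sample_acc, function(acc) {
      attrs_by_sample[[acc]] %||% empty_attributes()
    })
  )
  if ("sample_alias" %in% names(tbl)) {
    alias_map <- tbl[!duplicated(tbl$sample_accession), c("sample_accession", "sample_alias")]
    samples$alias <- dplyr::coalesce(
      alias_map$sample_alias[match(samples$accession, alias_map$sample_accession)],
      samples$accession)
  }
  bundle <- study_bundle(
    study = list(accession = study_accession, title = study_title, description = ""),
    samples = samples,
    runs = runs
  )
  if (length(extra_cols) > 0) {
    attr(bundle, "run_extra_columns") <-
      as_tibble(tbl[, c("run_accession", extra_cols), drop = FALSE])
  }
  bundle
}

read_biosample_attributes <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) {
    stop_adnaudit(sprintf("BioSample attribute file not found: %s", path),
                  "adnaudit_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    items <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    tbl <- bind_rows(map(items, function(a) {
      tibble(sample_accession = chr1(a$sample_accession), tag = chr1(a$tag),
             value = chr1(a$value), units = chr1(a$units))
    }))
  } else {
    tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing <- setdiff(c("sample_accession", "tag", "value"), names(tbl))
    if (length(missing) > 0) {
      stop_adnaudit(
        sprintf("BioSample attribute table is missing column(s): %s",
                paste(missing, collapse = ", ")),
        "adnaudit_parse_error")
    }
    if (!"units" %in% names(tbl)) tbl$units <- NA_character_
  }
  if (nrow(tbl) == 0) return(list())
  split_tbl <- split(tbl[, c("tag", "value", "units")], tbl$sample_accession)
  map(split_tbl, as_tibble)
}
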