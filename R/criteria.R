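# The rubric: every archiving criterion in the registry is evaluated for one
# study, with explicit applicability. A criterion can pass, fail, be not
# applicable, or be indeterminate (applicable but its inputs unavailable or
# below the confidence floor); indeterminate is not a failure and is excluded
# from cohort denominators.

#' Audit configuration
#'
#' Bundles every tunable the rubric uses. The configuration is fingerprinted
#' (content hash) and the fingerprint recorded in every verdict, so verdicts
#' produced under different configurations are never aggregated together.
#'
#' @param sample_reads Reads sampled from the head of each file.
#' @param adapter_threshold A raw-read file "has adapter residue" when its
#'   adapter-residue fraction exceeds this (1\% tolerates chance matches in
#'   clean libraries).
#' @param min_overlap,max_mismatch_rate Adapter-match parameters; see
#'   [detect_adapter_residue()].
#' @param mapq_trigger,length_trigger,min_confident_n Hard-filter inference
#'   parameters; see [infer_hard_filters()].
#' @param case_insensitive_match Fold case when matching read-group
#'   identifiers against archive metadata? Off by default: the identifiers
#'   are expected to match exactly.
#' @param suffix_tokens Informal duplicate-suffix tokens; see
#'   [detect_duplicate_samples()].
#' @param adapters Adapter set; see [default_adapters()].
#' @param lexicons Metadata vocabulary; see [default_lexicons()].
#' @return A list of class `audit_config` with a `fingerprint` element.
#' @export
audit_config <- function(sample_reads = 10000L,
                         adapter_threshold = 0.01,
                         min_overlap = 8L,
                         max_mismatch_rate = 0.1,
                         mapq_trigger = 25L,
                         length_trigger = 30L,
                         min_confident_n = 1000L,
                         case_insensitive_match = FALSE,
                         suffix_tokens = default_suffix_tokens(),
                         adapters = default_adapters(),
                         lexicons = default_lexicons()) {
  cfg <- list(
    sample_reads = as.integer(sample_reads),
    adapter_threshold = adapter_threshold,
    min_overlap = as.integer(min_overlap),
    max_mismatch_rate = max_mismatch_rate,
    mapq_trigger = as.integer(mapq_trigger),
    length_trigger = as.integer(length_trigger),
    min_confident_n = as.integer(min_confident_n),
    case_insensitive_match = isTRUE(case_insensitive_match),
    suffix_tokens = suffix_tokens,
    adapters = adapters,
    lexicons = unclass(lexicons)
  )
  cfg$fingerprint <- rlang::hash(cfg)
  structure(cfg, class = "audit_config")
}

#' Read an audit configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [audit_config()]; `adapters` may be
#' a path to a FASTA file and `lexicons` a path to a lexicon config.
#'
#' @param path Config file.
#' @return An `audit_config`.
#' @export
read_audit_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(audit_config)))]
  if (!is.null(args$adapters) && is.character(args$adapters) &&
      length(args$adapters) == 1 && file.exists(args$adapters)) {
    args$adapters <- read_adapters(args$adapters)
  }
  if (!is.null(args$lexicons) && is.character(args$lexicons)) {
    args$lexicons <- read_lexicons(args$lexicons)
  }
  do.call(audit_config, args)
}

#' The criterion registry
#'
#' Lists every archiving criterion the rubric evaluates, in stable survey
#' order, with its survey-table reference and a prose description of its
#' applicability condition and pass rule.
#'
#' @return A tibble with columns `criterion_id`, `label`, `table_ref`,
#'   `applicability`, `pass_rule`.
#' @export
list_criteria <- function() {
  tribble_reg <- function(...) {
    m <- matrix(c(...), ncol = 5, byrow = TRUE)
    tibble(criterion_id = m[, 1], label = m[, 2], table_ref = m[, 3],
           applicability = m[, 4], pass_rule = m[, 5])
  }
  tribble_reg(
    "raw_reads_archived", "Archived raw reads", "Table 1",
      "always", "some file holds the complete read set (FASTQ, unaligned BAM, or BAM retaining unmapped reads)",
    "capture_raw", "Used capture technology, and archived raw reads", "Table 1",
      "study used capture", "raw reads archived",
    "adapters_trimmed", "Trimmed adapter sequences", "Table 1",
      "raw reads archived", "adapter-residue fraction of every raw file at or below the threshold",
    "alignments_archived", "Archived read alignments", "Table 2",
      "always", "some archived file contains aligned records",
    "both_archived", "Archived both raw reads and read alignments", "Table 2",
      "always", "raw reads archived and alignments archived",
    "alignments_as_analysis", "Archived read alignments as analysis files", "Table 2",
      "alignments archived", "every alignment file is registered under an analysis record, none under a run",
    "no_any_hardfilter", "Archived read alignments without any apparent hard filtering", "Table 2",
      "alignments archived", "neither a MAPQ nor a read-length hard filter inferred",
    "no_mapq_hardfilter", "Archived read alignments without hard filtering on mapping quality", "Table 2",
      "alignments archived", "no MAPQ hard filter inferred (at adequate read depth)",
    "no_length_hardfilter", "Archived read alignments without hard filtering on read length", "Table 2",
      "alignments archived", "no read-length hard filter inferred (at adequate read depth)",
    "rawless_unfiltered", "Did not archive raw reads; archived unfiltered read alignments", "Table 2",
      "raw reads not archived and alignments archived", "no hard filter inferred",
    "sample_count_match", "Sample number in archive matches sample number in paper", "Table 3",
      "paper report available", "distinct archived samples with data equals the declared analysed count",
    "libraries_linked_single_sample", "Libraries correctly linked to a single sample accession", "Table 3",
      "always", "no suffix-pattern duplicate sample groups",
    "accession_reuse", "Correctly reused existing accessions of previously published samples", "Table 3",
      "paper declares previously published samples", "every declared existing accession reappears in the bundle",
    "library_metadata_present", "Included technical library preparation details in archive metadata", "Table 3",
      "always", "some run carries library-construction-protocol details",
    "bam_has_rg", "BAM files have read groups", "Table 3",
      "alignments archived", "every alignment file declares at least one read group",
    "bam_sm_present", "BAM files have SM (sample) read group fields", "Table 3",
      "read groups present", "every read group carries an SM field",
    "bam_sm_matches", "BAM SM field matches the archived sample name", "Table 3",
      "SM fields present", "every SM value matches the linked sample's alias, accession or title",
    "bam_single_sm", "BAM files contain only a single sample name in SM fields", "Table 3",
      "SM fields present", "at most one distinct SM value per file",
    "bam_lb_present", "BAM files have LB (library) read group fields", "Table 3",
      "alignments archived", "every read group carries an LB field",
    "bam_lb_matches", "BAM LB field matches the archived library name", "Table 3",
      "LB fields present", "every LB value matches a linked run's library name",
    "bam_valid", "BAM file passes validation", "Table 3",
      "alignments archived", "no issues from the structural validation rule set",
    "geo_any", "Metadata contains any geographical information", "Table 4",
      "always", "some sample has a geography finding",
    "geo_dedicated", "Geographical information in a dedicated metadata field", "Table 4",
      "geographical information present", "some sample uses a dedicated geography field",
    "geo_coords", "Metadata includes geographical coordinates", "Table 4",
      "geographical information present", "some sample has parseable latitude/longitude",
    "date_any", "Metadata contains any dating information", "Table 4",
      "always", "some sample has a dating finding",
    "date_dedicated", "Dating information in a dedicated metadata field", "Table 4",
      "dating information present", "some sample uses a dedicated date field",
    "date_c14", "Metadata includes radiocarbon lab codes", "Table 4",
      "dating information present", "some sample carries a radiocarbon lab code",
    "tissue_any", "Metadata contains any information on sampled tissue", "Table 4",
      "always", "some sample has a tissue finding",
    "tissue_dedicated", "Tissue information in a dedicated metadata field", "Table 4",
      "tissue information present", "some sample uses a dedicated tissue field",
    "voucher_present", "Metadata references specimen/collection identity", "Table 4",
      "always", "some sample carries a voucher or biological-material field",
    "total_reported", "Paper mentions the total number of studied samples", "Table 5",
      "paper report available", "the paper states the total studied-sample count",
    "all_samples_archived", "Data from all studied samples appears archived", "Table 5",
      "paper report declares a studied-sample total", "archived distinct samples with data >= declared total"
  )
}

#' Audit one study end to end
#'
#' Convenience wrapper: collects per-file statistics for every file the
#' bundle references, then evaluates the full criterion registry with
#' [evaluate_study()].
#'
#' @param bundle A [study_bundle()], or a path to a bundle JSON file.
#' @param config An [audit_config()].
#' @param data_dir Directory against which relative file paths are resolved;
#'   defaults to the bundle's own directory when `bundle` is a path.
#' @param file_checks Set `FALSE` to skip reading the data files; criteria
#'   that need file content are then reported indeterminate.
#' @return A `study_verdict`; see [evaluate_study()].
#' @export
audit_study <- function(bundle, config = audit_config(), data_dir = NULL,
                        file_checks = TRUE) {
  if (is.character(bundle)) {
    data_dir <- data_dir %||% dirname(bundle)
    bundle <- load_bundle(bundle)
  }
  file_stats <- if (file_checks) {
    collect_bundle_stats(bundle, config, data_dir)
  } else {
    list()
  }
  evaluate_study(bundle, file_stats, config, file_checks = file_checks)
}

#' Collect statistics for every file a bundle references
#'
#' @inheritParams audit_study
#' @return A named list of `seq_file_stats`, keyed by the paths recorded in
#'   the bundle.
#' @export
collect_bundle_stats <- function(bundle, config = audit_config(), data_dir = NULL) {
  refs <- bundle_file_refs(bundle)
  stats <- list()
  for (i in seq_len(nrow(refs))) {
    path <- refs$path[i]
    resolved <- resolve_path(path, data_dir)
    if (!file.exists(resolved)) {
      stop_adnaudit(sprintf("referenced data file not found: %s", resolved),
                    "adnaudit_io_error")
    }
    stats[[path]] <- collect_seq_stats(
      resolved, format = refs$declared_format[i],
      n_sample = config$sample_reads, adapters = config$adapters,
      min_overlap = config$min_overlap,
      max_mismatch_rate = config$max_mismatch_rate)
  }
  stats
}

resolve_path <- function(path, data_dir) {
  if (is.null(data_dir) || grepl("^(/|[A-Za-z]:)", path)) path
  else file.path(data_dir, path)
}

bundle_file_refs <- function(bundle) {
  run_files <- if (nrow(bundle$runs) > 0) {
    bind_rows(pmap(bundle$runs[, c("accession", "sample_accession", "files")],
      function(accession, sample_accession, files) {
        if (nrow(files) == 0) return(NULL)
        mutate(files, record_type = "run", record_accession = accession,
               sample_accession = sample_accession)
      }))
  } else NULL
  analysis_files <- if (nrow(bundle$analyses) > 0) {
    bind_rows(pmap(bundle$analyses[, c("accession", "linked_sample_accessions", "files")],
      function(accession, linked_sample_accessions, files) {
        if (nrow(files) == 0) return(NULL)
        mutate(files, record_type = "analysis", record_accession = accession,
               sample_accession = linked_sample_accessions[1] %||% NA_character_)
      }))
  } else NULL
  out <- bind_rows(run_files, analysis_files)
  if (is.null(out) || nrow(out) == 0) {
    tibble(path = character(), declared_format = character(),
           record_type = character(), record_accession = character(),
           sample_accession = character())
  } else out
}

#' Evaluate the criterion registry for one study
#'
#' The core of the rubric. Every criterion in [list_criteria()] receives
#' exactly one verdict: not applicable, pass, fail, or indeterminate
#' (applicable but undecidable from the available inputs). Failing verdicts
#' always carry evidence. The result is deterministic given the bundle, the
#' file statistics and the configuration.
#'
#' @param bundle A [study_bundle()].
#' @param file_stats Named list of `seq_file_stats` keyed by bundle file
#'   path, as from [collect_bundle_stats()].
#' @param config An [audit_config()].
#' @param file_checks Were file contents inspected? When `FALSE`,
#'   file-dependent criteria are indeterminate.
#' @return A `study_verdict`: a tibble with one row per registry criterion
#'   (`criterion_id`, `label`, `table_ref`, `applicable`, `passed`,
#'   `evidence` list-column) carrying the study accession and the config
#'   fingerprint as attributes.
#' @export
evaluate_study <- function(bundle, file_stats, config = audit_config(),
                           file_checks = TRUE) {
  validate_bundle(bundle)
  refs <- bundle_file_refs(bundle)
  if (file_checks) {
    missing <- setdiff(refs$path, names(file_stats))
    if (length(missing) > 0) {
      stop_adnaudit(sprintf("no statistics supplied for referenced file(s): %s",
                            paste(missing, collapse = ", ")),
                    "adnaudit_evaluation_error")
    }
  }
  pr <- bundle$paper_report

  if (file_checks && nrow(refs) > 0) {
    refs$role <- map_chr(refs$path, function(p) classify_file_role(file_stats[[p]]))
  } else {
    refs$role <- rep(NA_character_, nrow(refs))
  }
  raw_known <- file_checks
  raw_archived <- file_checks &&
    any(refs$role %in% c("raw_reads", "aligned_with_unmapped"))
  aln_refs <- refs[!is.na(refs$role) &
                     refs$role %in% c("aligned_only", "aligned_with_unmapped"), ]
  aln_archived <- file_checks && nrow(aln_refs) > 0
  aln_stats <- map(aln_refs$path, function(p) file_stats[[p]])

  verdicts <- list()
  say <- function(id, applicable, passed, evidence = character()) {
    verdicts[[id]] <<- list(applicable = applicable, passed = passed,
                            evidence = evidence)
  }
  na_if_unchecked <- function(value) if (file_checks) value else NA

  # ---- Table 1: raw reads ---------------------------------------------------
  role_evidence <- if (nrow(refs) > 0) {
    sprintf("%s [%s] -> %s", refs$path, refs$record_type,
            ifelse(is.na(refs$role), "not inspected", refs$role))
  } else "no data files referenced"
  say("raw_reads_archived", TRUE, na_if_unchecked(raw_archived), role_evidence)
  say("capture_raw", !is.null(pr) && isTRUE(pr$used_capture),
      na_if_unchecked(raw_archived), role_evidence)

  if (raw_known && raw_archived) {
    raw_paths <- refs$path[refs$role == "raw_reads"]
    if (length(raw_paths) > 0) {
      fracs <- map_dbl(raw_paths, function(p) file_stats[[p]]$adapter_residue_fraction)
      ok <- all(fracs <= config$adapter_threshold)
      say("adapters_trimmed", TRUE, ok,
          sprintf("%s: adapter residue fraction %.4f (threshold %.4f)",
                  raw_paths, fracs, config$adapter_threshold))
    } else {
      say("adapters_trimmed", TRUE, NA,
          "raw reads present only inside alignment files; adapter state not assessed")
    }
  } else {
    say("adapters_trimmed", FALSE, NULL)
  }

  # ---- Table 2: alignments --------------------------------------------------
  say("alignments_archived", TRUE, na_if_unchecked(aln_archived), role_evidence)
  say("both_archived", TRUE, na_if_unchecked(raw_archived && aln_archived),
      role_evidence)

  if (aln_archived) {
    in_analysis <- aln_refs$record_type == "analysis"
    say("alignments_as_analysis", TRUE, all(in_analysis),
        sprintf("%s registered as %s record", aln_refs$path, aln_refs$record_type))

    sigs <- map(aln_stats, infer_hard_filters,
                mapq_trigger = config$mapq_trigger,
                length_trigger = config$length_trigger,
                min_confident_n = config$min_confident_n)
    sig_evidence <- sprintf(
      "%s: min MAPQ %s over %d mapped read(s); min length %s over %d read(s); unmapped %d",
      aln_refs$path,
      map_chr(aln_stats, function(s) as.character(s$min_mapq_mapped)),
      map_int(aln_stats, function(s) s$n_mapped),
      map_chr(aln_stats, function(s) as.character(s$min_length)),
      map_int(aln_stats, function(s) s$n_reads_sampled),
      map_int(aln_stats, function(s) s$n_unmapped))
    three_way <- function(flags, confident) {
      if (any(flags)) FALSE else if (all(confident)) TRUE else NA
    }
    mapq_pass <- three_way(map_lgl(sigs, "mapq_filtered"),
                           map_int(aln_stats, function(s) s$n_mapped) >= config$min_confident_n)
    len_pass <- three_way(map_lgl(sigs, "length_filtered"),
                          map_int(aln_stats, function(s) s$n_reads_sampled) >= config$min_confident_n)
    any_pass <- if (isFALSE(mapq_pass) || isFALSE(len_pass)) FALSE
                else if (isTRUE(mapq_pass) && isTRUE(len_pass)) TRUE else NA
    say("no_any_hardfilter", TRUE, any_pass, sig_evidence)
    say("no_mapq_hardfilter", TRUE, mapq_pass, sig_evidence)
    say("no_length_hardfilter", TRUE, len_pass, sig_evidence)
    say("rawless_unfiltered", raw_known && !raw_archived, any_pass, sig_evidence)
  } else {
    say("alignments_as_analysis", FALSE, NULL)
    say("no_any_hardfilter", FALSE, NULL)
    say("no_mapq_hardfilter", FALSE, NULL)
    say("no_length_hardfilter", FALSE, NULL)
    say("rawless_unfiltered", FALSE, NULL)
  }

  # ---- Table 3: experiment metadata ----------------------------------------
  counts <- compare_sample_counts(bundle)
  say("sample_count_match", !is.null(pr), counts$matched,
      sprintf("declared analysed samples: %s; archived samples with data: %d",
              ifelse(is.na(counts$declared), "not stated", counts$declared),
              counts$observed))

  dups <- detect_duplicate_samples(bundle$samples, pr,
                                   suffix_tokens = config$suffix_tokens)
  suffix_groups <- dups[dups$reason == "suffix_pattern", ]
  say("libraries_linked_single_sample", TRUE, nrow(suffix_groups) == 0,
      if (nrow(suffix_groups) > 0) {
        map_chr(suffix_groups$member_accessions, function(m)
          sprintf("suffix-pattern duplicate group: %s", paste(m, collapse = ", ")))
      } else "no informal duplicate sample aliases detected")

  reuse_applicable <- !is.null(pr) && nrow(pr$previously_published_samples) > 0
  reuse_groups <- dups[dups$reason == "declared", ]
  say("accession_reuse", reuse_applicable, nrow(reuse_groups) == 0,
      if (nrow(reuse_groups) > 0) {
        map_chr(reuse_groups$member_accessions, function(m)
          sprintf("existing accession not reused: %s", paste(m, collapse = ", ")))
      } else character())

  if (nrow(bundle$runs) > 0) {
    exp_findings <- bind_rows(map(seq_len(nrow(bundle$runs)), function(i) {
      audit_experiment_metadata(bundle$runs[i, ], config$lexicons)
    }))
    say("library_metadata_present", TRUE, any(exp_findings$library_protocol_present),
        sprintf("%d of %d run(s) carry library-construction-protocol details",
                sum(exp_findings$library_protocol_present), nrow(bundle$runs)))
  } else {
    say("library_metadata_present", TRUE, FALSE, "no runs registered")
  }

  if (aln_archived) {
    rg_list <- map(aln_stats, "read_groups")
    has_rg <- map_lgl(rg_list, function(rg) nrow(rg) > 0)
    say("bam_has_rg", TRUE, all(has_rg),
        sprintf("%s: %d read group(s)", aln_refs$path, map_int(rg_list, nrow)))

    if (all(has_rg)) {
      sm_present <- map_lgl(rg_list, function(rg) all(!is.na(rg$sample_tag)))
      say("bam_sm_present", TRUE, all(sm_present),
          sprintf("%s: SM present in %d of %d read group(s)", aln_refs$path,
                  map_int(rg_list, function(rg) sum(!is.na(rg$sample_tag))),
                  map_int(rg_list, nrow)))
      if (all(sm_present)) {
        matches <- map(seq_len(nrow(aln_refs)), function(i) {
          samp <- bundle$samples[bundle$samples$accession ==
                                   aln_refs$sample_accession[i], ]
          if (nrow(samp) == 0) return(new_match_result(FALSE, "", character(), "none"))
          match_rg_sample(rg_list[[i]], samp, config$case_insensitive_match)
        })
        say("bam_sm_matches", TRUE, all(map_lgl(matches, "matched")),
            sprintf("%s: SM '%s' vs candidates {%s} -> %s", aln_refs$path,
                    map_chr(matches, "left_value"),
                    map_chr(matches, function(m)
                      paste(m$candidate_values[[1]], collapse = ", ")),
                    map_chr(matches, "match_kind")))
        n_sm <- map_int(aln_stats, count_distinct_sm)
        say("bam_single_sm", TRUE, all(n_sm <= 1L),
            sprintf("%s: %d distinct SM value(s)", aln_refs$path, n_sm))
      } else {
        say("bam_sm_matches", FALSE, NULL)
        say("bam_single_sm", FALSE, NULL)
      }
    } else {
      say("bam_sm_present", FALSE, NULL)
      say("bam_sm_matches", FALSE, NULL)
      say("bam_single_sm", FALSE, NULL)
    }

    lb_present <- map_lgl(rg_list, function(rg) nrow(rg) > 0 && all(!is.na(rg$library_tag)))
    say("bam_lb_present", TRUE, all(lb_present),
        sprintf("%s: LB present in %d of %d read group(s)", aln_refs$path,
                map_int(rg_list, function(rg) sum(!is.na(rg$library_tag))),
                map_int(rg_list, nrow)))
    if (all(lb_present)) {
      lb_matches <- map(seq_len(nrow(aln_refs)), function(i) {
        linked_runs <- bundle$runs[bundle$runs$sample_accession ==
                                     aln_refs$sample_accession[i], ]
        match_rg_library(rg_list[[i]], linked_runs, config$case_insensitive_match)
      })
      say("bam_lb_matches", TRUE, all(map_lgl(lb_matches, "matched")),
          sprintf("%s: LB '%s' -> %s", aln_refs$path,
                  map_chr(lb_matches, "left_value"),
                  map_chr(lb_matches, "match_kind")))
    } else {
      say("bam_lb_matches", FALSE, NULL)
    }

    issues <- map(aln_stats, "validation_issues")
    n_issues <- map_int(issues, nrow)
    say("bam_valid", TRUE, all(n_issues == 0L),
        unlist(map2(aln_refs$path, issues, function(p, iss) {
          if (nrow(iss) == 0) sprintf("%s: no validation issues", p)
          else sprintf("%s: %s %s", p, iss$rule_id, iss$detail)
        })))
  } else {
    for (id in c("bam_has_rg", "bam_sm_present", "bam_sm_matches", "bam_single_sm",
                 "bam_lb_present", "bam_lb_matches", "bam_valid")) {
      say(id, FALSE, NULL)
    }
  }

  # ---- Table 4: sample metadata ---------------------------------------------
  findings <- audit_samples(bundle$samples, config$lexicons)
  any_of <- function(col) nrow(findings) > 0 && any(findings[[col]])
  meta_evidence <- function(col) {
    hits <- findings$accession[findings[[col]]]
    if (length(hits) > 0) sprintf("finding '%s' true for sample(s): %s", col,
                                  paste(hits, collapse = ", "))
    else sprintf("finding '%s' true for no sample", col)
  }
  geo <- any_of("geo_any")
  say("geo_any", TRUE, geo, meta_evidence("geo_any"))
  say("geo_dedicated", geo, any_of("geo_dedicated_field"), meta_evidence("geo_dedicated_field"))
  say("geo_coords", geo, any_of("geo_coordinates"), meta_evidence("geo_coordinates"))
  dat <- any_of("date_any")
  say("date_any", TRUE, dat, meta_evidence("date_any"))
  say("date_dedicated", dat, any_of("date_dedicated_field"), meta_evidence("date_dedicated_field"))
  say("date_c14", dat, nrow(findings) > 0 && any(!is.na(findings$c14_lab_code)),
      if (any(!is.na(findings$c14_lab_code))) {
        sprintf("lab code(s): %s",
                paste(findings$c14_lab_code[!is.na(findings$c14_lab_code)], collapse = ", "))
      } else "no radiocarbon lab code found")
  tis <- any_of("tissue_any")
  say("tissue_any", TRUE, tis, meta_evidence("tissue_any"))
  say("tissue_dedicated", tis, any_of("tissue_dedicated_field"), meta_evidence("tissue_dedicated_field"))
  say("voucher_present", TRUE, any_of("voucher_present"), meta_evidence("voucher_present"))

  # ---- Table 5: negative-experiment reporting -------------------------------
  say("total_reported", !is.null(pr),
      !is.null(pr) && isTRUE(pr$total_reported_in_paper),
      if (!is.null(pr)) sprintf("paper states total studied samples: %s",
                                isTRUE(pr$total_reported_in_paper)) else character())
  total_known <- !is.null(pr) && !is.null(pr$n_samples_studied_total)
  say("all_samples_archived", total_known,
      if (total_known) counts$observed >= pr$n_samples_studied_total else NULL,
      if (total_known) sprintf("archived samples with data: %d; declared studied total: %d",
                               counts$observed, pr$n_samples_studied_total) else character())

  # ---- assemble -------------------------------------------------------------
  registry <- list_criteria()
  rows <- map(registry$criterion_id, function(id) {
    v <- verdicts[[id]]
    if (is.null(v)) {
      stop_adnaudit(sprintf("internal error: no verdict for criterion %s", id),
                    "adnaudit_evaluation_error")
    }
    applicable <- isTRUE(v$applicable)
    passed <- if (!applicable || is.null(v$passed)) NA else v$passed
    tibble(criterion_id = id, applicable = applicable, passed = as.logical(passed),
           evidence = list(as.character(v$evidence)))
  })
  out <- left_join(bind_rows(rows), registry[, c("criterion_id", "label", "table_ref")],
                   by = "criterion_id")
  out <- out[, c("criterion_id", "label", "table_ref", "applicable", "passed", "evidence")]
  structure(out,
            class = c("study_verdict", class(out)),
            study_accession = bundle$study$accession,
            config_fingerprint = config$fingerprint)
}

#' @export
print.study_verdict <- function(x, ...) {
  cat(sprintf("<study_verdict> %s (config %s)\n",
              attr(x, "study_accession"),
              substr(attr(x, "config_fingerprint"), 1, 8)))
  n_app <- sum(x$applicable)
  cat(sprintf("  %d criteria: %d applicable, %d pass, %d fail, %d indeterminate\n",
              nrow(x), n_app,
              sum(x$applicable & !is.na(x$passed) & x$passed),
              sum(x$applicable & !is.na(x$passed) & !x$passed),
              sum(x$applicable & is.na(x$passed))))
  fails <- x$criterion_id[x$applicable & !is.na(x$passed) & !x$passed]
  if (length(fails) > 0) cat("  failing:", paste(fails, collapse = ", "), "\n")
  invisible(x)
}
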