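# Seeded generator of complete synthetic study bundles: archive metadata plus
# FASTQ and SAM files on disk, with controlled archiving violations planted so
# that every detector in the rubric can be exercised against known ground
# truth. The violation-free baseline passes every applicable criterion; each
# violation code makes exactly its target criterion (plus logically entailed
# composites) fail.

#' Violation codes understood by the generator
#'
#' @return A character vector of codes accepted by [violation_profile()].
#' @export
violation_codes <- function() {
  c("aligned_only_no_raw", "raw_only_no_alignments", "untrimmed_adapters",
    "mapq_filter", "length_filter", "strip_unmapped",
    "no_read_groups", "no_sm", "sm_mismatch", "multi_sm", "no_lb", "lb_mismatch",
    "invalid_bam", "alignments_as_runs",
    "sample_overregistration", "duplicate_sample_suffix", "no_accession_reuse",
    "no_library_protocol",
    "no_geo", "geo_freetext_only", "no_coords",
    "no_date", "date_freetext_only", "date_no_c14",
    "no_tissue", "tissue_freetext_only", "no_voucher",
    "no_paper_total", "under_archive")
}

violation_incompatibilities <- function() {
  list(
    no_read_groups = c("no_sm", "sm_mismatch", "multi_sm", "no_lb", "lb_mismatch"),
    no_sm = c("sm_mismatch", "multi_sm"),
    no_lb = "lb_mismatch",
    no_geo = c("geo_freetext_only", "no_coords"),
    no_date = c("date_freetext_only", "date_no_c14"),
    no_tissue = "tissue_freetext_only",
    aligned_only_no_raw = c("untrimmed_adapters", "raw_only_no_alignments",
                            "sample_overregistration", "duplicate_sample_suffix"),
    raw_only_no_alignments = c("mapq_filter", "length_filter", "strip_unmapped",
                               "no_read_groups", "no_sm", "sm_mismatch", "multi_sm",
                               "no_lb", "lb_mismatch", "invalid_bam",
                               "alignments_as_runs")
  )
}

#' Build a planted-violation profile
#'
#' The ground-truth specification for one synthetic study: which archiving
#' defects to plant, plus the non-defect toggles (capture usage, a correctly
#' reused prior accession). Mutually contradictory codes are rejected.
#'
#' @param violations Character vector of codes from [violation_codes()].
#' @param used_capture Declare the study as a capture experiment (makes the
#'   capture criterion applicable).
#' @param reuse_ok Declare one sample as previously published *with* its
#'   existing accession correctly reused (makes the accession-reuse criterion
#'   applicable and passing).
#' @param mapq_threshold Threshold used by the `mapq_filter` code.
#' @param length_threshold Threshold used by the `length_filter` code.
#' @param invalid_rule Which validation rule the `invalid_bam` code breaks
#'   (`"V2"`, `"V3"`, `"V5"` or `"V7"`).
#' @param under_archive_k How many studied samples the `under_archive` code
#'   leaves unarchived.
#' @return A list of class `violation_profile`.
#' @export
violation_profile <- function(violations = character(),
                              used_capture = FALSE,
                              reuse_ok = FALSE,
                              mapq_threshold = 30L,
                              length_threshold = 35L,
                              invalid_rule = "V5",
                              under_archive_k = 1L) {
  violations <- unique(as.character(violations))
  unknown <- setdiff(violations, violation_codes())
  if (length(unknown) > 0) {
    stop_adnaudit(sprintf("unknown violation code(s): %s",
                          paste(unknown, collapse = ", ")),
                  "adnaudit_profile_error")
  }
  for (code in names(violation_incompatibilities())) {
    clash <- intersect(violation_incompatibilities()[[code]], violations)
    if (code %in% violations && length(clash) > 0) {
      stop_adnaudit(sprintf("contradictory violation codes: %s with %s",
                            code, paste(clash, collapse = ", ")),
                    "adnaudit_profile_error")
    }
  }
  if (!invalid_rule %in% c("V2", "V3", "V5", "V7")) {
    stop_adnaudit(sprintf("unsupported invalid_bam rule: %s", invalid_rule),
                  "adnaudit_profile_error")
  }
  structure(list(
    violations = violations,
    used_capture = isTRUE(used_capture),
    reuse_ok = isTRUE(reuse_ok),
    mapq_threshold = as.integer(mapq_threshold),
    length_threshold = as.integer(length_threshold),
    invalid_rule = invalid_rule,
    under_archive_k = as.integer(under_archive_k)
  ), class = "violation_profile")
}

#' Expected verdict changes for each violation code
#'
#' The entailment table the round-trip tests assert against: for every code,
#' which criteria it makes fail and which it renders not applicable,
#' relative to the violation-free baseline.
#'
#' @return A named list; each element has `fails` and `not_applicable`
#'   character vectors.
#' @export
violation_entailments <- function() {
  e <- function(fails = character(), not_applicable = character()) {
    list(fails = fails, not_applicable = not_applicable)
  }
  list(
    aligned_only_no_raw = e(
      # alignments double as the primary run files, so the analysis-file
      # criterion necessarily fails alongside the raw-read criteria
      c("raw_reads_archived", "both_archived", "alignments_as_analysis"),
      "adapters_trimmed"),
    raw_only_no_alignments = e(
      c("alignments_archived", "both_archived"),
      c("alignments_as_analysis", "no_any_hardfilter", "no_mapq_hardfilter",
        "no_length_hardfilter", "bam_has_rg", "bam_sm_present", "bam_sm_matches",
        "bam_single_sm", "bam_lb_present", "bam_lb_matches", "bam_valid")),
    untrimmed_adapters = e("adapters_trimmed"),
    mapq_filter = e(c("no_mapq_hardfilter", "no_any_hardfilter")),
    length_filter = e(c("no_length_hardfilter", "no_any_hardfilter")),
    strip_unmapped = e(),
    no_read_groups = e(c("bam_has_rg", "bam_lb_present"),
                       c("bam_sm_present", "bam_sm_matches", "bam_single_sm",
                         "bam_lb_matches")),
    no_sm = e("bam_sm_present", c("bam_sm_matches", "bam_single_sm")),
    sm_mismatch = e("bam_sm_matches"),
    multi_sm = e("bam_single_sm"),
    no_lb = e("bam_lb_present", "bam_lb_matches"),
    lb_mismatch = e("bam_lb_matches"),
    invalid_bam = e("bam_valid"),
    alignments_as_runs = e("alignments_as_analysis"),
    sample_overregistration = e("sample_count_match"),
    duplicate_sample_suffix = e("libraries_linked_single_sample"),
    no_accession_reuse = e("accession_reuse"),
    no_library_protocol = e("library_metadata_present"),
    no_geo = e("geo_any", c("geo_dedicated", "geo_coords")),
    geo_freetext_only = e(c("geo_dedicated", "geo_coords")),
    no_coords = e("geo_coords"),
    no_date = e("date_any", c("date_dedicated", "date_c14")),
    date_freetext_only = e("date_dedicated"),
    date_no_c14 = e("date_c14"),
    no_tissue = e("tissue_any", "tissue_dedicated"),
    tissue_freetext_only = e("tissue_dedicated"),
    no_voucher = e("voucher_present"),
    no_paper_total = e("total_reported"),
    under_archive = e("all_samples_archived")
  )
}

#' Simulate ancient-DNA-like reads
#'
#' Fragment lengths follow a triangular distribution (short molecules, a
#' mode well under the read length of modern platforms); bases are uniform
#' A/C/G/T. Deterministic for a fixed seed.
#'
#' @param n Number of reads.
#' @param seed Integer seed.
#' @param length_model Named vector `c(min =, mode =, max =)` in nucleotides.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
simulate_reads <- function(n, seed,
                           length_model = c(min = 25, mode = 45, max = 120)) {
  withr::with_seed(seed, simulate_reads_unseeded(n, length_model))
}

simulate_reads_unseeded <- function(n, length_model = c(min = 25, mode = 45, max = 120)) {
  if (n == 0) return(tibble(id = integer(), seq = character(), length = integer()))
  a <- length_model[["min"]]; cc <- length_model[["mode"]]; b <- length_model[["max"]]
  u <- stats::runif(n)
  fc <- (cc - a) / (b - a)
  len <- ifelse(u < fc, a + sqrt(u * (b - a) * (cc - a)),
                b - sqrt((1 - u) * (b - a) * (b - cc)))
  len <- pmin(pmax(as.integer(floor(len)), as.integer(a)), as.integer(b))
  total <- sum(len)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  big <- paste(chars, collapse = "")
  ends <- cumsum(len)
  tibble(id = seq_len(n), seq = substring(big, ends - len + 1L, ends),
         length = len)
}

syn_contigs <- function() c(ctg1 = 50000L, ctg2 = 50000L)
syn_mapq_values <- function() c(0L, 20L, 25L, 30L, 37L, 60L)
syn_mapq_probs <- function() c(0.10, 0.10, 0.05, 0.25, 0.30, 0.20)
syn_unmapped_fraction <- function() 0.7

# Draw one batch of alignment records with the baseline distributions.
draw_alignment_batch <- function(n) {
  reads <- simulate_reads_unseeded(n)
  contigs <- syn_contigs()
  unmapped <- stats::runif(n) < syn_unmapped_fraction()
  rname <- ifelse(unmapped, "*", sample(names(contigs), n, replace = TRUE))
  maxpos <- unname(contigs[1]) - reads$length + 1L
  pos <- ifelse(unmapped, 0L,
                as.integer(floor(stats::runif(n) * maxpos)) + 1L)
  mapq <- ifelse(unmapped, 0L,
                 sample(syn_mapq_values(), n, replace = TRUE,
                        prob = syn_mapq_probs()))
  reverse <- !unmapped & stats::runif(n) < 0.5
  tibble(
    flag = ifelse(unmapped, 4L, ifelse(reverse, 16L, 0L)),
    rname = rname, pos = as.integer(pos), mapq = as.integer(mapq),
    length = reads$length, seq = reads$seq
  )
}

# Generate alignment records until `n` survive the profile's hard filters.
generate_alignment_records <- function(n, profile) {
  has <- function(code) code %in% profile$violations
  keep_filtered <- function(batch) {
    keep <- rep(TRUE, nrow(batch))
    unmapped <- batch$flag == 4L
    if (has("strip_unmapped") || has("aligned_only_no_raw")) keep <- keep & !unmapped
    if (has("mapq_filter")) keep <- keep & !unmapped & batch$mapq >= profile$mapq_threshold
    if (has("length_filter")) keep <- keep & batch$length >= profile$length_threshold
    batch[keep, ]
  }
  acc <- NULL
  for (i in 1:40) {
    acc <- bind_rows(acc, keep_filtered(draw_alignment_batch(n)))
    if (nrow(acc) >= n) break
  }
  if (nrow(acc) < n) {
    stop_adnaudit("hard-filter acceptance rate too low to reach the target read count",
                  "adnaudit_profile_error")
  }
  acc[seq_len(n), ]
}

sort_alignment_records <- function(rec) {
  unmapped <- rec$flag == 4L
  mapped <- rec[!unmapped, ]
  mapped <- mapped[order(match(mapped$rname, names(syn_contigs())), mapped$pos), ]
  bind_rows(mapped, rec[unmapped, ])
}

write_fastq_file <- function(ids, seqs, path) {
  qual <- strrep("F", nchar(seqs))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

generate_sample_sam <- function(profile, alias, sample_accession, library_name,
                                qname_prefix, n_reads, path) {
  has <- function(code) code %in% profile$violations
  rec <- generate_alignment_records(n_reads, profile)
  rec <- sort_alignment_records(rec)

  rg_id <- paste0("RG_", alias)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(syn_contigs()), syn_contigs()))
  sm <- if (has("sm_mismatch")) paste0("EXT_", alias) else alias
  lb <- if (has("lb_mismatch")) "unregistered_lib" else library_name
  rg_lines <- NULL
  rec$rg <- NA_character_
  if (!has("no_read_groups")) {
    mk_rg <- function(id, sm_val) {
      parts <- c(sprintf("@RG\tID:%s", id),
                 if (!has("no_sm")) sprintf("SM:%s", sm_val),
                 if (!has("no_lb")) sprintf("LB:%s", lb),
                 "PL:ILLUMINA")
      paste(parts, collapse = "\t")
    }
    if (has("multi_sm")) {
      # Both SM values are legitimate identifiers of the same sample, so only
      # the single-SM rule is violated, not the SM-matching rule.
      rg_lines <- c(mk_rg(rg_id, sm), mk_rg(paste0(rg_id, "_b"), sample_accession))
      rec$rg <- ifelse(seq_len(nrow(rec)) %% 2L == 0L, paste0(rg_id, "_b"), rg_id)
    } else {
      rg_lines <- mk_rg(rg_id, sm)
      rec$rg <- rg_id
    }
    if (has("invalid_bam") && profile$invalid_rule == "V2") {
      rg_lines <- c(rg_lines, rg_lines[1])
    }
  }
  header <- c(header, rg_lines)

  out <- tibble(
    qname = sprintf("%s_a%06d", qname_prefix, seq_len(nrow(rec))),
    flag = rec$flag, rname = rec$rname, pos = rec$pos, mapq = rec$mapq,
    cigar = ifelse(rec$flag == 4L, "*", paste0(rec$length, "M")),
    seq = rec$seq, qual = strrep("F", rec$length), rg = rec$rg
  )
  if (has("invalid_bam")) {
    if (profile$invalid_rule == "V5" && nrow(out) > 0) {
      out$qual[1] <- substring(out$qual[1], 1, max(1L, nchar(out$qual[1]) - 2L))
    } else if (profile$invalid_rule == "V3" && nrow(out) > 0) {
      out$rg[1] <- "RG_undeclared"
    } else if (profile$invalid_rule == "V7") {
      mapped_idx <- which(out$flag != 4L)
      if (length(mapped_idx) >= 2) {
        out[mapped_idx[1:2], ] <- out[mapped_idx[2:1], ]
      }
    }
  }
  write_sam_file(header, out, path)
}

#' Generate one synthetic study bundle
#'
#' Fabricates a complete study on disk -- bundle JSON, per-sample FASTQ runs
#' and per-sample SAM alignment files -- whose audit outcome is fully
#' determined by the planted [violation_profile()]. FASTQ output is
#' byte-deterministic and SAM output record-deterministic for a fixed seed.
#'
#' @param profile A [violation_profile()].
#' @param seed Integer seed.
#' @param out_dir Output directory; the study is written to
#'   `out_dir/<study_accession>/`.
#' @param study_accession Accession for the generated study.
#' @param n_reads Reads per generated file.
#' @param n_samples Samples per study.
#' @return The generated [study_bundle()], invisibly, with the bundle path in
#'   attribute `path`.
#' @export
generate_study <- function(profile, seed, out_dir,
                           study_accession = "SYNSTU0001",
                           n_reads = 5000L, n_samples = 3L) {
  stopifnot(inherits(profile, "violation_profile"), n_reads >= 1, n_samples >= 1)
  has <- function(code) code %in% profile$violations
  study_dir <- file.path(out_dir, study_accession)
  dir.create(study_dir, recursive = TRUE, showWarnings = FALSE)

  withr::with_seed(as.integer(seed), {
    aliases <- sprintf("%s_S%d", study_accession, seq_len(n_samples))
    sample_acc <- sprintf("SAM%sX%02d", study_accession, seq_len(n_samples))
    samples <- tibble(
      accession = sample_acc, alias = aliases,
      title = sprintf("Ancient sample %s", aliases),
      attributes = map(aliases, function(a) synth_sample_attributes(profile))
    )

    lib_names <- sprintf("LIB_%s", aliases)
    runs <- empty_runs()
    protocol <- if (has("no_library_protocol")) NA_character_ else
      "double-stranded, UDG-half treated library"

    want_fastq <- !has("aligned_only_no_raw")
    if (want_fastq) {
      fastq_paths <- sprintf("%s.fastq", aliases)
      for (i in seq_len(n_samples)) {
        reads <- simulate_reads_unseeded(n_reads)
        seqs <- reads$seq
        if (has("untrimmed_adapters")) {
          seqs <- append_adapter_readthrough(seqs)
        }
        write_fastq_file(sprintf("%s_r%06d", aliases[i], reads$id), seqs,
                         file.path(study_dir, fastq_paths[i]))
      }
      runs <- bind_rows(runs, tibble(
        accession = sprintf("%sR%d", study_accession, seq_len(n_samples)),
        sample_accession = sample_acc, library_name = lib_names,
        library_construction_protocol = protocol,
        instrument_platform = "ILLUMINA", submitted_format = "FASTQ",
        files = map(fastq_paths, function(p) tibble(path = p, declared_format = "fastq"))
      ))
    }

    analyses <- empty_analyses()
    want_bam <- !has("raw_only_no_alignments")
    if (want_bam) {
      sam_paths <- sprintf("%s.sam", aliases)
      for (i in seq_len(n_samples)) {
        generate_sample_sam(profile, aliases[i], sample_acc[i], lib_names[i],
                            aliases[i], n_reads, file.path(study_dir, sam_paths[i]))
      }
      # Without raw reads the alignments ARE the primary data, so the archive
      # registers them as run records (as real aligned-only submissions do).
      if (has("alignments_as_runs") || has("aligned_only_no_raw")) {
        runs <- bind_rows(runs, tibble(
          accession = sprintf("%sRB%d", study_accession, seq_len(n_samples)),
          sample_accession = sample_acc, library_name = lib_names,
          library_construction_protocol = protocol,
          instrument_platform = "ILLUMINA", submitted_format = "BAM",
          files = map(sam_paths, function(p) tibble(path = p, declared_format = "sam"))
        ))
      } else {
        analyses <- tibble(
          accession = sprintf("%sA%d", study_accession, seq_len(n_samples)),
          analysis_type = "REFERENCE_ALIGNMENT",
          linked_run_accessions = map(seq_len(n_samples), function(i) {
            if (want_fastq) sprintf("%sR%d", study_accession, i) else character()
          }),
          linked_sample_accessions = map(sample_acc, identity),
          files = map(sam_paths, function(p) tibble(path = p, declared_format = "sam"))
        )
      }
    }

    # extra sample accessions: library-level over-registration and informal
    # "_new" duplicates (both carry their own data files)
    extra_runs <- NULL
    if (has("sample_overregistration") && want_fastq) {
      extra_alias <- sprintf("%sL2", aliases)
      extra_acc <- sprintf("%sB", sample_acc)
      samples <- bind_rows(samples, tibble(
        accession = extra_acc, alias = extra_alias,
        title = sprintf("Ancient sample %s", extra_alias),
        attributes = map(extra_alias, function(a) synth_sample_attributes(profile))
      ))
      for (i in seq_len(n_samples)) {
        reads <- simulate_reads_unseeded(n_reads)
        write_fastq_file(sprintf("%s_r%06d", extra_alias[i], reads$id), reads$seq,
                         file.path(study_dir, sprintf("%s.fastq", extra_alias[i])))
      }
      extra_runs <- tibble(
        accession = sprintf("%sRX%d", study_accession, seq_len(n_samples)),
        sample_accession = extra_acc,
        library_name = sprintf("LIB_%s", extra_alias),
        library_construction_protocol = protocol,
        instrument_platform = "ILLUMINA", submitted_format = "FASTQ",
        files = map(sprintf("%s.fastq", extra_alias), function(p)
          tibble(path = p, declared_format = "fastq"))
      )
    }
    n_dup <- 0L
    if (has("duplicate_sample_suffix") && want_fastq) {
      dup_alias <- paste0(aliases[1], "_new")
      dup_acc <- paste0(sample_acc[1], "N")
      samples <- bind_rows(samples, tibble(
        accession = dup_acc, alias = dup_alias,
        title = sprintf("Ancient sample %s", dup_alias),
        attributes = list(synth_sample_attributes(profile))
      ))
      reads <- simulate_reads_unseeded(n_reads)
      write_fastq_file(sprintf("%s_r%06d", dup_alias, reads$id), reads$seq,
                       file.path(study_dir, paste0(dup_alias, ".fastq")))
      extra_runs <- bind_rows(extra_runs, tibble(
        accession = sprintf("%sRN1", study_accession),
        sample_accession = dup_acc, library_name = paste0("LIB_", dup_alias),
        library_construction_protocol = protocol,
        instrument_platform = "ILLUMINA", submitted_format = "FASTQ",
        files = list(tibble(path = paste0(dup_alias, ".fastq"),
                            declared_format = "fastq"))
      ))
      n_dup <- 1L
    }
    if (!is.null(extra_runs)) runs <- bind_rows(runs, extra_runs)

    # paper-declared facts: the analysed count covers the informal duplicate
    # (so only the linkage criterion fails for it) but not over-registered
    # library-level accessions (the count-mismatch criterion's target).
    declared_analysed <- n_samples + n_dup
    pps <- NULL
    if (has("no_accession_reuse")) {
      pps <- tibble(alias = aliases[1], existing_accession = "SAMEAPREV00001")
    } else if (profile$reuse_ok) {
      pps <- tibble(alias = aliases[1], existing_accession = sample_acc[1])
    }
    pr <- paper_report(
      n_samples_analysed = declared_analysed,
      n_samples_studied_total = declared_analysed +
        if (has("under_archive")) profile$under_archive_k else 0L,
      used_capture = profile$used_capture,
      previously_published_samples = pps,
      total_reported_in_paper = !has("no_paper_total")
    )

    bundle <- study_bundle(
      study = list(accession = study_accession,
                   title = sprintf("Synthetic ancient genomics study %s", study_accession),
                   description = "Generated study bundle with planted archiving defects"),
      samples = samples, runs = runs, analyses = analyses, paper_report = pr
    )
    bundle_path <- file.path(study_dir, "bundle.json")
    write_bundle(bundle, bundle_path)
    attr(bundle, "path") <- bundle_path
    invisible(bundle)
  })
}

synth_sample_attributes <- function(profile) {
  has <- function(code) code %in% profile$violations
  date_text <- if (has("date_no_c14")) "4520 BP" else "4520 BP (OxA-12345)"
  description <- "Ancient DNA extract"
  attrs <- list()
  add <- function(tag, value) {
    attrs[[length(attrs) + 1L]] <<- tibble(tag = tag, value = value,
                                           units = NA_character_)
  }
  if (!has("no_geo")) {
    if (has("geo_freetext_only")) {
      description <- paste0(description, "; recovered near Norfolk, United Kingdom")
    } else {
      add("geographic location (region and locality)", "Norfolk, United Kingdom")
      if (!has("no_coords")) {
        add("geographic location (latitude)", "52.62")
        add("geographic location (longitude)", "1.24")
      }
    }
  }
  if (!has("no_date")) {
    if (has("date_freetext_only")) {
      description <- paste0(description, "; dated to ", date_text)
    } else {
      add("date", date_text)
    }
  }
  if (!has("no_tissue")) {
    if (has("tissue_freetext_only")) {
      description <- paste0(description, "; sampled from Bone")
    } else {
      add("tissue", "petrous part of temporal")
    }
  }
  if (!has("no_voucher")) {
    add("specimen voucher", "NHM-PV-0042")
  }
  add("Description", description)
  bind_rows(attrs)
}

# Deterministic read-through planting: the first `fraction` of reads gain a
# 3' adapter tail of at least `min_tail` nucleotides.
append_adapter_readthrough <- function(seqs, fraction = 0.35, min_tail = 10L) {
  adapter <- default_adapters()[[1]]
  idx <- seq_len(ceiling(length(seqs) * fraction))
  tail_len <- min_tail + (idx %% 9L)
  seqs[idx] <- paste0(seqs[idx], substring(adapter, 1, tail_len))
  seqs
}

#' Specify a synthetic cohort
#'
#' @param entries A list of entries, each a list with elements `profile` (a
#'   [violation_profile()]) and `n_studies`.
#' @param seed Cohort seed; study `i` is generated with seed `seed + i`.
#' @param n_reads Reads per generated file.
#' @param n_samples Samples per study.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(entries, seed = 1L, n_reads = 5000L, n_samples = 3L) {
  stopifnot(length(entries) > 0)
  entries <- map(entries, function(e) {
    stopifnot(inherits(e$profile, "violation_profile"))
    if (is.null(e$n_studies) || e$n_studies < 1) {
      stop_adnaudit("each cohort entry needs n_studies >= 1", "adnaudit_profile_error")
    }
    list(profile = e$profile, n_studies = as.integer(e$n_studies))
  })
  structure(list(entries = entries, seed = as.integer(seed),
                 n_reads = as.integer(n_reads), n_samples = as.integer(n_samples)),
            class = "cohort_spec")
}

#' Read a cohort specification from JSON
#'
#' The JSON form mirrors [cohort_spec()]: top-level `seed`, `n_reads`,
#' `n_samples` and an `entries` array of `{profile: {...}, n_studies: n}`
#' objects, where `profile` holds [violation_profile()] arguments.
#'
#' @param path JSON file.
#' @param seed,n_reads,n_samples Optional overrides of the file's values.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path, seed = NULL, n_reads = NULL, n_samples = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- map(raw$entries, function(e) {
    args <- e$profile %||% list()
    if (!is.null(args$violations)) args$violations <- unlist(args$violations)
    list(profile = do.call(violation_profile, args), n_studies = e$n_studies)
  })
  cohort_spec(entries,
              seed = seed %||% raw$seed %||% 1L,
              n_reads = n_reads %||% raw$n_reads %||% 5000L,
              n_samples = n_samples %||% raw$n_samples %||% 3L)
}

#' Generate a synthetic cohort
#'
#' Generates every study of a [cohort_spec()] (study `i` under seed
#' `spec$seed + i`) and writes a ground-truth manifest.
#'
#' @param spec A `cohort_spec` (or path to its JSON form).
#' @param out_dir Output directory.
#' @return The manifest tibble: `study_accession`, `planted_codes`
#'   (comma-separated), `used_capture`, `reuse_ok`, `seed`, `bundle_path`.
#'   Also written to `out_dir/manifest.tsv`.
#' @export
generate_cohort <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- unlist(map(spec$entries, function(e) {
    rep(list(e$profile), e$n_studies)
  }), recursive = FALSE)
  manifest <- map(seq_along(profiles), function(i) {
    acc <- sprintf("SYNSTU%04d", i)
    bundle <- generate_study(profiles[[i]], seed = spec$seed + i, out_dir = out_dir,
                             study_accession = acc, n_reads = spec$n_reads,
                             n_samples = spec$n_samples)
    tibble(
      study_accession = acc,
      planted_codes = paste(profiles[[i]]$violations, collapse = ","),
      used_capture = profiles[[i]]$used_capture,
      reuse_ok = profiles[[i]]$reuse_ok,
      seed = spec$seed + i,
      bundle_path = attr(bundle, "path")
    )
  }) |> bind_rows()
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  manifest
}

#' Audit every study of a generated cohort
#'
#' @param manifest A manifest tibble from [generate_cohort()], or the path of
#'   a cohort directory containing `manifest.tsv`.
#' @param config An [audit_config()].
#' @return A list of `study_verdict` objects, one per study.
#' @export
audit_cohort <- function(manifest, config = audit_config()) {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(file.path(manifest, "manifest.tsv"),
                                col_types = readr::cols(), progress = FALSE)
  }
  map(manifest$bundle_path, function(p) audit_study(p, config = config))
}
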