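# Read-level inspection: per-file statistics (MAPQ/length histograms,
# unmapped fraction, adapter residue, read-group roster), a hard-filter
# signature inferred from those statistics, and an internal SAM/BAM
# validation rule set (V1-V7).

#' Default adapter set
#'
#' Illumina TruSeq read-1/read-2 and Nextera adapter starts, shipped as a
#' small FASTA under `inst/extdata/adapters.fasta` that users can replace
#' with [read_adapters()].
#'
#' @return A named character vector of adapter sequences.
#' @export
default_adapters <- function() {
  read_adapters(system.file("extdata", "adapters.fasta", package = "adnaudit"))
}

#' Read an adapter set from a FASTA file
#'
#' @param path FASTA file of adapter sequences.
#' @return A named character vector of adapter sequences.
#' @export
read_adapters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  idx <- cumsum(startsWith(lines, ">"))
  headers <- sub("^>\\s*", "", lines[startsWith(lines, ">")])
  seqs <- vapply(split(lines[!startsWith(lines, ">")], idx[!startsWith(lines, ">")]),
                 paste0, character(1), collapse = "")
  setNames(toupper(unname(seqs)), vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1))
}

#' Detect residual adapter sequence at read 3' ends
#'
#' Looks for the read-through signature of an untrimmed library: a suffix of
#' the read that matches a prefix of one of the adapter sequences. The
#' leftmost (longest-overlap) match with overlap at least `min_overlap` and at
#' most `floor(max_mismatch_rate * overlap)` mismatches is reported.
#' Non-nucleotide symbols count as mismatches.
#'
#' @param reads Character vector of read sequences (vectorised).
#' @param adapters Adapter set, as from [default_adapters()].
#' @param min_overlap Minimum read/adapter overlap in nucleotides.
#' @param max_mismatch_rate Allowed mismatch rate within the overlap,
#'   in `[0, 0.5)`.
#' @return A tibble with one row per read: `start` (0-based offset of the
#'   adapter within the read), `length` (overlap length), `adapter` (name of
#'   the matching adapter). All-`NA` rows mark reads without adapter residue.
#' @export
detect_adapter_residue <- function(reads, adapters = default_adapters(),
                                   min_overlap = 8L, max_mismatch_rate = 0.1) {
  stopifnot(min_overlap >= 1, max_mismatch_rate >= 0, max_mismatch_rate < 0.5)
  n <- length(reads)
  out <- tibble(start = rep(NA_integer_, n), length = rep(NA_integer_, n),
                adapter = rep(NA_character_, n))
  if (n == 0) return(out)
  reads <- toupper(reads)
  lens <- nchar(reads)
  max_len <- max(lens, 0L)
  if (max_len < min_overlap) return(out)

  # Right-align all reads in one integer matrix of char codes so that a given
  # overlap length addresses the same columns for every read. Left-padding
  # with spaces keeps one decoding pass; padded cells never qualify because a
  # match additionally requires lens >= overlap.
  padded <- formatC(reads, width = max_len)   # right-justified: pads on the left
  codes <- matrix(utf8ToInt(paste0(padded, collapse = "")),
                  nrow = n, ncol = max_len, byrow = TRUE)

  ad_codes <- map(adapters, utf8ToInt)
  top <- min(max_len, max(nchar(adapters)))
  if (top < min_overlap) return(out)
  # Longest overlap first = leftmost match; adapter order breaks ties at a
  # given offset.
  for (o in seq(top, min_overlap)) {
    cols <- (max_len - o + 1L):max_len
    for (ad_i in seq_along(adapters)) {
      if (length(ad_codes[[ad_i]]) < o) next
      open <- which(is.na(out$start) & lens >= o)
      if (length(open) == 0) next
      mism <- rowSums(codes[open, cols, drop = FALSE] !=
                        matrix(ad_codes[[ad_i]][seq_len(o)], nrow = length(open),
                               ncol = o, byrow = TRUE))
      hit <- open[mism <= floor(max_mismatch_rate * o)]
      if (length(hit) > 0) {
        out$start[hit] <- lens[hit] - o
        out$length[hit] <- o
        out$adapter[hit] <- names(adapters)[ad_i] %||% as.character(ad_i)
      }
    }
  }
  out
}

#' Parse the read groups of an alignment file
#'
#' One entry is returned per `@RG` header line; absent tags are reported as
#' `NA`, never defaulted. Duplicate read-group IDs are flagged through a
#' `duplicate_rg_ids` attribute (and by rule V2 of
#' [validate_alignment_file()]).
#'
#' @param path A SAM or BAM file.
#' @return A tibble with columns `rg_id`, `sample_tag` (SM), `library_tag`
#'   (LB), `platform_tag` (PL).
#' @export
parse_read_groups <- function(path) {
  parsed <- read_alignment_file(path, n_max = 0)
  read_groups_from_header(parsed$header)
}

read_groups_from_header <- function(header) {
  rg_lines <- parse_header_tags(header, "@RG")
  out <- tibble(
    rg_id = map_chr(rg_lines, tag_or_na, "ID"),
    sample_tag = map_chr(rg_lines, tag_or_na, "SM"),
    library_tag = map_chr(rg_lines, tag_or_na, "LB"),
    platform_tag = map_chr(rg_lines, tag_or_na, "PL")
  )
  dup <- unique(out$rg_id[duplicated(out$rg_id)])
  if (length(dup) > 0) attr(out, "duplicate_rg_ids") <- dup
  out
}

#' Collect per-file read statistics
#'
#' Streams the first `n_sample` records of a FASTQ or SAM/BAM file and
#' summarises everything the read-level criteria need: mapped/unmapped
#' counts, MAPQ and read-length histograms, the minimum mapped MAPQ (255,
#' "unavailable", is excluded), adapter-residue fraction, the read-group
#' roster and its distinct SM values. Sampling the first records (rather
#' than a random subset) keeps the statistics deterministic.
#'
#' Adapter residue is only assessed where it is meaningful: on FASTQ files
#' and on alignment files that contain no aligned records (raw reads
#' deposited in BAM form).
#'
#' @param path Path to the file.
#' @param format File format, one of `"fastq"`, `"sam"`, `"bam"`, `"cram"`;
#'   guessed from the extension when `NULL`.
#' @param n_sample Number of records to sample from the head of the file.
#' @param adapters,min_overlap,max_mismatch_rate Passed to
#'   [detect_adapter_residue()].
#' @return An object of class `seq_file_stats`.
#' @export
collect_seq_stats <- function(path, format = NULL, n_sample = 10000L,
                              adapters = default_adapters(),
                              min_overlap = 8L, max_mismatch_rate = 0.1) {
  stopifnot(n_sample >= 1)
  format <- tolower(format %||% guess_format(path))
  if (format == "fastq") {
    reads <- read_fastq_records(path, n_max = n_sample)
    n <- nrow(reads)
    lens <- nchar(reads$seq)
    hits <- detect_adapter_residue(reads$seq, adapters, min_overlap, max_mismatch_rate)
    stats <- list(
      path = path, declared_format = "fastq",
      n_reads_sampled = n, n_mapped = 0L, n_unmapped = n,
      min_mapq_mapped = NA_integer_, mapq_histogram = integer(),
      min_length = if (n > 0) min(lens) else NA_integer_,
      length_histogram = int_table(lens),
      adapter_residue_fraction = if (n > 0) mean(!is.na(hits$start)) else 0,
      read_groups = read_groups_from_header(character()),
      distinct_sm_values = character(),
      paired_fraction = 0,
      validation_issues = empty_validation_issues()
    )
  } else if (format %in% c("sam", "bam", "cram")) {
    parsed <- read_alignment_file(path, n_max = n_sample)
    rec <- parsed$records
    n <- nrow(rec)
    unmapped <- bitwAnd(rec$flag, 4L) != 0L
    mapped_mapq <- rec$mapq[!unmapped & rec$mapq != 255L]
    lens <- nchar(rec$seq)
    lens[rec$seq == "*"] <- 0L
    rgs <- read_groups_from_header(parsed$header)
    adapter_frac <- 0
    if (n > 0 && all(unmapped)) {
      hits <- detect_adapter_residue(rec$seq, adapters, min_overlap, max_mismatch_rate)
      adapter_frac <- mean(!is.na(hits$start))
    }
    stats <- list(
      path = path, declared_format = format,
      n_reads_sampled = n, n_mapped = sum(!unmapped), n_unmapped = sum(unmapped),
      min_mapq_mapped = if (length(mapped_mapq) > 0) min(mapped_mapq) else NA_integer_,
      mapq_histogram = int_table(rec$mapq[!unmapped]),
      min_length = if (n > 0) min(lens) else NA_integer_,
      length_histogram = int_table(lens),
      adapter_residue_fraction = adapter_frac,
      read_groups = rgs,
      distinct_sm_values = sort(unique(rgs$sample_tag[!is.na(rgs$sample_tag)])),
      paired_fraction = if (n > 0) mean(bitwAnd(rec$flag, 1L) != 0L) else 0,
      validation_issues = validate_parsed_alignment(parsed)
    )
  } else {
    stop_adnaudit(sprintf("unsupported format '%s' for %s", format, path),
                  "adnaudit_format_error")
  }
  structure(stats, class = "seq_file_stats")
}

int_table <- function(x) {
  if (length(x) == 0) return(integer())
  tab <- table(x)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.seq_file_stats <- function(x, ...) {
  cat(sprintf("<seq_file_stats> %s (%s)\n", basename(x$path), x$declared_format))
  cat(sprintf("  %d read(s) sampled: %d mapped, %d unmapped\n",
              x$n_reads_sampled, x$n_mapped, x$n_unmapped))
  cat(sprintf("  min MAPQ (mapped): %s; min length: %s; adapter residue: %.4f\n",
              x$min_mapq_mapped, x$min_length, x$adapter_residue_fraction))
  cat(sprintf("  %d read group(s), %d distinct SM value(s), %d validation issue(s)\n",
              nrow(x$read_groups), length(x$distinct_sm_values),
              nrow(x$validation_issues)))
  invisible(x)
}

#' Infer the hard-filter signature of an alignment file
#'
#' Archived BAM files often betray irreversible "hard" filtering through
#' their distributions: a minimum mapped MAPQ at or above a typical analysis
#' threshold suggests a MAPQ filter, a minimum read length at or above a
#' typical length cutoff suggests a length filter, and the complete absence
#' of unmapped records shows they were removed. Because a high minimum can
#' also arise by chance in a small sample, each inference requires its
#' denominator to reach `min_confident_n` reads.
#'
#' @param stats A `seq_file_stats` object from [collect_seq_stats()].
#' @param mapq_trigger MAPQ at or above which the minimum mapped MAPQ is
#'   taken as evidence of filtering (surveyed studies filtered at 25 or
#'   higher).
#' @param length_trigger Read length at or above which the minimum length is
#'   taken as evidence of filtering (surveyed studies filtered at 30 or
#'   higher).
#' @param min_confident_n Minimum number of reads behind each inference.
#' @return A list of class `filter_signature` with elements
#'   `unmapped_removed`, `mapq_filtered`, `mapq_floor`, `length_filtered`,
#'   `length_floor`, `confident`.
#' @export
infer_hard_filters <- function(stats, mapq_trigger = 25L, length_trigger = 30L,
                               min_confident_n = 1000L) {
  stopifnot(inherits(stats, "seq_file_stats"))
  mapq_conf <- stats$n_mapped >= min_confident_n
  len_conf <- stats$n_reads_sampled >= min_confident_n
  mapq_filtered <- mapq_conf && !is.na(stats$min_mapq_mapped) &&
    stats$min_mapq_mapped >= mapq_trigger
  length_filtered <- len_conf && !is.na(stats$min_length) &&
    stats$min_length >= length_trigger
  structure(list(
    unmapped_removed = stats$declared_format %in% c("bam", "sam", "cram") &&
      stats$n_unmapped == 0L && stats$n_mapped > 0L,
    mapq_filtered = mapq_filtered,
    mapq_floor = if (mapq_filtered) stats$min_mapq_mapped else NA_integer_,
    length_filtered = length_filtered,
    length_floor = if (length_filtered) stats$min_length else NA_integer_,
    confident = mapq_conf && len_conf
  ), class = "filter_signature")
}

#' Classify the archival role of a sequence file
#'
#' FASTQ files are raw reads by definition. A BAM file with no aligned
#' records is raw reads deposited in BAM form; one with no unmapped records
#' is an alignment-only product; one with both is an alignment that retains
#' the complete read set.
#'
#' @param stats A `seq_file_stats` object.
#' @return One of `"raw_reads"`, `"aligned_only"`, `"aligned_with_unmapped"`,
#'   `"ambiguous"`.
#' @export
classify_file_role <- function(stats) {
  stopifnot(inherits(stats, "seq_file_stats"))
  if (stats$declared_format == "fastq") return("raw_reads")
  if (stats$n_reads_sampled == 0L) return("ambiguous")
  if (stats$n_mapped == 0L) return("raw_reads")
  if (stats$n_unmapped == 0L) return("aligned_only")
  "aligned_with_unmapped"
}

# ---- validation rule set ----------------------------------------------------

empty_validation_issues <- function() {
  tibble(rule_id = character(), detail = character(), record_index = integer())
}

#' Validate an alignment file against the internal rule set
#'
#' A fixed set of structural rules standing in for an external BAM validator:
#' \describe{
#'   \item{V1}{the header parses and carries an `@HD` line with a `VN` tag;}
#'   \item{V2}{read-group IDs are unique;}
#'   \item{V3}{every record's RG tag references a declared read group;}
#'   \item{V4}{mapped records name a declared reference and fall within its
#'     bounds;}
#'   \item{V5}{sequence and quality strings have equal length;}
#'   \item{V6}{flag bits are coherent (mate bits only on paired records);}
#'   \item{V7}{records respect the sort order the header declares.}
#' }
#' An empty result means the file passes.
#'
#' @param path A SAM or BAM file.
#' @param n_sample Number of records to validate from the head of the file.
#' @return A tibble of issues with columns `rule_id`, `detail`,
#'   `record_index`.
#' @export
validate_alignment_file <- function(path, n_sample = 10000L) {
  parsed <- read_alignment_file(path, n_max = n_sample)
  validate_parsed_alignment(parsed)
}

validate_parsed_alignment <- function(parsed) {
  issues <- list()
  add <- function(rule, detail, index = NA_integer_) {
    issues[[length(issues) + 1L]] <<- tibble(rule_id = rule, detail = detail,
                                             record_index = as.integer(index))
  }
  header <- parsed$header
  rec <- parsed$records

  hd <- parse_header_tags(header, "@HD")
  if (length(hd) == 0 || is.na(tag_or_na(hd[[1]], "VN"))) {
    add("V1", "header has no @HD line with a VN tag")
  }

  rgs <- read_groups_from_header(header)
  dup <- attr(rgs, "duplicate_rg_ids")
  if (!is.null(dup)) {
    add("V2", sprintf("duplicate read-group ID(s): %s", paste(dup, collapse = ", ")))
  }

  if (nrow(rec) > 0) {
    bad_rg <- which(!is.na(rec$rg) & !(rec$rg %in% rgs$rg_id))
    if (length(bad_rg) > 0) {
      add("V3", sprintf("record RG tag '%s' not declared in header",
                        rec$rg[bad_rg[1]]), bad_rg[1])
    }

    sq <- parse_header_tags(header, "@SQ")
    sq_names <- map_chr(sq, tag_or_na, "SN")
    sq_len <- suppressWarnings(as.integer(map_chr(sq, tag_or_na, "LN")))
    mapped <- bitwAnd(rec$flag, 4L) == 0L
    ref_idx <- match(rec$rname, sq_names)
    bad_ref <- which(mapped & (rec$rname == "*" | is.na(ref_idx)))
    if (length(bad_ref) > 0) {
      add("V4", sprintf("mapped record references undeclared contig '%s'",
                        rec$rname[bad_ref[1]]), bad_ref[1])
    }
    in_ref <- mapped & !is.na(ref_idx)
    bad_pos <- which(in_ref & (rec$pos < 1L | rec$pos > sq_len[ref_idx]))
    if (length(bad_pos) > 0) {
      add("V4", sprintf("mapped record position %d outside contig bounds",
                        rec$pos[bad_pos[1]]), bad_pos[1])
    }

    seq_len_ <- nchar(rec$seq)
    qual_len <- nchar(rec$qual)
    bad_len <- which(rec$seq != "*" & rec$qual != "*" & seq_len_ != qual_len)
    if (length(bad_len) > 0) {
      add("V5", sprintf("sequence length %d != quality length %d",
                        seq_len_[bad_len[1]], qual_len[bad_len[1]]), bad_len[1])
    }

    paired <- bitwAnd(rec$flag, 1L) != 0L
    mate_bits <- bitwAnd(rec$flag, 2L + 8L + 32L + 64L + 128L) != 0L
    bad_flag <- which(!paired & mate_bits)
    if (length(bad_flag) > 0) {
      add("V6", sprintf("unpaired record carries mate/pairing flag bits (flag=%d)",
                        rec$flag[bad_flag[1]]), bad_flag[1])
    }

    so <- if (length(hd) > 0) tag_or_na(hd[[1]], "SO") else "unknown"
    if (identical(so, "coordinate") && any(mapped)) {
      ord_ref <- ref_idx[mapped]
      ord_pos <- rec$pos[mapped]
      key <- ord_ref * (max(sq_len, 1L, na.rm = TRUE) + 1) + ord_pos
      desc <- which(diff(key) < 0)
      if (length(desc) > 0) {
        add("V7", "records out of coordinate order despite SO:coordinate header",
            which(mapped)[desc[1] + 1L])
      }
      first_unmapped <- which(!mapped & rec$rname == "*")
      if (length(first_unmapped) > 0 && any(which(mapped) > first_unmapped[1])) {
        add("V7", "mapped record after unmapped block in coordinate-sorted file",
            which(mapped)[which(mapped) > first_unmapped[1]][1])
      }
    }
  }

  if (length(issues) == 0) empty_validation_issues() else bind_rows(issues)
}
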