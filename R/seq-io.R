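# Low-level readers for the formats the auditor inspects. Sampling is always
# "the first N records" -- deterministic and streamable, mirroring the survey
# convention of looking at the first listed file of a study.

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
}

#' Read the first records of a FASTQ file
#'
#' @param path Plain or gzip-compressed FASTQ (4-line records).
#' @param n_max Maximum number of records to read.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @keywords internal
read_fastq_records <- function(path, n_max = Inf) {
  if (!file.exists(path)) {
    stop_adnaudit(sprintf("FASTQ file not found: %s", path), "adnaudit_io_error")
  }
  con <- open_text(path)
  on.exit(close(con))
  n_lines <- if (is.finite(n_max)) 4L * as.integer(n_max) else -1L
  lines <- readLines(con, n = n_lines, warn = FALSE)
  if (length(lines) == 0) return(tibble(id = character(), seq = character(), qual = character()))
  if (length(lines) %% 4 != 0) {
    stop_adnaudit(
      sprintf("truncated FASTQ record in %s near line %d", path, length(lines)),
      "adnaudit_format_error")
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  if (any(substr(ids, 1, 1) != "@")) {
    bad <- which(substr(ids, 1, 1) != "@")[1]
    stop_adnaudit(
      sprintf("malformed FASTQ header in %s at record %d", path, bad),
      "adnaudit_format_error")
  }
  tibble(
    id = sub("^@", "", ids),
    seq = lines[seq(2, length(lines), by = 4)],
    qual = lines[seq(4, length(lines), by = 4)]
  )
}

# Parsed alignment file: list(header = character() of "@..." lines,
# records = tibble(qname, flag, rname, pos, mapq, cigar, seq, qual, rg)).
read_alignment_file <- function(path, n_max = Inf) {
  if (!file.exists(path)) {
    stop_adnaudit(sprintf("alignment file not found: %s", path), "adnaudit_io_error")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    read_sam_text(path, n_max)
  } else {
    read_bam_binary(path, n_max)
  }
}

read_sam_text <- function(path, n_max = Inf) {
  con <- open_text(path)
  on.exit(close(con))
  header <- character()
  records <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0) break
    if (startsWith(line, "@")) header <- c(header, line) else { records <- line; break }
  }
  if (length(records) == 1) {
    n_more <- if (is.finite(n_max)) as.integer(n_max) - 1L else -1L
    if (n_more != 0L) records <- c(records, readLines(con, n = n_more, warn = FALSE))
  }
  parse_sam_records(records, path, header)
}

parse_sam_records <- function(lines, path, header) {
  if (length(lines) == 0) {
    return(list(header = header, records = empty_alignment_records()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- which(nf < 11)[1]
    stop_adnaudit(
      sprintf("malformed SAM record (only %d fields) in %s at record %d",
              nf[bad], path, bad),
      "adnaudit_format_error")
  }
  if (length(unique(nf)) == 1) {
    # uniform field count: one matrix instead of per-record lambdas
    m <- matrix(unlist(fields, use.names = FALSE), ncol = nf[1], byrow = TRUE)
    field <- function(i) m[, i]
    opt_cols <- if (nf[1] > 11) m[, 12:nf[1], drop = FALSE] else NULL
    rg <- rep(NA_character_, nrow(m))
    if (!is.null(opt_cols)) {
      for (j in seq_len(ncol(opt_cols))) {
        is_rg <- is.na(rg) & startsWith(opt_cols[, j], "RG:Z:")
        rg[is_rg] <- substring(opt_cols[is_rg, j], 6L)
      }
    }
  } else {
    field <- function(i) map_chr(fields, i)
    rg <- map_chr(fields, function(f) {
      if (length(f) <= 11) return(NA_character_)
      opt <- f[12:length(f)]
      hit <- opt[startsWith(opt, "RG:Z:")]
      if (length(hit) == 0) NA_character_ else substring(hit[[1]], 6L)
    })
  }
  flag <- suppressWarnings(as.integer(field(2)))
  pos <- suppressWarnings(as.integer(field(4)))
  mapq <- suppressWarnings(as.integer(field(5)))
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq)) {
    bad <- which(is.na(flag) | is.na(pos) | is.na(mapq))[1]
    stop_adnaudit(
      sprintf("non-numeric FLAG/POS/MAPQ in %s at record %d", path, bad),
      "adnaudit_format_error")
  }
  list(
    header = header,
    records = tibble(
      qname = field(1), flag = flag, rname = field(3), pos = pos, mapq = mapq,
      cigar = field(6), seq = field(10), qual = field(11), rg = rg
    )
  )
}

empty_alignment_records <- function() {
  tibble(qname = character(), flag = integer(), rname = character(),
         pos = integer(), mapq = integer(), cigar = character(),
         seq = character(), qual = character(), rg = character())
}

read_bam_binary <- function(path, n_max = Inf) {
  hdr <- tryCatch(Rsamtools::scanBamHeader(path)[[1]],
                  error = function(e) {
                    stop_adnaudit(sprintf("cannot read BAM header from %s: %s",
                                          path, conditionMessage(e)),
                                  "adnaudit_format_error")
                  })
  header <- unlist(imap(hdr$text, function(fields, tag) {
    paste(c(tag, fields), collapse = "\t")
  }), use.names = FALSE)
  yield <- if (is.finite(n_max)) as.integer(n_max) else NA_integer_
  bf <- Rsamtools::BamFile(path, yieldSize = yield)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "RG")
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  rg <- res$tag$RG %||% rep(NA_character_, length(res$qname))
  records <- tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    rname = ifelse(is.na(as.character(res$rname)), "*", as.character(res$rname)),
    pos = ifelse(is.na(res$pos), 0L, as.integer(res$pos)),
    mapq = ifelse(is.na(res$mapq), 255L, as.integer(res$mapq)),
    cigar = ifelse(is.na(res$cigar), "*", res$cigar),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    rg = as.character(rg)
  )
  list(header = header, records = records)
}

# Serialise parsed records back to SAM text lines (used by the generator).
sam_record_lines <- function(records) {
  opt <- ifelse(is.na(records$rg), "", paste0("\tRG:Z:", records$rg))
  paste0(records$qname, "\t", records$flag, "\t", records$rname, "\t",
         records$pos, "\t", records$mapq, "\t", records$cigar,
         "\t*\t0\t0\t", records$seq, "\t", records$qual, opt)
}

write_sam_file <- function(header, records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, sam_record_lines(records)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

tag_or_na <- function(x, tag) {
  if (tag %in% names(x)) x[[tag]] else NA_character_
}

# Parse "@RG\tID:x\tSM:y" style header lines into a tag->value list per line.
parse_header_tags <- function(header, type) {
  lines <- header[startsWith(header, type)]
  map(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
    kv <- strsplit(parts, ":", fixed = TRUE)
    vals <- map_chr(kv, function(p) paste(p[-1], collapse = ":"))
    setNames(vals, map_chr(kv, 1))
  })
}
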