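# Shared fixture builders: tiny bundles, SAM/FASTQ writers, and the reduced
# audit configuration used with small generated files (a few hundred mapped
# reads per file instead of the default confidence floor of 1000).

test_config <- function(...) {
  audit_config(min_confident_n = 200L, ...)
}

tiny_attrs <- function(...) {
  kv <- list(...)
  if (length(kv) == 0) {
    return(tibble::tibble(tag = character(), value = character(),
                          units = character()))
  }
  tibble::tibble(tag = names(kv), value = unlist(kv), units = NA_character_)
}

tiny_sample <- function(accession = "SAMEA1", alias = "S1", title = NA_character_,
                        attrs = tiny_attrs()) {
  tibble::tibble(accession = accession, alias = alias, title = title,
                 attributes = list(attrs))
}

tiny_bundle <- function(samples = tiny_sample(),
                        runs = NULL, analyses = NULL, paper_report = NULL) {
  if (is.null(runs)) {
    runs <- tibble::tibble(
      accession = "ERR1", sample_accession = samples$accession[1],
      library_name = "LIB1", library_construction_protocol = NA_character_,
      instrument_platform = "ILLUMINA", submitted_format = "FASTQ",
      files = list(tibble::tibble(path = character(),
                                  declared_format = character())))
  }
  study_bundle(
    study = list(accession = "PRJTEST1", title = "t", description = "d"),
    samples = samples, runs = runs,
    analyses = analyses %||% tibble::tibble(),
    paper_report = paper_report
  )
}

write_tiny_fastq <- function(seqs, path = tempfile(fileext = ".fastq"),
                             gz = FALSE) {
  lines <- paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                  strrep("I", nchar(seqs)))
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  path
}

# Hand-rolled SAM writer independent of the package's generator.
write_tiny_sam <- function(records, path = tempfile(fileext = ".sam"),
                           header = NULL) {
  header <- header %||% c("@HD\tVN:1.6\tSO:coordinate",
                          "@SQ\tSN:ctgA\tLN:1000",
                          "@RG\tID:rg1\tSM:S1\tLB:LIB1\tPL:ILLUMINA")
  writeLines(c(header, records), path)
  path
}

sam_line <- function(qname = "q", flag = 0L, rname = "ctgA", pos = 100L,
                     mapq = 37L, seq = "ACGTACGTAC", qual = NULL,
                     rg = "rg1", cigar = NULL) {
  qual <- qual %||% strrep("F", nchar(seq))
  cigar <- cigar %||% if (bitwAnd(flag, 4L) != 0L) "*" else paste0(nchar(seq), "M")
  line <- paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, qual,
                sep = "\t")
  if (!is.na(rg)) line <- paste0(line, "\tRG:Z:", rg)
  line
}

# Independent brute-force adapter scan used as the oracle for the vectorised
# detector: for one read, walk every start offset left to right and report the
# first qualifying overlap.
oracle_adapter_scan <- function(read, adapters, min_overlap, rate) {
  L <- nchar(read)
  chars <- strsplit(toupper(read), "")[[1]]
  for (s in 0:(L - min_overlap)) {
    o <- L - s
    for (ai in seq_along(adapters)) {
      ad <- strsplit(adapters[[ai]], "")[[1]]
      if (o > length(ad)) next
      mism <- sum(chars[(s + 1):L] != ad[1:o])
      if (mism <= floor(rate * o)) {
        return(list(start = s, length = o, adapter = names(adapters)[ai]))
      }
    }
  }
  NULL
}
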