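test_that("FASTQ statistics treat every read as unmapped and count the head sample", {
  seqs <- c(strrep("ACGT", 8), strrep("GATTACA", 5), strrep("AC", 20))
  p <- write_tiny_fastq(seqs)
  s <- collect_seq_stats(p, n_sample = 1000)
  expect_equal(s$n_reads_sampled, 3)
  expect_equal(s$n_unmapped, 3)
  expect_equal(s$n_mapped, 0)
  expect_equal(s$min_length, 32)
  expect_equal(classify_file_role(s), "raw_reads")

  s2 <- collect_seq_stats(p, n_sample = 2)
  expect_equal(s2$n_reads_sampled, 2)

  gz <- write_tiny_fastq(seqs, tempfile(fileext = ".fastq.gz"), gz = TRUE)
  expect_equal(collect_seq_stats(gz)$length_histogram, s$length_histogram)

  writeLines(c("@r1", "ACGT", "+"), p)  # truncated record
  expect_error(collect_seq_stats(p), class = "adnaudit_format_error")
})

test_that("SAM statistics match a direct recount on a generated 500-read file", {
  b <- generate_study(violation_profile(), seed = 11, out_dir = tempfile(),
                      n_reads = 500, n_samples = 1)
  sam <- file.path(dirname(attr(b, "path")), paste0(b$samples$alias[1], ".sam"))
  s <- collect_seq_stats(sam, n_sample = 10000)

  # independent recount straight off the text lines
  lines <- readLines(sam)
  rec <- strsplit(lines[!startsWith(lines, "@")], "\t")
  flags <- vapply(rec, function(f) as.integer(f[2]), 1L)
  mapqs <- vapply(rec, function(f) as.integer(f[5]), 1L)
  lens <- vapply(rec, function(f) nchar(f[10]), 1L)
  unmapped <- bitwAnd(flags, 4L) != 0L
  expect_equal(s$n_reads_sampled, length(rec))
  expect_equal(s$n_unmapped, sum(unmapped))
  expect_equal(s$n_mapped + s$n_unmapped, s$n_reads_sampled)
  expect_equal(sum(s$mapq_histogram), s$n_mapped)
  expect_equal(sum(s$length_histogram), s$n_reads_sampled)
  expect_equal(s$min_mapq_mapped, min(mapqs[!unmapped & mapqs != 255L]))
  expect_equal(s$min_length, min(lens))
  expect_equal(unname(s$length_histogram), unname(as.integer(table(lens))))
  expect_equal(classify_file_role(s), "aligned_with_unmapped")

  # determinism: identical file -> identical stats
  expect_equal(collect_seq_stats(sam, n_sample = 10000)[names(s) != "path"],
               s[names(s) != "path"])
})

test_that("SAM text and Rsamtools BAM paths agree on the same records", {
  b <- generate_study(violation_profile(), seed = 12, out_dir = tempfile(),
                      n_reads = 400, n_samples = 1)
  sam <- file.path(dirname(attr(b, "path")), paste0(b$samples$alias[1], ".sam"))
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  s_sam <- collect_seq_stats(sam)
  s_bam <- collect_seq_stats(bam)
  for (field in c("n_reads_sampled", "n_mapped", "n_unmapped", "min_mapq_mapped",
                  "min_length", "distinct_sm_values", "paired_fraction")) {
    expect_equal(s_bam[[field]], s_sam[[field]], info = field)
  }
  expect_equal(s_bam$mapq_histogram, s_sam$mapq_histogram)
  expect_equal(s_bam$read_groups, s_sam$read_groups)
  expect_equal(nrow(s_bam$validation_issues), 0)
})

test_that("adapter detection agrees with an exhaustive offset-scan oracle", {
  adapters <- default_adapters()
  set.seed(401)
  n <- 1000
  bases <- c("A", "C", "G", "T")
  reads <- character(n)
  for (i in seq_len(n)) {
    L <- sample(20:80, 1)
    insert <- paste(sample(bases, L, replace = TRUE), collapse = "")
    style <- sample(c("clean", "readthrough", "mutated"), 1)
    if (style == "readthrough") {
      ad <- adapters[[sample(length(adapters), 1)]]
      insert <- paste0(insert, substring(ad, 1, sample(8:25, 1)))
    } else if (style == "mutated") {
      ad <- substring(adapters[[sample(length(adapters), 1)]], 1, sample(10:25, 1))
      chars <- strsplit(ad, "")[[1]]
      k <- sample(0:2, 1)
      if (k > 0) {
        at <- sample(length(chars), k)
        chars[at] <- sample(bases, k, replace = TRUE)
      }
      insert <- paste0(insert, paste(chars, collapse = ""))
    }
    reads[i] <- insert
  }
  got <- detect_adapter_residue(reads, adapters, min_overlap = 8,
                                max_mismatch_rate = 0.1)
  for (i in seq_len(n)) {
    want <- oracle_adapter_scan(reads[i], adapters, 8, 0.1)
    if (is.null(want)) {
      expect_true(is.na(got$start[i]), info = paste("read", i))
    } else {
      expect_equal(got$start[i], want$start, info = paste("read", i))
      expect_equal(got$length[i], want$length, info = paste("read", i))
      expect_equal(got$adapter[i], want$adapter, info = paste("read", i))
    }
  }
})

test_that("adapter detection handles the contract edge cases", {
  no_hit <- detect_adapter_residue(strrep("ACGT", 8))
  expect_true(is.na(no_hit$start[1]))
  # 30-nt insert plus the first 13 adapter nucleotides
  ad <- default_adapters()[[1]]
  read <- paste0(strrep("ACGTA", 6), substring(ad, 1, 13))
  hit <- detect_adapter_residue(read, min_overlap = 8, max_mismatch_rate = 0.1)
  expect_equal(hit$start[1], 30)
  expect_equal(hit$length[1], 13)
  # reads shorter than min_overlap never match; empty input gives empty output
  expect_true(is.na(detect_adapter_residue("ACGTA", min_overlap = 8)$start[1]))
  expect_equal(nrow(detect_adapter_residue(character())), 0)
})

test_that("hard-filter inference follows the trigger rules and is monotone", {
  mk_stats <- function(min_mapq, n_mapped, min_len = 25, n_reads = n_mapped,
                       fmt = "sam") {
    structure(list(path = "x", declared_format = fmt,
                   n_reads_sampled = n_reads, n_mapped = n_mapped,
                   n_unmapped = n_reads - n_mapped,
                   min_mapq_mapped = min_mapq, mapq_histogram = integer(),
                   min_length = min_len, length_histogram = integer(),
                   adapter_residue_fraction = 0,
                   read_groups = parse_read_groups(write_tiny_sam(character())),
                   distinct_sm_values = character(), paired_fraction = 0,
                   validation_issues = NULL),
              class = "seq_file_stats")
  }
  expect_true(infer_hard_filters(mk_stats(30, 10000), mapq_trigger = 25)$mapq_filtered)
  expect_false(infer_hard_filters(mk_stats(0, 10000), mapq_trigger = 25)$mapq_filtered)
  s0 <- mk_stats(NA_integer_, 0, min_len = NA_integer_, n_reads = 0)
  f0 <- infer_hard_filters(s0)
  expect_false(f0$mapq_filtered); expect_false(f0$length_filtered)
  expect_false(f0$confident); expect_false(f0$unmapped_removed)

  expect_true(infer_hard_filters(mk_stats(37, 5000, min_len = 35))$length_filtered)
  expect_true(infer_hard_filters(mk_stats(37, 5000))$unmapped_removed)
  expect_false(infer_hard_filters(mk_stats(37, 3000, n_reads = 5000))$unmapped_removed)

  # monotone non-increasing in the trigger
  s <- mk_stats(30, 5000, min_len = 32)
  for (stat_flag in c("mapq_filtered", "length_filtered")) {
    prev <- TRUE
    for (trig in seq(10, 60, by = 5)) {
      cur <- infer_hard_filters(s, mapq_trigger = trig, length_trigger = trig)[[stat_flag]]
      expect_false(!prev && cur)  # never flips FALSE -> TRUE as trigger rises
      prev <- cur
    }
  }
})

test_that("planted MAPQ floors are recovered whenever the trigger is at or below them", {
  for (q in c(25L, 30L)) {
    b <- generate_study(violation_profile("mapq_filter", mapq_threshold = q),
                        seed = 13, out_dir = tempfile(), n_reads = 600,
                        n_samples = 1)
    sam <- file.path(dirname(attr(b, "path")), paste0(b$samples$alias[1], ".sam"))
    s <- collect_seq_stats(sam)
    sig <- infer_hard_filters(s, mapq_trigger = 25, min_confident_n = 200)
    expect_true(sig$mapq_filtered)
    expect_gte(sig$mapq_floor, q)
    expect_false(infer_hard_filters(s, mapq_trigger = q + 30L,
                                    min_confident_n = 200)$mapq_filtered)
  }
})

test_that("read groups are parsed verbatim and absent tags stay absent", {
  p <- write_tiny_sam(character(), header = c("@HD\tVN:1.6", "@SQ\tSN:ctgA\tLN:1000"))
  expect_equal(nrow(parse_read_groups(p)), 0)

  p <- write_tiny_sam(character(), header = c(
    "@HD\tVN:1.6",
    "@RG\tID:rg1\tSM:Samp A\tLB:lib.1\tPL:ILLUMINA",
    "@RG\tID:rg2\tSM:other\tPL:ILLUMINA"))
  rg <- parse_read_groups(p)
  expect_equal(rg$rg_id, c("rg1", "rg2"))
  expect_equal(rg$sample_tag, c("Samp A", "other"))
  expect_equal(rg$library_tag, c("lib.1", NA))
  expect_equal(length(unique(rg$sample_tag)), 2)
})

test_that("the validation rule set flags each planted defect and passes clean files", {
  clean <- write_tiny_sam(c(sam_line(qname = "q1", pos = 10),
                            sam_line(qname = "q2", pos = 20)))
  expect_equal(nrow(validate_alignment_file(clean)), 0)

  no_hd <- write_tiny_sam(sam_line(), header = c("@SQ\tSN:ctgA\tLN:1000",
                                                 "@RG\tID:rg1\tSM:S1"))
  expect_true("V1" %in% validate_alignment_file(no_hd)$rule_id)

  dup_rg <- write_tiny_sam(sam_line(), header = c(
    "@HD\tVN:1.6", "@SQ\tSN:ctgA\tLN:1000",
    "@RG\tID:rg1\tSM:S1", "@RG\tID:rg1\tSM:S2"))
  expect_true("V2" %in% validate_alignment_file(dup_rg)$rule_id)

  undeclared <- write_tiny_sam(sam_line(rg = "rgX"))
  expect_true("V3" %in% validate_alignment_file(undeclared)$rule_id)

  off_contig <- write_tiny_sam(sam_line(pos = 5000L))
  expect_true("V4" %in% validate_alignment_file(off_contig)$rule_id)
  bad_ref <- write_tiny_sam(sam_line(rname = "ctgZ"))
  expect_true("V4" %in% validate_alignment_file(bad_ref)$rule_id)

  bad_qual <- write_tiny_sam(sam_line(qual = "FFF"))
  expect_true("V5" %in% validate_alignment_file(bad_qual)$rule_id)

  bad_flag <- write_tiny_sam(sam_line(flag = 8L))
  expect_true("V6" %in% validate_alignment_file(bad_flag)$rule_id)
})

test_that("the coordinate-order rule matches a pairwise brute-force check", {
  set.seed(77)
  for (rep in 1:20) {
    pos <- sample(1:900, 12)
    lines <- vapply(seq_along(pos), function(i) {
      sam_line(qname = paste0("q", i), pos = pos[i])
    }, "")
    issues <- validate_alignment_file(write_tiny_sam(lines))
    brute_sorted <- all(diff(pos) >= 0)
    expect_equal(!"V7" %in% issues$rule_id, brute_sorted,
                 info = paste(pos, collapse = ","))
  }
})

test_that("file roles separate raw, aligned-only and mixed alignment files", {
  all_unmapped <- write_tiny_sam(
    vapply(1:5, function(i) sam_line(qname = paste0("u", i), flag = 4L,
                                     rname = "*", pos = 0L, mapq = 0L), ""))
  expect_equal(classify_file_role(collect_seq_stats(all_unmapped)), "raw_reads")

  aligned <- write_tiny_sam(c(sam_line(pos = 1), sam_line(qname = "q2", pos = 5)))
  expect_equal(classify_file_role(collect_seq_stats(aligned)), "aligned_only")

  mixed <- write_tiny_sam(c(sam_line(pos = 1),
                            sam_line(qname = "u1", flag = 4L, rname = "*",
                                     pos = 0L, mapq = 0L)))
  expect_equal(classify_file_role(collect_seq_stats(mixed)), "aligned_with_unmapped")

  empty <- write_tiny_sam(character())
  expect_equal(classify_file_role(collect_seq_stats(empty)), "ambiguous")
})
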