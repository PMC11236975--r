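test_that("read simulation is seeded, bounded and empty-safe", {
  expect_equal(nrow(simulate_reads(0, seed = 1)), 0)
  r1 <- simulate_reads(500, seed = 42)
  r2 <- simulate_reads(500, seed = 42)
  expect_identical(r1, r2)
  r3 <- simulate_reads(500, seed = 43)
  expect_false(identical(r1$seq, r3$seq))
  expect_gte(min(r1$length), 25)
  expect_lte(max(r1$length), 120)
  expect_true(all(grepl("^[ACGT]+$", r1$seq)))
  expect_equal(nchar(r1$seq), r1$length)
})

test_that("profiles reject contradictory and unknown codes", {
  expect_error(violation_profile(c("no_read_groups", "sm_mismatch")),
               class = "adnaudit_profile_error")
  expect_error(violation_profile(c("no_sm", "multi_sm")),
               class = "adnaudit_profile_error")
  expect_error(violation_profile(c("no_geo", "no_coords")),
               class = "adnaudit_profile_error")
  expect_error(violation_profile(c("aligned_only_no_raw", "untrimmed_adapters")),
               class = "adnaudit_profile_error")
  expect_error(violation_profile("not_a_code"), class = "adnaudit_profile_error")
  expect_error(violation_profile("invalid_bam", invalid_rule = "V99"),
               class = "adnaudit_profile_error")
  expect_silent(violation_profile(c("mapq_filter", "length_filter")))
})

test_that("generation is deterministic: same seed gives byte-identical FASTQ and SAM", {
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- generate_study(violation_profile("untrimmed_adapters"), seed = 5,
                       out_dir = d1, n_reads = 400, n_samples = 2)
  b2 <- generate_study(violation_profile("untrimmed_adapters"), seed = 5,
                       out_dir = d2, n_reads = 400, n_samples = 2)
  for (f in c("SYNSTU0001_S1.fastq", "SYNSTU0001_S2.fastq",
              "SYNSTU0001_S1.sam", "SYNSTU0001_S2.sam", "bundle.json")) {
    p1 <- file.path(d1, "SYNSTU0001", f); p2 <- file.path(d2, "SYNSTU0001", f)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)), info = f)
  }
  b3 <- generate_study(violation_profile("untrimmed_adapters"), seed = 6,
                       out_dir = tempfile(), n_reads = 400, n_samples = 2)
  expect_false(identical(
    readLines(file.path(d1, "SYNSTU0001", "SYNSTU0001_S1.fastq")),
    readLines(file.path(dirname(attr(b3, "path")), "SYNSTU0001_S1.fastq"))))
})

test_that("planted hard filters are visible in the generated files themselves", {
  b <- generate_study(violation_profile(c("mapq_filter", "length_filter",
                                          "strip_unmapped")),
                      seed = 31, out_dir = tempfile(), n_reads = 500, n_samples = 1)
  sam <- file.path(dirname(attr(b, "path")), "SYNSTU0001_S1.sam")
  s <- collect_seq_stats(sam)
  expect_equal(s$n_reads_sampled, 500)   # generator refills to the target count
  expect_equal(s$n_unmapped, 0)
  expect_gte(s$min_mapq_mapped, 30)
  expect_gte(s$min_length, 35)
})

test_that("single-violation round-trip: each code fails exactly its entailed criteria", {
  cfg <- test_config()
  ent <- violation_entailments()
  base <- generate_study(violation_profile(), seed = 100, out_dir = tempfile(),
                         n_reads = 1000, n_samples = 2)
  vb <- tidy(audit_study(attr(base, "path"), config = cfg))
  base_na <- vb$criterion_id[vb$status == "not_applicable"]
  expect_equal(sum(vb$status == "fail"), 0)

  for (code in names(ent)) {
    b <- generate_study(violation_profile(code), seed = 100,
                        out_dir = tempfile(), n_reads = 1000, n_samples = 2)
    v <- tidy(audit_study(attr(b, "path"), config = cfg))
    fails <- v$criterion_id[v$status == "fail"]
    new_na <- setdiff(v$criterion_id[v$status == "not_applicable"], base_na)
    expect_setequal(fails, ent[[code]]$fails)
    expect_setequal(new_na, ent[[code]]$not_applicable)
    expect_equal(sum(v$status == "indeterminate"), 0, info = code)
  }
})

test_that("capture and prior-publication toggles drive the conditional criteria", {
  cfg <- test_config()
  b <- generate_study(violation_profile(used_capture = TRUE, reuse_ok = TRUE),
                      seed = 33, out_dir = tempfile(), n_reads = 1000, n_samples = 2)
  v <- audit_study(attr(b, "path"), config = cfg)
  expect_true(v$passed[v$criterion_id == "capture_raw"])
  expect_true(v$passed[v$criterion_id == "accession_reuse"])

  b <- generate_study(violation_profile("aligned_only_no_raw", used_capture = TRUE),
                      seed = 33, out_dir = tempfile(), n_reads = 1000, n_samples = 2)
  v <- audit_study(attr(b, "path"), config = cfg)
  expect_false(v$passed[v$criterion_id == "capture_raw"])
})

test_that("cohort generation is manifest-deterministic and spec-conservative", {
  spec <- cohort_spec(list(
    list(profile = violation_profile(), n_studies = 2),
    list(profile = violation_profile("no_geo"), n_studies = 3)),
    seed = 9, n_reads = 200, n_samples = 1)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  expect_equal(nrow(m1), 5)
  expect_identical(m1$planted_codes, m2$planted_codes)
  expect_identical(m1$study_accession, m2$study_accession)
  expect_error(cohort_spec(list(list(profile = violation_profile(), n_studies = 0))),
               class = "adnaudit_profile_error")

  # JSON round trip of the spec
  p <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    seed = 9, n_reads = 200, n_samples = 1,
    entries = list(
      list(n_studies = 2, profile = list(violations = list())),
      list(n_studies = 3, profile = list(violations = list("no_geo"))))),
    auto_unbox = TRUE), p)
  spec2 <- read_cohort_spec(p)
  m3 <- generate_cohort(spec2, tempfile())
  expect_identical(m3$planted_codes, m1$planted_codes)
})

test_that("a planted cohort's audit recovers the manifest's marginal pass counts", {
  spec <- cohort_spec(list(
    list(profile = violation_profile(), n_studies = 3),
    list(profile = violation_profile("no_tissue"), n_studies = 2),
    list(profile = violation_profile("no_voucher"), n_studies = 4)),
    seed = 17, n_reads = 200, n_samples = 1)
  man <- generate_cohort(spec, tempfile())
  cfg <- test_config()
  summ <- aggregate_verdicts(audit_cohort(man, cfg))
  expect_equal(summ$n_pass[summ$criterion_id == "tissue_any"], 7)
  expect_equal(summ$n_fail[summ$criterion_id == "tissue_any"], 2)
  expect_equal(summ$n_pass[summ$criterion_id == "voucher_present"], 5)
  expect_equal(summ$n_fail[summ$criterion_id == "voucher_present"], 4)
  expect_equal(summ$n_applicable[summ$criterion_id == "geo_any"], 9)
})
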