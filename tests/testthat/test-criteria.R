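test_that("the registry is complete, ordered and rooted in the survey tables", {
  reg <- list_criteria()
  expect_gte(nrow(reg), 25)
  expect_equal(reg$criterion_id[1], "raw_reads_archived")
  expect_false(anyDuplicated(reg$criterion_id) > 0)
  expect_true(all(reg$table_ref %in% paste("Table", 1:5)))
  # stable table order
  expect_equal(reg$table_ref, sort(reg$table_ref))
})

test_that("a violation-free study passes every applicable criterion", {
  b <- generate_study(violation_profile(), seed = 21, out_dir = tempfile(),
                      n_reads = 1200, n_samples = 2)
  v <- audit_study(attr(b, "path"), config = test_config())
  expect_equal(nrow(v), nrow(list_criteria()))
  decided <- v$applicable & !is.na(v$passed)
  expect_true(all(v$passed[decided]))
  expect_equal(sum(v$applicable & is.na(v$passed)), 0)
})

test_that("hard-filtered aligned-only studies fail raw archiving and trigger the rawless criterion", {
  b <- generate_study(violation_profile(c("aligned_only_no_raw", "mapq_filter")),
                      seed = 22, out_dir = tempfile(), n_reads = 1200, n_samples = 2)
  v <- audit_study(attr(b, "path"), config = test_config())
  pick <- function(id) v[v$criterion_id == id, ]
  expect_false(pick("raw_reads_archived")$passed)
  expect_true(pick("rawless_unfiltered")$applicable)
  expect_false(pick("rawless_unfiltered")$passed)
  expect_false(pick("no_mapq_hardfilter")$passed)
  # failing verdicts carry evidence
  failing <- v[v$applicable & !is.na(v$passed) & !v$passed, ]
  expect_true(all(lengths(failing$evidence) > 0))
})

test_that("FASTQ runs plus analysis-registered alignments satisfy both-archived and analysis-file criteria", {
  b <- generate_study(violation_profile(), seed = 23, out_dir = tempfile(),
                      n_reads = 800, n_samples = 1)
  v <- audit_study(attr(b, "path"), config = test_config())
  expect_true(v$passed[v$criterion_id == "both_archived"])
  expect_true(v$passed[v$criterion_id == "alignments_as_analysis"])
})

test_that("verdicts are complete, deterministic and composite-consistent", {
  b <- generate_study(violation_profile("length_filter"), seed = 24,
                      out_dir = tempfile(), n_reads = 1200, n_samples = 2)
  cfg <- test_config()
  v1 <- audit_study(attr(b, "path"), config = cfg)
  v2 <- audit_study(attr(b, "path"), config = cfg)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  expect_equal(sort(v1$criterion_id), sort(list_criteria()$criterion_id))
  # passed present implies applicable
  expect_true(all(v1$applicable | is.na(v1$passed)))
  # composite: no_any_hardfilter passing requires both components passing
  comp <- function(v, id) v$passed[v$criterion_id == id]
  if (isTRUE(comp(v1, "no_any_hardfilter"))) {
    expect_true(comp(v1, "no_mapq_hardfilter") && comp(v1, "no_length_hardfilter"))
  }
  expect_false(comp(v1, "no_any_hardfilter"))
})

test_that("below the confidence floor the filter criteria go indeterminate, not fail", {
  b <- generate_study(violation_profile(), seed = 25, out_dir = tempfile(),
                      n_reads = 300, n_samples = 1)
  v <- audit_study(attr(b, "path"), config = audit_config(min_confident_n = 100000))
  for (id in c("no_mapq_hardfilter", "no_length_hardfilter", "no_any_hardfilter")) {
    row <- v[v$criterion_id == id, ]
    expect_true(row$applicable)
    expect_true(is.na(row$passed))
  }
})

test_that("disabling file checks marks file-dependent criteria indeterminate", {
  b <- generate_study(violation_profile(), seed = 26, out_dir = tempfile(),
                      n_reads = 300, n_samples = 1)
  v <- audit_study(attr(b, "path"), config = test_config(), file_checks = FALSE)
  raw <- v[v$criterion_id == "raw_reads_archived", ]
  expect_true(raw$applicable)
  expect_true(is.na(raw$passed))
  # metadata-only criteria still decide
  expect_true(v$passed[v$criterion_id == "geo_any"])
  expect_true(v$passed[v$criterion_id == "total_reported"])
})

test_that("missing statistics for a referenced file raise an evaluation error", {
  b <- generate_study(violation_profile(), seed = 27, out_dir = tempfile(),
                      n_reads = 300, n_samples = 1)
  expect_error(evaluate_study(b, file_stats = list(), config = test_config()),
               class = "adnaudit_evaluation_error")
})

test_that("the preflight checklist maps failures onto the right steps", {
  clean <- generate_study(violation_profile(), seed = 28, out_dir = tempfile(),
                          n_reads = 1200, n_samples = 2)
  lint <- lint_submission(attr(clean, "path"), config = test_config())
  expect_equal(nrow(lint), 8)
  expect_true(all(lint$status == "ok"))

  stripped <- generate_study(violation_profile("no_read_groups"), seed = 28,
                             out_dir = tempfile(), n_reads = 1200, n_samples = 2)
  lint <- lint_submission(attr(stripped, "path"), config = test_config())
  expect_equal(lint$status[lint$step == 6], "action_needed")
  expect_true("bam_has_rg" %in% lint$failing_criteria[[6]])

  # without a paper report the documentation step cannot be checked
  b <- tiny_bundle()
  p <- tempfile(); write_bundle(b, p)
  lint <- lint_submission(p, config = test_config())
  expect_equal(lint$status[lint$step == 8], "not_checked")
})

test_that("tidiers summarise verdicts faithfully", {
  b <- generate_study(violation_profile("no_voucher"), seed = 29,
                      out_dir = tempfile(), n_reads = 800, n_samples = 1)
  v <- audit_study(attr(b, "path"), config = test_config())
  td <- tidy(v)
  expect_equal(nrow(td), nrow(v))
  expect_equal(td$status[td$criterion_id == "voucher_present"], "fail")
  g <- glance(v)
  expect_equal(g$n_fail, 1)
  expect_equal(g$n_pass + g$n_fail + g$n_indeterminate, g$n_applicable)
  p <- autoplot(v)
  expect_s3_class(p, "ggplot")
})
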