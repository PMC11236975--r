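# adnaudit

Auditing how completely ancient-genomics sequencing studies are archived.

Ancient-DNA studies consume finite, often irreplaceable biological material,
yet the sequencing data they deposit in the INSDC archives (ENA, SRA, DDBJ)
is frequently incomplete: only the reads that aligned to a reference are
archived, BAM files are hard-filtered or carry read groups that contradict
the archive metadata, sample records lack geography, dating or tissue
information, and data from negative or screening experiments never reaches
the archive at all. `adnaudit` turns a survey rubric for these practices into
a reusable pipeline, aimed at data submitters who want to check a submission
before (or after) it goes in, and at methodologists studying archiving
practice across many studies.

## What it computes

The unit of input is a **study bundle**: the study record, its samples (with
free-form tag/value attributes, as in BioSample), its sequencing runs, its
analysis records, the referenced FASTQ and SAM/BAM files, and optionally the
facts the accompanying paper declares (sample counts, capture usage,
previously published samples). A registry of 32 criteria is evaluated per
study, grouped the way the survey tables group them:

* **Raw reads** — was the complete read set archived (FASTQ, unaligned BAM,
  or a BAM retaining unmapped reads)? Were adapters trimmed? A file "has
  adapter residue" when more than 1% of sampled reads end in a suffix
  matching an adapter prefix with ≥ 8 nt overlap and a mismatch rate ≤ 0.1.
* **Read alignments** — archived at all, registered as analysis records
  rather than fake sequencing runs, and free of *hard filtering*: a file
  whose minimum mapped MAPQ is ≥ 25, or whose minimum read length is ≥ 30,
  over at least 1,000 reads, is inferred to have been irreversibly filtered
  (the thresholds mirror the filters observed in published studies, where a
  MAPQ cutoff of 30 and a length cutoff of 35 are typical).
* **Experiment metadata** — archived sample count vs the paper's count,
  duplicate sample accessions (informal `_new`-style suffixes), reuse of
  existing accessions for previously published samples, library-protocol
  details, and BAM read-group consistency: `@RG` present, SM/LB fields
  present, SM matching the archived sample alias/accession/title, a single
  SM per file, LB matching the run's library name, and a structural
  validation rule set (V1–V7: header, read-group uniqueness and reference,
  reference bounds, seq/qual lengths, flag coherence, declared sort order).
* **Sample metadata** — geography (any / dedicated field / parseable
  coordinates), dating (any / dedicated field / radiocarbon lab code such as
  `OxA-12345`), tissue (any / dedicated field), specimen voucher.
* **Negative experiments** — does the paper state the total number of
  studied samples, and is data archived for all of them?

Criteria can be *not applicable* (e.g. the adapter criterion for a study
without raw reads) or *indeterminate* (inputs unavailable or below the
confidence floor); both are excluded from cohort denominators, so each
criterion keeps its own "applicable studies" count, exactly as in the survey
tables. `aggregate_verdicts()` turns many per-study verdicts into the
per-criterion table `n_pass (pct)` / `n_fail` / `n_applicable`.

Because re-auditing real archive studies requires bulk downloads, the package
ships a seeded generator that fabricates complete synthetic studies —
metadata plus FASTQ/SAM files — with controlled violations planted, one code
per failure mode. The violation-free baseline passes every applicable
criterion; each code makes exactly its target criterion (plus logically
entailed composites) fail. This is what makes every detector testable
offline.

## Worked example

```r
library(adnaudit)

# fabricate a study that archived hard-filtered alignments and no raw reads
bundle <- generate_study(
  violation_profile(c("aligned_only_no_raw", "mapq_filter")),
  seed = 1, out_dir = tempdir(), n_reads = 5000, n_samples = 3)

verdict <- audit_study(attr(bundle, "path"))
glance(verdict)
#> # A tibble: 1 × 7
#>   study_accession n_criteria n_applicable n_pass n_fail n_indeterminate config_fingerprint
#>   <chr>                <int>        <int>  <int>  <int>           <int> <chr>
#> 1 SYNSTU0001              32           29     23      6               0 43b56d79…

subset(tidy(verdict), status == "fail")$criterion_id
#> [1] "raw_reads_archived"     "both_archived"          "alignments_as_analysis"
#> [4] "no_any_hardfilter"      "no_mapq_hardfilter"     "rawless_unfiltered"
```

Six criteria fail: raw reads are missing (so "both archived" and the
capture-independent raw criterion fail), the BAMs are registered as run
records rather than analysis files, and the minimum mapped MAPQ of 30 over
thousands of reads betrays a MAPQ hard filter — which, for a study without
raw reads, also fails the "rawless but unfiltered" criterion. A cohort of
such verdicts aggregates and renders as a survey table:

```r
summ <- aggregate_verdicts(list(verdict))
render_table(summ, table = "Table 2")
#> Criterion                                                  Meeting  Not meeting  Applicable
#> Archived read alignments                                   1 (100%)  0 (0%)      1
#> Archived both raw reads and read alignments                0 (0%)    1 (100%)    1
#> ...
```

`lint_submission()` renders the same verdict as an eight-step preflight
checklist for submitters, and the `inst/exec/adnaudit` script exposes
`audit`, `lint`, `generate` and `cohort` subcommands with exit codes 0
(clean), 1 (failures) and 2 (error). Real archive exports are ingested with
`from_ena_filereport()` (ENA filereport TSV + BioSample attribute dump).

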