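---
title: "Auditing ancient-genomics archiving: model, rubric and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ancient-genomics archiving: model, rubric and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnaudit)
```

## The problem

Ancient-DNA sequencing destroys part of a finite specimen, which puts an
unusual weight on whether the resulting data is archived completely and
described well enough to be reusable. In practice, archived datasets are
often partial: only reads that aligned to one reference genome, BAM files
with reads below some mapping-quality or length cutoff irreversibly removed,
sample records with no geography or dating, read groups whose sample names
match nothing in the archive metadata, and screening or negative experiments
that never reach the archive at all. None of these defects is visible from
an accession number; each requires looking at the files and the metadata
together.

`adnaudit` operationalises a survey rubric for these practices. Its one
input shape is the *study bundle*: the study record, samples with verbatim
tag/value attributes, runs, analysis records, file references, and the facts
the accompanying paper declares. Adapters convert ENA filereport TSVs and
BioSample attribute dumps into this shape; everything downstream is
offline-only and deterministic.

## The rubric

`list_criteria()` returns the registry: 32 criteria in fixed survey-table
order. Each criterion receives exactly one of four outcomes per study —
**pass**, **fail**, **not applicable**, or **indeterminate**. The last two
differ: *not applicable* means the criterion does not concern this study (a
study with no alignments has no read-group criteria); *indeterminate* means
it concerns the study but could not be decided from the available inputs
(file checks disabled, or too few reads for a confident inference).
Both are excluded from cohort denominators, which is how the survey tables
end up with per-row "applicable studies" counts. Failing verdicts always
carry evidence naming the file, tag or value that decided them.

Study-level semantics for per-sample metadata criteria are "any sample": a
study passes `geo_any` when at least one sample has a geography finding.
This matches the study-granularity of the survey tables; the per-sample
breakdown is kept as evidence.

### Read-level statistics

`collect_seq_stats()` samples the **first** `sample_reads` records (default
10,000) of each file — not a random subset. The convention keeps the auditor
seed-free and streamable, and mirrors how a human surveyor inspects the
first listed file of a study. From the sample it computes mapped/unmapped
counts, MAPQ and length histograms, the minimum mapped MAPQ (MAPQ 255,
"unavailable", is excluded), the adapter-residue fraction, and the
read-group roster.

File roles follow from the statistics: FASTQ is raw by definition; a BAM
with no aligned records is raw reads in BAM form; a BAM without unmapped
records is an alignment-only product; one with both counts as a complete
read set. That last point decides the raw-read criterion: a study whose BAM
retains unmapped reads has lost nothing, even without FASTQ files.

### Adapter residue

When the DNA insert is shorter than the read length — the normal case for
ancient libraries — the sequencer reads through into the adapter, so an
untrimmed library shows adapter prefixes at read 3′ ends in a large fraction
of reads. `detect_adapter_residue()` reports, per read, the leftmost suffix
matching a prefix of any adapter with overlap ≥ `min_overlap` (default 8 nt)
and at most `floor(max_mismatch_rate × overlap)` mismatches (default rate
0.1). Ties at the same offset break by adapter order. The default adapter
set (TruSeq R1/R2, Nextera) ships as a FASTA users can replace.

The criterion threshold is an adapter-residue fraction of 0.01: genuinely
untrimmed libraries show read-through in tens of percent of reads, while
chance matches of random sequence at ≥ 8 nt overlap occur in well under 0.1%
of reads, so the two regimes are separated by orders of magnitude and the 1%
line is not sensitive. Tests assert equivalence of the vectorised detector
with an exhaustive per-offset scan on 1,000 random reads.

### Hard-filter inference

Archived BAMs do not record what was removed from them, so filtering is
inferred from distributional signatures: a minimum mapped MAPQ at or above
`mapq_trigger` (default 25) or a minimum length at or above `length_trigger`
(default 30) — the lower edges of the cutoffs observed across published
studies. The study-level
"no apparent hard filtering" composite is the conjunction of the MAPQ and
length criteria only; the removal of unmapped reads is reported in the
filter signature but deliberately not counted as a hard filter here, because
it is scored by the raw-read criteria instead, and the absence of
duplicate-flagged reads is ignored as uninformative.

A minimum over a small sample is weak evidence, so each inference requires
its denominator (mapped reads for MAPQ, all reads for length) to reach
`min_confident_n`, default 1,000. Below the floor the corresponding
criteria are indeterminate rather than passes: an absence of evidence is not
archived innocence. The test suite, which generates files of
1,000–1,200 reads with a 70% unmapped baseline (so ~300–360 mapped reads),
sets `min_confident_n = 200` in its audit configuration for exactly this
reason; the shipped default is meant for the 10,000-read sampling depth of
real audits.

The inference is monotone by construction: raising a trigger can only turn a
"filtered" flag off, never on — asserted as a property test.

### Validation rules

A fixed structural rule set (V1–V7) stands in for an external BAM validator:
header presence and version, read-group ID uniqueness, record RG references,
reference names and position bounds, sequence/quality length agreement, flag
coherence, and declared sort order. It is deliberately a defined, documented
subset — full parity with an external tool is a non-goal; what matters for
the rubric is a deterministic, testable notion of "file passes validation".

### Identifier matching

Read-group SM values must *all* equal (after whitespace trimming) one of the
sample's alias, accession or title; LB values must match a linked run's
library name. Matching is exact by default — archives are machine-read, and
the rubric demands exact identity — with an optional case-insensitive mode.
Duplicate sample detection normalises aliases by case-folding, separator
stripping and removal of the informal suffix tokens
`{new, ss, capture, repeat, rerun, v2}`; bare trailing digits are *not*
stripped, since `S1` vs `S11` are almost always distinct samples. The token
list is configuration, not hard-coded truth: on real data this heuristic can
only find the informal patterns it knows about.

## Configuration and fingerprinting

All tunables live in one `audit_config()` object: sampling depth, adapter
parameters and threshold, filter triggers and confidence floor, matching
mode, suffix tokens, the adapter set and the metadata lexicons. The
configuration is content-hashed and the fingerprint is stamped into every
verdict; `aggregate_verdicts()` and the `cohort` command refuse to combine
verdicts from different fingerprints, so a cohort table can never silently
mix rubric versions.

The metadata lexicons (dedicated tag lists per category, gazetteer terms,
tissue terms, dating patterns, radiocarbon lab-code prefixes, protocol
keywords) ship as YAML and are overridable. Free-text geography detection is
a flat gazetteer lookup, not named-entity recognition: the synthetic data
plants only terms from the shipped list, making detection exact in tests,
and real-world recall is explicitly not guaranteed. The same honesty applies
to radiocarbon codes: the grammar is `prefix[- ]digits{1,6}` over a list of
common lab prefixes, checked in tests against a regex-free scan.

## The synthetic-data generator

`generate_study()` fabricates a complete study under a seed: per-sample
FASTQ runs, per-sample SAM alignment files registered as analysis records,
full sample metadata, and a paper report. The baseline emulates ancient-DNA
data only as far as the auditor looks at it: fragment lengths triangular on
25–120 nt with mode 45; bases uniform; alignments placed uniformly on a toy
two-contig (2 × 50 kb) reference; MAPQ drawn from a mixture with mass at
0, 20, 25, 30, 37 and 60 (0.10/0.10/0.05/0.25/0.30/0.20); 70% of records
unmapped, reflecting typical endogenous fractions. No aligner runs and no
damage patterns are simulated — the auditor inspects distributions and
metadata, not biological signal — so passing tests say nothing about, e.g.,
deamination-aware tools.

Each violation code is the inverse of one criterion. `mapq_filter` drops
records below MAPQ 30 *including unmapped records* (the behaviour of
`samtools view -q`); `length_filter` drops records under 35 nt;
`aligned_only_no_raw` removes the FASTQ runs, strips unmapped records and —
as real aligned-only submissions do — registers the BAMs as primary run
records; `untrimmed_adapters` appends 10–18 nt adapter prefixes to 35% of
FASTQ reads; `multi_sm` writes two read groups whose SM values are both
legitimate identifiers of the sample (alias and accession), so only the
single-SM rule breaks; `duplicate_sample_suffix` registers an extra
`<alias>_new` accession with data and counts it in the declared analysed
number, isolating the linkage criterion from the count criterion. Filtered
files are refilled to the target record count, so the confidence floor is
met at every scale. The full
code → consequence map ships as `violation_entailments()`, and the central
property — audit(generate(code)) fails exactly the entailed set, at two read
scales — is asserted for all 29 codes.

Where the generator needed codes the failure-mode list did not name, it
gained them: `raw_only_no_alignments` (a study archiving only FASTQ) and
`sample_overregistration` (each library registered as its own sample
accession, with aliases that do *not* match the informal-suffix pattern, so
only the count criterion fires). The dating category splits into
`date_freetext_only` (dating text outside a dedicated field, lab code kept)
and `date_no_c14` (lab code removed), so the two dating sub-criteria are
independently plantable and composable.

`generate_cohort()` derives per-study seeds as `seed + i` and writes a
ground-truth manifest. The shipped fixture specs
`fixtures/table{1..5}.json` encode the per-criterion marginals of the five
survey tables as joint per-study profiles; the joint assignment across
criteria within a table is the fixtures' own construction (only the
marginals are constrained), and the acceptance tests verify that auditing
the generated cohorts recovers every marginal count exactly.

## Aggregation and rendering

`aggregate_verdicts()` counts pass/fail/applicable per criterion and
computes `pct_pass` with **half-up** rounding at one decimal
(`round_half_up()`), matching the printed style of survey tables (34.45 →
34.5, where R's default rounds half to even); all 32 printed percentages of
the five tables are recomputed independently in the tests.
`render_table()` prints `count (percentage)` cells with a trailing `.0`
dropped (45.0 → "45%") and a TSV form that re-parses losslessly — a
conservation property the tests assert.

## Problem sizes and determinism

Everything is deterministic: generation under `withr::with_seed`, auditing
seed-free. The test suite runs its cohorts at 400–1,200 reads per file and
the full round-trip property at 1,000 and 10,000 reads; the acceptance
script uses the generator defaults of 42-study cohorts, 3 samples per
study and 5,000 reads per file. These sizes are the package's chosen
operating points for synthetic work; the auditor itself has no scale
assumptions beyond the confidence floor.

## Known limitations

* Free-text metadata detection is lexicon-bound; recall on real archives is
  untested and untestable offline.
* The duplicate-sample heuristic reproduces informal suffix patterns, not
  the literature review a human surveyor would do.
* CRAM is accepted only where the local toolchain can decode it; the
  generator emits SAM.
* Hard-filter inference reads distributions, so it cannot distinguish a
  filtered archive from a genuinely truncated experiment — the confidence
  floor bounds, but does not eliminate, that ambiguity.
* The validation rule set is a documented subset of what a full external
  validator checks.
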