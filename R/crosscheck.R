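# Cross-record consistency: BAM read-group identifiers against archive
# metadata, archived sample counts against paper-declared counts, and
# duplicate sample-accession detection.

new_match_result <- function(matched, left_value, candidates, kind) {
  tibble(matched = matched, left_value = left_value,
         candidate_values = list(candidates), match_kind = kind)
}

match_values <- function(values, candidates, case_insensitive = FALSE) {
  values <- trimws(values)
  candidates <- trimws(candidates[!is.na(candidates)])
  if (length(values) == 0) {
    return(new_match_result(FALSE, "", candidates, "none"))
  }
  if (all(values %in% candidates)) {
    return(new_match_result(TRUE, paste(values, collapse = ","), candidates, "exact"))
  }
  if (case_insensitive && all(tolower(values) %in% tolower(candidates))) {
    return(new_match_result(TRUE, paste(values, collapse = ","), candidates, "normalized"))
  }
  new_match_result(FALSE, paste(values, collapse = ","), candidates, "none")
}

#' Match BAM read-group SM values against a sample record
#'
#' The sample identifiers inside a per-sample BAM (the SM read-group fields)
#' should exactly match the identifiers in the archive metadata. The match
#' succeeds when every SM value equals (after whitespace trimming; optionally
#' case-folded) the sample's alias, accession or title.
#'
#' @param read_groups A read-group tibble, as from [parse_read_groups()].
#' @param sample A one-row slice of a bundle's `samples` table (or equivalent
#'   list).
#' @param case_insensitive Fold case before comparing?
#' @return A one-row tibble: `matched`, `left_value`, `candidate_values`
#'   (list-column), `match_kind` (`"exact"`, `"normalized"` or `"none"`).
#' @export
match_rg_sample <- function(read_groups, sample, case_insensitive = FALSE) {
  if (is.data.frame(sample)) sample <- as.list(sample[1, ])
  sm <- unique(read_groups$sample_tag[!is.na(read_groups$sample_tag)])
  candidates <- c(sample$alias, sample$accession, sample$title)
  match_values(sm, unlist(candidates), case_insensitive)
}

#' Match BAM read-group LB values against run library names
#'
#' @param read_groups A read-group tibble, as from [parse_read_groups()].
#' @param runs Run records linked to the same sample (rows of a bundle's
#'   `runs` table).
#' @param case_insensitive Fold case before comparing?
#' @return A one-row match tibble; see [match_rg_sample()].
#' @export
match_rg_library <- function(read_groups, runs, case_insensitive = FALSE) {
  lb <- unique(read_groups$library_tag[!is.na(read_groups$library_tag)])
  match_values(lb, runs$library_name, case_insensitive)
}

#' Count distinct SM values in a file's read groups
#'
#' A BAM corresponding to one sample must carry a single sample name across
#' its SM read-group fields; more than one makes variant callers treat read
#' subsets as different samples.
#'
#' @param stats A `seq_file_stats` object.
#' @return Integer count of distinct SM values.
#' @export
count_distinct_sm <- function(stats) {
  stopifnot(inherits(stats, "seq_file_stats"))
  length(stats$distinct_sm_values)
}

default_suffix_tokens <- function() c("new", "ss", "capture", "repeat", "rerun", "v2")

normalise_alias <- function(alias, suffix_tokens) {
  tokens <- strsplit(tolower(alias), "[ _.-]+")
  map_chr(tokens, function(tk) {
    while (length(tk) > 1 && tk[length(tk)] %in% suffix_tokens) {
      tk <- tk[-length(tk)]
    }
    paste(tk, collapse = "")
  })
}

#' Detect duplicate sample registrations
#'
#' Finds two kinds of duplicate: (i) sample aliases that collapse to the same
#' identifier once separators and informal suffix tokens (`_new`, `_ss`,
#' `_capture`, ...) are stripped -- the informal "same sample, new accession"
#' pattern; and (ii) samples the paper declares as previously published whose
#' existing accession was not reused in this bundle (an accession-reuse
#' failure). Bare trailing digits are deliberately not stripped.
#'
#' @param samples The `samples` table of a [study_bundle()].
#' @param paper_report Optional [paper_report()] carrying
#'   `previously_published_samples`.
#' @param suffix_tokens Suffix tokens treated as informal duplicate markers.
#' @return A tibble of disjoint groups with columns `member_accessions`
#'   (list-column, each of size >= 2) and `reason` (`"suffix_pattern"` or
#'   `"declared"`).
#' @export
detect_duplicate_samples <- function(samples, paper_report = NULL,
                                     suffix_tokens = default_suffix_tokens()) {
  groups <- list()
  if (nrow(samples) > 0) {
    key <- normalise_alias(samples$alias, suffix_tokens)
    for (k in unique(key[duplicated(key)])) {
      members <- samples$accession[key == k]
      groups[[length(groups) + 1L]] <- tibble(
        member_accessions = list(sort(members)), reason = "suffix_pattern")
    }
  }
  if (!is.null(paper_report)) {
    pps <- paper_report$previously_published_samples
    if (!is.null(pps) && nrow(pps) > 0) {
      for (i in seq_len(nrow(pps))) {
        if (pps$existing_accession[i] %in% samples$accession) next
        own <- samples$accession[samples$alias == pps$alias[i]]
        members <- unique(c(own, pps$existing_accession[i]))
        if (length(members) >= 2) {
          groups[[length(groups) + 1L]] <- tibble(
            member_accessions = list(sort(members)), reason = "declared")
        }
      }
    }
  }
  if (length(groups) == 0) {
    tibble(member_accessions = list(), reason = character())
  } else {
    bind_rows(groups)
  }
}

#' Compare archived sample count against the paper-declared count
#'
#' The observed count is the number of distinct sample accessions with at
#' least one linked run or analysis file; the declared count is the number of
#' samples the paper says were analysed. They match only when the declared
#' count is present and equal.
#'
#' @param bundle A [study_bundle()].
#' @return A one-row tibble: `declared`, `observed`, `matched`.
#' @export
compare_sample_counts <- function(bundle) {
  observed <- length(samples_with_data(bundle))
  declared <- bundle$paper_report$n_samples_analysed
  tibble(
    declared = if (is.null(declared)) NA_integer_ else as.integer(declared),
    observed = as.integer(observed),
    matched = !is.null(declared) && identical(as.integer(declared), as.integer(observed))
  )
}

samples_with_data <- function(bundle) {
  with_files <- function(tbl, acc_col) {
    has <- map_lgl(tbl$files, function(f) nrow(f) > 0)
    tbl[[acc_col]][has]
  }
  run_samples <- with_files(bundle$runs, "sample_accession")
  analysis_samples <- unlist(bundle$analyses$linked_sample_accessions[
    map_lgl(bundle$analyses$files, function(f) nrow(f) > 0)])
  unique(c(run_samples, analysis_samples))
}
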