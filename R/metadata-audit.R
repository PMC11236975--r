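# Sample- and experiment-metadata completeness scoring. Each category
# (geography, dating, tissue, voucher) distinguishes "any information"
# (a dedicated-field hit OR a lexicon/pattern match in free text) from
# information placed in a dedicated, machine-readable field. Every positive
# finding carries the tag and text that fired, as evidence.

the_lexicons <- new.env(parent = emptyenv())

#' Default metadata lexicons
#'
#' Loads (and caches) the vocabulary shipped with the package:
#' dedicated-field tag lists for geography, dating, tissue and voucher; a
#' flat gazetteer of place terms; tissue terms; dating text patterns;
#' radiocarbon lab-code prefixes; and library-protocol keywords. The shipped
#' gazetteer is a flat term list, not a geocoder: free-text geography is only
#' recognised when it uses a term from the list.
#'
#' @return A named list of character vectors (class `lexicons`).
#' @export
default_lexicons <- function() {
  if (is.null(the_lexicons$default)) {
    the_lexicons$default <- read_lexicons(
      system.file("extdata", "lexicons.yaml", package = "adnaudit"))
  }
  the_lexicons$default
}

#' Read metadata lexicons from a YAML or JSON config
#'
#' @param path Path to a lexicon config; see the shipped
#'   `extdata/lexicons.yaml` for the expected lists.
#' @return A named list of character vectors (class `lexicons`).
#' @export
read_lexicons <- function(path) {
  lex <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("geo_dedicated_tags", "date_dedicated_tags", "tissue_dedicated_tags",
                "voucher_tags", "tissue_terms", "gazetteer_terms", "date_patterns",
                "c14_prefixes", "protocol_terms")
  for (nm in required) {
    if (length(lex[[nm]]) == 0) {
      stop_adnaudit(sprintf("lexicon list '%s' is missing or empty in %s", nm, path),
                    "adnaudit_parse_error")
    }
    lex[[nm]] <- as.character(lex[[nm]])
  }
  structure(lex, class = "lexicons")
}

norm_tag <- function(x) tolower(trimws(x))

free_text_tags <- c("description", "note", "notes", "comment", "title")

#' Audit the metadata completeness of one sample
#'
#' Scores one sample record against the sample-metadata criteria: any/dedicated
#' geography, parseable coordinates, any/dedicated dating, radiocarbon lab
#' code, any/dedicated tissue, and specimen voucher. Dedicated findings fire
#' only on tags from the dedicated lists; "any" findings additionally fire on
#' lexicon or pattern matches in free-text fields (Description-like tags and
#' the sample title). Dedicated implies any, by construction.
#'
#' @param sample A one-row slice of a bundle's `samples` table, or a list with
#'   elements `accession`, `alias`, `title`, `attributes` (a tibble of
#'   `tag`/`value`/`units`).
#' @param lexicons Vocabulary, as from [default_lexicons()].
#' @return A one-row tibble of findings:
#'   `geo_any`, `geo_dedicated_field`, `geo_coordinates`, `parsed_lat`,
#'   `parsed_lon`, `date_any`, `date_dedicated_field`, `c14_lab_code`,
#'   `tissue_any`, `tissue_dedicated_field`, `voucher_present`, plus an
#'   `evidence` list-column (tibble of `finding`, `tag`, `matched`).
#' @export
audit_sample_metadata <- function(sample, lexicons = default_lexicons()) {
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1)
    sample <- as.list(sample)
    sample$attributes <- sample$attributes[[1]]
  }
  attrs <- normalise_attributes(sample$attributes)
  tags_n <- norm_tag(attrs$tag)
  evidence <- list()
  note <- function(finding, tag, matched) {
    evidence[[length(evidence) + 1L]] <<- tibble(finding = finding, tag = tag,
                                                 matched = matched)
  }

  free_idx <- which(tags_n %in% free_text_tags)
  free_text <- c(attrs$value[free_idx], if (!is.null(sample$title) &&
                                            !is.na(sample$title)) sample$title)
  free_tags <- c(attrs$tag[free_idx], if (!is.null(sample$title) &&
                                          !is.na(sample$title)) "title")

  dedicated_hits <- function(tag_list, finding) {
    idx <- which(tags_n %in% norm_tag(tag_list) & !is.na(attrs$value) &
                   nzchar(trimws(attrs$value)))
    for (i in idx) note(finding, attrs$tag[i], attrs$value[i])
    idx
  }

  # geography
  geo_idx <- dedicated_hits(lexicons$geo_dedicated_tags, "geo_dedicated_field")
  geo_dedicated <- length(geo_idx) > 0
  geo_free <- FALSE
  if (length(free_text) > 0) {
    for (term in lexicons$gazetteer_terms) {
      hit <- which(grepl(paste0("\\b", escape_regex(term), "\\b"), free_text,
                         ignore.case = TRUE))
      if (length(hit) > 0) {
        geo_free <- TRUE
        note("geo_any", free_tags[hit[1]], term)
      }
    }
  }
  geo_any <- geo_dedicated || geo_free

  coords <- extract_coordinates(attrs, tags_n, lexicons)
  if (!is.null(coords)) note("geo_coordinates", coords$tag, coords$text)

  # dating
  date_idx <- dedicated_hits(lexicons$date_dedicated_tags, "date_dedicated_field")
  date_dedicated <- length(date_idx) > 0
  date_free <- FALSE
  search_text <- c(free_text, attrs$value[date_idx])
  search_tags <- c(free_tags, attrs$tag[date_idx])
  if (length(free_text) > 0) {
    for (pat in lexicons$date_patterns) {
      hit <- which(grepl(pat, free_text, perl = TRUE, ignore.case = TRUE))
      if (length(hit) > 0) {
        date_free <- TRUE
        note("date_any", free_tags[hit[1]],
             regmatches(free_text[hit[1]],
                        regexpr(pat, free_text[hit[1]], perl = TRUE, ignore.case = TRUE)))
      }
    }
  }
  date_any <- date_dedicated || date_free

  c14 <- NA_character_
  if (length(search_text) > 0) {
    codes <- find_c14_lab_code(search_text, lexicons$c14_prefixes)
    hit <- which(!is.na(codes))
    if (length(hit) > 0) {
      c14 <- codes[hit[1]]
      note("c14_lab_code", search_tags[hit[1]], c14)
    }
  }

  # tissue
  tissue_idx <- dedicated_hits(lexicons$tissue_dedicated_tags, "tissue_dedicated_field")
  tissue_dedicated <- length(tissue_idx) > 0
  tissue_free <- FALSE
  if (length(free_text) > 0) {
    for (term in lexicons$tissue_terms) {
      hit <- which(grepl(paste0("\\b", escape_regex(term), "\\b"), free_text,
                         ignore.case = TRUE))
      if (length(hit) > 0) {
        tissue_free <- TRUE
        note("tissue_any", free_tags[hit[1]], term)
      }
    }
  }
  tissue_any <- tissue_dedicated || tissue_free

  voucher_idx <- dedicated_hits(lexicons$voucher_tags, "voucher_present")

  tibble(
    accession = chr1(sample$accession),
    geo_any = geo_any,
    geo_dedicated_field = geo_dedicated,
    geo_coordinates = !is.null(coords),
    parsed_lat = if (!is.null(coords)) coords$lat else NA_real_,
    parsed_lon = if (!is.null(coords)) coords$lon else NA_real_,
    date_any = date_any || !is.na(c14),
    date_dedicated_field = date_dedicated,
    c14_lab_code = c14,
    tissue_any = tissue_any,
    tissue_dedicated_field = tissue_dedicated,
    voucher_present = length(voucher_idx) > 0,
    evidence = list(if (length(evidence) > 0) bind_rows(evidence) else
      tibble(finding = character(), tag = character(), matched = character()))
  )
}

escape_regex <- function(x) gsub("([^A-Za-z0-9 ])", "\\\\\\1", x)

extract_coordinates <- function(attrs, tags_n, lexicons) {
  lat_tags <- c("geographic location (latitude)", "latitude", "lat")
  lon_tags <- c("geographic location (longitude)", "longitude", "lon", "long")
  lat_i <- which(tags_n %in% lat_tags)[1]
  lon_i <- which(tags_n %in% lon_tags)[1]
  if (!is.na(lat_i) && !is.na(lon_i)) {
    parsed <- tryCatch(parse_coordinates(attrs$value[lat_i], attrs$value[lon_i]),
                       error = function(e) NULL)
    if (!is.null(parsed)) {
      return(list(lat = parsed[["lat"]], lon = parsed[["lon"]],
                  tag = attrs$tag[lat_i],
                  text = paste(attrs$value[lat_i], attrs$value[lon_i])))
    }
  }
  ll_i <- which(tags_n %in% c("lat_lon", "lat lon", "latitude and longitude"))[1]
  if (!is.na(ll_i)) {
    # e.g. "52.2 N 0.12 E" or "52.2 0.12"
    parts <- strsplit(trimws(attrs$value[ll_i]), "\\s+")[[1]]
    if (length(parts) == 4) {
      parsed <- tryCatch(parse_coordinates(paste(parts[1], parts[2]),
                                           paste(parts[3], parts[4])),
                         error = function(e) NULL)
    } else if (length(parts) == 2) {
      parsed <- tryCatch(parse_coordinates(parts[1], parts[2]),
                         error = function(e) NULL)
    } else parsed <- NULL
    if (!is.null(parsed)) {
      return(list(lat = parsed[["lat"]], lon = parsed[["lon"]],
                  tag = attrs$tag[ll_i], text = attrs$value[ll_i]))
    }
  }
  NULL
}

#' Audit several samples at once
#'
#' @param samples The `samples` table of a [study_bundle()] (or any data frame
#'   with the same columns).
#' @param lexicons Vocabulary, as from [default_lexicons()].
#' @return A tibble with one findings row per sample; see
#'   [audit_sample_metadata()].
#' @export
audit_samples <- function(samples, lexicons = default_lexicons()) {
  if (nrow(samples) == 0) {
    return(audit_sample_metadata(list(accession = "x", attributes = NULL),
                                 lexicons)[0, ])
  }
  bind_rows(map(seq_len(nrow(samples)), function(i) {
    audit_sample_metadata(samples[i, ], lexicons)
  }))
}

#' Parse latitude/longitude text into decimal degrees
#'
#' Accepts signed decimal degrees (optionally with a trailing hemisphere
#' letter, e.g. `"52.2 N"`) and space-separated sexagesimal
#' degrees-minutes-seconds with a hemisphere letter (e.g. `"52 12 0 N"`).
#'
#' @param lat_text,lon_text Non-empty coordinate texts.
#' @return A named numeric vector `c(lat = , lon = )` in decimal degrees.
#'   Out-of-range values (|lat| > 90, |lon| > 180) raise a range error;
#'   unparseable text raises a format error.
#' @export
parse_coordinates <- function(lat_text, lon_text) {
  lat <- parse_one_coordinate(lat_text, c("N", "S"))
  lon <- parse_one_coordinate(lon_text, c("E", "W"))
  if (abs(lat) > 90) {
    stop_adnaudit(sprintf("latitude out of range: %s", lat_text), "adnaudit_range_error")
  }
  if (abs(lon) > 180) {
    stop_adnaudit(sprintf("longitude out of range: %s", lon_text), "adnaudit_range_error")
  }
  c(lat = lat, lon = lon)
}

parse_one_coordinate <- function(text, hemispheres) {
  stopifnot(is.character(text), length(text) == 1)
  txt <- trimws(text)
  if (!nzchar(txt)) {
    stop_adnaudit("empty coordinate text", "adnaudit_format_error")
  }
  txt <- gsub("[°'\"′″]", " ", txt)  # degree/minute/second marks
  txt <- gsub(",", ".", txt)
  parts <- strsplit(trimws(txt), "\\s+")[[1]]
  sign <- 1
  if (toupper(parts[length(parts)]) %in% c("N", "S", "E", "W")) {
    hemi <- toupper(parts[length(parts)])
    if (!hemi %in% hemispheres) {
      stop_adnaudit(sprintf("hemisphere letter '%s' inconsistent with axis in '%s'",
                            hemi, text), "adnaudit_format_error")
    }
    if (hemi %in% c("S", "W")) sign <- -1
    parts <- parts[-length(parts)]
  }
  nums <- suppressWarnings(as.numeric(parts))
  if (length(nums) == 0 || anyNA(nums)) {
    stop_adnaudit(sprintf("cannot parse coordinate '%s'", text), "adnaudit_format_error")
  }
  if (length(nums) == 1) return(sign * nums)
  if (length(nums) %in% c(2, 3)) {
    if (any(nums[-1] < 0) || nums[1] < 0) {
      stop_adnaudit(sprintf("mixed signs in sexagesimal coordinate '%s'", text),
                    "adnaudit_format_error")
    }
    dms <- c(nums, 0, 0)[1:3]
    return(sign * (dms[1] + dms[2] / 60 + dms[3] / 3600))
  }
  stop_adnaudit(sprintf("cannot parse coordinate '%s'", text), "adnaudit_format_error")
}

#' Find a radiocarbon lab code in text
#'
#' Radiocarbon dates are uniquely identified by a lab code: a laboratory
#' prefix followed by a serial number, e.g. `OxA-12345`. The first substring
#' matching `prefix`, an optional hyphen or space, and one to six digits is
#' returned; prefixes are matched case-sensitively and must not be embedded
#' in a longer word or number.
#'
#' @param text Character vector of texts to scan (vectorised).
#' @param prefixes Character vector of lab-code prefixes.
#' @return A character vector the length of `text`: the matched code, or
#'   `NA` where none was found.
#' @export
find_c14_lab_code <- function(text, prefixes = default_lexicons()$c14_prefixes) {
  stopifnot(length(prefixes) > 0)
  pat <- paste0("(?<![A-Za-z])(", paste(escape_regex(prefixes), collapse = "|"),
                ")[- ]?([0-9]{1,6})(?![0-9])")
  m <- regexpr(pat, text, perl = TRUE)
  out <- rep(NA_character_, length(text))
  hit <- which(m != -1L)
  out[hit] <- regmatches(text, m)[seq_along(hit)]
  out
}

#' Audit the experiment metadata of a run
#'
#' Library-preparation details matter downstream (single- versus
#' double-stranded protocols, enzymatic damage removal), and belong in the
#' run's free-text library-construction-protocol field. The finding is
#' positive when that field is non-empty or when protocol keywords appear in
#' it.
#'
#' @param run A one-row slice of a bundle's `runs` table, or a list with a
#'   `library_construction_protocol` element.
#' @param lexicons Vocabulary, as from [default_lexicons()].
#' @return A one-row tibble: `library_protocol_present` and a
#'   `protocol_keywords` list-column of matched terms.
#' @export
audit_experiment_metadata <- function(run, lexicons = default_lexicons()) {
  if (is.data.frame(run)) {
    stopifnot(nrow(run) == 1)
    run <- as.list(run)
  }
  proto <- run$library_construction_protocol
  proto <- if (is.null(proto) || is.na(proto)) "" else trimws(proto)
  keywords <- character()
  if (nzchar(proto)) {
    for (term in lexicons$protocol_terms) {
      if (grepl(escape_regex(term), proto, ignore.case = TRUE)) {
        keywords <- c(keywords, term)
      }
    }
  }
  tibble(
    accession = chr1(run$accession),
    library_protocol_present = nzchar(proto),
    protocol_keywords = list(keywords)
  )
}
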