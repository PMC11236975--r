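test_that("sample metadata findings fire on dedicated fields and free text as specified", {
  f0 <- audit_sample_metadata(tiny_sample(attrs = tiny_attrs())[1, ])
  expect_false(any(unlist(f0[, c("geo_any", "geo_dedicated_field", "geo_coordinates",
                                 "date_any", "date_dedicated_field",
                                 "tissue_any", "tissue_dedicated_field",
                                 "voucher_present")])))

  f <- audit_sample_metadata(tiny_sample(attrs = tiny_attrs(
    "geographic location (region and locality)" = "Norfolk, UK"))[1, ])
  expect_true(f$geo_any && f$geo_dedicated_field)
  expect_false(f$geo_coordinates)
  expect_true(nrow(f$evidence[[1]]) > 0)

  f <- audit_sample_metadata(tiny_sample(attrs = tiny_attrs("Description" = "Bone"))[1, ])
  expect_true(f$tissue_any)
  expect_false(f$tissue_dedicated_field)

  f <- audit_sample_metadata(tiny_sample(attrs = tiny_attrs(
    "Description" = "burial near Norfolk, dated to 4520 BP (OxA-12345)"))[1, ])
  expect_true(f$geo_any && !f$geo_dedicated_field)
  expect_true(f$date_any && !f$date_dedicated_field)
  expect_equal(f$c14_lab_code, "OxA-12345")

  f <- audit_sample_metadata(tiny_sample(attrs = tiny_attrs(
    "geographic location (latitude)" = "52 12 0 N",
    "geographic location (longitude)" = "0 7 0 E"))[1, ])
  expect_true(f$geo_coordinates)
  expect_equal(f$parsed_lat, 52.2, tolerance = 1e-6)
  expect_equal(f$parsed_lon, 0.116667, tolerance = 1e-5)
})

test_that("dedicated-implies-any and monotonicity hold across attribute sets", {
  lex <- default_lexicons()
  pools <- list(
    tiny_attrs("geographic location (region and locality)" = "Siberia"),
    tiny_attrs("lat_lon" = "52.2 N 0.12 E"),
    tiny_attrs("date" = "900 CE"),
    tiny_attrs("collection date" = "1200 BCE"),
    tiny_attrs("tissue" = "petrous"),
    tiny_attrs("Description" = "Tooth from Anatolia, 4000 BP"),
    tiny_attrs("specimen voucher" = "MUS-001"),
    tiny_attrs("note" = "no useful content here")
  )
  set.seed(9)
  flag_cols <- c("geo_any", "geo_dedicated_field", "geo_coordinates", "date_any",
                 "date_dedicated_field", "tissue_any", "tissue_dedicated_field",
                 "voucher_present")
  for (rep in 1:25) {
    pick <- sample(length(pools), sample(0:5, 1))
    attrs <- if (length(pick) > 0) dplyr::bind_rows(pools[pick]) else tiny_attrs()
    f <- audit_sample_metadata(tiny_sample(attrs = attrs)[1, ], lex)
    expect_true(!f$geo_dedicated_field || f$geo_any)
    expect_true(!f$geo_coordinates || f$geo_any)
    expect_true(!f$date_dedicated_field || f$date_any)
    expect_true(!f$tissue_dedicated_field || f$tissue_any)
    # every positive finding carries evidence naming a tag
    if (any(unlist(f[, flag_cols]))) expect_true(nrow(f$evidence[[1]]) > 0)
    # monotone: adding one more attribute never turns a true finding false
    extra <- dplyr::bind_rows(attrs, pools[[sample(length(pools), 1)]])
    f2 <- audit_sample_metadata(tiny_sample(attrs = extra)[1, ], lex)
    for (col in flag_cols) {
      expect_true(!f[[col]] || f2[[col]], info = col)
    }
  }
})

test_that("coordinate parsing covers decimal, sexagesimal and error cases", {
  expect_equal(parse_coordinates("0", "0"), c(lat = 0, lon = 0))
  expect_equal(parse_coordinates("52 12 0 N", "0 7 0 E"),
               c(lat = 52.2, lon = 0.11666667), tolerance = 1e-6)
  expect_equal(parse_coordinates("-33.5", "151.2")[["lat"]], -33.5)
  expect_equal(parse_coordinates("33.5 S", "18.4 E")[["lat"]], -33.5)
  expect_error(parse_coordinates("95", "10"), class = "adnaudit_range_error")
  expect_error(parse_coordinates("10", "191"), class = "adnaudit_range_error")
  expect_error(parse_coordinates("not a number", "10"),
               class = "adnaudit_format_error")
  expect_error(parse_coordinates("12.1 E", "10"), class = "adnaudit_format_error")
})

test_that("radiocarbon lab codes match a brute-force scan with the same grammar", {
  prefixes <- default_lexicons()$c14_prefixes
  # regex-free scan: try every substring start, longest digit run up to 6
  brute_scan <- function(text) {
    chars <- strsplit(text, "")[[1]]
    for (s in seq_along(chars)) {
      for (pref in prefixes) {
        np <- nchar(pref)
        if (s + np - 1 > length(chars)) next
        if (substr(text, s, s + np - 1) != pref) next
        if (s > 1 && grepl("[A-Za-z]", chars[s - 1])) next
        j <- s + np
        if (j <= length(chars) && chars[j] %in% c("-", " ")) j <- j + 1
        k <- j
        while (k <= length(chars) && grepl("[0-9]", chars[k])) k <- k + 1
        ndig <- k - j
        if (ndig >= 1 && ndig <= 6) return(substr(text, s, k - 1))
      }
    }
    NA_character_
  }
  texts <- c(
    "4520±30 BP (OxA-12345)", "dated to the Bronze Age",
    "Beta 99821 and OxA-1", "sample UBA-4411a", "no code 123456 here",
    "PSUAMS-2211", "prefix-less 4521", "GrA 11 ok", "Wk-123456",
    "code Wk-1234567 too long", "text OxA12345 compact", "LOxA-123 embedded",
    "Ua 22170", "KIA-4", "nested (GrM-13240) parens", "AAR-7919.2",
    "mixed Poz-352 and KIA-1", "UCIAMS 186312", "ends with Beta-", "Beta-007"
  )
  got <- find_c14_lab_code(texts, prefixes)
  for (i in seq_along(texts)) {
    expect_equal(got[i], brute_scan(texts[i]), info = texts[i])
  }
  # the two contract examples
  expect_equal(find_c14_lab_code("4520±30 BP (OxA-12345)", prefixes), "OxA-12345")
  expect_true(is.na(find_c14_lab_code("dated to the Bronze Age", prefixes)))
})

test_that("experiment metadata flags library-protocol details and keywords", {
  run <- function(proto) list(accession = "ERR1",
                              library_construction_protocol = proto)
  f <- audit_experiment_metadata(run("ss library, half-UDG treated"))
  expect_true(f$library_protocol_present)
  expect_true("UDG" %in% f$protocol_keywords[[1]])
  f <- audit_experiment_metadata(run("double-stranded library"))
  expect_true(f$library_protocol_present)
  expect_true("double-stranded" %in% f$protocol_keywords[[1]])
  f <- audit_experiment_metadata(run(NA_character_))
  expect_false(f$library_protocol_present)
  expect_equal(length(f$protocol_keywords[[1]]), 0)
})
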