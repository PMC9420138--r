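cfg <- default_config()

raw_row <- function(...) {
  base <- data.frame(
    org_name_raw = "USGS", st_abbr = "IA", st_name = "Iowa",
    orig_MLI = "S1", orig_x = 0, orig_y = 0, date = "2001-06-05",
    time = "10:00:00", media = "Water", activity_type = "Sample-Routine",
    result_type = "Actual", nutrient_handle = "Nitrate as N",
    analytical_method = NA_character_, sample_fraction_raw = "dissolved",
    orig_conc = "1.5", orig_conc_units = "mg/l as N",
    DL_code = NA_character_, DL_text = NA_character_,
    orig_DL_val = NA_real_, orig_DL_units = NA_character_,
    provider = "NWIS", stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("organization names are trimmed, aliased and otherwise preserved", {
  al <- c("usgs" = "USGS")
  expect_equal(standardize_org_name("  usgs ", al), "USGS")
  expect_equal(standardize_org_name("U.S. Geological Survey",
                                    cfg$org_alias_table), "USGS")
  expect_equal(standardize_org_name("Org-X", c()), "Org-X")
  expect_equal(standardize_org_name("  Org-X  \t", c()), "Org-X")
})

test_that("each cascade rule drops on its own predicate", {
  rows <- rbind(
    raw_row(),                                         # kept
    raw_row(media = "soil"),                           # step 3
    raw_row(date = ""),                                # step 4
    raw_row(nutrient_handle = "Phosphate",
            orig_conc_units = "mg/l"),                 # step 5
    raw_row(orig_conc = "-0.5"),                       # step 6
    raw_row(orig_conc = "0"),                          # step 6 (zero, no ND)
    raw_row(orig_conc_units = "% recovery"),           # step 7
    raw_row(DL_code = "Contaminated"),                 # step 8
    raw_row(sample_fraction_raw = "bed sediment"),     # step 9
    raw_row(activity_type = "Quality Control Sample-Field Blank"), # step 10
    raw_row(result_type = "Educated Guess")            # step 11
  )
  rows$record_id <- seq_len(nrow(rows)) - 1L
  out <- apply_filter_cascade(rows, cfg)
  expect_equal(out$.drop_step, c(0L, 3L, 4L, 5L, 6L, 6L, 7L, 8L, 9L, 10L, 11L))
  expect_equal(out$media_flag[2], "drop")
  expect_equal(out$chem_form_flag[4], "chem_form_unknown")
  expect_equal(out$conc_flag[5:6], c("drop", "drop"))
  expect_equal(out$ND_flag[8], "drop")
  expect_equal(out$result_type_flag[11], "drop")
})

test_that("a row has at most one drop flag and NA everywhere after it", {
  # this row violates several rules at once; only the earliest fires
  r <- raw_row(media = "soil", orig_conc = "-2", result_type = "Approximation")
  r$record_id <- 0L
  out <- apply_filter_cascade(r, cfg)
  expect_equal(out$media_flag, "drop")
  expect_equal(out$date_flag, "keep")       # date flag has no NA state
  expect_true(is.na(out$chem_form_flag))
  expect_true(is.na(out$conc_flag))
  expect_true(is.na(out$result_type_flag))
})

test_that("adding a later-step corruption never changes an earlier flag", {
  r0 <- raw_row(); r0$record_id <- 0L
  base <- apply_filter_cascade(r0, cfg)
  r1 <- raw_row(result_type = "Approximation"); r1$record_id <- 0L
  out <- apply_filter_cascade(r1, cfg)
  for (col in c("media_flag", "date_flag", "chem_form_flag", "conc_flag",
                "conc_unit_flag", "ND_flag", "sample_fraction_flag",
                "activity_type_flag"))
    expect_identical(out[[col]], base[[col]], label = col)
  expect_equal(out$result_type_flag, "drop")
})

test_that("cascade flags equal rule-by-rule brute force on a random fixture", {
  d <- generate_dataset(generator_spec(n_sites = 4, n_years = 2, seed = 99))
  raw <- utils::head(d$raw, 50)
  out <- apply_filter_cascade(raw, cfg)
  for (i in seq_len(nrow(raw)))
    expect_equal(out$.drop_step[i], oracle_cascade_step(raw[i, ], cfg),
                 label = sprintf("row %d", i))
})

test_that("non-detects require both a censored value and non-detect metadata", {
  r <- rbind(raw_row(orig_conc = "0", DL_code = "U"),
             raw_row(orig_conc = "0"),
             raw_row(orig_conc = "2.1", DL_code = "U"),
             raw_row(orig_conc = "", DL_text = "Not Detected"),
             raw_row(orig_conc = "-0.1", DL_code = "ND"),
             raw_row(orig_conc = "1", DL_code = "Contaminated"))
  expect_equal(identify_nondetects(r, cfg),
               c("ND", "keep", "keep", "ND", "ND", "drop"))
})
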