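cfg <- default_config()

test_that("chemical form is recovered from name, then units, then method", {
  expect_equal(infer_chemical_form("Nitrate as N", NA, NA, cfg), "elemental")
  expect_equal(infer_chemical_form("Nitrate", "mg/l", "4500-NO3-E", cfg),
               "elemental")
  expect_equal(infer_chemical_form("Phosphate", "mg/l", NA, cfg), "unknown")
  expect_equal(infer_chemical_form("Orthophosphate as PO4", NA, NA, cfg), "PO4")
  expect_equal(infer_chemical_form("Nitrate", "mg/l as NO3", NA, cfg), "NO3")
  expect_equal(infer_chemical_form("Phosphorus", "mg/l as P", NA, cfg),
               "elemental")
  # flagged-export style handles (underscored subscripts) normalize too
  expect_equal(infer_chemical_form("ammonia_N_as_N", NA, NA, cfg), "elemental")
  expect_equal(infer_chemical_form("Ammonia as NH_3_", NA, NA, cfg), "NH3")
})

test_that("molecular concentrations convert to the elemental basis", {
  ct <- cfg$conversion_table
  expect_equal(convert_to_elemental(1.0, "NO3", ct), 0.225)
  expect_equal(convert_to_elemental(2.0, "PO4", ct), 0.652)
  expect_equal(convert_to_elemental(1.0, "elemental", ct), 1.0)
  expect_equal(convert_to_elemental(1.0, "NH3", ct), 0.822)
  expect_true(is.na(convert_to_elemental(1.0, "SO4", ct)))
})

test_that("unit conversion rescales to mg/L and rejects non-volumetric units", {
  reg <- cfg$unit_registry
  expect_equal(convert_units(1000, "ug/l", reg), 1.0)
  expect_equal(convert_units(3.5, "ppm", reg), 3.5)
  expect_equal(convert_units(2, "MG/L", reg), 2)       # case-insensitive
  expect_true(is.na(convert_units(5, "% recovery", reg)))
  expect_true(is.na(convert_units(5, "furlongs", reg)))
})

test_that("nutrient renaming joins name and fraction into the parameter", {
  out <- harmonize_nutrient_name("ammonia", "filtered")
  expect_equal(out$nutrient_parameter, "ammonia_filtered")
  expect_equal(out$N_or_P, "N")
  out <- harmonize_nutrient_name("total nitrogen", "unfiltered")
  expect_equal(out$nutrient_parameter, "total nitrogen_unfiltered")
  out <- harmonize_nutrient_name("total phosphorus", "unfiltered")
  expect_equal(out$nutrient_parameter, "total phosphorus_unfiltered")
  expect_equal(out$N_or_P, "P")
  expect_error(harmonize_nutrient_name("unobtainium", "filtered"),
               "vocabulary error")
  expect_error(harmonize_nutrient_name("ammonia", "centrifuged"),
               "vocabulary error")
})

test_that("every vocabulary entry resolves through form inference", {
  voc <- cfg$nutrient_vocabulary
  forms <- infer_chemical_form(voc$raw_handle, NA, NA, cfg)
  expect_true(all(forms %in% c("elemental", "NH3", "NH4", "NO3", "PO4",
                               "unknown")))
  # names carrying an explicit "as X" suffix are never unknown
  as_named <- grepl(" as ", voc$raw_handle)
  expect_false(any(forms[as_named] == "unknown"))
})

test_that("unit and form conversion compose to recover the truth", {
  ct <- cfg$conversion_table
  reg <- cfg$unit_registry
  set.seed(1)
  for (i in 1:200) {
    true <- rlnorm(1, -1, 1)
    entry <- ct[sample(nrow(ct), 1), ]
    units <- sample(c("mg/l", "ug/l", "ppm"), 1)
    ufac <- reg$factor[reg$unit == units]
    reported <- generate_molecular_report(true, entry) / ufac
    back <- convert_to_elemental(convert_units(reported, units, reg),
                                 entry$reported_form, ct)
    expect_lt(abs(back - true) / true, 1e-9)
  }
})
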