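daily_row <- function(param = "total phosphorus_filtered", conc = 0.1,
                      mli = "S1", date = as.Date("2005-07-01"),
                      impute_flag = "detected", dl = NA_real_) {
  parts <- strsplit(param, "_", fixed = TRUE)[[1]]
  data.frame(media = "water", st_abbr = "IA", st_name = "Iowa",
             org_name = "USGS", N_or_P = if (grepl("phosph", parts[1])) "P" else "N",
             nutrient_name = parts[1], sample_fraction = parts[2],
             nutrient_parameter = param, year = 2005L, date = date, MLI = mli,
             conc = conc, outlier_flag = "not_flagged_as_outlier",
             num_obs_per_date = 1L, impute_flag = impute_flag, DL = dl,
             x = 0, y = 0, stringsAsFactors = FALSE)
}

test_that("percentile outlier flags use interpolated order statistics", {
  rec <- data.frame(conc = c(1:100, NA), nutrient_parameter = "p")
  out <- flag_outliers(rec, 1, 99)
  expect_equal(out$pct1[1], 1.99)       # type-7 interpolation on 1..100
  expect_equal(out$pct99[1], 99.01)
  expect_equal(out$outlier_flag[100], "potential_outlier")
  expect_equal(out$outlier_flag[1], "potential_outlier")
  expect_equal(out$outlier_flag[50], "not_flagged_as_outlier")
  expect_true(is.na(out$outlier_flag[101]))
})

test_that("degenerate concentration distributions flag nothing", {
  out <- flag_outliers(data.frame(conc = rep(2, 10), nutrient_parameter = "p"))
  expect_true(all(out$outlier_flag == "not_flagged_as_outlier"))
  out <- flag_outliers(data.frame(conc = c(1, 2), nutrient_parameter = "p"))
  expect_true(all(out$outlier_flag == "not_flagged_as_outlier"))
  expect_true(all(is.na(out$pct1)))
})

wrk_row <- function(conc, status = "detected", org = "USGS",
                    time = "10:00:00", dl = NA_real_, mli = "S1",
                    param = "nitrate_filtered",
                    outlier = "not_flagged_as_outlier") {
  parts <- strsplit(param, "_", fixed = TRUE)[[1]]
  data.frame(record_id = NA_integer_, new_MLI = mli, new_x = 0, new_y = 0,
             date = as.Date("2005-07-01"), time = time, year = 2005L,
             org_name = org, st_abbr = "IA", st_name = "Iowa",
             media = "water", nutrient_parameter = param,
             nutrient_name = parts[1], sample_fraction = parts[2],
             N_or_P = "N", conc = conc, status = status, DL = dl,
             outlier_flag = outlier, stringsAsFactors = FALSE)
}

test_that("same-day concentrations average into one daily value", {
  w <- rbind(wrk_row(2, time = "01:00:00"), wrk_row(4, time = "02:00:00"))
  w$record_id <- 0:1
  out <- resolve_duplicates(w)
  expect_equal(nrow(out$daily), 1L)
  expect_equal(out$daily$conc, 3)
  expect_equal(out$daily$num_obs_per_date, 2L)
  expect_equal(out$daily$impute_flag, "detected")
})

test_that("averages mixing detected and imputed members are flagged imputed", {
  w <- rbind(wrk_row(1.0, time = "01:00:00"),
             wrk_row(0.2, status = "imputed", dl = 0.4, time = "02:00:00"))
  w$record_id <- 0:1
  out <- resolve_duplicates(w)
  expect_equal(out$daily$conc, 0.6)
  expect_equal(out$daily$impute_flag, "imputed")
  expect_equal(out$daily$DL, 0.4)
  expect_equal(out$per_record$num_nds_per_obs, c(2L, 2L))
})

test_that("identical records from two organizations collapse to one", {
  w <- rbind(wrk_row(1.5, org = "ZULU ORG"), wrk_row(1.5, org = "ALPHA ORG"))
  w$record_id <- 0:1
  out <- resolve_duplicates(w)
  expect_equal(nrow(out$daily), 1L)
  expect_equal(out$daily$conc, 1.5)
  expect_equal(out$daily$org_name, "ALPHA ORG")
  expect_equal(out$per_record$num_orgs_per_obs, c(2L, 2L))
  expect_equal(out$daily$num_obs_per_date, 1L)
})

test_that("all-unimputed non-detect groups yield one missing-value row", {
  w <- rbind(wrk_row(NA_real_, status = "nd_na", dl = 0.2, time = "01:00:00"),
             wrk_row(NA_real_, status = "nd_na", dl = 0.3, time = "02:00:00"))
  w$record_id <- 0:1
  out <- resolve_duplicates(w)
  expect_equal(nrow(out$daily), 1L)
  expect_true(is.na(out$daily$conc))
  expect_equal(out$daily$impute_flag, "imputed")
  expect_true(is.na(out$daily$outlier_flag))
})

test_that("daily averaging matches the brute-force oracle and preserves sums", {
  set.seed(21)
  n <- 90
  w <- do.call(rbind, lapply(seq_len(n), function(i)
    wrk_row(rlnorm(1),
            time = sprintf("%02d:00:00", sample(0:23, 1)),
            mli = sample(c("S1", "S2", "S3"), 1),
            param = sample(c("nitrate_filtered", "ammonia_filtered"), 1))))
  w$record_id <- seq_len(n) - 1L
  w$date <- as.Date("2005-07-01") + sample(0:2, n, replace = TRUE)
  out <- resolve_duplicates(w)
  orc <- oracle_daily_mean(w$new_MLI, w$date, w$nutrient_parameter, w$conc)
  dk <- paste(out$daily$MLI, out$daily$date, out$daily$nutrient_parameter)
  expect_setequal(dk, orc$key)
  expect_equal(out$daily$conc[match(orc$key, dk)], orc$conc)
  # mean preservation: conc * members averaged == sum of member values
  expect_equal(sum(out$daily$conc * out$daily$num_obs_per_date),
               sum(w$conc), tolerance = 1e-9)
})

test_that("fraction combination adds totals only where they are missing", {
  d1 <- rbind(daily_row("total phosphorus_filtered", 0.1),
              daily_row("total phosphorus_particulate", 0.2))
  out <- combine_fractions(d1)
  expect_equal(nrow(out), 3L)
  add <- out[3, ]
  expect_equal(add$nutrient_parameter, "total phosphorus_unfiltered")
  expect_equal(add$conc, 0.3)
  expect_equal(add$impute_flag, "calculated_by_combining")

  # missing component: nothing added
  expect_equal(nrow(combine_fractions(daily_row("total phosphorus_filtered"))),
               1L)
  # target already measured that day: nothing added
  d3 <- rbind(d1, daily_row("total phosphorus_unfiltered", 0.5))
  expect_equal(nrow(combine_fractions(d3)), 3L)
})

test_that("inconsistent filtered/unfiltered pairs are flagged and consistent kept", {
  d <- rbind(daily_row("total phosphorus_filtered", 0.5),
             daily_row("total phosphorus_unfiltered", 0.4),
             daily_row("total phosphorus_filtered", 0.3, mli = "S2"),
             daily_row("total phosphorus_unfiltered", 0.4, mli = "S2"),
             daily_row("total phosphorus_filtered", 0.2, mli = "S3"))
  out <- qc_filtered_vs_unfiltered(d)
  expect_equal(out$filt2unfilt_flag[1:2],
               rep("unfilt conc <= filt conc", 2))
  expect_equal(out$filt2unfilt_flag[3:4], c("keep", "keep"))
  expect_true(is.na(out$filt2unfilt_flag[5]))
  # equality counts as inconsistent
  d2 <- rbind(daily_row("total phosphorus_filtered", 0.4, mli = "S9"),
              daily_row("total phosphorus_unfiltered", 0.4, mli = "S9"))
  out2 <- qc_filtered_vs_unfiltered(d2)
  expect_equal(unique(out2$filt2unfilt_flag), "unfilt conc <= filt conc")
  expect_equal(oracle_step19(d2), c(TRUE, TRUE))
  expect_equal(oracle_step19(d)[1:5], !is.na(out$filt2unfilt_flag) &
                 out$filt2unfilt_flag == "unfilt conc <= filt conc")
})
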