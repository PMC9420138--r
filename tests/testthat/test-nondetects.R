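test_that("the common detection limit is the max of per-organization minima", {
  # orgs A and B both have limit-less NDs; min detected A = 0.02, B = 0.05
  df <- data.frame(
    org_name = c("A", "A", "A", "B", "B", "B", "C"),
    nutrient_parameter = "nitrate_filtered", year = 1995L,
    new_conc = c(0.02, 0.9, NA, 0.05, 1.2, NA, 0.01),
    new_DL = NA_real_,
    ND_flag = c("keep", "keep", "ND", "keep", "keep", "ND", "keep"),
    stringsAsFactors = FALSE
  )
  out <- approximate_detection_limits(df)
  expect_equal(out$new_DL[c(3, 6)], c(0.05, 0.05))
  expect_true(all(out$.dl_approximated[c(3, 6)]))
  expect_true(all(is.na(out$new_DL[out$ND_flag == "keep"])))
  expect_equal(oracle_common_dl(df$org_name, df$new_conc,
                                df$ND_flag == "ND", !is.na(df$new_DL)), 0.05)
})

test_that("a single qualifying organization gives its own minimum as the limit", {
  df <- data.frame(org_name = c("A", "A"), nutrient_parameter = "p",
                   year = 2000L, new_conc = c(0.1, NA), new_DL = NA_real_,
                   ND_flag = c("keep", "ND"), stringsAsFactors = FALSE)
  out <- approximate_detection_limits(df)
  expect_equal(out$new_DL[2], 0.1)
})

test_that("reported detection limits are kept, unassignable ones stay missing", {
  df <- data.frame(org_name = c("A", "A", "B"), nutrient_parameter = "p",
                   year = 2000L, new_conc = c(0.2, NA, NA),
                   new_DL = c(NA, 0.03, NA),
                   ND_flag = c("keep", "ND", "ND"), stringsAsFactors = FALSE)
  out <- approximate_detection_limits(df)
  expect_equal(out$new_DL[2], 0.03)                 # reported limit untouched
  # B is the only qualifying org (its ND lacks a limit) but has no detected
  # value of its own; minima pool over qualifying orgs only, so no limit
  expect_true(is.na(out$new_DL[3]))
})

test_that("imputed draws lie strictly inside (0, DL]", {
  set.seed(3)
  obs <- rlnorm(30, 0, 1)
  dl <- c(0.4, 0.2, 0.7)
  res <- impute_censored(obs, dl, K = 10)
  expect_true(res$did_impute)
  expect_true(all(res$imputed > 0))
  expect_true(all(res$imputed <= dl))
})

test_that("groups at or above the cutoff share are left unimputed", {
  set.seed(4)
  res <- impute_censored(rlnorm(1), rep(0.5, 9), max_share = 0.8)
  expect_equal(res$pct_nd, 90)
  expect_false(res$did_impute)
  expect_true(all(is.na(res$imputed)))
  # exactly at the cutoff also refuses (imputes only below it)
  res <- impute_censored(rlnorm(2), rep(0.5, 8), max_share = 0.8)
  expect_equal(res$pct_nd, 80)
  expect_false(res$did_impute)
})

test_that("imputation is deterministic under a fixed seed", {
  obs <- exp(c(-0.5, 0.2, 0.9, 0.1))
  set.seed(11); a <- impute_censored(obs, c(0.3, 0.5))
  set.seed(11); b <- impute_censored(obs, c(0.3, 0.5))
  expect_identical(a, b)
})

test_that("imputed values vanish as the detection limit goes to zero", {
  obs <- exp(c(0, 0.5, -0.5, 0.2, 0.1, -0.2))
  set.seed(5)
  for (dl in c(1e-4, 1e-8, 1e-12)) {
    res <- impute_censored(obs, dl)
    expect_lte(res$imputed, dl)
  }
})

test_that("upper-truncated normal draws respect the bound in both regimes", {
  set.seed(6)
  z <- wqharmonize:::rtnorm_upper(rep(0, 500), rep(1, 500), rep(-0.5, 500))
  expect_true(all(z <= -0.5))
  expect_gt(mean(z > -2.2), 0.5)             # mass concentrates near the bound
  z <- wqharmonize:::rtnorm_upper(rep(0, 200), rep(1, 200), rep(-8, 200))
  expect_true(all(z <= -8))
  expect_true(all(is.finite(z)))
})
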