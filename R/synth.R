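# Synthetic raw-record generator. Emulates the messiness of multi-
# organization nutrient exports — spelling variants, duplicate sites,
# mixed elemental/molecular reporting, unit dialects, non-detects with and
# without detection limits, quality-control rows, sub-daily duplicates,
# filtered/unfiltered pairs — while recording the latent truth and the
# expected fate of every row, so the whole pipeline is testable without
# any download.

#' Default synthetic nutrient set
#'
#' The nutrient parameters the generator draws from, with lognormal
#' parameters (log mg/L) for the latent concentration of each. Levels are
#' typical of riverine nutrient monitoring: nitrate around 1 mg N/L,
#' total phosphorus a few tenths of mg P/L, orthophosphate lower.
#'
#' @return Data frame with columns \code{parameter}, \code{nutrient_name},
#'   \code{fraction}, \code{mu}, \code{sigma}.
#' @export
default_nutrients <- function() {
  data.frame(
    parameter = c("ammonia_filtered", "nitrate_filtered",
                  "kjeldahl nitrogen_unfiltered", "total nitrogen_unfiltered",
                  "total nitrogen_filtered", "orthophosphate_filtered",
                  "total phosphorus_unfiltered", "total phosphorus_filtered"),
    nutrient_name = c("ammonia", "nitrate", "kjeldahl nitrogen",
                      "total nitrogen", "total nitrogen", "orthophosphate",
                      "total phosphorus", "total phosphorus"),
    fraction = c("filtered", "filtered", "unfiltered", "unfiltered",
                 "filtered", "filtered", "unfiltered", "filtered"),
    mu = c(-1.2, 0.0, -0.3, 0.3, 0.1, -2.3, -1.6, -1.9),
    sigma = c(0.9, 1.0, 0.8, 0.9, 0.9, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic raw dataset
#'
#' Collects every knob of the synthetic generator: study dimensions,
#' censoring behaviour, reporting-dialect weights, and the per-fault
#' corruption rates that exercise each step of the harmonization cascade.
#' All rates are probabilities in [0, 1]; a fixed seed makes the output
#' fully reproducible.
#'
#' @param n_orgs,n_sites,n_years,start_year Study dimensions (years within
#'   1980--2018).
#' @param records_per_site_year Poisson mean of records per site-year.
#' @param nd_rate Fraction of records censored (the per-org-nutrient-year
#'   detection limit is placed at this quantile of the latent lognormal).
#' @param nd_missing_dl_rate Fraction of non-detects reported without a
#'   detection limit.
#' @param dup_coord_rate,dup_mli_rate Fraction of sites given a second
#'   coordinate pair (offset uniform in (0, 800) m, so both the merge and
#'   keep-separate branches occur) or a second MLI.
#' @param sub_daily_dup_rate,cross_org_dup_rate Per-record probabilities of
#'   a same-day repeat measurement and of a verbatim duplicate under a
#'   different organization name.
#' @param unit_dialect_weights Named probabilities over unit texts;
#'   \code{"{elem}"} is replaced by the record's N/P basis.
#' @param molecular_report_rate Probability that an eligible nutrient
#'   (ammonia, nitrate, orthophosphate) is reported on a molecular basis.
#' @param unknown_form_rate,bad_conc_rate,bad_unit_rate,contaminated_rate,bad_fraction_rate,qc_activity_rate,estimated_result_rate,bad_media_rate,missing_date_rate
#'   Per-record probabilities of the mutually exclusive metadata faults
#'   that feed cascade steps 5, 6, 7, 8, 9, 10, 11, 3 and 4 respectively.
#' @param org_alias_rate Probability an organization name is emitted as a
#'   spelling variant.
#' @param filtered_pair_rate,inconsistency_rate Probabilities that a
#'   filtered record gains an unfiltered counterpart (consistent, or
#'   inconsistent with filtered >= unfiltered).
#' @param combine_pair_rate Probability that a filtered total-nutrient
#'   record gains a particulate counterpart (a fraction-combination
#'   source pair).
#' @param nutrients Nutrient set, see \code{\link{default_nutrients}}.
#' @param seed Integer RNG seed.
#' @return An object of class \code{wq_generator_spec}.
#' @export
generator_spec <- function(n_orgs = 6L, n_sites = 25L, n_years = 8L,
                           start_year = 2000L, records_per_site_year = 6,
                           nd_rate = 0.2, nd_missing_dl_rate = 0.3,
                           dup_coord_rate = 0.15, dup_mli_rate = 0.1,
                           sub_daily_dup_rate = 0.05,
                           cross_org_dup_rate = 0.03,
                           unit_dialect_weights = c("mg/l as {elem}" = 0.5,
                                                    "mg/l" = 0.2,
                                                    "ug/l" = 0.15,
                                                    "ug/l as {elem}" = 0.1,
                                                    "ppm" = 0.05),
                           molecular_report_rate = 0.15,
                           unknown_form_rate = 0.03, bad_conc_rate = 0.02,
                           bad_unit_rate = 0.02, contaminated_rate = 0.01,
                           bad_fraction_rate = 0.02, qc_activity_rate = 0.03,
                           estimated_result_rate = 0.02,
                           bad_media_rate = 0.02, missing_date_rate = 0.01,
                           org_alias_rate = 0.1, filtered_pair_rate = 0.06,
                           inconsistency_rate = 0.02,
                           combine_pair_rate = 0.02,
                           nutrients = default_nutrients(), seed = 1L) {
  spec <- as.list(environment())
  class(spec) <- "wq_generator_spec"
  rates <- c("nd_rate", "nd_missing_dl_rate", "dup_coord_rate",
             "dup_mli_rate", "sub_daily_dup_rate", "cross_org_dup_rate",
             "molecular_report_rate", "unknown_form_rate", "bad_conc_rate",
             "bad_unit_rate", "contaminated_rate", "bad_fraction_rate",
             "qc_activity_rate", "estimated_result_rate", "bad_media_rate",
             "missing_date_rate", "org_alias_rate", "filtered_pair_rate",
             "inconsistency_rate", "combine_pair_rate")
  for (r in rates) {
    v <- spec[[r]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stopf("generator spec: '%s' must be a probability in [0, 1]", r)
  }
  if (spec$n_sites < 1L) stopf("generator spec: need at least one site")
  if (spec$n_years < 1L) stopf("generator spec: need at least one year")
  if (spec$start_year < 1980L || spec$start_year + spec$n_years - 1L > 2018L)
    stopf("generator spec: years must lie within 1980-2018")
  if (sum(unlist(spec[fault_rate_names])) >= 1)
    stopf("generator spec: fault rates must sum to less than 1")
  spec
}

fault_rate_names <- c(bad_media_rate = "media", missing_date_rate = "date",
                      unknown_form_rate = "form", bad_conc_rate = "conc",
                      bad_unit_rate = "unit", contaminated_rate = "contaminated",
                      bad_fraction_rate = "fraction", qc_activity_rate = "qc",
                      estimated_result_rate = "estimated")

fault_step <- c(media = 3L, date = 4L, form = 5L, conc = 6L, unit = 7L,
                contaminated = 8L, fraction = 9L, qc = 10L, estimated = 11L)

#' Report a molecular-basis concentration
#'
#' The generator-side inverse of the molecular-to-elemental conversion:
#' given a true elemental concentration and a conversion entry, returns the
#' value an organization reporting on the molecular basis would print
#' (true divided by the factor), so that downstream conversion recovers the
#' truth exactly.
#'
#' @param true_conc True elemental concentration (mg/L).
#' @param entry One row of a conversion table (needs a positive
#'   \code{factor}).
#' @return The molecular-basis value.
#' @export
generate_molecular_report <- function(true_conc, entry) {
  fac <- if (is.data.frame(entry)) entry$factor else entry[["factor"]]
  if (!is.numeric(fac) || any(fac <= 0))
    stopf("generate_molecular_report: conversion factor must be positive")
  true_conc / fac
}

# elemental / starred raw-name choices per harmonized nutrient
elem_handle <- c("ammonia" = "Ammonia N as N", "nitrate" = "Nitrate as N",
                 "kjeldahl nitrogen" = "Kjeldahl N",
                 "total nitrogen" = "Nitrogen, mixed forms",
                 "organic nitrogen" = "Organic Nitrogen",
                 "orthophosphate" = "Orthophosphate as P",
                 "total phosphorus" = "Phosphorus",
                 "organic phosphorus" = "Organic Phosphorus")
starred_handle <- c("ammonia" = "Ammonia", "nitrate" = "Nitrate",
                    "orthophosphate" = "Phosphate",
                    "total phosphorus" = "Phosphorus",
                    "kjeldahl nitrogen" = "Kjeldahl N (form unspecified)",
                    "total nitrogen" = "Nitrogen (form unspecified)",
                    "organic nitrogen" = "Organic Nitrogen (form unspecified)",
                    "organic phosphorus" = "Organic Phosphorus (form unspecified)")

#' Generate a synthetic raw dataset with latent truth
#'
#' Draws latent sites, dates and lognormal concentrations, then corrupts
#' the reporting per the requested rates: molecular-basis values (the inverse
#' of the conversion factors), unit dialects, censoring below a
#' per-org-nutrient-year detection limit, metadata faults, organization
#' spelling variants, duplicate sites and duplicate records. The truth
#' sidecar records each row's latent site, true elemental concentration in
#' mg/L, an anomaly tag and its expected fate through the pipeline.
#' Expected fates are exact when at most one corruption family is active;
#' with many families combined, rare interactions (e.g. a non-detect inside
#' an inconsistent filtered pair) are resolved in cascade order.
#'
#' @param spec A \code{\link{generator_spec}}.
#' @return A list with data frames \code{raw} (WQP-style columns plus
#'   \code{record_id}) and \code{truth} (one row per raw record).
#' @export
generate_dataset <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "wq_generator_spec"))
  set.seed(spec$seed)
  nut <- spec$nutrients

  ## organizations ----------------------------------------------------
  org_pool <- c("USGS", "EPA", sprintf("ORG-%02d", seq_len(max(spec$n_orgs, 2L))))
  orgs <- org_pool[seq_len(spec$n_orgs)]
  org_variants <- list(
    "USGS" = c("U.S. Geological Survey", "usgs", " USGS "),
    "EPA" = c("U.S. Environmental Protection Agency", " epa ")
  )
  variant_of <- function(o) {
    v <- org_variants[[o]]
    if (is.null(v)) v <- c(paste0(" ", o), paste0(o, "  "))
    sample(v, 1L)
  }

  states <- data.frame(
    st_abbr = c("IA", "IL", "MO", "MN", "AR", "LA"),
    st_name = c("Iowa", "Illinois", "Missouri", "Minnesota", "Arkansas",
                "Louisiana"),
    stringsAsFactors = FALSE
  )

  ## sites -------------------------------------------------------------
  ns <- spec$n_sites
  sites <- data.frame(
    site = seq_len(ns),
    mli = sprintf("SITE-%04d", seq_len(ns)),
    x = round(stats::runif(ns, 0, 5e5), 1),
    y = round(stats::runif(ns, 0, 5e5), 1),
    org = sample(orgs, ns, replace = TRUE),
    st = sample(nrow(states), ns, replace = TRUE),
    stringsAsFactors = FALSE
  )
  sites$dup_coord <- stats::runif(ns) < spec$dup_coord_rate
  ang <- stats::runif(ns, 0, 2 * pi)
  dd <- stats::runif(ns, 0, 800)
  sites$x2 <- round(sites$x + dd * cos(ang), 1)
  sites$y2 <- round(sites$y + dd * sin(ang), 1)
  sites$dup_mli <- stats::runif(ns) < spec$dup_mli_rate
  sites$alt_mli <- paste0(sites$mli, "-ALT")

  ## core latent records ----------------------------------------------
  years <- spec$start_year + seq_len(spec$n_years) - 1L
  m_per <- stats::rpois(ns * spec$n_years, spec$records_per_site_year)
  site_idx <- rep(rep(sites$site, each = spec$n_years), m_per)
  year_v <- rep(rep(years, times = ns), m_per)
  n0 <- length(site_idx)
  if (n0 == 0L) stopf("generator spec: no records generated; raise records_per_site_year")
  pidx <- sample(nrow(nut), n0, replace = TRUE)
  date_v <- as.Date(sprintf("%d-01-01", year_v)) + (sample.int(365, n0, TRUE) - 1L)
  time_v <- ifelse(stats::runif(n0) < 0.7,
                   sprintf("%02d:%02d:00", sample(0:23, n0, TRUE),
                           sample(0:59, n0, TRUE)), "")
  true_v <- stats::rlnorm(n0, nut$mu[pidx], nut$sigma[pidx])
  faults <- sample(c("none", unname(fault_rate_names)), n0, replace = TRUE,
                   prob = c(1 - sum(unlist(spec[names(fault_rate_names)])),
                            unlist(spec[names(fault_rate_names)])))

  # one base record per site-date-nutrient: same-day repeats and
  # filtered/unfiltered pairs are injected deliberately below, so natural
  # date collisions are bumped to the next free day within the year
  nm0 <- nut$nutrient_name[pidx]
  day0 <- as.integer(date_v - as.Date(sprintf("%d-01-01", year_v)))
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n0)) {
    tries <- 0L
    repeat {
      k <- paste(site_idx[i], year_v[i], day0[i], nm0[i], sep = "\r")
      if (is.null(get0(k, envir = seen)) || tries > 365L) {
        assign(k, TRUE, envir = seen); break
      }
      day0[i] <- (day0[i] + 1L) %% 365L
      tries <- tries + 1L
    }
  }
  date_v <- as.Date(sprintf("%d-01-01", year_v)) + day0

  core <- data.frame(site = site_idx, year = year_v, pidx = pidx,
                     date = date_v, time = time_v, true = true_v,
                     fault = faults, nd_exempt = FALSE,
                     anomaly = ifelse(faults == "none", "", faults),
                     stringsAsFactors = FALSE)

  ## sub-daily duplicates ---------------------------------------------
  dup <- core$fault == "none" & stats::runif(n0) < spec$sub_daily_dup_rate
  if (any(dup)) {
    extra <- core[dup, , drop = FALSE]
    extra$true <- stats::rlnorm(nrow(extra), nut$mu[extra$pidx],
                                nut$sigma[extra$pidx])
    extra$time <- sprintf("%02d:%02d:00", sample(0:23, nrow(extra), TRUE),
                          sample(0:59, nrow(extra), TRUE))
    extra$anomaly <- "sub_daily_dup"
    core$anomaly[dup] <- paste0(core$anomaly[dup], ",sub_daily_dup")
    core <- rbind(core, extra)
  }

  ## filtered/unfiltered and combination pairs ------------------------
  pair_rows <- function(rows, kind) {
    if (!length(rows)) return(NULL)
    extra <- core[rows, , drop = FALSE]
    src_name <- nut$nutrient_name[extra$pidx]
    if (kind == "combine") {
      target_frac <- "particulate"
      mult <- stats::runif(length(rows), 0.1, 0.5)
    } else if (kind == "consistent") {
      target_frac <- "unfiltered"
      mult <- stats::runif(length(rows), 1.2, 2.0)
    } else {
      target_frac <- "unfiltered"
      mult <- stats::runif(length(rows), 0.5, 0.99)
    }
    tp <- paste0(src_name, "_", target_frac)
    keep <- tp %in% nut$parameter | kind == "combine"
    extra <- extra[keep, , drop = FALSE]
    if (!nrow(extra)) return(NULL)
    mult <- mult[keep]; src_name <- src_name[keep]; tp <- tp[keep]
    extra$true <- extra$true * mult
    extra$pidx <- ifelse(tp %in% nut$parameter, match(tp, nut$parameter),
                         NA_integer_)
    extra$alt_param <- tp          # for combine pairs outside the table
    extra$nd_exempt <- TRUE
    extra$anomaly <- kind
    extra
  }
  core$alt_param <- NA_character_
  # pair sources must sit alone on their site-date-nutrient so the pair's
  # daily comparison involves exactly the two injected members
  nkey0 <- paste(core$site, as.character(core$date),
                 nut$nutrient_name[core$pidx], sep = "\r")
  singleton <- stats::ave(rep(1L, nrow(core)), nkey0, FUN = sum) == 1L
  filt <- which(core$fault == "none" & singleton &
                  nut$fraction[core$pidx] == "filtered" &
                  nut$nutrient_name[core$pidx] %in%
                    c("total nitrogen", "total phosphorus"))
  u <- stats::runif(length(filt))
  cons <- filt[u < spec$filtered_pair_rate]
  incons <- filt[u >= spec$filtered_pair_rate &
                   u < spec$filtered_pair_rate + spec$inconsistency_rate]
  comb <- filt[u >= spec$filtered_pair_rate + spec$inconsistency_rate &
                 u < spec$filtered_pair_rate + spec$inconsistency_rate +
                   spec$combine_pair_rate]
  core$nd_exempt[c(cons, incons, comb)] <- TRUE
  core$anomaly[cons] <- paste0(core$anomaly[cons], ",filtered_pair")
  core$anomaly[incons] <- paste0(core$anomaly[incons], ",inconsistent_pair")
  core$anomaly[comb] <- paste0(core$anomaly[comb], ",combine_pair")
  core <- rbind(core,
                pair_rows(cons, "consistent"),
                pair_rows(incons, "inconsistent"),
                pair_rows(comb, "combine"))
  n <- nrow(core)
  core$anomaly <- sub("^,", "", core$anomaly)

  ## nutrient identity per row ----------------------------------------
  has_p <- !is.na(core$pidx)
  core$name <- ifelse(has_p, nut$nutrient_name[core$pidx],
                      sub("_[a-z]+$", "", core$alt_param))
  core$fraction <- ifelse(has_p, nut$fraction[core$pidx],
                          sub("^.*_", "", core$alt_param))
  core$param <- ifelse(has_p, nut$parameter[core$pidx], core$alt_param)
  core$basis <- ifelse(grepl("phosph", core$name), "P", "N")
  mu_row <- ifelse(has_p, nut$mu[core$pidx], 0)
  sig_row <- ifelse(has_p, nut$sigma[core$pidx], 1)

  ## censoring ---------------------------------------------------------
  dkey <- paste(sites$org[core$site], core$param, core$year, sep = "\r")
  udk <- unique(dkey)
  if (spec$nd_rate > 0) {
    jit <- exp(stats::runif(length(udk), -0.2, 0.2))
    first_of <- match(udk, dkey)
    dl_of <- stats::qlnorm(spec$nd_rate, mu_row[first_of], sig_row[first_of]) *
      jit^sig_row[first_of]
    names(dl_of) <- udk
    core$dl <- unname(dl_of[dkey])
  } else {
    core$dl <- 0
  }
  core$is_nd <- core$fault == "none" & !core$nd_exempt & core$true < core$dl
  core$dl_missing <- core$is_nd & stats::runif(n) < spec$nd_missing_dl_rate
  core$anomaly[core$is_nd] <- paste0(core$anomaly[core$is_nd],
                                     ifelse(nzchar(core$anomaly[core$is_nd]), ",", ""),
                                     ifelse(core$dl_missing[core$is_nd],
                                            "nd_missing_dl", "nd"))

  ## reporting ---------------------------------------------------------
  ct <- default_config()$conversion_table
  fac_of <- function(f) ct$factor[match(f, ct$reported_form)]
  w <- spec$unit_dialect_weights / sum(spec$unit_dialect_weights)
  dialect <- sample(names(w), n, replace = TRUE, prob = w)
  unit_text <- mapply(function(d, b) gsub("{elem}", b, d, fixed = TRUE),
                      dialect, core$basis, USE.NAMES = FALSE)

  handle <- unname(elem_handle[core$name])
  form_fac <- rep(1, n)
  mol_elig <- core$fault == "none" &
    core$name %in% c("ammonia", "nitrate", "orthophosphate")
  mol <- mol_elig & stats::runif(n) < spec$molecular_report_rate
  amm4 <- mol & core$name == "ammonia" & stats::runif(n) < 0.3
  i <- mol & core$name == "ammonia" & !amm4
  handle[i] <- "Ammonia as NH3"; form_fac[i] <- fac_of("NH3")
  handle[amm4] <- "Ammonium as NH4"; form_fac[amm4] <- fac_of("NH4")
  i <- mol & core$name == "nitrate"
  handle[i] <- "Nitrate"; form_fac[i] <- fac_of("NO3")
  unit_text[i] <- "mg/l as NO3"
  i <- mol & core$name == "orthophosphate"
  handle[i] <- "Orthophosphate as PO4"; form_fac[i] <- fac_of("PO4")
  core$anomaly[mol] <- paste0(core$anomaly[mol],
                              ifelse(nzchar(core$anomaly[mol]), ",", ""),
                              "molecular")
  # molecular handles must not carry contradictory "as N/P" unit text
  strip_as <- mol & core$name %in% c("ammonia", "orthophosphate") &
    grepl(" as ", unit_text)
  unit_text[strip_as] <- sub(" as .*$", "", unit_text[strip_as])

  i <- core$fault == "form"
  handle[i] <- unname(starred_handle[core$name[i]])
  unit_text[i] <- sub(" as .*$", "", unit_text[i])
  bad_units <- c("%", "mg/kg", "none", "ntu", "% recovery", "umol/l")
  i <- core$fault == "unit"
  unit_text[i] <- sample(bad_units, sum(i), replace = TRUE)

  ufac <- rep(1, n)
  ufac[startsWith(unit_text, "ug/l")] <- 0.001
  ufac[core$fault == "unit"] <- 1
  rep_mult <- 1 / (form_fac * ufac)

  method <- rep(NA_character_, n)
  starred_elem <- handle == "Phosphorus" & core$fault != "form" &
    !grepl(" as ", unit_text)
  method[starred_elem] <- "365.1"

  ## assemble raw fields ----------------------------------------------
  conc_txt <- sprintf("%.15g", core$true * rep_mult)
  i <- core$fault == "conc"
  conc_txt[i] <- sample(c("n/a", "--", "-0.5", "0"), sum(i), replace = TRUE)
  nd_style <- sample(c("zero", "negative", "missing"), n, replace = TRUE)
  i <- core$is_nd & nd_style == "zero"; conc_txt[i] <- "0"
  i <- core$is_nd & nd_style == "negative"
  conc_txt[i] <- sprintf("%.15g", -core$dl[i] * rep_mult[i])
  i <- core$is_nd & nd_style == "missing"; conc_txt[i] <- ""

  dl_code <- rep(NA_character_, n)
  dl_text <- rep(NA_character_, n)
  nd_tokens <- c("U", "ND", "BDL")
  use_text <- stats::runif(n) < 0.3
  i <- core$is_nd & !use_text
  dl_code[i] <- sample(nd_tokens, sum(i), replace = TRUE)
  i <- core$is_nd & use_text
  dl_text[i] <- "Not Detected"
  i <- core$fault == "contaminated"
  dl_code[i] <- "Contaminated"

  dl_val <- rep(NA_real_, n)
  dl_units <- rep(NA_character_, n)
  i <- core$is_nd & !core$dl_missing
  dl_val[i] <- core$dl[i] * rep_mult[i]
  dl_units[i] <- unit_text[i]

  media <- rep("Water", n)
  i <- core$fault == "media"
  media[i] <- sample(c("Soil", "Air", "Sediment"), sum(i), replace = TRUE)
  date_txt <- format(core$date, "%Y-%m-%d")
  date_txt[core$fault == "date"] <- ""
  activity <- rep("Sample-Routine", n)
  i <- core$fault == "qc"
  activity[i] <- sample(c("Quality Control Sample-Field Blank",
                          "Quality Control Sample-Lab Duplicate",
                          "Quality Control-Calibration Check"),
                        sum(i), replace = TRUE)
  result_type <- rep("Actual", n)
  i <- core$fault == "estimated"
  result_type[i] <- sample(c("Approximation", "Educated Guess"),
                           sum(i), replace = TRUE)
  frac_syn <- list(filtered = c("filtered", "dissolved"),
                   unfiltered = c("unfiltered", "total"),
                   particulate = c("particulate", "suspended"))
  frac_txt <- vapply(core$fraction,
                     function(f) sample(frac_syn[[f]], 1L), character(1))
  i <- core$fault == "fraction"
  frac_txt[i] <- sample(c("bed sediment", "unknown", ""), sum(i),
                        replace = TRUE)

  use_alt_coord <- sites$dup_coord[core$site] & stats::runif(n) < 0.5
  use_alt_mli <- sites$dup_mli[core$site] & stats::runif(n) < 0.5
  mli <- ifelse(use_alt_mli, sites$alt_mli[core$site], sites$mli[core$site])
  x <- ifelse(use_alt_coord, sites$x2[core$site], sites$x[core$site])
  y <- ifelse(use_alt_coord, sites$y2[core$site], sites$y[core$site])

  org_canon <- sites$org[core$site]
  core$org_rep <- org_canon                    # canonical org after step 1
  alias <- stats::runif(n) < spec$org_alias_rate
  org_txt <- org_canon
  org_txt[alias] <- vapply(org_canon[alias], variant_of, character(1))
  core$anomaly[alias] <- paste0(core$anomaly[alias],
                                ifelse(nzchar(core$anomaly[alias]), ",", ""),
                                "alias")

  raw <- data.frame(
    org_name_raw = org_txt,
    st_abbr = states$st_abbr[sites$st[core$site]],
    st_name = states$st_name[sites$st[core$site]],
    orig_MLI = mli,
    orig_x = x,
    orig_y = y,
    date = date_txt,
    time = core$time,
    media = media,
    activity_type = activity,
    result_type = result_type,
    nutrient_handle = handle,
    analytical_method = method,
    sample_fraction_raw = frac_txt,
    orig_conc = conc_txt,
    orig_conc_units = unit_text,
    DL_code = dl_code,
    DL_text = dl_text,
    orig_DL_val = dl_val,
    orig_DL_units = dl_units,
    provider = sample(c("NWIS", "STORET", "STEWARDS"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## verbatim cross-organization duplicates ---------------------------
  if (spec$n_orgs > 1L && spec$cross_org_dup_rate > 0) {
    xd <- which(core$fault == "none" & !core$is_nd &
                  stats::runif(n) < spec$cross_org_dup_rate)
    if (length(xd)) {
      other <- vapply(org_canon[xd],
                      function(o) sample(setdiff(orgs, o), 1L), character(1))
      raw2 <- raw[xd, , drop = FALSE]
      raw2$org_name_raw <- other
      core2 <- core[xd, , drop = FALSE]
      core2$org_rep <- other
      core2$anomaly <- "cross_org_dup"
      core$anomaly[xd] <- paste0(core$anomaly[xd],
                                 ifelse(nzchar(core$anomaly[xd]), ",", ""),
                                 "cross_org_dup")
      raw <- rbind(raw, raw2)
      core <- rbind(core, core2)
      n <- nrow(core)
    }
  }
  rownames(raw) <- rownames(core) <- NULL
  raw$record_id <- seq_len(n) - 1L

  ## expected fates ----------------------------------------------------
  fate <- ifelse(core$fault == "none", "kept",
                 paste0("dropped_step", fault_step[core$fault]))
  surv <- core$fault == "none"

  # non-detects: imputed / left-NA / no assignable detection limit
  if (any(core$is_nd)) {
    gkey <- paste(core$site, core$param, core$year, sep = "\r")
    nd_n <- stats::ave(as.numeric(core$is_nd & surv), gkey, FUN = sum)
    all_n <- stats::ave(as.numeric(surv), gkey, FUN = sum)
    share <- nd_n / pmax(all_n, 1)
    pykey <- paste(core$param, core$year, sep = "\r")
    approximable <- logical(n)
    for (k in unique(pykey[core$dl_missing])) {
      ink <- pykey == k & surv
      qual <- unique(core$org_rep[ink & core$dl_missing])
      approximable[ink] <- any(ink & !core$is_nd & core$org_rep %in% qual)
    }
    nd <- which(core$is_nd)
    fate[nd] <- ifelse(core$dl_missing[nd] & !approximable[nd],
                       "dropped_step14",
                       ifelse(share[nd] >= 0.8, "kept", "imputed"))
  }

  # filtered/unfiltered daily consistency, mirrored on true values over
  # every site-date-nutrient carrying both fractions (these only arise
  # from injected pairs, whose members are never censored)
  val <- surv & !core$is_nd
  if (any(val)) {
    fkey <- paste(core$site, as.character(core$date), core$name, sep = "\r")
    both <- intersect(fkey[val & core$fraction == "filtered"],
                      fkey[val & core$fraction == "unfiltered"])
    for (k in both) {
      rows <- which(fkey == k & surv)
      if (any(core$is_nd[rows])) next
      fr <- rows[core$fraction[rows] == "filtered"]
      ur <- rows[core$fraction[rows] == "unfiltered"]
      if (!length(fr) || !length(ur)) next
      if (mean(unique(core$true[fr])) >= mean(unique(core$true[ur])))
        fate[c(fr, ur)] <- "dropped_step19"
    }
  }

  # combination sources (only where the target is genuinely absent)
  sdkey <- paste(core$site, as.character(core$date), sep = "\r")
  for (r in which(grepl("combine", core$anomaly) & fate == "kept")) {
    target <- paste0(core$name[r], "_unfiltered")
    clash <- any(surv & sdkey == sdkey[r] & core$param == target)
    if (!clash) fate[r] <- "combined_source"
  }

  # daily averaging: more than one value member in the daily group
  akey <- paste(core$site, as.character(core$date), core$param, sep = "\r")
  val_now <- (fate %in% c("kept", "combined_source") & !core$is_nd) |
    fate == "imputed"
  sig <- paste(akey, core$time, raw$orig_conc, sep = "\r")
  nsig <- stats::ave(as.numeric(!duplicated(sig) & val_now), akey,
                     FUN = sum)
  avg <- val_now & nsig > 1 & fate == "kept" & !core$is_nd
  fate[avg] <- "averaged"

  truth <- data.frame(
    record_id = raw$record_id,
    true_conc_mgL = core$true,
    latent_site = sites$mli[core$site],
    expected_fate = fate,
    injected_anomaly = ifelse(nzchar(core$anomaly), core$anomaly, "none"),
    stringsAsFactors = FALSE
  )
  list(raw = raw, truth = truth)
}
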