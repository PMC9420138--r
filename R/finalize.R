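# Outlier flagging, daily duplicate resolution, sample-fraction
# combination into total nutrients, and the filtered-vs-unfiltered
# consistency check.

#' Flag percentile outliers
#'
#' Flags concentrations below the lower or above the upper percentile of
#' their nutrient parameter, pooled across all years. Percentiles use
#' linear interpolation between order statistics
#' (\code{stats::quantile}, type 7). Groups with fewer than three non-missing
#' values have degenerate thresholds and are left unflagged. Missing
#' concentrations get an NA flag.
#'
#' @param records Data frame with columns \code{conc} and
#'   \code{nutrient_parameter}.
#' @param lower_pct,upper_pct Percentile bounds (defaults 1 and 99).
#' @return A data frame with columns \code{outlier_flag}, \code{pct1},
#'   \code{pct99} aligned with \code{records}.
#' @export
flag_outliers <- function(records, lower_pct = 1, upper_pct = 99) {
  n <- nrow(records)
  flag <- rep(NA_character_, n)
  p_lo <- rep(NA_real_, n)
  p_hi <- rep(NA_real_, n)
  for (rows in split(seq_len(n), records$nutrient_parameter)) {
    v <- records$conc[rows]
    ok <- !is.na(v)
    if (sum(ok) >= 3L) {
      q <- stats::quantile(v[ok], c(lower_pct, upper_pct) / 100,
                           type = 7, names = FALSE)
      p_lo[rows] <- q[1L]
      p_hi[rows] <- q[2L]
      flag[rows][ok] <- ifelse(v[ok] < q[1L] | v[ok] > q[2L],
                               "potential_outlier", "not_flagged_as_outlier")
    } else {
      flag[rows][ok] <- "not_flagged_as_outlier"
    }
  }
  data.frame(outlier_flag = flag, pct1 = p_lo, pct99 = p_hi,
             stringsAsFactors = FALSE)
}

#' Resolve duplicate observations to the daily level
#'
#' Groups records by (site, date, nutrient parameter) and, within each
#' group: collapses exact duplicates reported by different organizations to
#' a single record under the lexicographically first canonical organization
#' name; averages detected and imputed concentrations (arithmetic mean,
#' sub-daily values included whether or not they carry a timestamp) into
#' one daily value; and counts the duplicate structure. A daily average
#' that includes an imputed member is flagged \code{"imputed"}. Groups
#' whose members are all unimputed non-detects yield one row with a
#' missing concentration.
#'
#' @param records Data frame of surviving records with columns
#'   \code{record_id}, \code{new_MLI}, \code{new_x}, \code{new_y},
#'   \code{date}, \code{time}, \code{year}, \code{org_name},
#'   \code{st_abbr}, \code{st_name}, \code{media},
#'   \code{nutrient_parameter}, \code{nutrient_name},
#'   \code{sample_fraction}, \code{N_or_P}, \code{conc}, \code{status}
#'   (\code{"detected"}, \code{"imputed"} or \code{"nd_na"}), \code{DL} and
#'   \code{outlier_flag}.
#' @return A list: \code{daily}, one row per (site, date, nutrient
#'   parameter); \code{per_record}, the duplicate-structure counts
#'   (\code{num_obs_per_date}, \code{num_orgs_per_obs},
#'   \code{num_nds_per_obs}, \code{num_conc_per_time}) for every input
#'   record.
#' @export
resolve_duplicates <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    daily <- data.frame(
      media = character(0), st_abbr = character(0), st_name = character(0),
      org_name = character(0), N_or_P = character(0),
      nutrient_name = character(0), sample_fraction = character(0),
      nutrient_parameter = character(0), year = integer(0),
      date = as.Date(character(0)), MLI = character(0), conc = numeric(0),
      outlier_flag = character(0), num_obs_per_date = integer(0),
      impute_flag = character(0), DL = numeric(0), x = numeric(0),
      y = numeric(0), stringsAsFactors = FALSE)
    per_rec <- data.frame(record_id = integer(0),
                          num_obs_per_date = integer(0),
                          num_orgs_per_obs = integer(0),
                          num_nds_per_obs = integer(0),
                          num_conc_per_time = integer(0))
    return(list(daily = daily, per_record = per_rec))
  }
  time_tok <- ifelse(is_blank(records$time), "", as.character(records$time))
  key <- paste(records$new_MLI, records$date, records$nutrient_parameter,
               sep = "\r")
  tkey <- paste(key, time_tok, sep = "\r")
  conc_tok <- ifelse(is.na(records$conc), "", format(records$conc, digits = 15))
  dup_key <- paste(tkey, records$status, conc_tok, sep = "\r")

  num_conc_per_time <- stats::ave(seq_len(n), tkey, FUN = length)
  norgs_by_dup <- tapply(records$org_name, dup_key,
                         function(o) length(unique(o)))
  num_orgs_per_obs <- as.integer(norgs_by_dup[dup_key])

  per_rec <- data.frame(record_id = records$record_id,
                        num_obs_per_date = NA_integer_,
                        num_orgs_per_obs = num_orgs_per_obs,
                        num_nds_per_obs = NA_integer_,
                        num_conc_per_time = as.integer(num_conc_per_time))
  ord <- order(records$new_MLI, as.character(records$date),
               records$nutrient_parameter, records$record_id)
  grp <- split(ord, key[ord])
  ng <- length(grp)
  first_i <- integer(ng); conc_v <- numeric(ng); nobs_v <- integer(ng)
  flag_v <- character(ng); dl_v <- numeric(ng); out_v <- character(ng)
  org_v <- character(ng)
  for (g in seq_len(ng)) {
    rows <- grp[[g]]
    # cross-organization exact duplicates collapse to one member
    reps <- rows[!duplicated(dup_key[rows])]
    member_conc <- records$conc[reps]
    member_status <- records$status[reps]
    has_val <- !is.na(member_conc)
    n_obs <- if (any(has_val)) sum(has_val) else length(reps)
    per_rec$num_obs_per_date[rows] <- n_obs
    per_rec$num_nds_per_obs[rows] <- length(unique(member_status == "detected"))

    conc <- if (any(has_val)) mean(member_conc[has_val]) else NA_real_
    impute_flag <- if (any(member_status == "imputed" & has_val)) "imputed"
      else if (any(member_status == "detected")) "detected"
      else "imputed"                           # all unimputed non-detects
    dl <- NA_real_
    if (impute_flag == "imputed") {
      dls <- records$DL[reps][member_status != "detected"]
      if (any(!is.na(dls))) dl <- max(dls, na.rm = TRUE)
    }
    out_flags <- records$outlier_flag[reps]
    first_i[g] <- rows[1L]
    conc_v[g] <- conc
    nobs_v[g] <- n_obs
    flag_v[g] <- impute_flag
    dl_v[g] <- dl
    org_v[g] <- min(records$org_name[rows])
    out_v[g] <- if (is.na(conc)) NA_character_
      else if (any(!is.na(out_flags) & out_flags == "potential_outlier"))
        "potential_outlier"
      else "not_flagged_as_outlier"
  }
  daily <- data.frame(
    media = records$media[first_i],
    st_abbr = records$st_abbr[first_i],
    st_name = records$st_name[first_i],
    org_name = org_v,
    N_or_P = records$N_or_P[first_i],
    nutrient_name = records$nutrient_name[first_i],
    sample_fraction = records$sample_fraction[first_i],
    nutrient_parameter = records$nutrient_parameter[first_i],
    year = records$year[first_i],
    date = records$date[first_i],
    MLI = records$new_MLI[first_i],
    conc = conc_v,
    outlier_flag = out_v,
    num_obs_per_date = nobs_v,
    impute_flag = flag_v,
    DL = dl_v,
    x = records$new_x[first_i],
    y = records$new_y[first_i],
    stringsAsFactors = FALSE
  )
  rownames(daily) <- NULL
  list(daily = daily, per_record = per_rec)
}

#' Combine sample fractions into total nutrients
#'
#' For each site-date where both components of a combination rule are
#' present with concentrations and the target parameter is absent, adds a
#' new observation whose concentration is the sum of the components,
#' flagged \code{"calculated_by_combining"}. Default rules sum filtered and
#' particulate total nitrogen into unfiltered total nitrogen, and likewise
#' for total phosphorus.
#'
#' @param daily Daily records from \code{\link{resolve_duplicates}}.
#' @param rules Combination rules (see \code{\link{default_config}}).
#' @return \code{daily} with the combined rows appended.
#' @export
combine_fractions <- function(daily,
                              rules = default_config()$combination_rules) {
  sd_key <- paste(daily$MLI, daily$date, sep = "\r")
  new_rows <- list()
  for (k in unique(sd_key)) {
    rows <- which(sd_key == k)
    pars <- daily$nutrient_parameter[rows]
    for (j in seq_len(nrow(rules))) {
      ia <- rows[match(rules$component_a[j], pars)]
      ib <- rows[match(rules$component_b[j], pars)]
      if (is.na(ia) || is.na(ib) || rules$target[j] %in% pars) next
      if (is.na(daily$conc[ia]) || is.na(daily$conc[ib])) next
      row <- daily[ia, , drop = FALSE]
      parts <- strsplit(rules$target[j], "_", fixed = TRUE)[[1L]]
      row$nutrient_parameter <- rules$target[j]
      row$nutrient_name <- parts[1L]
      row$sample_fraction <- parts[2L]
      row$conc <- daily$conc[ia] + daily$conc[ib]
      row$impute_flag <- "calculated_by_combining"
      row$outlier_flag <- "not_flagged_as_outlier"
      row$num_obs_per_date <- 1L
      row$DL <- NA_real_
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }
  if (length(new_rows)) daily <- rbind(daily, do.call(rbind, new_rows))
  rownames(daily) <- NULL
  daily
}

#' Filtered-versus-unfiltered consistency check
#'
#' For each site-date-nutrient where both a filtered and an unfiltered
#' daily concentration exist: a filtered concentration greater than or
#' equal to the unfiltered one is physically inconsistent (the filtered
#' fraction is a subset of the whole sample), so both rows are flagged
#' \code{"unfilt conc <= filt conc"} and excluded from the harmonized
#' output; consistent pairs are flagged \code{"keep"}. Rows without a
#' comparable counterpart get an NA flag and are kept.
#'
#' @param daily Daily records (after combination).
#' @return \code{daily} with a \code{filt2unfilt_flag} column added.
#' @export
qc_filtered_vs_unfiltered <- function(daily) {
  flag <- rep(NA_character_, nrow(daily))
  key <- paste(daily$MLI, daily$date, daily$nutrient_name, sep = "\r")
  for (rows in split(seq_len(nrow(daily)), key)) {
    f <- rows[daily$sample_fraction[rows] == "filtered"]
    u <- rows[daily$sample_fraction[rows] == "unfiltered"]
    f <- f[!is.na(daily$conc[f])]
    u <- u[!is.na(daily$conc[u])]
    if (length(f) == 0L || length(u) == 0L) next
    if (min(daily$conc[f]) >= max(daily$conc[u])) {
      flag[c(f, u)] <- "unfilt conc <= filt conc"
    } else {
      flag[c(f, u)] <- "keep"
    }
  }
  daily$filt2unfilt_flag <- flag
  daily
}
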