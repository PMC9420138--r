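# End-to-end orchestration: org standardization -> site resolution ->
# filter cascade -> chemical/unit normalization -> non-detect handling ->
# imputation -> outlier flagging -> daily duplicate resolution -> fraction
# combination -> filtered/unfiltered QC -> assembly of the two outputs.

#' Run the full harmonization pipeline
#'
#' Executes every harmonization step on a raw result-level table and
#' assembles the two outputs: the harmonized daily dataset (surviving rows
#' only, one per site-date-nutrient-parameter) and the flagged audit
#' dataset (every raw row with per-step keep/drop/NA flags). All
#' randomness (the imputation sampler) is funneled through one generator
#' seeded from \code{config$rng_seed}, so a fixed input and configuration
#' give byte-identical outputs.
#'
#' @param raw A raw record data frame (see \code{\link{read_raw_table}})
#'   or a path to a raw CSV.
#' @param config A \code{wq_config}.
#' @param out_dir Optional directory; when given, \code{snapd.csv},
#'   \code{flagged.csv}, report tables and a run log are written there.
#' @return An object of class \code{wq_harmonization}: a list with
#'   \code{harmonized}, \code{flagged}, \code{log} (per-step affected-row
#'   counts), \code{report} and \code{config}.
#' @export
run_pipeline <- function(raw, config = default_config(), out_dir = NULL) {
  if (is.character(raw)) raw <- read_raw_table(raw)
  if (is.null(raw$record_id)) raw$record_id <- seq_len(nrow(raw)) - 1L
  n <- nrow(raw)
  set.seed(config$rng_seed)
  log <- list(step0_raw = n)

  ## Step 1: organization names (never drops)
  rec <- raw
  rec$org_name <- standardize_org_name(rec$org_name_raw, config$org_alias_table)
  log$step1_org_standardized <- sum(rec$org_name != squish(rec$org_name_raw),
                                    na.rm = TRUE)

  ## Step 2: unique monitoring sites
  rec <- resolve_sites(rec, config$coord_merge_threshold_m)
  log$step2_multiple_coords <- sum(rec$dup_coords_flag == "dup_coords",
                                   na.rm = TRUE)
  log$step2_multiple_mlis <- sum(rec$dup_MLI_flag == "dup_MLI", na.rm = TRUE)

  ## Steps 3-11: filter cascade
  rec <- apply_filter_cascade(rec, config)
  for (s in 3:11) {
    log[[sprintf("step%d_dropped", s)]] <- sum(rec$.drop_step == s)
  }

  ## Steps 12-13: conversions and nutrient renaming
  surv <- rec$.drop_step == 0L
  voc <- config$nutrient_vocabulary
  vi <- match(norm_handle(rec$nutrient_handle), voc$raw_handle)
  rec$N_or_P <- voc$N_or_P[vi]
  ct <- config$conversion_table
  ff <- ifelse(rec$.form == "elemental", 1,
               ct$factor[match(rec$.form, ct$reported_form)])
  conc_num <- parse_number(rec$orig_conc)
  uf <- unit_factor(rec$orig_conc_units, config$unit_registry)
  detected <- surv & rec$ND_flag == "keep"
  is_nd <- surv & rec$ND_flag == "ND"
  rec$new_conc <- ifelse(detected, conc_num * uf * ff, NA_real_)
  dl_uf <- unit_factor(rec$orig_DL_units, config$unit_registry)
  dl_uf[is.na(rec$orig_DL_units)] <- 1    # unitless DL assumed mg/L
  new_dl <- rec$orig_DL_val * dl_uf * ff
  new_dl[!is.na(new_dl) & new_dl <= 0] <- NA_real_
  rec$new_DL <- ifelse(is_nd, new_dl, NA_real_)
  rec$new_conc_units <- ifelse(surv, paste("mg/L as", rec$N_or_P),
                               NA_character_)
  rec$new_DL_units <- ifelse(is_nd & !is.na(rec$new_DL),
                             paste("mg/L as", rec$N_or_P), NA_character_)
  log$step12_converted <- sum(surv)

  named <- harmonize_nutrient_name(
    voc$nutrient_name[vi[surv]], rec$.fraction[surv])
  rec$nutrient_name <- rec$sample_fraction <- rec$nutrient_parameter <-
    NA_character_
  rec$nutrient_name[surv] <- named$nutrient_name
  rec$sample_fraction[surv] <- named$sample_fraction
  rec$nutrient_parameter[surv] <- named$nutrient_parameter
  log$step13_renamed <- sum(surv)

  rec$.date <- parse_date(rec$date)
  rec$year <- as.integer(format(rec$.date, "%Y"))

  ## Step 14: detection limit approximation
  sub <- rec[surv, , drop = FALSE]
  sub <- approximate_detection_limits(sub)
  rec$new_DL[surv] <- sub$new_DL
  rec$new_DL_units[surv] <- ifelse(
    !is.na(sub$new_DL), paste("mg/L as", sub$N_or_P), NA_character_)
  log$step14_dl_approximated <- sum(sub$.dl_approximated)
  dl_unassignable <- surv & rec$ND_flag == "ND" & is.na(rec$new_DL)
  log$step14_dl_unassignable <- sum(dl_unassignable)
  if (any(dl_unassignable))
    warnf("%d non-detect(s) have no assignable detection limit and are excluded from imputation",
          sum(dl_unassignable))

  ## Step 15: imputation per (site, nutrient parameter, year)
  rec$pct_ND <- NA_real_
  rec$impute_flag <- NA_character_
  rec$.conc_final <- rec$new_conc
  rec$.status <- NA_character_
  rec$.status[detected] <- "detected"
  rec$.status[is_nd] <- "nd_na"
  gkey <- paste(rec$new_MLI, rec$nutrient_parameter, rec$year, sep = "\r")
  n_imp <- 0L; n_left_na <- 0L
  groups <- split(which(surv), gkey[surv])
  for (rows in groups[order(names(groups))]) {
    nd_rows <- rows[rec$ND_flag[rows] == "ND"]
    obs_rows <- rows[rec$ND_flag[rows] == "keep"]
    pct <- 100 * length(nd_rows) / length(rows)
    rec$pct_ND[rows] <- pct
    imp_rows <- nd_rows[!is.na(rec$new_DL[nd_rows])]
    if (length(nd_rows) && pct < 100 * config$nd_impute_max_share &&
        length(imp_rows)) {
      # the group-level cutoff is decided here on the full group share,
      # so the sampler is told to impute unconditionally
      res <- impute_censored(rec$new_conc[obs_rows], rec$new_DL[imp_rows],
                             max_share = 1, K = config$n_imputations,
                             burn_in = config$burn_in, thin = config$thin)
      rec$.conc_final[imp_rows] <- res$imputed
      rec$new_conc[imp_rows] <- res$imputed    # audit trail of imputed values
      rec$.status[imp_rows] <- "imputed"
      rec$impute_flag[rows] <- "impute"
      n_imp <- n_imp + length(imp_rows)
    } else {
      rec$impute_flag[rows] <- "dont_impute"
      n_left_na <- n_left_na + length(nd_rows)
    }
  }
  log$step15_imputed <- n_imp
  log$step15_left_na <- n_left_na

  ## working table of records that can appear in the harmonized output
  keep_out <- surv & !dl_unassignable
  wrk <- data.frame(
    record_id = rec$record_id[keep_out],
    new_MLI = rec$new_MLI[keep_out],
    new_x = rec$new_x[keep_out],
    new_y = rec$new_y[keep_out],
    date = rec$.date[keep_out],
    time = rec$time[keep_out],
    year = rec$year[keep_out],
    org_name = rec$org_name[keep_out],
    st_abbr = rec$st_abbr[keep_out],
    st_name = rec$st_name[keep_out],
    media = rep("water", sum(keep_out)),
    nutrient_parameter = rec$nutrient_parameter[keep_out],
    nutrient_name = rec$nutrient_name[keep_out],
    sample_fraction = rec$sample_fraction[keep_out],
    N_or_P = rec$N_or_P[keep_out],
    conc = rec$.conc_final[keep_out],
    status = rec$.status[keep_out],
    DL = rec$new_DL[keep_out],
    stringsAsFactors = FALSE
  )

  ## Step 16: outlier flagging (pre-averaging values, pooled years)
  ofl <- flag_outliers(wrk, config$outlier_lower_pct, config$outlier_upper_pct)
  wrk$outlier_flag <- ofl$outlier_flag
  rec$outlier_flag <- rec$pct1 <- rec$pct99 <- NA
  rec$outlier_flag[keep_out] <- ofl$outlier_flag
  rec$pct1[keep_out] <- ofl$pct1
  rec$pct99[keep_out] <- ofl$pct99
  log$step16_outliers_flagged <-
    sum(ofl$outlier_flag == "potential_outlier", na.rm = TRUE)

  ## Step 17: duplicates to the daily level
  dup <- resolve_duplicates(wrk)
  daily <- dup$daily
  per_rec <- dup$per_record
  rec$num_obs_per_date <- rec$num_orgs_per_obs <- rec$num_nds_per_obs <-
    rec$num_conc_per_time <- NA_integer_
  pi <- match(rec$record_id, per_rec$record_id)
  rec$num_obs_per_date <- per_rec$num_obs_per_date[pi]
  rec$num_orgs_per_obs <- per_rec$num_orgs_per_obs[pi]
  rec$num_nds_per_obs <- per_rec$num_nds_per_obs[pi]
  rec$num_conc_per_time <- per_rec$num_conc_per_time[pi]
  log$step17_in_daily_averages <- sum(per_rec$num_obs_per_date > 1,
                                      na.rm = TRUE)
  log$step17_cross_org_duplicates <- sum(per_rec$num_orgs_per_obs > 1,
                                         na.rm = TRUE)
  log$step17_mixed_detection_status <- sum(per_rec$num_nds_per_obs > 1,
                                           na.rm = TRUE)

  ## Step 18: combine sample fractions into total nutrients
  n_before <- nrow(daily)
  daily <- combine_fractions(daily, config$combination_rules)
  log$step18_combined_added <- nrow(daily) - n_before

  ## Step 19: filtered vs unfiltered consistency
  daily <- qc_filtered_vs_unfiltered(daily)
  bad19 <- !is.na(daily$filt2unfilt_flag) &
    daily$filt2unfilt_flag == "unfilt conc <= filt conc"
  log$step19_dropped <- sum(bad19)
  f19 <- match(paste(rec$new_MLI, rec$.date, rec$nutrient_parameter, sep = "\r"),
               paste(daily$MLI, daily$date, daily$nutrient_parameter, sep = "\r"))
  rec$filt2unfilt_flag <- daily$filt2unfilt_flag[f19]
  rec$filt2unfilt_flag[!keep_out] <- NA_character_

  ## assemble outputs
  harmonized <- daily[!bad19, , drop = FALSE]
  harmonized$conc_units <- if (nrow(harmonized))
    paste("mg/L as", harmonized$N_or_P) else character(0)
  harmonized$DL_units <- ifelse(is.na(harmonized$DL), NA_character_,
                                paste("mg/L as", harmonized$N_or_P))
  rownames(harmonized) <- NULL
  harmonized <- harmonized[snapd_columns]

  flagged <- assemble_flagged(rec)
  result <- structure(
    list(harmonized = harmonized, flagged = flagged, log = log,
         config = config),
    class = "wq_harmonization"
  )
  result$report <- harmonization_report(result)
  if (!is.null(out_dir)) {
    write_outputs(harmonized, flagged, out_dir, n_raw = n)
    write_report(result, out_dir)
  }
  result
}

assemble_flagged <- function(rec) {
  out <- rec
  out$date <- ifelse(is.na(out$.date), NA_character_,
                     format(out$.date, "%Y-%m-%d"))
  out[flagged_columns]
}

write_report <- function(result, dir) {
  rep <- result$report
  utils::write.csv(rep$unit_flows, file.path(dir, "report_unit_flows.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(rep$org_summary, file.path(dir, "report_org_summary.csv"),
                   row.names = FALSE, na = "")
  con <- file(file.path(dir, "run_log.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    "Harmonization run log",
    sprintf("  %-32s %d", names(result$log), unlist(result$log)),
    sprintf("  standardized fraction (N): %.1f%%",
            rep$standardized_pct[["N"]]),
    sprintf("  standardized fraction (P): %.1f%%",
            rep$standardized_pct[["P"]])
  ), con)
  invisible(dir)
}

#' Summarize a harmonization run
#'
#' Builds the validation report: (a) the flow from each raw concentration
#' unit to its harmonized unit (or to "dropped") per nutrient basis, i.e.
#' the input of a Sankey diagram; (b) per-organization summary statistics
#' of log concentrations for total nitrogen and total phosphorus, before
#' and after harmonization; (c) the fraction of observations standardized
#' per basis; (d) the per-step counts of the run log.
#'
#' @param result A \code{wq_harmonization} object from
#'   \code{\link{run_pipeline}}.
#' @return An object of class \code{wq_report}.
#' @export
harmonization_report <- function(result) {
  flagged <- result$flagged
  harmonized <- result$harmonized

  unit <- norm_text(flagged$orig_conc_units)
  unit[is.na(unit)] <- "(missing)"
  outcome <- ifelse(is.na(flagged$new_conc_units), "dropped",
                    flagged$new_conc_units)
  basis <- ifelse(is.na(flagged$N_or_P), "(unknown)", flagged$N_or_P)
  flows <- as.data.frame(table(basis = basis, raw_unit = unit,
                               outcome = outcome),
                         responseName = "n", stringsAsFactors = FALSE)
  flows <- flows[flows$n > 0, , drop = FALSE]
  flows <- flows[order(flows$basis, -flows$n), , drop = FALSE]
  rownames(flows) <- NULL

  standardized_pct <- vapply(c(N = "N", P = "P"), function(b) {
    rows <- !is.na(flagged$N_or_P) & flagged$N_or_P == b
    if (!any(rows)) return(NA_real_)
    100 * sum(!is.na(flagged$new_conc_units[rows])) / sum(rows)
  }, numeric(1))

  org_summary <- do.call(rbind, lapply(
    c("total nitrogen", "total phosphorus"), function(nm) {
      pre_rows <- !is.na(flagged$nutrient_parameter) &
        startsWith(flagged$nutrient_parameter, nm)
      pre <- parse_number(flagged$orig_conc[pre_rows])
      pre_org <- flagged$org_name[pre_rows]
      post_rows <- harmonized$nutrient_name == nm & !is.na(harmonized$conc) &
        harmonized$conc > 0
      stat <- function(v, org, stage) {
        ok <- !is.na(v) & v > 0
        if (!any(ok)) return(NULL)
        lv <- split(log(v[ok]), org[ok])
        data.frame(nutrient = nm, stage = stage, org_name = names(lv),
                   n = lengths(lv),
                   mean_log = vapply(lv, mean, numeric(1)),
                   sd_log = vapply(lv, stats::sd, numeric(1)),
                   stringsAsFactors = FALSE)
      }
      rbind(stat(pre, pre_org, "pre"),
            stat(harmonized$conc[post_rows], harmonized$org_name[post_rows],
                 "post"))
    }))
  rownames(org_summary) <- NULL

  structure(list(unit_flows = flows, org_summary = org_summary,
                 standardized_pct = standardized_pct,
                 step_counts = result$log),
            class = "wq_report")
}

#' @export
print.wq_harmonization <- function(x, ...) {
  cat("Water-quality harmonization run\n")
  cat(sprintf("  raw records:        %d\n", x$log$step0_raw))
  cat(sprintf("  harmonized records: %d\n", nrow(x$harmonized)))
  drops <- unlist(x$log[grep("^step([3-9]|1[01])_dropped", names(x$log))])
  cat(sprintf("  cascade drops:      %d\n", sum(drops)))
  cat(sprintf("  imputed non-detects: %d (left missing: %d)\n",
              x$log$step15_imputed, x$log$step15_left_na))
  cat(sprintf("  combined observations added: %d\n",
              x$log$step18_combined_added))
  cat(sprintf("  inconsistent filtered/unfiltered daily pairs dropped: %d\n",
              x$log$step19_dropped))
  invisible(x)
}

#' @export
print.wq_report <- function(x, ...) {
  cat("Harmonization report\n")
  cat(sprintf("  standardized: N %.1f%%, P %.1f%%\n",
              x$standardized_pct[["N"]], x$standardized_pct[["P"]]))
  cat(sprintf("  unit flows (top rows):\n"))
  print(utils::head(x$unit_flows, 8))
  invisible(x)
}
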