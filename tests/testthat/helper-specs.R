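# Shared generator-spec helpers: a fully clean spec (no corruption, no
# censoring, one unit dialect) and single-fault variants.

zero_rates <- list(
  nd_rate = 0, nd_missing_dl_rate = 0, dup_coord_rate = 0, dup_mli_rate = 0,
  sub_daily_dup_rate = 0, cross_org_dup_rate = 0,
  unit_dialect_weights = c("mg/l as {elem}" = 1),
  molecular_report_rate = 0, unknown_form_rate = 0, bad_conc_rate = 0,
  bad_unit_rate = 0, contaminated_rate = 0, bad_fraction_rate = 0,
  qc_activity_rate = 0, estimated_result_rate = 0, bad_media_rate = 0,
  missing_date_rate = 0, org_alias_rate = 0, filtered_pair_rate = 0,
  inconsistency_rate = 0, combine_pair_rate = 0
)

clean_spec <- function(seed = 1L, ...) {
  do.call(generator_spec, utils::modifyList(c(zero_rates, seed = seed),
                                            list(...)))
}

fault_spec <- function(which, rate = 0.3, seed = 1L, ...) {
  args <- zero_rates
  args[[which]] <- rate
  args$seed <- seed
  do.call(generator_spec, utils::modifyList(args, list(...)))
}

run_quiet <- function(raw, ...) suppressWarnings(run_pipeline(raw, ...))

# record ids the pipeline excluded from the harmonized output
dropped_ids <- function(result) {
  fl <- result$flagged
  h <- result$harmonized
  hk <- paste(h$MLI, h$date, h$nutrient_parameter)
  fk <- paste(fl$new_MLI, fl$date, fl$nutrient_parameter)
  sort(fl$record_id[is.na(fl$nutrient_parameter) | !(fk %in% hk)])
}
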