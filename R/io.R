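# Reading WQP-style raw tables and writing the two output schemas with
# exact column vocabularies. CSV throughout: UTF-8, comma-delimited,
# RFC-4180 quoting. Missing values are empty strings, except in flag
# columns where the literal string "NA" is itself a flag value (meaning
# "already dropped at an earlier step") and is written as such.

raw_columns <- c(
  "org_name_raw", "st_abbr", "st_name", "orig_MLI", "orig_x", "orig_y",
  "date", "time", "media", "activity_type", "result_type",
  "nutrient_handle", "analytical_method", "sample_fraction_raw",
  "orig_conc", "orig_conc_units", "DL_code", "DL_text", "orig_DL_val",
  "orig_DL_units", "provider"
)

snapd_columns <- c(
  "media", "st_abbr", "st_name", "org_name", "N_or_P", "nutrient_name",
  "sample_fraction", "nutrient_parameter", "year", "date", "MLI", "conc",
  "conc_units", "outlier_flag", "num_obs_per_date", "impute_flag", "DL",
  "DL_units", "x", "y"
)

flagged_columns <- c(
  "st_abbr", "st_name", "org_name", "N_or_P", "nutrient_parameter",
  "nutrient_handle", "new_MLI", "new_x", "new_y", "year", "date", "time",
  "chem_form_flag", "new_conc", "new_conc_units", "new_DL", "new_DL_units",
  "ND_flag", "impute_flag", "sample_fraction", "sample_fraction_flag",
  "result_type", "result_type_flag", "media", "media_flag",
  "activity_type", "activity_type_flag", "filt2unfilt_flag",
  "analytical_method", "provider", "orig_conc", "orig_conc_units",
  "conc_flag", "conc_unit_flag", "orig_DL_val", "orig_DL_units",
  "DL_code", "DL_text", "orig_MLI", "dup_MLI_flag", "num_MLIs_at_loc",
  "orig_x", "orig_y", "num_coords_at_loc", "dup_coords_flag",
  "combine_coords_flag", "pct1", "pct99", "outlier_flag",
  "num_obs_per_date", "num_orgs_per_obs", "num_nds_per_obs",
  "num_conc_per_time", "pct_ND", "date_flag", "record_id"
)

# columns where the string "NA" is a flag value, not a missing value
flag_value_columns <- c(
  "chem_form_flag", "ND_flag", "impute_flag", "sample_fraction_flag",
  "result_type_flag", "media_flag", "activity_type_flag",
  "filt2unfilt_flag", "conc_flag", "conc_unit_flag", "date_flag",
  "outlier_flag", "pct_ND"
)

#' Read a raw WQP-style result table
#'
#' Reads a comma-delimited export with one row per nutrient result.
#' \code{orig_MLI} and \code{nutrient_handle} are mandatory; other known
#' columns are filled with missing values when absent, and unknown columns
#' are dropped with a warning. \code{record_id} is assigned 0..n-1 in file
#' order; empty strings become missing values; coordinates and detection
#' limit values are parsed as numbers, the concentration is kept as text
#' (raw exports contain non-numeric entries, which the cascade handles).
#'
#' @param path Path to a CSV file.
#' @return A data frame of raw records.
#' @export
read_raw_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  missing_mand <- setdiff(c("orig_MLI", "nutrient_handle"), names(df))
  if (length(missing_mand))
    stopf("schema error: mandatory column(s) missing from '%s': %s",
          path, paste(missing_mand, collapse = ", "))
  unknown <- setdiff(names(df), raw_columns)
  if (length(unknown)) {
    warnf("ignoring unknown column(s): %s", paste(unknown, collapse = ", "))
    df <- df[setdiff(names(df), unknown)]
  }
  for (col in setdiff(raw_columns, names(df))) df[[col]] <- NA_character_
  df <- df[raw_columns]
  for (col in names(df)) df[[col]][is_blank(df[[col]])] <- NA
  df$orig_x <- parse_number(df$orig_x)
  df$orig_y <- parse_number(df$orig_y)
  df$orig_DL_val <- parse_number(df$orig_DL_val)
  df$record_id <- seq_len(nrow(df)) - 1L
  df
}

validate_harmonized <- function(harmonized) {
  key <- paste(harmonized$MLI, harmonized$date, harmonized$nutrient_parameter,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("invariant violation: duplicate (MLI, date, nutrient_parameter) at row %d",
          dup[1L])
  bad <- which(!is.na(harmonized$conc) & harmonized$conc < 0)
  if (length(bad))
    stopf("invariant violation: negative concentration at row %d", bad[1L])
  bad <- which(xor(!is.na(harmonized$DL), harmonized$impute_flag == "imputed"))
  if (length(bad))
    stopf("invariant violation: DL present iff impute_flag = imputed fails at row %d",
          bad[1L])
  bad <- which(xor(is.na(harmonized$outlier_flag), is.na(harmonized$conc)))
  if (length(bad))
    stopf("invariant violation: outlier_flag NA iff conc absent fails at row %d",
          bad[1L])
  invisible(harmonized)
}

#' Write the harmonized and flagged outputs
#'
#' Writes the harmonized daily dataset and the flagged audit dataset as CSV
#' with the exact column names and order of their schemas, after checking
#' the schema invariants (unique (MLI, date, nutrient_parameter); no
#' negative concentrations; detection limit present exactly on imputed
#' rows; outlier flag missing exactly where the concentration is missing).
#' Dates are written as YYYY-MM-DD, missing values as empty strings, and
#' the literal string \code{"NA"} in flag columns (where it is a flag
#' value, not a missing value).
#'
#' @param harmonized Harmonized records (SNAPD-style schema).
#' @param flagged Flagged records (one per raw input row).
#' @param dir Output directory (created if needed).
#' @param n_raw Optional raw row count to check conservation against.
#' @return Invisibly, the two file paths.
#' @export
write_outputs <- function(harmonized, flagged, dir, n_raw = NULL) {
  validate_harmonized(harmonized)
  if (!is.null(n_raw) && nrow(flagged) != n_raw)
    stopf("invariant violation: flagged row count %d != raw row count %d",
          nrow(flagged), n_raw)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(harmonized = file.path(dir, "snapd.csv"),
             flagged = file.path(dir, "flagged.csv"))
  write_schema_csv(harmonized, snapd_columns, paths[["harmonized"]])
  write_schema_csv(flagged, flagged_columns, paths[["flagged"]])
  invisible(paths)
}

write_schema_csv <- function(df, columns, path) {
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stopf("schema error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  out <- df[columns]
  for (col in intersect(flag_value_columns, columns)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- "NA"
    out[[col]] <- v
  }
  if ("date" %in% columns && inherits(out$date, "Date"))
    out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
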