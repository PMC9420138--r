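# The keep/drop flag cascade. Rules run in harmonization-step order; once a
# row earns a "drop", every later rule on that row emits NA ("already
# flagged in another harmonization step as drop").

#' Standardize an organization name
#'
#' Trims and collapses whitespace, then looks the case-folded name up in the
#' alias table; unmatched names are returned trimmed but otherwise
#' untouched. Standardization never drops rows.
#'
#' @param raw Raw organization name(s).
#' @param alias_table Named character vector mapping normalized variants to
#'   canonical names (see \code{\link{default_config}}).
#' @return Character vector of canonical names.
#' @export
standardize_org_name <- function(raw,
                                 alias_table = default_config()$org_alias_table) {
  out <- squish(as.character(raw))
  hit <- match(norm_text(out), names(alias_table))
  out[!is.na(hit)] <- unname(alias_table[hit[!is.na(hit)]])
  out
}

# Cascade order: flag column -> harmonization step number.
cascade_steps <- c(
  media_flag = 3L, date_flag = 4L, chem_form_flag = 5L, conc_flag = 6L,
  conc_unit_flag = 7L, ND_flag = 8L, sample_fraction_flag = 9L,
  activity_type_flag = 10L, result_type_flag = 11L
)

#' Identify non-detect records
#'
#' A record is a non-detect when both conditions hold: (1) the reported
#' concentration is zero, negative, or missing (including non-numeric
#' text), and (2) the detection code or detection text maps to a non-detect
#' token in the configured vocabulary. Records whose code maps to a
#' contamination / quality-control failure token are marked \code{"drop"};
#' everything else is \code{"keep"}.
#'
#' @param records Data frame with \code{orig_conc}, \code{DL_code},
#'   \code{DL_text}.
#' @param config A \code{wq_config}.
#' @return Character vector: \code{"ND"}, \code{"drop"} or \code{"keep"}.
#' @export
identify_nondetects <- function(records, config = default_config()) {
  conc <- parse_number(records$orig_conc)
  cond1 <- is.na(conc) | conc <= 0
  voc <- config$nd_code_vocabulary
  code_meaning <- voc$meaning[match(norm_text(records$DL_code), voc$token)]
  text_meaning <- voc$meaning[match(norm_text(records$DL_text), voc$token)]
  contaminated <- (!is.na(code_meaning) & code_meaning == "contaminated_drop") |
    (!is.na(text_meaning) & text_meaning == "contaminated_drop")
  cond2 <- (!is.na(code_meaning) & code_meaning == "nondetect") |
    (!is.na(text_meaning) & text_meaning == "nondetect")
  out <- rep("keep", nrow(records))
  out[cond1 & cond2] <- "ND"
  out[contaminated] <- "drop"
  out
}

#' Apply the metadata filter cascade
#'
#' Evaluates the drop/keep predicates of the harmonization cascade on every
#' record and emits the per-step flag columns. Predicates, in step order:
#' medium must be water; date must parse; the chemical form must be
#' recoverable from name, units or method; the concentration must be a
#' positive number unless the record is a non-detect; the concentration
#' units must convert to mg/L (non-detects with no reported concentration
#' are exempt, their detection limit carries the units); the detection code
#' must not indicate contamination; the sample fraction must map to a
#' harmonized fraction; the activity type must not be a quality-control
#' activity; and the result type must not contain an estimation term
#' ("approximation", "educated guess"). A row has at most one drop flag;
#' every later flag on that row is NA.
#'
#' @param records Data frame of raw records (see
#'   \code{\link{read_raw_table}}), with site resolution columns optional.
#' @param config A \code{wq_config}.
#' @return \code{records} with the flag columns of the flagged schema plus
#'   working columns \code{.form} (inferred chemical form), \code{.is_nd},
#'   \code{.fraction} (harmonized fraction) and \code{.drop_step} (first
#'   step that dropped the row; 0 when kept).
#' @export
apply_filter_cascade <- function(records, config = default_config()) {
  n <- nrow(records)
  conc_num <- parse_number(records$orig_conc)
  nd_status <- identify_nondetects(records, config)
  is_nd <- nd_status == "ND"

  form <- infer_chemical_form(records$nutrient_handle,
                              records$orig_conc_units,
                              records$analytical_method, config)

  media_keep <- !is.na(match(norm_text(records$media), config$media_whitelist))
  date_keep <- !is.na(parse_date(records$date))
  chem_keep <- form != "unknown"
  conc_keep <- (!is.na(conc_num) & conc_num > 0) | is_nd
  ufac <- unit_factor(records$orig_conc_units, config$unit_registry)
  # non-detects without a usable reported value carry no informative units
  unit_keep <- !is.na(ufac) | is_nd
  nd_keep <- nd_status != "drop"
  fraction <- unname(config$fraction_map[norm_text(records$sample_fraction_raw)])
  fraction_keep <- !is.na(fraction)
  act <- norm_text(records$activity_type)
  activity_keep <- is.na(act) |
    (!act %in% config$qc_activity_types & !startsWith(act, "quality control"))
  rt <- norm_text(records$result_type)
  pat <- paste(config$result_type_drop_terms, collapse = "|")
  result_keep <- is.na(rt) | !grepl(pat, rt, fixed = FALSE)

  keep <- cbind(media_flag = media_keep, date_flag = date_keep,
                chem_form_flag = chem_keep, conc_flag = conc_keep,
                conc_unit_flag = unit_keep, ND_flag = nd_keep,
                sample_fraction_flag = fraction_keep,
                activity_type_flag = activity_keep,
                result_type_flag = result_keep)

  first_fail <- apply(keep, 1L, function(r) {
    i <- which(!r)
    if (length(i)) i[1L] else 0L
  })
  drop_step <- rep(0L, n)
  drop_step[first_fail > 0L] <- cascade_steps[first_fail[first_fail > 0L]]

  flag_of <- function(col, keep_val, drop_val, j) {
    out <- ifelse(keep[, col], keep_val, drop_val)
    out[first_fail > 0L & first_fail < j] <- NA_character_
    out
  }
  # media and date are always evaluated: these two flags have no NA state
  records$media_flag <- flag_of("media_flag", "keep", "drop", 1L)
  records$date_flag <- flag_of("date_flag", "keep", "drop", 1L)
  records$chem_form_flag <-
    flag_of("chem_form_flag", "chem_form_known", "chem_form_unknown", 3L)
  records$conc_flag <- flag_of("conc_flag", "keep", "drop", 4L)
  records$conc_unit_flag <- flag_of("conc_unit_flag", "keep", "drop", 5L)
  nd_flag <- ifelse(nd_status == "drop", "drop",
                    ifelse(is_nd, "ND", "keep"))
  nd_flag[first_fail > 0L & first_fail < 6L] <- NA_character_
  records$ND_flag <- nd_flag
  records$sample_fraction_flag <-
    flag_of("sample_fraction_flag", "keep", "drop", 7L)
  records$activity_type_flag <-
    flag_of("activity_type_flag", "keep", "drop", 8L)
  records$result_type_flag <-
    flag_of("result_type_flag", "keep", "drop", 9L)

  records$.form <- form
  records$.is_nd <- is_nd
  records$.fraction <- fraction
  records$.drop_step <- unname(drop_step)
  records
}
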