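# Chemical-form inference, molecular -> elemental conversion and unit
# conversion to mg/L.

harmonized_nutrient_names <- c(
  "ammonia", "nitrate", "organic nitrogen", "kjeldahl nitrogen",
  "total nitrogen", "inorganic nitrogen",
  "organic phosphorus", "orthophosphate", "total phosphorus"
)

harmonized_fractions <- c("filtered", "unfiltered", "inorganic", "organic",
                          "particulate")

#' Infer the chemical form of a nutrient result
#'
#' Recovers whether a reported concentration is on an elemental basis
#' (mass of N or P only) or a molecular basis (mass of the whole compound,
#' e.g. NO3), using three metadata elements in order of precedence:
#' (1) the raw nutrient name ("Nitrate as N" is elemental, "Orthophosphate
#' as PO4" is molecular); (2) the concentration units ("mg/l as N",
#' "mg/l as NO3"); (3) the analytical method code, looked up in the
#' configured method registry. When none of the three resolves the form,
#' \code{"unknown"} is returned and the record is later dropped as
#' \code{chem_form_unknown}.
#'
#' @param handle Raw nutrient name(s).
#' @param units Concentration unit text (or \code{NA}).
#' @param method Analytical method code (or \code{NA}).
#' @param config A \code{wq_config} object.
#' @return Character vector: \code{"elemental"}, a molecular form
#'   (\code{"NH3"}, \code{"NH4"}, \code{"NO3"}, \code{"PO4"}), or
#'   \code{"unknown"}.
#' @export
infer_chemical_form <- function(handle, units = NA, method = NA,
                                config = default_config()) {
  n <- max(length(handle), length(units), length(method))
  handle <- rep_len(handle, n)
  units <- rep_len(units, n)
  method <- rep_len(method, n)

  voc <- config$nutrient_vocabulary
  i <- match(norm_handle(handle), voc$raw_handle)
  form <- ifelse(is.na(i), "unknown", voc$form_status[i])

  # units carry form information for names that do not
  need <- form == "unknown"
  if (any(need)) {
    u <- norm_text(units[need])
    ureg <- config$unit_registry
    uform <- ureg$form[match(u, ureg$unit)]
    # also parse a trailing "as X" on unregistered unit text
    miss <- is.na(uform) & !is.na(u) & grepl(" as ", u, fixed = TRUE)
    if (any(miss)) {
      suffix <- sub("^.* as ", "", u[miss])
      uform[miss] <- c(n = "N", p = "P", no3 = "NO3", nh3 = "NH3",
                       nh4 = "NH4", po4 = "PO4")[suffix]
    }
    uform <- ifelse(uform %in% c("N", "P"), "elemental", uform)
    form[need] <- ifelse(is.na(uform), "unknown", uform)
  }

  # analytical method as the last resort
  need <- form == "unknown"
  if (any(need)) {
    mreg <- config$method_registry
    mform <- mreg$form[match(norm_text(method[need]), mreg$method)]
    form[need] <- ifelse(is.na(mform), "unknown", mform)
  }
  form
}

#' Convert a molecular concentration to its elemental basis
#'
#' Multiplies a molecular-form concentration (e.g. mg NO3/L) by the
#' configured conversion factor to obtain the elemental concentration
#' (mg N/L or mg P/L). Elemental inputs pass through unchanged; molecular
#' forms absent from the conversion table yield \code{NA} (the record is
#' then unconvertible).
#'
#' @param conc Numeric concentration(s).
#' @param form \code{"elemental"} or a molecular form code such as
#'   \code{"NO3"}.
#' @param conversion_table The conversion table from a \code{wq_config}.
#' @return Numeric vector of elemental-basis concentrations.
#' @export
convert_to_elemental <- function(conc, form,
                                 conversion_table = default_config()$conversion_table) {
  n <- max(length(conc), length(form))
  conc <- rep_len(as.numeric(conc), n)
  form <- rep_len(form, n)
  fac <- conversion_table$factor[match(form, conversion_table$reported_form)]
  fac[form == "elemental"] <- 1
  conc * fac
}

#' Convert a concentration to mg/L
#'
#' Looks the unit text up in the configured unit registry (case-insensitive,
#' whitespace-normalized) and rescales the value to mg/L. Units without a
#' mass-per-volume meaning (percentages, mass ratios, counts, turbidity,
#' etc.) and units missing from the registry return \code{NA}: the record is
#' unconvertible. Molar units (umol/l) are deliberately unconvertible
#' because the molar mass depends on an often-unknown chemical form.
#'
#' @param conc Numeric concentration(s).
#' @param units Unit text.
#' @param registry The unit registry from a \code{wq_config}.
#' @return Numeric vector in mg/L, \code{NA} where unconvertible.
#' @export
convert_units <- function(conc, units,
                          registry = default_config()$unit_registry) {
  n <- max(length(conc), length(units))
  conc <- rep_len(as.numeric(conc), n)
  units <- rep_len(units, n)
  fac <- registry$factor[match(norm_text(units), registry$unit)]
  conc * fac
}

# Factor to mg/L for a unit, NA when unconvertible; vectorized.
unit_factor <- function(units, registry) {
  registry$factor[match(norm_text(units), registry$unit)]
}

#' Build the harmonized nutrient parameter name
#'
#' Joins a harmonized nutrient name and sample fraction into the
#' \code{nutrient_parameter} comparability class, e.g.
#' \code{"ammonia_filtered"}, and emits the companion fields.
#'
#' @param nutrient_name Harmonized nutrient name (one of the nine
#'   harmonized categories, e.g. \code{"total nitrogen"}).
#' @param fraction Harmonized sample fraction (\code{"filtered"},
#'   \code{"unfiltered"}, \code{"inorganic"}, \code{"organic"} or
#'   \code{"particulate"}).
#' @return A data frame with columns \code{nutrient_name},
#'   \code{sample_fraction}, \code{nutrient_parameter} and \code{N_or_P}.
#' @export
harmonize_nutrient_name <- function(nutrient_name, fraction) {
  if (length(nutrient_name) == 0L && length(fraction) == 0L)
    return(data.frame(nutrient_name = character(0),
                      sample_fraction = character(0),
                      nutrient_parameter = character(0),
                      N_or_P = character(0), stringsAsFactors = FALSE))
  n <- max(length(nutrient_name), length(fraction))
  nutrient_name <- rep_len(tolower(squish(nutrient_name)), n)
  fraction <- rep_len(tolower(squish(fraction)), n)
  bad <- !nutrient_name %in% harmonized_nutrient_names
  if (any(bad))
    stopf("vocabulary error: unknown harmonized nutrient name '%s'",
          nutrient_name[which(bad)[1]])
  bad <- !fraction %in% harmonized_fractions
  if (any(bad))
    stopf("vocabulary error: unknown sample fraction '%s'",
          fraction[which(bad)[1]])
  data.frame(
    nutrient_name = nutrient_name,
    sample_fraction = fraction,
    nutrient_parameter = paste0(nutrient_name, "_", fraction),
    N_or_P = ifelse(grepl("phosph", nutrient_name), "P", "N"),
    stringsAsFactors = FALSE
  )
}
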