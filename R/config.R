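#' Default harmonization configuration
#'
#' Builds the configuration object that houses every fixed constant and
#' registry used by the harmonization pipeline: the 400 m coordinate-merge
#' threshold, the 80% non-detect imputation cutoff, the number of imputed
#' datasets (K = 10), the 1st/99th outlier percentiles, the four
#' molecular-to-elemental conversion factors, the concentration-unit
#' registry, the raw-nutrient-name vocabulary, the analytical-method
#' registry, detection-code vocabulary, organization alias table, sample
#' fraction map, media whitelist, quality-control activity types, and the
#' sample-fraction combination rules.
#'
#' All registries are plain data frames or named vectors and are intended to
#' be user-editable: the raw vocabularies found in real exports vary by
#' provider, and the defaults cover the common Water Quality Portal terms
#' plus everything the bundled synthetic generator emits.
#'
#' @return An object of class \code{wq_config} (a named list).
#' @seealso \code{\link{load_config}}
#' @export
default_config <- function() {
  cfg <- list(
    coord_merge_threshold_m = 400,
    nd_impute_max_share     = 0.80,
    n_imputations           = 10L,
    burn_in                 = 1000L,
    thin                    = 10L,
    outlier_lower_pct       = 1,
    outlier_upper_pct       = 99,
    rng_seed                = 1L,

    # Molecular -> elemental conversion factors (multiply reported molecular
    # concentration by `factor` to obtain the elemental concentration).
    conversion_table = data.frame(
      nutrient      = c("ammonia", "ammonia", "nitrate", "orthophosphate"),
      reported_form = c("NH3", "NH4", "NO3", "PO4"),
      factor        = c(0.822, 0.776, 0.225, 0.326),
      target_form   = c("N", "N", "N", "P"),
      stringsAsFactors = FALSE
    ),

    # Concentration-unit registry: factor converts to mg/L; NA factor means
    # the unit carries no mass-per-volume meaning and is unconvertible.
    # `form` records chemical-form information carried by the unit text.
    unit_registry = rbind(
      data.frame(
        unit = c("mg/l", "mg/l as n", "mg/l as p",
                 "mg/l as no3", "mg/l as nh3", "mg/l as nh4", "mg/l as po4",
                 "mg n/l", "mg p/l", "ppm",
                 "ug/l", "ug/l as n", "ug/l as p", "ppb"),
        factor = c(rep(1, 10), rep(0.001, 4)),
        form = c(NA, "N", "P", "NO3", "NH3", "NH4", "PO4",
                 "N", "P", NA, NA, "N", "P", NA),
        stringsAsFactors = FALSE
      ),
      data.frame(
        unit = c("%", "% by vol", "% by wt", "% recovery",
                 "cm3/g @stp", "cm3/g stp", "cm3/g", "g/kg", "g/m2",
                 "mg/g", "mg/kg", "mg/kg as n", "mg/kg as p", "mg/kg po4",
                 "mg/m2 nh4", "mgd", "mpn", "mpn/100 ml", "none", "ntu",
                 "pci/l", "ueq/l", "ug/kg", "umol/l", "#/100 ml",
                 "cfu/100 ml", "lb/day", "ml/l", "mv"),
        factor = NA_real_,
        form = NA_character_,
        stringsAsFactors = FALSE
      )
    ),

    # Raw nutrient-name vocabulary. form_status: "elemental", a molecular
    # form ("NH3", "NH4", "NO3", "PO4"), or "unknown" (form not recoverable
    # from the name alone; units or analytical method may still resolve it).
    nutrient_vocabulary = data.frame(
      raw_handle = c(
        "ammonia", "ammonia as nh3", "ammonia n", "ammonia n as n",
        "ammonium as nh4", "kjeldahl n", "nitrate", "nitrate as n",
        "nitrate as no3", "nitrogen", "nitrogen mixed forms",
        "nitrogen nutrient", "organic nitrogen", "total ammonia",
        "total kjeldahl n", "total kjeldahl n (organic n plus nitrate)",
        "total nitrogen mixed forms",
        "organic phosphorus", "organic phosphorus particulate",
        "orthophosphate", "orthophosphate as p", "orthophosphate as po4",
        "phosphate", "phosphate as p", "phosphate as po4",
        "phosphate phosphorus", "phosphate phosphorus as p",
        "phosphate phosphorus as po4", "phosphorus",
        "phosphorus hydrolyzable", "soluble reactive phosphorus",
        "total phosphorus mixed forms"
      ),
      nutrient_name = c(
        "ammonia", "ammonia", "ammonia", "ammonia",
        "ammonia", "kjeldahl nitrogen", "nitrate", "nitrate",
        "nitrate", "total nitrogen", "total nitrogen",
        "total nitrogen", "organic nitrogen", "ammonia",
        "kjeldahl nitrogen", "kjeldahl nitrogen",
        "total nitrogen",
        "organic phosphorus", "organic phosphorus",
        "orthophosphate", "orthophosphate", "orthophosphate",
        "orthophosphate", "orthophosphate", "orthophosphate",
        "orthophosphate", "orthophosphate",
        "orthophosphate", "total phosphorus",
        "total phosphorus", "orthophosphate",
        "total phosphorus"
      ),
      N_or_P = c(rep("N", 17), rep("P", 15)),
      form_status = c(
        "unknown", "NH3", "unknown", "elemental",
        "NH4", "elemental", "unknown", "elemental",
        "NO3", "elemental", "elemental",
        "elemental", "elemental", "unknown",
        "elemental", "elemental",
        "elemental",
        "elemental", "elemental",
        "unknown", "elemental", "PO4",
        "unknown", "elemental", "PO4",
        "unknown", "elemental",
        "PO4", "unknown",
        "unknown", "unknown",
        "unknown"
      ),
      stringsAsFactors = FALSE
    ),

    # Analytical-method registry: method code -> chemical form the method
    # reports in. Small static table; editable, no web lookup.
    method_registry = data.frame(
      method = c("4500-no3-e", "4500-nh3-h", "4500-norg-b",
                 "4500-p-e", "365.1", "353.2", "350.1"),
      form   = c("elemental", "elemental", "elemental",
                 "elemental", "elemental", "elemental", "elemental"),
      stringsAsFactors = FALSE
    ),

    # Detection code/text vocabulary.
    nd_code_vocabulary = data.frame(
      token = c("u", "nd", "not detected", "below detection limit", "bdl",
                "non-detect", "nondetect", "<",
                "contaminated", "sample contaminated",
                "quality control failure", "rejected"),
      meaning = c(rep("nondetect", 8), rep("contaminated_drop", 4)),
      stringsAsFactors = FALSE
    ),

    result_type_drop_terms = c("approximation", "educated guess"),

    media_whitelist = c("water", "surface water", "ground water",
                        "groundwater"),

    # Activity types dropped as quality-control / not-at-site samples.
    # Any activity type starting with "quality control" is also dropped.
    qc_activity_types = c(
      "quality control sample-field blank",
      "quality control sample-lab blank",
      "quality control sample-equipment blank",
      "quality control sample-lab duplicate",
      "quality control sample-field replicate",
      "quality control-calibration check"
    ),

    # Raw sample-fraction text -> harmonized fraction level.
    fraction_map = c(
      "dissolved"         = "filtered",
      "filtered"          = "filtered",
      "filterable"        = "filtered",
      "total"             = "unfiltered",
      "unfiltered"        = "unfiltered",
      "total recoverable" = "unfiltered",
      "suspended"         = "particulate",
      "particulate"       = "particulate",
      "non-filterable"    = "particulate",
      "inorganic"         = "inorganic",
      "organic"           = "organic"
    ),

    # Organization alias table: normalized variant -> canonical name.
    org_alias_table = c(
      "usgs"                                  = "USGS",
      "u.s. geological survey"                = "USGS",
      "us geological survey"                  = "USGS",
      "united states geological survey"       = "USGS",
      "epa"                                   = "EPA",
      "us epa"                                = "EPA",
      "u.s. environmental protection agency"  = "EPA",
      "environmental protection agency"       = "EPA"
    ),

    # Sample-fraction combination rules: components summed into a total
    # nutrient where the target is not already measured that site-date.
    combination_rules = data.frame(
      component_a = c("total nitrogen_filtered", "total phosphorus_filtered"),
      component_b = c("total nitrogen_particulate",
                      "total phosphorus_particulate"),
      target      = c("total nitrogen_unfiltered",
                      "total phosphorus_unfiltered"),
      stringsAsFactors = FALSE
    )
  )
  class(cfg) <- "wq_config"
  validate_config(cfg)
  cfg
}

# Scalar keys that a configuration file may override.
config_scalar_keys <- c(
  "coord_merge_threshold_m", "nd_impute_max_share", "n_imputations",
  "burn_in", "thin", "outlier_lower_pct", "outlier_upper_pct", "rng_seed"
)

# Character-vector keys that a configuration file may replace wholesale.
config_vector_keys <- c(
  "result_type_drop_terms", "media_whitelist", "qc_activity_types"
)

validate_config <- function(cfg) {
  num1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stopf("configuration error: '%s' must be a single finite number", key)
    v
  }
  if (num1("coord_merge_threshold_m") <= 0)
    stopf("configuration error: 'coord_merge_threshold_m' must be positive")
  s <- num1("nd_impute_max_share")
  if (s <= 0 || s > 1)
    stopf("configuration error: 'nd_impute_max_share' must be in (0, 1]")
  for (key in c("n_imputations", "burn_in", "thin")) {
    if (num1(key) < 1)
      stopf("configuration error: '%s' must be a positive integer", key)
  }
  if (num1("outlier_lower_pct") >= num1("outlier_upper_pct"))
    stopf("configuration error: 'outlier_lower_pct' must be below 'outlier_upper_pct'")
  ct <- cfg$conversion_table
  if (!is.data.frame(ct) ||
      !all(c("nutrient", "reported_form", "factor", "target_form") %in% names(ct)))
    stopf("configuration error: 'conversion_table' is malformed")
  if (any(ct$factor <= 0 | ct$factor >= 1))
    stopf("configuration error: 'conversion_table' factors must lie in (0, 1)")
  invisible(cfg)
}

#' Load a harmonization configuration
#'
#' Reads a YAML key-value document and overlays it on the defaults from
#' \code{\link{default_config}}. Scalar thresholds
#' (\code{coord_merge_threshold_m}, \code{nd_impute_max_share},
#' \code{n_imputations}, \code{burn_in}, \code{thin},
#' \code{outlier_lower_pct}, \code{outlier_upper_pct}, \code{rng_seed}) and
#' the term/whitelist vectors may be overridden; unspecified keys keep their
#' defaults.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return A \code{wq_config} object.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("configuration error: file '%s' not found", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopf("configuration error: %s", conditionMessage(e)))
  if (is.null(doc)) return(cfg)
  if (!is.list(doc)) stopf("configuration error: top level must be a mapping")
  for (key in names(doc)) {
    if (key %in% config_scalar_keys) {
      v <- doc[[key]]
      if (!is.numeric(v) || length(v) != 1L)
        stopf("configuration error: key '%s' must be a single number", key)
      cfg[[key]] <- if (key %in% c("n_imputations", "burn_in", "thin", "rng_seed"))
        as.integer(v) else v
    } else if (key %in% config_vector_keys) {
      cfg[[key]] <- as.character(unlist(doc[[key]]))
    } else if (key == "org_alias_table") {
      extra <- unlist(doc[[key]])
      cfg$org_alias_table[norm_text(names(extra))] <- as.character(extra)
    } else {
      stopf("configuration error: unknown key '%s'", key)
    }
  }
  validate_config(cfg)
  cfg
}

#' @export
print.wq_config <- function(x, ...) {
  cat("Harmonization configuration\n")
  cat(sprintf("  coordinate merge threshold: %g m\n", x$coord_merge_threshold_m))
  cat(sprintf("  non-detect imputation cutoff: %g%% of group\n",
              100 * x$nd_impute_max_share))
  cat(sprintf("  imputed datasets K: %d (burn-in %d, thin %d)\n",
              x$n_imputations, x$burn_in, x$thin))
  cat(sprintf("  outlier percentiles: %g / %g\n",
              x$outlier_lower_pct, x$outlier_upper_pct))
  cat(sprintf("  conversion factors: %s\n",
              paste(sprintf("%s %.3f", x$conversion_table$reported_form,
                            x$conversion_table$factor), collapse = ", ")))
  cat(sprintf("  unit registry: %d units (%d convertible)\n",
              nrow(x$unit_registry), sum(!is.na(x$unit_registry$factor))))
  cat(sprintf("  nutrient vocabulary: %d raw names\n",
              nrow(x$nutrient_vocabulary)))
  invisible(x)
}
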