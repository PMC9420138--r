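# Internal string/number helpers shared across the pipeline.

# Trim, collapse internal whitespace. Keeps case.
squish <- function(x) {
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Case-folded, whitespace-normalized token used for all vocabulary lookups.
norm_text <- function(x) {
  out <- tolower(squish(as.character(x)))
  out[is.na(x)] <- NA_character_
  out
}

# Normalize a raw nutrient handle: underscores become spaces (WQP-export
# dialects write e.g. "ammonia_N_as_N"), subscript markers like "NH_3_"
# collapse to "nh3", commas are dropped.
norm_handle <- function(x) {
  out <- as.character(x)
  out <- gsub("_", " ", out)
  out <- tolower(squish(out))
  out <- gsub(",", "", out)
  # rejoin chemical subscripts split by the underscore removal: "nh 3" -> "nh3"
  out <- gsub("(?<=[a-z]) (?=[0-9])", "", out, perl = TRUE)
  out <- squish(out)
  out[is.na(x)] <- NA_character_
  out
}

# TRUE where x is NA or an empty / whitespace-only string.
is_blank <- function(x) {
  is.na(x) | !nzchar(trimws(as.character(x)))
}

# Strict numeric parse: returns NA for anything that is not a plain number.
parse_number <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  # tolerate unicode minus signs occasionally seen in exports
  x <- gsub("−|–", "-", x)
  suppressWarnings(as.numeric(x))
}

# Parse ISO dates; anything unparseable becomes NA.
parse_date <- function(x) {
  x <- as.character(x)
  x[is_blank(x)] <- NA_character_
  as.Date(x, format = "%Y-%m-%d", optional = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
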