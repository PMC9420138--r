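# Independent brute-force re-implementations used as oracles on small
# fixtures. Deliberately naive: explicit loops, one rule at a time.

oracle_resolve_sites <- function(df, thr) {
  df <- df[order(df$record_id), ]
  n <- nrow(df)
  new_x <- df$orig_x; new_y <- df$orig_y; new_mli <- df$orig_MLI
  for (m in unique(df$orig_MLI)) {
    i <- which(df$orig_MLI == m)
    pairs <- unique(data.frame(x = df$orig_x[i], y = df$orig_y[i]))
    if (nrow(pairs) < 2) next
    allclose <- TRUE
    for (a in seq_len(nrow(pairs) - 1)) for (b in (a + 1):nrow(pairs)) {
      dsq <- (pairs$x[a] - pairs$x[b])^2 + (pairs$y[a] - pairs$y[b])^2
      if (sqrt(dsq) > thr) allclose <- FALSE
    }
    if (allclose) { new_x[i] <- pairs$x[1]; new_y[i] <- pairs$y[1] }
  }
  keys <- paste(new_x, new_y)
  for (k in unique(keys)) {
    i <- which(keys == k)
    mlis <- unique(df$orig_MLI[i])
    if (length(mlis) > 1) new_mli[i] <- mlis[1]
  }
  data.frame(record_id = df$record_id, new_x = new_x, new_y = new_y,
             new_MLI = new_mli)
}

oracle_common_dl <- function(org, conc, is_nd, has_dl) {
  # one nutrient-year; returns the common DL or NA
  qual <- unique(org[is_nd & !has_dl])
  mins <- c()
  for (o in qual) {
    v <- conc[org == o & !is_nd & !is.na(conc)]
    if (length(v)) mins <- c(mins, min(v))
  }
  if (length(mins)) max(mins) else NA_real_
}

oracle_daily_mean <- function(mli, date, param, conc) {
  key <- paste(mli, date, param)
  out <- data.frame(key = unique(key), conc = NA_real_, n = NA_integer_)
  for (i in seq_len(nrow(out))) {
    v <- conc[key == out$key[i]]
    v <- v[!is.na(v)]
    if (length(v)) { out$conc[i] <- mean(v); out$n[i] <- length(v) }
  }
  out
}

oracle_step19 <- function(daily) {
  drop <- rep(FALSE, nrow(daily))
  for (i in seq_len(nrow(daily))) {
    if (is.na(daily$conc[i])) next
    for (j in seq_len(nrow(daily))) {
      if (i == j || is.na(daily$conc[j])) next
      same <- daily$MLI[i] == daily$MLI[j] &&
        daily$date[i] == daily$date[j] &&
        daily$nutrient_name[i] == daily$nutrient_name[j]
      if (!same) next
      if (daily$sample_fraction[i] == "filtered" &&
          daily$sample_fraction[j] == "unfiltered" &&
          daily$conc[i] >= daily$conc[j]) drop[i] <- drop[j] <- TRUE
    }
  }
  drop
}

oracle_cascade_step <- function(row, config) {
  # first dropping step for one raw record, rules applied one at a time
  if (!(norm_txt(row$media) %in% config$media_whitelist)) return(3L)
  if (is.na(row$date) || is.na(as.Date(row$date, "%Y-%m-%d", optional = TRUE)))
    return(4L)
  if (infer_chemical_form(row$nutrient_handle, row$orig_conc_units,
                          row$analytical_method, config) == "unknown")
    return(5L)
  conc <- suppressWarnings(as.numeric(row$orig_conc))
  nd <- identify_nondetects(as.data.frame(row), config)
  if (nd != "ND" && (is.na(conc) || conc <= 0)) return(6L)
  reg <- config$unit_registry
  fac <- reg$factor[match(norm_txt(row$orig_conc_units), reg$unit)]
  if (nd != "ND" && is.na(fac)) return(7L)
  if (nd == "drop") return(8L)
  if (!(norm_txt(row$sample_fraction_raw) %in% names(config$fraction_map)))
    return(9L)
  a <- norm_txt(row$activity_type)
  if (!is.na(a) && (a %in% config$qc_activity_types ||
                    grepl("^quality control", a))) return(10L)
  r <- norm_txt(row$result_type)
  if (!is.na(r) && (grepl("approximation", r) || grepl("educated guess", r)))
    return(11L)
  0L
}

norm_txt <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_character_)
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}
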