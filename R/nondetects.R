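# Detection-limit approximation and Bayesian multiple imputation of
# left-censored concentrations.
#
# Model: log-concentration ~ Normal(mu, sigma^2) with vague conjugate
# priors mu ~ Normal(0, 1000^2), sigma^2 ~ InverseGamma(0.001, 0.001).
# Censored observations are latent values truncated above at log(DL) and
# drawn by Gibbs data augmentation; after burn-in, K thinned draws per
# censored value are retained and averaged on the concentration scale.

#' Approximate missing detection limits
#'
#' Non-detects lacking a reported detection limit receive a common,
#' conservative limit per nutrient-parameter-year: among organizations that
#' report at least one limit-less non-detect for that nutrient-year, take
#' each organization's minimum detected concentration, then assign the
#' largest of those minima (the least-sensitive method plausibly in use) to
#' every limit-less non-detect of that nutrient-year. Non-detects with a
#' reported limit keep it. When no qualifying organization has any detected
#' value that nutrient-year, the limit is unassignable and those records
#' are excluded from imputation.
#'
#' @param records Data frame with columns \code{org_name},
#'   \code{nutrient_parameter}, \code{year}, \code{new_conc} (mg/L,
#'   detected values), \code{new_DL} (mg/L or NA) and \code{ND_flag}.
#' @return \code{records} with \code{new_DL} filled where approximable and
#'   a logical column \code{.dl_approximated} added.
#' @export
approximate_detection_limits <- function(records) {
  records$.dl_approximated <- logical(nrow(records))
  is_nd <- !is.na(records$ND_flag) & records$ND_flag == "ND"
  needs <- is_nd & is.na(records$new_DL)
  if (!any(needs)) return(records)

  key <- paste(records$nutrient_parameter, records$year, sep = "\r")
  for (k in unique(key[needs])) {
    in_key <- key == k
    qual_orgs <- unique(records$org_name[in_key & needs])
    detected <- in_key & !is.na(records$new_conc) &
      !is.na(records$ND_flag) & records$ND_flag == "keep" &
      records$org_name %in% qual_orgs
    if (!any(detected)) next                   # unassignable, leave NA
    minima <- tapply(records$new_conc[detected], records$org_name[detected],
                     min)
    common_dl <- max(minima)
    fill <- in_key & needs
    records$new_DL[fill] <- common_dl
    records$.dl_approximated[fill] <- TRUE
  }
  records
}

# Draw from N(mean, sd^2) truncated to (-Inf, upper]; vectorized and
# numerically safe far into the lower tail (Robert's exponential rejection
# for the extreme case, inverse CDF otherwise).
rtnorm_upper <- function(mean, sd, upper) {
  n <- max(length(mean), length(sd), length(upper))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); upper <- rep_len(upper, n)
  alpha <- (upper - mean) / sd
  out <- numeric(n)
  easy <- alpha > -6
  if (any(easy)) {
    p <- stats::pnorm(alpha[easy])
    u <- stats::runif(sum(easy)) * p
    u <- pmax(u, .Machine$double.xmin)
    out[easy] <- stats::qnorm(u)
  }
  if (any(!easy)) out[!easy] <- -rtail_std(-alpha[!easy])
  mean + sd * pmin(out, alpha)
}

# Standard normal truncated to [a, Inf) for large a > 0 (Robert 1995).
rtail_std <- function(a) {
  n <- length(a)
  out <- numeric(n)
  todo <- seq_len(n)
  lambda <- (a + sqrt(a^2 + 4)) / 2
  while (length(todo)) {
    z <- a[todo] + stats::rexp(length(todo), 1) / lambda[todo]
    acc <- stats::runif(length(todo)) <= exp(-(z - lambda[todo])^2 / 2)
    out[todo[acc]] <- z[acc]
    todo <- todo[!acc]
  }
  out
}

#' Impute left-censored concentrations for one site-nutrient-year group
#'
#' Runs the censored-lognormal Gibbs sampler on one group of observations
#' sharing a site, nutrient parameter and year. If the group's non-detect
#' share is at or above \code{max_share} (default 80%), nothing is imputed
#' and the censored members keep a missing concentration. Otherwise each
#' censored member receives the mean of \code{K} retained posterior draws
#' (back-transformed to mg/L), each draw truncated to lie in (0, DL].
#'
#' @param observed Numeric vector of detected concentrations (mg/L).
#' @param dl Numeric vector of detection limits (mg/L), one per censored
#'   member.
#' @param max_share Maximum non-detect share that still imputes (fraction).
#' @param K Number of retained posterior draws per censored value.
#' @param burn_in,thin Gibbs sampler schedule.
#' @return A list: \code{imputed} (numeric, NA when not imputed),
#'   \code{pct_nd} (percent censored), \code{did_impute} (logical),
#'   \code{mu_mean}, \code{mu_sd} (posterior summary of the log-scale mean
#'   from the retained draws).
#' @export
impute_censored <- function(observed, dl, max_share = 0.8, K = 10L,
                            burn_in = 1000L, thin = 10L) {
  m <- length(observed)
  cns <- length(dl)
  pct_nd <- 100 * cns / (m + cns)
  res <- list(imputed = rep(NA_real_, cns), pct_nd = pct_nd,
              did_impute = FALSE, mu_mean = NA_real_, mu_sd = NA_real_)
  if (cns > 0L && pct_nd >= 100 * max_share) return(res)
  if (m == 0L) return(res)
  if (any(!is.finite(dl) | dl <= 0))
    stopf("impute_censored: every censored member needs a positive detection limit")

  y <- log(observed)
  b <- log(dl)
  mu0 <- 0; tau2 <- 1000^2; a0 <- 0.001; b0 <- 0.001
  init <- c(y, b)
  mu <- mean(init)
  sigma2 <- if (length(init) > 1L) max(stats::var(init), 1e-6) else 1
  ntot <- burn_in + K * thin
  zdraws <- matrix(NA_real_, nrow = K, ncol = cns)
  mudraws <- numeric(K)
  kept <- 0L
  for (it in seq_len(ntot)) {
    if (cns > 0L) {
      s <- sqrt(sigma2)
      alpha <- (b - mu) / s
      if (all(alpha > -6)) {
        # inline inverse-CDF draw (common case; avoids dispatch overhead)
        u <- stats::runif(cns) * stats::pnorm(alpha)
        z <- mu + s * pmin(stats::qnorm(pmax(u, .Machine$double.xmin)), alpha)
      } else {
        z <- rtnorm_upper(mu, s, b)
      }
    } else z <- numeric(0)
    all_v <- c(y, z)
    nn <- length(all_v)
    v_mu <- 1 / (nn / sigma2 + 1 / tau2)
    mu <- stats::rnorm(1, v_mu * (sum(all_v) / sigma2 + mu0 / tau2),
                       sqrt(v_mu))
    sigma2 <- 1 / stats::rgamma(1, a0 + nn / 2,
                                b0 + sum((all_v - mu)^2) / 2)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      zdraws[kept, ] <- z
      mudraws[kept] <- mu
    }
  }
  res$imputed <- colMeans(exp(zdraws))
  res$did_impute <- cns > 0L
  res$mu_mean <- mean(mudraws)
  res$mu_sd <- stats::sd(mudraws)
  res
}
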