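# MR-PRESSO: global heterogeneity, outlier and distortion tests -----------

# leave-one-out IVW slopes for observed or simulated (x, y) with fixed
# weights w = 1/se_y^2; x, y may be matrices (rows = simulations)
loo_slopes <- function(x, y, w) {
  if (is.matrix(x)) {
    wx <- sweep(x, 2, w, `*`)
    sxy <- rowSums(wx * y)
    sxx <- rowSums(wx * x)
    (sxy - wx * y) / (sxx - wx * x)
  } else {
    sxy <- sum(w * x * y)
    sxx <- sum(w * x^2)
    (sxy - w * x * y) / (sxx - w * x^2)
  }
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy through the weighted residual sum of
#' squares around leave-one-out IVW fits. The observed RSS is compared to
#' its distribution under `n_sim` parametric simulations of the
#' no-pleiotropy model (global test); each instrument's squared residual is
#' compared to its own simulated distribution with Bonferroni correction
#' over k (outlier test); and when outliers are removed, the shift between
#' the raw and outlier-corrected IVW estimates is compared to the shifts
#' obtained by removing random subsets of the same size (distortion test).
#' Outlier removal is a single pass, not iterated. Empirical p-values use
#' the add-one estimator, so the smallest attainable p is `1/(n_sim+1)`.
#'
#' @param h A `tmr_harmonized` set, k >= 4.
#' @param n_sim Number of null simulations (default 1000).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-instrument test (default 0.05).
#' @param seed Integer seed; the result is fully reproducible given the
#'   seed.
#' @param ivw_mode Mode for the raw and corrected IVW estimates.
#' @return An object of class `tmr_presso`: list with `rss_obs`,
#'   `global_pval`, `per_snp` (tibble: variant, residual, raw and
#'   Bonferroni-adjusted p, outlier flag), `outlier_ids`, `beta_raw`,
#'   `beta_corrected`, `corrected_estimate` (a `tmr_mr` row),
#'   `distortion_pval`, `n_sim`, `seed`.
#' @export
presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed,
                   ivw_mode = "multiplicative_random") {
  k <- nrow(h)
  if (k < 4) abort("MR-PRESSO requires at least 4 instruments",
                   class = "tmr_data_error")
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  x <- h$beta_x; y <- h$beta_y
  sx <- h$se_x; sy <- h$se_y
  w <- 1 / sy^2

  b_loo <- loo_slopes(x, y, w)
  resid_obs <- w * (y - b_loo * x)^2
  rss_obs <- sum(resid_obs)

  sim <- withr::with_seed(seed, {
    xs <- matrix(rnorm(n_sim * k, mean = rep(x, each = n_sim),
                       sd = rep(sx, each = n_sim)), nrow = n_sim)
    ys <- matrix(rnorm(n_sim * k, mean = rep(b_loo * x, each = n_sim),
                       sd = rep(sy, each = n_sim)), nrow = n_sim)
    bs <- loo_slopes(xs, ys, w)
    r2 <- sweep((ys - bs * xs)^2, 2, w, `*`)
    list(rss = rowSums(r2), resid = r2)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- (colSums(sweep(sim$resid, 2, resid_obs, `>=`)) + 1) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * k)
  outlier <- p_adj < outlier_alpha
  if (all(outlier)) abort("all instruments flagged as outliers",
                          class = "tmr_data_error")
  per_snp <- tibble(variant_id = h$variant_id, residual = resid_obs,
                    pval = p_raw, pval_bonferroni = p_adj, outlier = outlier)
  outlier_ids <- h$variant_id[outlier]

  raw <- ivw(h, mode = ivw_mode)
  hc <- h[!outlier, ]
  corrected <- ivw(hc, mode = ivw_mode)
  corrected$method <- "mr_presso"

  distortion_pval <- NA_real_
  if (any(outlier)) {
    n_out <- sum(outlier)
    n_rem <- 1000
    d_null <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_rem), function(i) {
        drop <- sample.int(k, n_out)
        bsub <- ivw(h[-drop, ], mode = "fixed")$beta
        (bsub - raw$beta) / abs(raw$beta)
      }, numeric(1))
    })
    d_obs <- (corrected$beta - raw$beta) / abs(raw$beta)
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_rem + 1)
  }

  structure(list(
    rss_obs = rss_obs,
    global_pval = global_pval,
    per_snp = per_snp,
    outlier_ids = outlier_ids,
    beta_raw = raw$beta,
    beta_corrected = corrected$beta,
    corrected_estimate = corrected,
    distortion_pval = distortion_pval,
    n_sim = n_sim,
    outlier_alpha = outlier_alpha,
    seed = seed
  ), class = "tmr_presso")
}

#' @export
print.tmr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d, seed = %d)\n", x$n_sim, x$seed))
  cat(sprintf("  global RSS = %.4g, p = %.4g\n", x$rss_obs, x$global_pval))
  cat(sprintf("  outliers: %s\n",
              if (length(x$outlier_ids)) paste(x$outlier_ids, collapse = ", ")
              else "none"))
  cat(sprintf("  beta raw = %.4g, corrected = %.4g", x$beta_raw,
              x$beta_corrected))
  if (!is.na(x$distortion_pval)) {
    cat(sprintf(" (distortion p = %.3g)", x$distortion_pval))
  }
  cat("\n")
  invisible(x)
}

#' @method tidy tmr_presso
#' @export
tidy.tmr_presso <- function(x, ...) x$per_snp

#' @method glance tmr_presso
#' @export
glance.tmr_presso <- function(x, ...) {
  tibble(rss_obs = x$rss_obs, global_pval = x$global_pval,
         n_outliers = length(x$outlier_ids),
         beta_raw = x$beta_raw, beta_corrected = x$beta_corrected,
         distortion_pval = x$distortion_pval)
}
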