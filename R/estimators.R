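# Two-sample MR estimators and diagnostics --------------------------------

mr_row <- function(method, beta, se, pval, k,
                   q = NA_real_, q_pval = NA_real_,
                   egger_intercept = NA_real_, intercept_pval = NA_real_,
                   binary = FALSE) {
  out <- tibble(
    method = method, beta = beta, se = se,
    ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
    pval = pval, k = as.integer(k),
    q = q, q_pval = q_pval,
    egger_intercept = egger_intercept, intercept_pval = intercept_pval,
    odds_ratio = NA_real_, or_low = NA_real_, or_high = NA_real_
  )
  if (binary) {
    out$odds_ratio <- exp(out$beta)
    out$or_low <- exp(out$ci_low)
    out$or_high <- exp(out$ci_high)
  }
  class(out) <- c("tmr_mr", class(out))
  out
}

h_binary <- function(h) identical(attr(h, "outcome_type"), "binary")

#' Wald ratio estimate from a single instrument
#'
#' The single-SNP causal estimate: outcome beta divided by exposure beta,
#' with the first-order standard error `se_y / |beta_x|`.
#'
#' @param bx,sx Exposure beta and standard error.
#' @param by,sy Outcome beta and standard error.
#' @param binary Populate odds-ratio columns (outcome on log-odds scale)?
#' @return One-row `tmr_mr` tibble.
#' @export
wald_ratio <- function(bx, sx, by, sy, binary = FALSE) {
  if (bx == 0) abort("exposure beta is zero: degenerate instrument",
                     class = "tmr_data_error")
  beta <- by / bx
  se <- sy / abs(bx)
  mr_row("wald", beta, se, p_normal(beta, se), 1L, binary = binary)
}

#' Inverse-variance weighted estimate
#'
#' Pools the per-instrument Wald ratios with weights
#' `w_j = beta_x_j^2 / se_y_j^2` — algebraically a weighted regression of
#' outcome betas on exposure betas through the origin. Cochran's Q is
#' reported against chi-square with k-1 df. In the default
#' multiplicative-random-effects mode the standard error is inflated by
#' `max(1, sqrt(Q/(k-1)))`; fixed mode reports the unscaled standard error.
#'
#' @param h A `tmr_harmonized` set (see [harmonize_pair()]), k >= 2.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row `tmr_mr` tibble with Q diagnostics.
#' @export
ivw <- function(h, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  k <- nrow(h)
  if (k < 2) abort("IVW requires at least 2 instruments",
                   class = "tmr_data_error")
  if (any(h$beta_x == 0)) abort("exposure beta of zero: degenerate instrument",
                                class = "tmr_data_error")
  w <- h$beta_x^2 / h$se_y^2
  ratio <- h$beta_y / h$beta_x
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  q_pval <- pchisq(q, df = k - 1, lower.tail = FALSE)
  se <- if (mode == "multiplicative_random") {
    se_fixed * max(1, sqrt(q / (k - 1)))
  } else se_fixed
  mr_row(paste0("ivw_", if (mode == "fixed") "fe" else "mre"),
         beta, se, p_normal(beta, se), k, q = q, q_pval = q_pval,
         binary = h_binary(h))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an
#' intercept, each instrument oriented so its exposure beta is
#' non-negative. A non-zero intercept indicates directional horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate.
#' Standard errors use the weighted-least-squares covariance with
#' multiplicative overdispersion floored at 1; the residual Q has k-2 df.
#'
#' @param h A `tmr_harmonized` set, k >= 3.
#' @return One-row `tmr_mr` tibble with intercept columns filled.
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) abort("MR-Egger requires at least 3 instruments",
                   class = "tmr_data_error")
  flip <- sign(h$beta_x)
  flip[flip == 0] <- 1
  x <- h$beta_x * flip
  y <- h$beta_y * flip
  w <- 1 / h$se_y^2

  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= 0) abort("degenerate design in MR-Egger", class = "tmr_data_error")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  fitted <- intercept + slope * x
  q <- sum(w * (y - fitted)^2)
  phi <- max(1, q / (k - 2))
  se_slope <- sqrt(sw / det * phi)
  se_int <- sqrt(swxx / det * phi)
  mr_row("egger", slope, se_slope, p_normal(slope, se_slope), k,
         q = q, q_pval = pchisq(q, df = k - 2, lower.tail = FALSE),
         egger_intercept = intercept,
         intercept_pval = p_normal(intercept, se_int),
         binary = h_binary(h))
}

weighted_median_point <- function(ratio, w) {
  w <- w / sum(w)
  ord <- order(ratio)
  b <- ratio[ord]
  w <- w[ord]
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  j <- max(which(s < 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median estimate
#'
#' The median of the inverse-variance-weighted empirical distribution of
#' per-instrument Wald ratios; consistent when instruments carrying more
#' than half of the weight are valid. The standard error is the standard
#' deviation of the estimate over `n_boot` parametric bootstrap resamples
#' (exposure and outcome betas redrawn from normal distributions at their
#' observed values).
#'
#' @param h A `tmr_harmonized` set, k >= 3.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (mandatory: no hidden
#'   global randomness).
#' @return One-row `tmr_mr` tibble.
#' @export
weighted_median <- function(h, n_boot = 1000, seed) {
  k <- nrow(h)
  if (k < 3) abort("weighted median requires at least 3 instruments",
                   class = "tmr_data_error")
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  w <- h$beta_x^2 / h$se_y^2
  beta <- weighted_median_point(h$beta_y / h$beta_x, w)

  boot <- withr::with_seed(seed, {
    bx <- matrix(rnorm(n_boot * k, mean = rep(h$beta_x, each = n_boot),
                       sd = rep(h$se_x, each = n_boot)), nrow = n_boot)
    by <- matrix(rnorm(n_boot * k, mean = rep(h$beta_y, each = n_boot),
                       sd = rep(h$se_y, each = n_boot)), nrow = n_boot)
    vapply(seq_len(n_boot), function(i) {
      xb <- bx[i, ]
      xb[xb == 0] <- .Machine$double.eps
      weighted_median_point(by[i, ] / xb, xb^2 / h$se_y^2)
    }, numeric(1))
  })
  se <- sd(boot)
  mr_row("weighted_median", beta, se, p_normal(beta, se), k,
         binary = h_binary(h))
}

#' Run the full two-sample MR estimator suite
#'
#' Returns the primary IVW estimate together with the weighted-median,
#' MR-Egger and MR-PRESSO-corrected estimates as a tidy table, one row per
#' method. Odds-ratio columns are populated when the harmonized outcome is
#' binary (log-odds betas).
#'
#' @param h A `tmr_harmonized` set with k >= 3 (k >= 4 for MR-PRESSO).
#' @param seed Integer seed driving the weighted-median bootstrap and the
#'   MR-PRESSO simulations.
#' @param ivw_mode Passed to [ivw()].
#' @param n_boot,n_sim Resample counts for the weighted median and
#'   MR-PRESSO respectively.
#' @param include_presso Set FALSE to skip the (simulation-heavy) MR-PRESSO
#'   step, e.g. inside large batch screens.
#' @return A `tmr_mr` tibble, one row per method; attribute `presso` holds
#'   the full [presso()] result when run.
#' @export
run_mr_suite <- function(h, seed, ivw_mode = "multiplicative_random",
                         n_boot = 1000, n_sim = 1000,
                         include_presso = TRUE) {
  out <- bind_rows(
    ivw(h, mode = ivw_mode),
    weighted_median(h, n_boot = n_boot, seed = seed),
    mr_egger(h)
  )
  pres <- NULL
  if (include_presso && nrow(h) >= 4) {
    pres <- presso(h, n_sim = n_sim, seed = seed, ivw_mode = ivw_mode)
    out <- bind_rows(out, pres$corrected_estimate)
  }
  class(out) <- c("tmr_mr", class(out))
  attr(out, "exposure_label") <- attr(h, "exposure_label")
  attr(out, "outcome_label") <- attr(h, "outcome_label")
  attr(out, "presso") <- pres
  out
}

#' @method tidy tmr_mr
#' @export
tidy.tmr_mr <- function(x, ...) as_tibble(x)

#' @method glance tmr_mr
#' @export
glance.tmr_mr <- function(x, ...) {
  primary <- x[x$method %in% c("ivw_mre", "ivw_fe"), ][1, ]
  tibble(beta = primary$beta, se = primary$se, pval = primary$pval,
         k = primary$k, q = primary$q, q_pval = primary$q_pval,
         n_methods = nrow(x))
}
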