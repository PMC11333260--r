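# Multivariable MR and two-step mediation ---------------------------------

#' Multivariable inverse-variance weighted regression
#'
#' Regresses outcome betas on several exposures' betas jointly (no
#' intercept, weights `1/se_y^2`), yielding each exposure's direct
#' (conditional) effect. Standard errors come from the weighted
#' least-squares covariance with multiplicative overdispersion floored
#' at 1.
#'
#' @param beta_x k x m matrix of per-instrument exposure betas (one column
#'   per exposure); column names label the exposures.
#' @param se_x k x m matrix of exposure standard errors (carried through
#'   for reporting; first-order weights ignore them).
#' @param beta_y,se_y Outcome betas and standard errors (length k).
#' @param check_rank Abort on rank-deficient exposure matrices (default
#'   TRUE). When FALSE, degenerate directions are dropped from the
#'   solution via the pseudoinverse (their coefficients are 0), which
#'   reduces the fit to the lower-dimensional regression.
#' @return A tibble with one row per exposure: `exposure`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, plus `k`, `q` and `q_pval` attributes in
#'   columns (identical across rows).
#' @export
mvmr_ivw <- function(beta_x, se_x = NULL, beta_y, se_y, check_rank = TRUE) {
  beta_x <- as.matrix(beta_x)
  k <- nrow(beta_x)
  m <- ncol(beta_x)
  if (m < 2) abort("mvmr_ivw expects at least 2 exposures; use ivw() for one",
                   class = "tmr_config_error")
  if (k <= m) abort("more instruments than exposures required",
                    class = "tmr_data_error")
  labels <- colnames(beta_x) %||% paste0("exposure_", seq_len(m))
  qrd <- qr(beta_x)
  if (check_rank && qrd$rank < m) {
    bad <- labels[qrd$pivot[seq(qrd$rank + 1, m)]]
    abort(paste0("collinear exposure columns: ", paste(bad, collapse = ", ")),
          class = "tmr_collinearity_error")
  }
  w <- 1 / se_y^2
  # solve the weighted normal equations through the SVD of sqrt(w)X:
  # stable when one exposure's signal is many orders below the other's
  sv <- svd(beta_x * sqrt(w))
  keep_d <- sv$d > max(sv$d) * 1e-10
  dinv <- ifelse(keep_d, 1 / sv$d, 0)
  cinv <- sv$v %*% (dinv^2 * t(sv$v))
  coefs <- drop(sv$v %*% (dinv * crossprod(sv$u, sqrt(w) * beta_y)))
  fitted <- drop(beta_x %*% coefs)
  q <- sum(w * (beta_y - fitted)^2)
  phi <- max(1, q / (k - m))
  ses <- sqrt(diag(cinv) * phi)
  tibble(
    exposure = labels,
    beta = coefs,
    se = ses,
    ci_low = coefs - CI_Z * ses,
    ci_high = coefs + CI_Z * ses,
    pval = p_normal(coefs, ses),
    k = k,
    q = q,
    q_pval = pchisq(q, df = k - m, lower.tail = FALSE)
  )
}

#' Proportion of a total effect carried through a mediator
#'
#' The product-of-coefficients mediated share: `beta1 * beta2_path / beta3`,
#' where `beta1` is the exposure-to-mediator effect, `beta2_path` the
#' mediator-to-outcome effect (univariable, or exposure-adjusted from
#' multivariable MR), and `beta3` the total exposure-to-outcome effect.
#' The value is signed and not clamped; estimates outside [0, 1] indicate
#' inconsistent-sign mediation and raise a warning, not an error.
#'
#' @param beta1,beta2_path,beta3 Path coefficients; `beta3` must be nonzero.
#' @return The signed proportion mediated.
#' @export
#' @examples
#' proportion_mediated(-0.84, log(1.13), log(0.34))
proportion_mediated <- function(beta1, beta2_path, beta3) {
  if (beta3 == 0) abort("total effect beta3 is zero: proportion undefined",
                        class = "tmr_data_error")
  p <- beta1 * beta2_path / beta3
  if (p < 0 || p > 1) {
    warn(sprintf("proportion mediated %.3f lies outside [0, 1]: inconsistent path signs", p))
  }
  p
}

#' Two-step MR mediation through a circulating mediator
#'
#' Estimates the three univariable legs of the mediation triangle by IVW
#' (`beta1`: exposure to mediator; `beta2`: mediator to outcome; `beta3`:
#' total exposure to outcome), then re-estimates the mediator-to-outcome
#' path adjusted for the exposure (`beta2_adj`) by multivariable MR on the
#' union of the exposure and mediator instruments. Both product
#' decompositions of the mediated share are returned: `beta1*beta2/beta3`
#' (univariable) and `beta1*beta2_adj/beta3` (multivariable-adjusted).
#'
#' @param exposure_instruments `tmr_instruments` for the exposure.
#' @param mediator_gwas `tmr_gwas` summary statistics for the mediator.
#' @param mediator_instruments `tmr_instruments` for the mediator.
#' @param outcome_gwas `tmr_gwas` for the outcome (binary traits on the
#'   log-odds scale).
#' @param exposure_gwas Optional full exposure GWAS (same effect scale as
#'   the instruments) used to look up exposure betas at the mediator's
#'   instruments; when NULL the multivariable step uses the exposure
#'   instruments only.
#' @param seed Integer seed (weighted-median/bootstrap components of the
#'   per-leg suites).
#' @param ivw_mode IVW mode for every leg.
#' @return An object of class `tmr_mediation`: list with per-leg `tmr_mr`
#'   rows (`beta1`, `beta2`, `beta3`), the MVMR table (`mvmr`),
#'   `beta2_adj`, and a `proportions` tibble (method_tag, indirect,
#'   proportion).
#' @export
two_step_mediation <- function(exposure_instruments, mediator_gwas,
                               mediator_instruments, outcome_gwas,
                               exposure_gwas = NULL, seed,
                               ivw_mode = "multiplicative_random") {
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  h1 <- harmonize_pair(exposure_instruments, mediator_gwas)
  h2 <- harmonize_pair(mediator_instruments, outcome_gwas)
  h3 <- harmonize_pair(exposure_instruments, outcome_gwas)
  b1 <- ivw(h1, mode = ivw_mode)
  b2 <- ivw(h2, mode = ivw_mode)
  b3 <- ivw(h3, mode = ivw_mode)

  # multivariable leg: outcome on (exposure, mediator) betas over the
  # instrument union, everything aligned to the exposure-side effect allele
  if (!is.null(exposure_gwas)) {
    ids <- union(exposure_instruments$variant_id,
                 mediator_instruments$variant_id)
    ids <- ids[ids %in% exposure_gwas$variant_id]
    expo_tbl <- instrument_set(exposure_gwas, ids)
  } else {
    expo_tbl <- exposure_instruments
  }
  hx_out <- harmonize_pair(expo_tbl, outcome_gwas)
  hx_med <- harmonize_pair(expo_tbl, mediator_gwas)
  common <- intersect(hx_out$variant_id, hx_med$variant_id)
  if (length(common) <= 2) {
    abort("multivariable step needs more than 2 shared instruments",
          class = "tmr_data_error")
  }
  io <- match(common, hx_out$variant_id)
  im <- match(common, hx_med$variant_id)
  bx <- cbind(exposure = hx_out$beta_x[io], mediator = hx_med$beta_y[im])
  sx <- cbind(exposure = hx_out$se_x[io], mediator = hx_med$se_y[im])
  mv <- mvmr_ivw(bx, sx, beta_y = hx_out$beta_y[io], se_y = hx_out$se_y[io])
  beta2_adj <- mv$beta[mv$exposure == "mediator"]

  props <- tibble(
    method_tag = c("product_uvmr", "product_mvmr"),
    beta1 = b1$beta,
    beta2_path = c(b2$beta, beta2_adj),
    beta3 = b3$beta,
    indirect = b1$beta * c(b2$beta, beta2_adj),
    proportion = b1$beta * c(b2$beta, beta2_adj) / b3$beta
  )
  structure(list(
    beta1 = b1, beta2 = b2, beta3 = b3,
    mvmr = mv, beta2_adj = beta2_adj,
    proportions = props,
    legs = list(exposure_mediator = h1, mediator_outcome = h2,
                exposure_outcome = h3)
  ), class = "tmr_mediation")
}

#' @export
print.tmr_mediation <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta1 (exposure -> mediator): %.4g (se %.3g)\n",
              x$beta1$beta, x$beta1$se))
  cat(sprintf("  beta2 (mediator -> outcome): %.4g; adjusted beta2': %.4g\n",
              x$beta2$beta, x$beta2_adj))
  cat(sprintf("  beta3 (total effect): %.4g (se %.3g)\n",
              x$beta3$beta, x$beta3$se))
  print(x$proportions)
  invisible(x)
}

#' @method tidy tmr_mediation
#' @export
tidy.tmr_mediation <- function(x, ...) x$proportions

#' @method glance tmr_mediation
#' @export
glance.tmr_mediation <- function(x, ...) {
  tibble(beta1 = x$beta1$beta, beta2 = x$beta2$beta,
         beta2_adj = x$beta2_adj, beta3 = x$beta3$beta,
         proportion_uvmr = x$proportions$proportion[1],
         proportion_mvmr = x$proportions$proportion[2])
}
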