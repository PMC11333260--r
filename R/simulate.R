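# Synthetic GWAS summary statistics with known causal truth ---------------

ar1_matrix <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), `-`))

# one draw from N(mu, sigma2 * Sigma) given the Cholesky factor of Sigma
mvn_draw <- function(mu, chol_sigma, scale) {
  mu + scale * drop(crossprod(chol_sigma, rnorm(length(mu))))
}

sim_gwas <- function(variant_id, chrom, pos, beta, se, n, label,
                     trait_type = "quantitative", eaf = NULL) {
  gwas_table(tibble(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = eaf %||% rep(0.3, length(beta)),
    beta = beta, se = se,
    pval = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n
  ), trait_label = label, trait_type = trait_type)
}

#' Ground-truth record for a mediation simulation
#'
#' Bundles the causal parameters of the simulated DAG: the
#' exposure-to-mediator path `theta_xm`, the mediator-to-outcome path
#' `theta_my`, the direct exposure-to-outcome path `theta_direct` (the
#' total effect is `theta_direct + theta_xm * theta_my` by construction),
#' the pleiotropy regime, per-trait GWAS sample sizes and the seed.
#'
#' @param theta_xm,theta_my,theta_direct Structural path coefficients.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`:
#'   per-instrument direct effects on the outcome drawn from
#'   `N(pleiotropy_mean, pleiotropy_sd)` (mean forced to 0 when balanced).
#' @param pleiotropy_sd,pleiotropy_mean Pleiotropy distribution parameters.
#' @param pleiotropy_frac Fraction of exposure instruments that are
#'   invalid (carry the pleiotropic effect); default 1, i.e. all of them.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes per trait.
#' @param ld_rho AR(1) LD parameter used by region simulations.
#' @param shared_causal Whether region simulations share the causal variant.
#' @param seed Mandatory integer seed.
#' @return A list of class `tmr_truth` with a computed `theta_total`.
#' @export
simulation_truth <- function(theta_xm = 0.4, theta_my = 0.25,
                             theta_direct = -0.9,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional"),
                             pleiotropy_sd = 0, pleiotropy_mean = 0,
                             pleiotropy_frac = 1,
                             n_exposure = 344182, n_mediator = 100000,
                             n_outcome = 100000,
                             ld_rho = 0.5, shared_causal = TRUE, seed) {
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (pleiotropy_mode == "balanced") pleiotropy_mean <- 0
  stopifnot(pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  structure(list(
    theta_xm = theta_xm, theta_my = theta_my, theta_direct = theta_direct,
    theta_total = theta_direct + theta_xm * theta_my,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_frac = pleiotropy_frac,
    n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
    ld_rho = ld_rho, shared_causal = shared_causal, seed = as.integer(seed)
  ), class = "tmr_truth")
}

#' Simulate two traits' summary statistics over one LD region
#'
#' Builds an AR(1) LD structure (`r_ij = ld_rho^|i-j|`), places one causal
#' variant per trait (the same index for both iff `shared_causal`), sets
#' marginal effects to LD-propagated joint effects, and adds sampling
#' noise that is multivariate normal with covariance `LD/n` — the standard
#' distribution of marginal GWAS betas for standardized genotypes and
#' trait. Used to exercise colocalization with a known H3/H4 answer.
#'
#' @param m_variants Number of variants in the region (>= 2).
#' @param ld_rho AR(1) correlation parameter in [0, 1).
#' @param n1,n2 GWAS sample sizes for the two traits.
#' @param shared_causal Single shared causal variant (H4 scenario) versus
#'   two causal variants at least 10 positions apart (H3 scenario).
#' @param effect_size Joint (causal) effect size in per-sd trait units.
#' @param seed Mandatory integer seed; output is a pure function of the
#'   arguments.
#' @return List with `trait1`, `trait2` (`tmr_gwas` tables), `ld` (the LD
#'   matrix) and `truth` (causal indices and parameters).
#' @export
simulate_region <- function(m_variants = 50, ld_rho = 0.5,
                            n1 = 10000, n2 = 10000,
                            shared_causal = TRUE, effect_size = 0.1,
                            seed) {
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  stopifnot(m_variants >= 2, ld_rho >= 0, ld_rho < 1)
  ld <- ar1_matrix(m_variants, ld_rho)
  chol_ld <- chol(ld)
  idx1 <- ceiling(m_variants / 3)
  idx2 <- if (shared_causal) idx1 else
    min(m_variants, idx1 + max(10, ceiling(m_variants / 3)))

  b1 <- numeric(m_variants); b1[idx1] <- effect_size
  b2 <- numeric(m_variants); b2[idx2] <- effect_size
  mu1 <- drop(ld %*% b1)
  mu2 <- drop(ld %*% b2)

  withr::with_seed(seed, {
    beta1 <- mvn_draw(mu1, chol_ld, 1 / sqrt(n1))
    beta2 <- mvn_draw(mu2, chol_ld, 1 / sqrt(n2))
    ids <- sprintf("rs%04d", seq_len(m_variants))
    pos <- 1000000L + seq_len(m_variants) * 1000L
    list(
      trait1 = sim_gwas(ids, "1", pos, beta1, rep(1 / sqrt(n1), m_variants),
                        n1, "trait1"),
      trait2 = sim_gwas(ids, "1", pos, beta2, rep(1 / sqrt(n2), m_variants),
                        n2, "trait2"),
      ld = `dimnames<-`(ld, list(ids, ids)),
      truth = list(causal1 = idx1, causal2 = idx2,
                   shared_causal = shared_causal,
                   effect_size = effect_size, ld_rho = ld_rho, seed = seed)
    )
  })
}

#' Simulate the full mediation DAG at summary level
#'
#' Draws independent instruments for the exposure (`k_exposure_snps`) and
#' mediator-specific instruments (`k_mediator_snps`), then generates four
#' GWAS tables over their union: exposure, mediator, outcome, and an
#' independent replicate of the mediator (fresh noise; for meta-analysis).
#' Mediator betas are `theta_xm * beta_x` at exposure instruments plus the
#' mediator-specific effects; outcome betas are `theta_total * beta_x`
#' plus `theta_my *` (mediator-specific effects) plus per-instrument
#' pleiotropic effects per the truth's pleiotropy regime. Standard errors
#' are `1/sqrt(n)` per trait (standardized scale) and the outcome is
#' labeled binary (log-odds) to exercise odds-ratio reporting.
#'
#' @param truth A [simulation_truth()] record.
#' @param k_exposure_snps Exposure instruments (>= 4, the MR-PRESSO
#'   minimum).
#' @param k_mediator_snps Mediator-specific instruments.
#' @param instrument_strength Scale of the per-SNP exposure (and
#'   mediator-specific) effects.
#' @param seed Overrides `truth$seed` when given.
#' @return List of `tmr_gwas` tables `exposure`, `mediator`,
#'   `mediator_replicate`, `outcome`, plus `truth` and the instrument id
#'   vectors `exposure_ids`, `mediator_ids`.
#' @export
simulate_mediation_gwas <- function(truth, k_exposure_snps = 10,
                                    k_mediator_snps = 10,
                                    instrument_strength = 0.05,
                                    seed = truth$seed) {
  stopifnot(inherits(truth, "tmr_truth"), k_exposure_snps >= 4,
            instrument_strength > 0)
  kx <- k_exposure_snps
  km <- k_mediator_snps
  m <- kx + km
  se_x <- 1 / sqrt(truth$n_exposure)
  se_m <- 1 / sqrt(truth$n_mediator)
  se_y <- 1 / sqrt(truth$n_outcome)

  withr::with_seed(seed, {
    # true per-SNP effects: magnitudes bounded away from zero so every
    # instrument is individually strong at the stated sample sizes;
    # instruments are coded on the exposure-increasing allele (bx > 0),
    # the orientation MR-Egger assumes for directional pleiotropy
    bx <- runif(kx, 0.5, 1.5) * instrument_strength
    bm_own <- if (km > 0) {
      sample(c(-1, 1), km, TRUE) * runif(km, 0.5, 1.5) * instrument_strength
    } else numeric(0)

    pleio <- switch(truth$pleiotropy_mode,
      none = numeric(kx),
      balanced = rnorm(kx, 0, truth$pleiotropy_sd),
      directional = rnorm(kx, truth$pleiotropy_mean, truth$pleiotropy_sd))
    n_invalid <- round((truth$pleiotropy_frac %||% 1) * kx)
    if (n_invalid < kx) pleio[seq(n_invalid + 1, kx)] <- 0

    mu_x <- c(bx, numeric(km))
    mu_m <- c(truth$theta_xm * bx, bm_own)
    mu_y <- c(truth$theta_total * bx + pleio, truth$theta_my * bm_own)

    ids <- sprintf("rs%04d", seq_len(m))
    pos <- 5000000L + seq_len(m) * 250000L
    eaf <- runif(m, 0.1, 0.45)

    obs <- function(mu, se) rnorm(m, mu, se)
    list(
      exposure = sim_gwas(ids, "16", pos, obs(mu_x, se_x), rep(se_x, m),
                          truth$n_exposure, "exposure", eaf = eaf),
      mediator = sim_gwas(ids, "16", pos, obs(mu_m, se_m), rep(se_m, m),
                          truth$n_mediator, "mediator", eaf = eaf),
      mediator_replicate = sim_gwas(ids, "16", pos, obs(mu_m, se_m),
                                    rep(se_m, m), truth$n_mediator,
                                    "mediator_replicate", eaf = eaf),
      outcome = sim_gwas(ids, "16", pos, obs(mu_y, se_y), rep(se_y, m),
                         truth$n_outcome, "outcome",
                         trait_type = "binary", eaf = eaf),
      truth = truth,
      exposure_ids = ids[seq_len(kx)],
      mediator_ids = if (km > 0) ids[kx + seq_len(km)] else character(0)
    )
  })
}

#' Simulate a panel of outcome GWAS tables for screen testing
#'
#' Generates `n_outcomes` outcome tables over the instrument variants;
#' `n_true` of them carry the causal effect `true_effect`, the remainder
#' are null. Truth labels are returned for scoring sensitivity and
#' family-wise error of [screen_outcomes()].
#'
#' @param instruments A `tmr_instruments` tibble (its betas are the true
#'   instrument-exposure effects).
#' @param n_outcomes Panel size.
#' @param n_true Number of outcomes with a real effect (first `n_true`
#'   labels, before shuffling by name).
#' @param true_effect Causal effect of the exposure on the non-null
#'   outcomes (log-odds scale).
#' @param n_outcome_gwas Sample size per outcome GWAS.
#' @param seed Mandatory integer seed.
#' @return List with `outcomes` (named list of `tmr_gwas`) and `truth`
#'   (tibble: outcome, causal flag).
#' @export
simulate_outcome_panel <- function(instruments, n_outcomes, n_true = 0,
                                   true_effect = 0, n_outcome_gwas = 50000,
                                   seed) {
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  stopifnot(n_true >= 0, n_true <= n_outcomes)
  k <- nrow(instruments)
  se_y <- 1 / sqrt(n_outcome_gwas)
  labels <- sprintf("outcome_%03d", seq_len(n_outcomes))
  causal <- seq_len(n_outcomes) <= n_true

  outcomes <- withr::with_seed(seed, {
    purrr::map2(labels, causal, function(lab, is_causal) {
      eff <- if (is_causal) true_effect else 0
      beta <- rnorm(k, eff * instruments$beta, se_y)
      sim_gwas(instruments$variant_id, instruments$chrom, instruments$pos,
               beta, rep(se_y, k), n_outcome_gwas, lab,
               trait_type = "binary", eaf = instruments$eaf)
    })
  })
  names(outcomes) <- labels
  list(outcomes = outcomes,
       truth = tibble(outcome = labels, causal = causal))
}
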