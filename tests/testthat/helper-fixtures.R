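# builders for tiny in-memory fixtures ------------------------------------

make_gwas <- function(variant_id,
                      beta, se,
                      effect_allele = rep("A", length(beta)),
                      other_allele = rep("G", length(beta)),
                      chrom = rep("16", length(beta)),
                      pos = seq_along(beta) * 1000L,
                      eaf = rep(0.3, length(beta)),
                      pval = 2 * pnorm(-abs(beta / se)),
                      n = rep(10000, length(beta)),
                      trait_label = "trait",
                      trait_type = "quantitative") {
  gwas_table(
    data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
               effect_allele = effect_allele, other_allele = other_allele,
               eaf = eaf, beta = beta, se = se,
               pval = pmax(pval, 1e-300), n = n),
    trait_label = trait_label, trait_type = trait_type
  )
}

# a harmonized set built directly, bypassing allele alignment, for
# estimator-level tests
make_hset <- function(beta_x, se_x, beta_y, se_y, binary = FALSE) {
  k <- length(beta_x)
  out <- tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
    eaf_x = 0.3, eaf_y = 0.3
  )
  structure(out, exposure_label = "x", outcome_label = "y",
            outcome_type = if (binary) "binary" else "quantitative",
            class = c("tmr_harmonized", class(out)))
}

# a clean instrument/outcome pair with a known causal slope
make_consistent_pair <- function(k = 10, slope = -0.5, seed = 1,
                                 n_x = 344182, n_y = 1e5) {
  tr <- simulation_truth(theta_xm = 0, theta_my = 0, theta_direct = slope,
                         n_exposure = n_x, n_outcome = n_y, seed = seed)
  simulate_mediation_gwas(tr, k_exposure_snps = k, k_mediator_snps = 0)
}
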