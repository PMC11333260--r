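# Drug-target instrument construction: cis selection, clumping, inversion ---

#' Built-in instrument-selection profiles
#'
#' Named threshold bundles for instrument selection: `"sglt2"` uses the
#' lenient drug-target settings (association p < 1e-4, clump r2 < 0.8
#' within 1,000 kb); `"metabolite_relaxed"` uses p < 1e-5, r2 < 0.1 within
#' 500 kb; `"metabolite_strict"` uses genome-wide p < 5e-8, r2 < 0.001
#' within 10 Mb.
#'
#' @param name Profile name.
#' @return A list with elements `assoc_p`, `r2_threshold`, `window_bp`.
#' @export
#' @examples
#' selection_profile("metabolite_relaxed")
selection_profile <- function(name = c("sglt2", "metabolite_relaxed",
                                       "metabolite_strict")) {
  name <- match.arg(name)
  switch(name,
    sglt2 = list(assoc_p = 1e-4, r2_threshold = 0.8, window_bp = 1000000L),
    metabolite_relaxed = list(assoc_p = 1e-5, r2_threshold = 0.1,
                              window_bp = 500000L),
    metabolite_strict = list(assoc_p = 5e-8, r2_threshold = 0.001,
                             window_bp = 10000000L)
  )
}

#' Select cis variants jointly associated with target expression and a biomarker
#'
#' Implements the drug-target proxy filters: a variant is retained when it
#' (a) lies within the gene region padded by `cis_window_bp`, (b) is
#' associated with target-gene expression below `expression_p`, and (c) is
#' associated with the downstream biomarker below `assoc_p`. The result is
#' ordered by biomarker p-value, ascending.
#'
#' @param expression `tmr_gwas` table of target-gene eQTL associations.
#' @param biomarker `tmr_gwas` table of biomarker (e.g. HbA1c) associations.
#' @param gene_region List or vector `(chrom, start, end)` of the target gene.
#' @param cis_window_bp Padding around the gene region (default 100 kb).
#' @param assoc_p Biomarker association threshold (default 1e-4).
#' @param expression_p Expression association threshold (default 1e-4).
#' @return Character vector of variant ids passing all three filters.
#' @export
select_target_variants <- function(expression, biomarker, gene_region,
                                   cis_window_bp = 100000L,
                                   assoc_p = 1e-4, expression_p = 1e-4) {
  if (nrow(expression) == 0 || nrow(biomarker) == 0) {
    abort("expression and biomarker tables must be nonempty",
          class = "tmr_config_error")
  }
  chrom <- as.character(gene_region[[1]])
  start <- as.numeric(gene_region[[2]])
  end <- as.numeric(gene_region[[3]])
  if (start > end) abort("gene_region start > end", class = "tmr_config_error")

  in_region <- expression$chrom == chrom &
    expression$pos >= start - cis_window_bp &
    expression$pos <= end + cis_window_bp
  n_region <- sum(in_region)
  expr_hit <- in_region & expression$pval < expression_p
  n_expr <- sum(expr_hit)

  bio <- biomarker[match(expression$variant_id[expr_hit], biomarker$variant_id), ]
  bio_keep <- !is.na(bio$pval) & bio$pval < assoc_p
  ids <- expression$variant_id[expr_hit][bio_keep]
  ids <- ids[order(bio$pval[bio_keep])]

  if (length(ids) == 0) {
    abort(sprintf(
      "no variants pass selection (in region: %d; expression p < %g: %d; biomarker p < %g: 0)",
      n_region, expression_p, n_expr, assoc_p),
      class = "tmr_selection_error")
  }
  ids
}

#' Greedy LD clumping
#'
#' Sorts candidates by p-value (ties by position, then id) and accepts each
#' variant only if its squared correlation with every previously accepted
#' variant within `window_bp` is below `r2_threshold`. Deterministic and
#' invariant to the input row order.
#'
#' @param variants Data frame with columns `variant_id`, `pos`, `pval`.
#' @param ld Correlation matrix (`r`, signed) with variant ids as dimnames,
#'   covering all candidates.
#' @param r2_threshold Squared-correlation ceiling for retained pairs.
#' @param window_bp Window outside which LD is ignored.
#' @return Character vector of retained (index) variant ids, in acceptance
#'   order.
#' @export
clump <- function(variants, ld, r2_threshold, window_bp) {
  stopifnot(all(c("variant_id", "pos", "pval") %in% names(variants)))
  missing_ld <- setdiff(variants$variant_id, rownames(ld))
  if (length(missing_ld)) {
    abort(paste0("variants absent from LD matrix: ",
                 paste(missing_ld, collapse = ", ")),
          class = "tmr_config_error")
  }
  v <- as_tibble(variants) %>%
    arrange(.data$pval, .data$pos, .data$variant_id)
  accepted <- character(0)
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]
    pos <- v$pos[i]
    near <- accepted[abs(v$pos[match(accepted, v$variant_id)] - pos) <= window_bp]
    if (length(near) == 0 ||
        all(ld[id, near]^2 < r2_threshold)) {
      accepted <- c(accepted, id)
    }
  }
  accepted
}

#' Build an instrument set from a weighting GWAS
#'
#' Extracts the selected variants from the weighting (biomarker) GWAS and
#' attaches per-variant F statistics. Use [invert_effects()] afterwards when
#' the instruments should represent pharmacological *inhibition* of the
#' target (i.e. the mirror image of the biomarker-raising allele effects).
#'
#' @param gwas `tmr_gwas` table supplying betas and ses.
#' @param variant_ids Variants to extract; all must be present.
#' @param exposure_label Label for the proxied exposure.
#' @return A tibble of class `tmr_instruments`: the GWAS columns plus
#'   `f_stat`, with attributes `exposure_label` and `inverted` (FALSE).
#' @export
instrument_set <- function(gwas, variant_ids,
                           exposure_label = trait_label(gwas)) {
  if (!all(variant_ids %in% gwas$variant_id)) {
    abort("some variant_ids are absent from the weighting GWAS",
          class = "tmr_config_error")
  }
  x <- as_tibble(gwas)[match(variant_ids, gwas$variant_id), ]
  x$f_stat <- (x$beta / x$se)^2
  structure(x,
            exposure_label = exposure_label,
            inverted = FALSE,
            class = c("tmr_instruments", class(x)))
}

#' Invert instrument effects to represent target inhibition
#'
#' Negates every beta so the instrument set proxies a *decrease* in the
#' weighting biomarker (pharmacological inhibition). Standard errors and F
#' statistics are unchanged. Refuses to invert twice.
#'
#' @param instruments A `tmr_instruments` tibble.
#' @return The same tibble with betas negated and `inverted = TRUE`.
#' @export
invert_effects <- function(instruments) {
  if (isTRUE(attr(instruments, "inverted"))) {
    abort("instrument set is already inverted", class = "tmr_state_error")
  }
  instruments$beta <- -instruments$beta
  attr(instruments, "inverted") <- TRUE
  instruments
}

#' Per-variant instrument-strength F statistics
#'
#' The single-SNP F statistic from summary data is the squared z-score,
#' `(beta/se)^2`; instruments with F below `weak_threshold` (conventionally
#' 10) are flagged as weak.
#'
#' @param betas,ses Numeric vectors of equal length; `ses` all positive.
#' @param weak_threshold Weak-instrument cutoff (default 10).
#' @return A tibble with columns `f_stat` and `weak`.
#' @export
#' @examples
#' f_statistics(c(0.1, 0.03), c(0.025, 0.01))
f_statistics <- function(betas, ses, weak_threshold = 10) {
  stopifnot(length(betas) == length(ses))
  if (any(ses <= 0)) abort("all ses must be > 0", class = "tmr_data_error")
  f <- (betas / ses)^2
  tibble(f_stat = f, weak = f < weak_threshold)
}

#' Run the full drug-target instrument construction
#'
#' Chains the selection steps: cis/expression/biomarker filtering,
#' greedy LD clumping, extraction from the weighting GWAS, beta inversion,
#' and F statistics. A warning is raised when any retained pair of
#' instruments has r2 > 0.1, since the downstream estimators assume
#' independent instruments.
#'
#' @inheritParams select_target_variants
#' @param ld Signed LD correlation matrix covering the candidate variants.
#' @param profile A [selection_profile()] list (or name) providing
#'   `r2_threshold` and `window_bp` for clumping; its `assoc_p` is used as
#'   the biomarker threshold.
#' @param invert Negate betas to represent inhibition (default TRUE).
#' @return A `tmr_instruments` tibble; attribute `selection_log` records
#'   the count surviving each step.
#' @export
select_instruments <- function(expression, biomarker, gene_region, ld,
                               profile = "sglt2",
                               cis_window_bp = 100000L,
                               expression_p = 1e-4,
                               invert = TRUE) {
  if (is.character(profile)) profile <- selection_profile(profile)
  ids <- select_target_variants(expression, biomarker, gene_region,
                                cis_window_bp = cis_window_bp,
                                assoc_p = profile$assoc_p,
                                expression_p = expression_p)
  cand <- as_tibble(biomarker)[match(ids, biomarker$variant_id), ]
  kept <- clump(cand[c("variant_id", "pos", "pval")], ld,
                r2_threshold = profile$r2_threshold,
                window_bp = profile$window_bp)
  ins <- instrument_set(biomarker, kept)
  if (invert) ins <- invert_effects(ins)
  if (nrow(ins) > 1) {
    sub <- ld[ins$variant_id, ins$variant_id]^2
    if (max(sub[upper.tri(sub)]) > 0.1) {
      warn("retained instruments include pairs with r2 > 0.1; estimators assume independence")
    }
  }
  attr(ins, "selection_log") <- tibble(
    step = c("association_filter", "clump"),
    n = c(length(ids), length(kept))
  )
  ins
}
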