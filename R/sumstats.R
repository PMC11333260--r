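# GWAS summary-statistics containers, IO, harmonization, LD ----------------

GWAS_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
GWAS_REQUIRED <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "beta", "se", "pval")

#' Construct a validated GWAS summary-statistics table
#'
#' A GWAS table holds one row per variant with the per-allele effect (`beta`),
#' its standard error, p-value and allele information for a single trait.
#' Binary traits are expected on the log-odds scale. Rows violating the
#' per-variant invariants (`se > 0`, `pval` in (0, 1], distinct alleles,
#' `eaf` in [0, 1] when present) are dropped and counted; duplicated
#' `variant_id`s keep the smallest-p row (ties broken by input order).
#'
#' @param x A data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf` and `n`.
#' @param trait_label Character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"` (log-odds betas).
#' @return A tibble of class `tmr_gwas` with attributes `trait_label`,
#'   `trait_type` and `drop_log` (a tibble of reason/count pairs).
#' @export
#' @examples
#' gwas_table(
#'   data.frame(variant_id = "rs1", chrom = "16", pos = 31494323,
#'              effect_allele = "A", other_allele = "G",
#'              beta = 0.013, se = 0.003, pval = 1.5e-5),
#'   trait_label = "hba1c", trait_type = "quantitative"
#' )
gwas_table <- function(x, trait_label, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  x <- as_tibble(x)
  missing_cols <- setdiff(GWAS_REQUIRED, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tmr_config_error")
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_real_
  x <- x[GWAS_FIELDS]
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)

  drops <- c(
    invalid_se        = sum(!is.finite(x$se) | x$se <= 0),
    invalid_pval      = sum(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1),
    identical_alleles = sum(x$effect_allele == x$other_allele),
    invalid_eaf       = sum(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))
  )
  keep <- is.finite(x$se) & x$se > 0 &
    is.finite(x$pval) & x$pval > 0 & x$pval <= 1 &
    x$effect_allele != x$other_allele &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  x <- x[keep, ]

  # duplicate ids: smallest p wins, ties by original row order
  n_dup <- sum(duplicated(x$variant_id))
  if (n_dup > 0) {
    x <- x %>%
      mutate(.ord = row_number()) %>%
      arrange(.data$variant_id, .data$pval, .data$.ord) %>%
      distinct(.data$variant_id, .keep_all = TRUE) %>%
      arrange(.data$.ord) %>%
      select(-".ord")
  }
  drops <- c(drops, duplicate_id = n_dup)

  if (nrow(x) == 0) {
    abort("no rows survive validation", class = "tmr_data_error")
  }
  structure(
    x,
    trait_label = trait_label,
    trait_type = trait_type,
    drop_log = tibble(reason = names(drops), n = unname(drops)),
    class = c("tmr_gwas", class(x))
  )
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the physical column names in the file.
#'   Fields absent from the map fall back to their canonical name if present
#'   in the file; `eaf` and `n` are optional.
#' @inheritParams gwas_table
#' @return A `tmr_gwas` tibble (see [gwas_table()]).
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = basename(path),
                          trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad)) {
      abort(paste0("column_map names absent from file: ",
                   paste(bad, collapse = ", ")),
            class = "tmr_config_error")
    }
    for (field in names(column_map)) {
      raw[[field]] <- raw[[column_map[[field]]]]
    }
  }
  gwas_table(raw[intersect(GWAS_FIELDS, names(raw))],
             trait_label = trait_label, trait_type = trait_type)
}

#' Write a GWAS table or harmonized set to a delimited file
#'
#' @param x A `tmr_gwas` or `tmr_harmonized` tibble.
#' @param path Output path; tab-delimited with a header row.
#' @return `x`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}

trait_label <- function(x) attr(x, "trait_label") %||% "trait"
trait_type <- function(x) attr(x, "trait_type") %||% "quantitative"

#' @export
print.tmr_gwas <- function(x, ...) {
  cat(sprintf("# GWAS summary statistics: %s (%s), %d variants\n",
              trait_label(x), trait_type(x), nrow(x)))
  NextMethod()
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

allele_complement <- function(a) {
  vapply(strsplit(a, ""), function(ch) {
    paste(COMPLEMENT[ch], collapse = "")
  }, character(1))
}

is_palindromic <- function(ea, oa) ea == allele_complement(oa)

#' Align outcome summary statistics to the exposure's effect alleles
#'
#' For each requested variant present in both tables, the outcome effect is
#' re-expressed on the exposure's effect allele: identical alleles pass
#' through, swapped alleles negate the outcome beta (and reflect its eaf),
#' strand-complement alleles are complemented first and then the same rules
#' apply. Palindromic variants (A/T or C/G) cannot be strand-resolved from
#' alleles alone: they are excluded when the effect-allele frequency in
#' either table is missing or within `palindrome_eaf_window` of 0.5, and
#' otherwise resolved by comparing which side of 0.5 the two frequencies
#' fall on.
#'
#' @param exposure,outcome `tmr_gwas` tables (see [gwas_table()]).
#' @param variant_ids Character vector of instrument variants; each must be
#'   present in `exposure`.
#' @param palindrome_eaf_window Half-width of the ambiguity band around
#'   eaf = 0.5 within which palindromic variants are dropped (default 0.08).
#' @return A tibble of class `tmr_harmonized` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y`,
#'   `eaf_x`, `eaf_y`; attributes `exposure_label`, `outcome_label`,
#'   `outcome_type` and `exclusions` (variant/reason pairs).
#' @export
harmonize_pair <- function(exposure, outcome, variant_ids = exposure$variant_id,
                           palindrome_eaf_window = 0.08) {
  if (length(variant_ids) == 0) {
    abort("variant_ids is empty", class = "tmr_config_error")
  }
  if (!all(variant_ids %in% exposure$variant_id)) {
    abort("some variant_ids are absent from the exposure table",
          class = "tmr_config_error")
  }
  ex <- exposure[match(variant_ids, exposure$variant_id), ]
  oy <- outcome[match(variant_ids, outcome$variant_id), ]

  excl <- list()
  note <- function(id, reason) tibble(variant_id = id, reason = reason)

  miss <- is.na(oy$variant_id)
  if (any(miss)) excl <- c(excl, list(note(variant_ids[miss], "missing_in_outcome")))

  keep <- !miss
  beta_y <- oy$beta
  se_y <- oy$se
  eaf_y <- oy$eaf
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in which(keep)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- oy$effect_allele[i]; oa_y <- oy$other_allele[i]
    if (pal[i]) {
      # palindromic: alleles cannot distinguish strand; use allele frequency
      pal_y <- is_palindromic(ea_y, oa_y) &&
        (ea_y == ea_x || ea_y == oa_x)
      if (!pal_y) {
        keep[i] <- FALSE
        excl <- c(excl, list(note(variant_ids[i], "allele_mismatch")))
        next
      }
      ambiguous <- is.na(ex$eaf[i]) || is.na(eaf_y[i]) ||
        abs(ex$eaf[i] - 0.5) < palindrome_eaf_window ||
        abs(eaf_y[i] - 0.5) < palindrome_eaf_window
      if (ambiguous) {
        keep[i] <- FALSE
        excl <- c(excl, list(note(variant_ids[i], "palindromic_ambiguous")))
        next
      }
      # frequency side alone identifies the measured allele: allele labels
      # carry no strand information for palindromes
      same_side <- (ex$eaf[i] - 0.5) * (eaf_y[i] - 0.5) > 0
      if (!same_side) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
      }
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      next
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
    } else {
      cea <- allele_complement(ea_y); coa <- allele_complement(oa_y)
      if (cea == ea_x && coa == oa_x) {
        # strand flip only; effect allele unchanged
      } else if (cea == oa_x && coa == ea_x) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
      } else {
        keep[i] <- FALSE
        excl <- c(excl, list(note(variant_ids[i], "allele_mismatch")))
      }
    }
  }

  exclusions <- if (length(excl)) bind_rows(excl) else
    tibble(variant_id = character(), reason = character())

  if (!any(keep)) {
    reasons <- paste(sprintf("%s (%s)", exclusions$variant_id, exclusions$reason),
                     collapse = "; ")
    abort(paste0("no variants survive harmonization: ", reasons),
          class = "tmr_data_error")
  }

  out <- tibble(
    variant_id = variant_ids[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_x = ex$beta[keep],
    se_x = ex$se[keep],
    beta_y = beta_y[keep],
    se_y = se_y[keep],
    eaf_x = ex$eaf[keep],
    eaf_y = eaf_y[keep]
  )
  structure(out,
            exposure_label = trait_label(exposure),
            outcome_label = trait_label(outcome),
            outcome_type = trait_type(outcome),
            exclusions = exclusions,
            class = c("tmr_harmonized", class(out)))
}

#' Pairwise LD from a reference dosage matrix
#'
#' Computes the Pearson correlation `r` (not r-squared) between variant
#' dosage columns of a reference panel.
#'
#' @param genotypes Numeric matrix, individuals in rows, variants in
#'   columns; column names are variant ids.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(genotypes)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    abort(paste0("constant dosage column(s): ", paste(bad, collapse = ", ")),
          class = "tmr_data_error")
  }
  r <- cor(genotypes)
  diag(r) <- 1
  r
}
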