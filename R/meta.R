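# Inverse-variance meta-analysis, Bonferroni, batch screens ---------------

meta_row <- function(beta, se, q, tau2, mode, k, inputs) {
  structure(tibble(
    beta = beta, se = se,
    ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
    pval = p_normal(beta, se),
    odds_ratio = exp(beta), or_low = exp(beta - CI_Z * se),
    or_high = exp(beta + CI_Z * se),
    q = q, q_pval = pchisq(q, df = k - 1, lower.tail = FALSE),
    tau2 = tau2, mode = mode, k = as.integer(k)
  ), inputs = inputs, class = c("tmr_meta", class(tibble())))
}

check_meta_inputs <- function(estimates) {
  estimates <- as_tibble(estimates)
  stopifnot(all(c("beta", "se") %in% names(estimates)))
  if (nrow(estimates) < 2) abort("need at least 2 estimates to pool",
                                 class = "tmr_data_error")
  if (any(estimates$se <= 0)) abort("all ses must be > 0",
                                    class = "tmr_data_error")
  if (!"label" %in% names(estimates)) {
    estimates$label <- paste0("study_", seq_len(nrow(estimates)))
  }
  estimates
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools estimates with weights `1/se^2`. The exponentiated columns give
#' the pooled odds ratio when the inputs are log-odds (or, for a
#' quantitative trait expressed multiplicatively, the fold change).
#'
#' @param estimates Data frame with columns `beta`, `se` and optionally
#'   `label`.
#' @return One-row `tmr_meta` tibble with pooled beta, se, CI, OR columns,
#'   Cochran's Q and `tau2 = 0`.
#' @export
#' @examples
#' meta_fixed(data.frame(beta = c(-0.84, -0.40),
#'                       se = c(1.40, 0.96) / (2 * 1.96)))
meta_fixed <- function(estimates) {
  e <- check_meta_inputs(estimates)
  w <- 1 / e$se^2
  beta <- sum(w * e$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (e$beta - beta)^2)
  meta_row(beta, se, q, 0, "fixed", nrow(e), e)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`; pooling then uses `1/(se^2 + tau2)`. Homogeneous
#' inputs (Q <= df) reduce exactly to the fixed-effect result.
#'
#' @inheritParams meta_fixed
#' @return One-row `tmr_meta` tibble.
#' @export
meta_dl_random <- function(estimates) {
  e <- check_meta_inputs(estimates)
  w <- 1 / e$se^2
  beta_f <- sum(w * e$beta) / sum(w)
  q <- sum(w * (e$beta - beta_f)^2)
  df <- nrow(e) - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (e$se^2 + tau2)
  beta <- sum(wr * e$beta) / sum(wr)
  se <- sqrt(1 / sum(wr))
  meta_row(beta, se, q, tau2, "dl_random", nrow(e), e)
}

#' Convert a reported 95% confidence interval to a standard error
#'
#' `(upper - lower) / (2 * 1.96)`; used when ingesting literature-style
#' estimates reported as point estimate plus interval.
#'
#' @param lower,upper Interval bounds on the beta (log) scale.
#' @return Standard error.
#' @export
ci_to_se <- function(lower, upper) (upper - lower) / (2 * CI_Z)

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 1400)
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Filter a long association table at a Bonferroni threshold
#'
#' Generic lookup-and-correct screen over a precomputed SNP-by-trait
#' association table (as exported by phenome-wide databases): flags rows
#' with `p < alpha / n_tests`. By default `n_tests` is the number of rows
#' (e.g. SNPs x traits queried).
#'
#' @param associations Data frame with at least columns `snp`, `trait`,
#'   `pval`.
#' @param alpha Family-wise error rate.
#' @param n_tests Total number of tests corrected for; defaults to
#'   `nrow(associations)`.
#' @return The input with `significant` and `adjusted_alpha` columns added.
#' @export
phewas_lookup <- function(associations, alpha = 0.05,
                          n_tests = nrow(associations)) {
  a <- as_tibble(associations)
  stopifnot(all(c("snp", "trait", "pval") %in% names(a)))
  thr <- bonferroni_alpha(alpha, n_tests)
  a$adjusted_alpha <- thr
  a$significant <- a$pval < thr
  a
}

#' Batch-MR screen of one instrument set across many outcomes
#'
#' Harmonizes the instrument set against each outcome and runs the MR
#' estimators, flagging outcomes whose primary (IVW) p-value falls below
#' the Bonferroni-adjusted threshold `alpha / n_tests`. Outcomes that fail
#' harmonization are reported with a failure code and still count toward
#' `n_tests`.
#'
#' @param instruments A `tmr_instruments` tibble.
#' @param outcomes Named list of `tmr_gwas` outcome tables.
#' @param alpha Family-wise error rate (default 0.05).
#' @param seed Integer seed driving the per-outcome estimator suites.
#' @param methods Estimators to run per outcome; the first IVW entry is
#'   the significance-bearing method. MR-PRESSO is omitted by default for
#'   screen-scale tractability.
#' @param n_boot Weighted-median bootstrap size when that method is
#'   requested.
#' @return A tibble of class `tmr_screen`, one row per outcome per method
#'   (plus one row per failed outcome), with columns from the `tmr_mr`
#'   rows plus `outcome`, `status`, `significant`; attributes `n_tests`,
#'   `alpha`, `adjusted_alpha`.
#' @export
screen_outcomes <- function(instruments, outcomes, alpha = 0.05, seed,
                            methods = c("ivw", "egger"), n_boot = 200) {
  if (length(outcomes) == 0) abort("no outcome tables supplied",
                                   class = "tmr_data_error")
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- vapply(outcomes, trait_label, character(1))
  }
  n_tests <- length(outcomes)
  thr <- bonferroni_alpha(alpha, n_tests)

  rows <- purrr::imap(outcomes, function(out_tbl, label) {
    res <- tryCatch({
      h <- harmonize_pair(instruments, out_tbl)
      est <- purrr::map(methods, function(m) {
        switch(m,
          ivw = ivw(h),
          egger = mr_egger(h),
          weighted_median = weighted_median(h, n_boot = n_boot, seed = seed),
          abort(paste0("unknown method: ", m), class = "tmr_config_error"))
      })
      bind_rows(est) %>%
        mutate(outcome = label, status = "ok", .before = 1)
    }, tmr_data_error = function(e) {
      tibble(outcome = label, status = paste0("failed: ", conditionMessage(e)))
    })
    res
  })
  out <- bind_rows(rows)
  if (all(out$status != "ok")) {
    abort("every outcome failed harmonization", class = "tmr_data_error")
  }
  if (!"method" %in% names(out)) out$method <- NA_character_
  primary <- !is.na(out$method) & grepl("^ivw", out$method)
  out$significant <- ifelse(out$status == "ok" & primary,
                            out$pval < thr, NA)
  structure(out, n_tests = n_tests, alpha = alpha, adjusted_alpha = thr,
            class = c("tmr_screen", class(out)))
}

#' @method tidy tmr_screen
#' @export
tidy.tmr_screen <- function(x, ...) as_tibble(x)

#' @method glance tmr_screen
#' @export
glance.tmr_screen <- function(x, ...) {
  tibble(n_tests = attr(x, "n_tests"), alpha = attr(x, "alpha"),
         adjusted_alpha = attr(x, "adjusted_alpha"),
         n_significant = sum(x$significant, na.rm = TRUE),
         n_failed = sum(x$status != "ok") )
}

#' @method tidy tmr_meta
#' @export
tidy.tmr_meta <- function(x, ...) as_tibble(x)

#' @method glance tmr_meta
#' @export
glance.tmr_meta <- function(x, ...) {
  as_tibble(x)[c("beta", "se", "odds_ratio", "or_low", "or_high",
                 "q", "tau2", "mode", "k")]
}
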