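# Approximate-Bayes-factor colocalization --------------------------------

#' Wakefield log approximate Bayes factor
#'
#' For a single variant with estimate `beta`, standard error `se` and a
#' normal effect prior with standard deviation `prior_sd`, the log
#' approximate Bayes factor against the null is
#' `0.5 * (log(V/(V+W)) + z^2 * W/(V+W))` with `V = se^2`, `W = prior_sd^2`
#' and `z = beta/se`.
#'
#' @param beta,se Estimate and standard error (`se > 0`). Vectorized.
#' @param prior_sd Prior standard deviation of the true effect (> 0).
#' @return Log ABF, same length as `beta`.
#' @export
wakefield_labf <- function(beta, se, prior_sd = 0.15) {
  stopifnot(all(se > 0), prior_sd > 0)
  V <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + W)) + z2 * W / (V + W))
}

log_sum_exp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, guarding tiny negative round-off
log_diff_exp <- function(a, b) {
  d <- 1 - exp(b - a)
  if (d <= 0) return(-Inf)
  a + log(d)
}

#' Colocalization of two traits in a region via approximate Bayes factors
#'
#' Computes posterior probabilities for the five regional hypotheses:
#' H0 no association with either trait; H1/H2 association with one trait
#' only; H3 both traits, distinct causal variants; H4 both traits sharing
#' one causal variant. Per-variant evidence comes from [wakefield_labf()];
#' hypothesis sums are combined with the single-variant priors `p1`, `p2`,
#' `p12` and normalized with log-sum-exp so large z-scores cannot overflow.
#'
#' @param trait1,trait2 Data frames with columns `beta` and `se`, one row
#'   per variant, covering the same variants in the same order.
#' @param p1,p2 Prior probability a variant is causal for trait 1 (2) only.
#' @param p12 Prior probability a variant is causal for both traits.
#' @param prior_sd1,prior_sd2 Effect-size prior sd per trait.
#' @param h4_threshold Posterior-probability cutoff for declaring
#'   colocalization (default 0.70; the decision is `PP.H4 > threshold`).
#' @return An object of class `tmr_coloc`: list with `pp` (named numeric,
#'   PP.H0..PP.H4), `n_variants`, `priors`, `colocalized`.
#' @export
#' @examples
#' coloc_abf(data.frame(beta = c(0.8, 0.1), se = c(0.1, 0.1)),
#'           data.frame(beta = c(0.5, 0.0), se = c(0.06, 0.06)))
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15,
                      h4_threshold = 0.70) {
  if (nrow(trait1) != nrow(trait2)) {
    abort("trait1 and trait2 must cover the same variants in the same order",
          class = "tmr_data_error")
  }
  if (nrow(trait1) < 1) abort("at least one variant required",
                              class = "tmr_data_error")
  l1 <- wakefield_labf(trait1$beta, trait1$se, prior_sd1)
  l2 <- wakefield_labf(trait2$beta, trait2$se, prior_sd2)

  s1 <- log_sum_exp(l1)                 # sum_i ABF1_i
  s2 <- log_sum_exp(l2)                 # sum_j ABF2_j
  s12 <- log_sum_exp(l1 + l2)           # sum_i ABF1_i ABF2_i (same variant)

  lh <- c(
    H0 = 0,
    H1 = log(p1) + s1,
    H2 = log(p2) + s2,
    H3 = log(p1) + log(p2) + log_diff_exp(s1 + s2, s12),
    H4 = if (p12 > 0) log(p12) + s12 else -Inf
  )
  denom <- log_sum_exp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("PP.", names(lh))

  structure(list(
    pp = pp,
    n_variants = nrow(trait1),
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    h4_threshold = h4_threshold,
    colocalized = unname(pp["PP.H4"] > h4_threshold)
  ), class = "tmr_coloc")
}

#' @export
print.tmr_coloc <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants (p1=%g, p2=%g, p12=%g)\n",
              x$n_variants, x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  print(round(x$pp, 4))
  cat(sprintf("colocalized (PP.H4 > %.2f): %s\n", x$h4_threshold,
              x$colocalized))
  invisible(x)
}

#' @method tidy tmr_coloc
#' @export
tidy.tmr_coloc <- function(x, ...) {
  tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @method glance tmr_coloc
#' @export
glance.tmr_coloc <- function(x, ...) {
  tibble(n_variants = x$n_variants,
         pp_h4 = unname(x$pp["PP.H4"]),
         colocalized = x$colocalized)
}
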