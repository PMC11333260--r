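---
title: "Drug-target Mendelian randomization with metabolite mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with metabolite mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Whether inhibiting a pharmacological target (for example SGLT2, the
sodium-glucose cotransporter encoded by *SLC5A2*) changes the risk of a
disease, and how much of that change flows through a circulating
metabolite, can be asked genetically. Variants in or near the target gene
that alter its expression and shift a downstream biomarker (HbA1c for
SGLT2) act as lifelong, randomized mini-exposures to target inhibition.
`targetmr` implements the full analysis chain on GWAS summary statistics:

1. **Instrument construction** — cis variants associated with target-gene
   expression and with the biomarker, checked for a shared causal signal
   by colocalization, thinned by LD clumping, and sign-inverted so the
   instrument set proxies pharmacological *inhibition*.
2. **Two-sample MR** — IVW as the primary estimator with weighted-median,
   MR-Egger and MR-PRESSO sensitivity analyses.
3. **Mediation** — two-step MR plus multivariable MR to decompose the
   total effect into mediated and direct components and report the
   proportion mediated.
4. **Replication and screening** — inverse-variance meta-analysis across
   replicate mediator datasets and Bonferroni-controlled batch-MR screens
   over many outcomes.
5. **Synthetic data** — summary-level generators with known causal truth
   for every stage, so the whole pipeline is testable without any
   external download.

## Models and estimators

### Harmonization

All estimators consume a harmonized set: per instrument $j$, the
exposure association $(\hat\beta_{Xj}, \sigma_{Xj})$ and the outcome
association $(\hat\beta_{Yj}, \sigma_{Yj})$ expressed on the same effect
allele. Alignment handles label swaps (negate), strand complements
(relabel) and their combination. Palindromic variants (A/T, C/G) carry no
strand information in their labels; they are resolved by comparing which
side of 0.5 the effect-allele frequencies fall on, and excluded when
either frequency is missing or within 0.08 of 0.5. The 0.08 half-width is
the common two-sample MR convention; it is a parameter
(`palindrome_eaf_window`) because the right value depends on the ancestry
match between datasets.

### IVW and diagnostics

With ratio estimates $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ and
first-order weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, the IVW
estimate is $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, identical to
a weighted regression of outcome on exposure betas through the origin.
Cochran's $Q = \sum w_j(\hat\theta_j - \hat\theta)^2$ is referred to
$\chi^2_{k-1}$. The default standard error is multiplicative
random-effects: the fixed-effect $(\sum w_j)^{-1/2}$ inflated by
$\max(1, \sqrt{Q/(k-1)})$ — the dominant convention in two-sample MR
software, retained here because the floor at 1 never rewards
underdispersion. The fixed mode is available and recorded in run reports.

MR-Egger refits with an intercept after orienting every instrument to a
non-negative exposure beta; the intercept estimates the average
directional pleiotropic effect and its test is the pleiotropy diagnostic.
The weighted median inverts the weighted empirical CDF of the
$\hat\theta_j$ at 0.5 and is consistent while valid instruments carry
more than half the weight; its standard error comes from a parametric
bootstrap (betas redrawn at their observed means and ses) with a
mandatory seed. MR-PRESSO simulates the no-pleiotropy model `n_sim` times
to calibrate the observed leave-one-out residual sum of squares (global
test), flags instruments whose squared residual is extreme after
Bonferroni correction over $k$ (outlier test, single pass), and compares
the raw-versus-corrected estimate shift against random same-size
removals (distortion test). All empirical p-values use the add-one
estimator so they are bounded below by $1/(n_\text{sim}+1)$.

### Colocalization

Per-variant evidence is the Wakefield log approximate Bayes factor
$\tfrac12[\log\frac{V}{V+W} + z^2\frac{W}{V+W}]$ with $V$ the squared
standard error and $W$ the squared prior effect sd. Regional hypotheses
H0–H4 are accumulated from these lABFs with single-variant priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the canonical defaults, kept
because the source analyses name no values — and normalized with
log-sum-exp so $|z| > 30$ cannot overflow. The decision rule is
PP.H4 > 0.70, applied strictly and to PP.H4 alone. Note the lABF depends
on $V$ and $W$ separately, not only on $z$: rescaling a trait's units
leaves the posteriors unchanged only if the prior sd is rescaled with
them, which is how the invariance is tested.

### Mediation

For exposure $X$, mediator $M$ and outcome $Y$: $\beta_1$ (X→M),
$\beta_2$ (M→Y, univariable) and $\beta_3$ (X→Y, total) are IVW
estimates; $\beta_2'$ re-estimates M→Y conditional on X by multivariable
IVW (weighted regression of outcome betas on both exposures' betas, no
intercept) over the union of the exposure and mediator instruments. The
proportion mediated is $\beta_1\beta_2'/\beta_3$ (and
$\beta_1\beta_2/\beta_3$ for the unadjusted variant). Proportions are
reported signed and unclamped — a value outside $[0,1]$ is a warning,
because inconsistent path signs are a finding, not an input error. The
instrument union (rather than exposure instruments alone) is the default
because the conditional mediator effect is unidentified without variants
that move the mediator independently of the exposure; the choice is an
argument. No confidence interval is attached to the proportion by
default; a first-order delta-method se would ignore cross-GWAS
covariances and so is deliberately not reported.

## The synthetic-data generator

`simulate_mediation_gwas()` draws independent instruments with per-SNP
effects $|b_{Xj}| \in 0.05\times[0.5, 1.5]$ coded on the
exposure-increasing allele (the orientation MR-Egger assumes when
pleiotropy is directional), propagates them through the structural DAG
$(\theta_{XM}, \theta_{MY}, \theta_\text{direct})$, and adds sampling
noise at $1/\sqrt{n}$ per trait. Defaults: exposure GWAS $n = 344{,}182$
(the scale of the HbA1c biomarker GWAS used to weight SGLT2-inhibition
proxies), mediator and outcome GWAS $n = 100{,}000$, ten exposure and ten
mediator instruments — giving per-SNP F statistics in the hundreds.
Pleiotropy regimes add per-instrument direct effects on the outcome:
`balanced` (mean zero) or `directional` (nonzero mean), optionally on a
fraction of instruments only. `simulate_region()` generates the
colocalization test bed: AR(1) LD ($r_{ij} = \rho^{|i-j|}$, default
$\rho = 0.5$, 50 variants), one causal variant per trait (shared or
$\geq$ 10 positions apart), marginal betas equal to LD-propagated joint
effects plus multivariate normal noise with covariance LD$/n$.

Summary statistics are generated directly at summary level rather than
from individual genotypes — faster, and exactly the distribution every
estimator here consumes; an individual-level path exists only to test
`ld_matrix()`. What the generator does *not* emulate: realistic allele
frequency spectra, imputation error, overlapping GWAS samples (the real
biomarker and some outcome datasets share UK Biobank participants), or
liability-scale case-control effects (binary outcomes are simulated on
the log-odds scale directly). Passing tests therefore demonstrate
correctness of the estimators under clean two-sample assumptions, not
robustness to those real-data complications.

## Numerical and design choices

- **Duplicate variant ids** on input keep the smallest-p row, ties by
  file order — deterministic and assertable.
- **Clumping** is greedy by ascending p with ties broken by position then
  id, so the result is invariant to input row order. The drug-target
  profile deliberately exposes the lenient $r^2 < 0.8$/1,000 kb setting
  used for cis instruments; because the estimators assume independent
  instruments, any retained pair with $r^2 > 0.1$ triggers a warning.
  Correlated-instrument (generalized least squares) estimation is out of
  scope.
- **Confidence intervals** use 1.96 throughout; p-values are two-sided
  normal, consistent with summary-data MR practice.
- **Every stochastic routine takes an explicit seed**; no function reads
  or perturbs the global RNG state un-seeded, and identical calls are
  bit-identical.
- **F statistics** are per-SNP squared z-scores; the weak-instrument
  flag uses the conventional F < 10.

## Problem sizes used in the test-suite

Calibration and recovery checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerance being asserted: 500 replicates for
IVW bias/coverage, 300 for the invalid-instrument weighted-median
comparison, 200 per truth setting for mediation recovery, 100 seeds per
colocalization scenario and for MR-PRESSO detection, and 500 null panels
of 20 outcomes for screen calibration.

## Known limitations

- First-order Wald-ratio weights ignore exposure-beta uncertainty
  (the NOME approximation). With exposure and outcome GWAS of equal size
  and moderate effects this measurably under-covers (the ratio variance
  carries a $\beta^2\sigma_X^2/\sigma_Y^2$ term); with the default
  larger exposure GWAS the approximation is good.
- MR-PRESSO's outlier removal is single-pass by design; heavily
  contaminated sets (>50% invalid weight) defeat both it and the
  weighted median.
- Colocalization assumes at most one causal variant per trait per
  region; multi-causal architectures dilute PP.H4.
- The screen's Bonferroni control is family-wise and strict-inequality;
  no FDR option is provided.
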