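test_that("read_sumstats reads, validates and maps columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(
    rsid = c("rs1", "rs2", "rs3"), chr = "16", bp = c(100L, 200L, 300L),
    ea = c("A", "C", "T"), oa = c("G", "T", "G"),
    freq = c(0.2, 0.3, 0.4), b = c(0.1, -0.2, 0.05),
    stderr = c(0.02, 0.03, 0.02), p = c(1e-6, 1e-8, 0.01), nobs = 1000L
  ), f)
  cmap <- c(variant_id = "rsid", chrom = "chr", pos = "bp",
            effect_allele = "ea", other_allele = "oa", eaf = "freq",
            beta = "b", se = "stderr", pval = "p", n = "nobs")
  g <- read_sumstats(f, cmap, trait_label = "toy")
  expect_s3_class(g, "tmr_gwas")
  expect_equal(nrow(g), 3)
  expect_equal(g$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(g$beta, c(0.1, -0.2, 0.05))

  # mapping a column that does not exist is a configuration error
  expect_error(read_sumstats(f, c(cmap[-1], chrom = "nope")),
               class = "tmr_config_error")
})

test_that("rows violating invariants are dropped and counted", {
  d <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
    pos = 1:4, effect_allele = c("A", "C", "G", "A"),
    other_allele = c("G", "T", "G", "T"),
    beta = 0.1, se = c(0.02, 0, 0.02, 0.02), pval = c(0.01, 0.01, 0.01, 0.01)
  )
  g <- gwas_table(d, "toy")  # rs2: se = 0; rs3: identical alleles
  expect_equal(nrow(g), 2)
  log <- attr(g, "drop_log")
  expect_equal(log$n[log$reason == "invalid_se"], 1)
  expect_equal(log$n[log$reason == "identical_alleles"], 1)
  expect_error(gwas_table(d[2, ], "toy"), class = "tmr_data_error")
  expect_error(gwas_table(d[, -2], "toy"), class = "tmr_config_error")
})

test_that("duplicate variant ids keep the smallest-p row, ties by file order", {
  d <- data.frame(
    variant_id = c("rs1", "rs1", "rs2", "rs2"), chrom = "1", pos = 1:4,
    effect_allele = "A", other_allele = "G",
    beta = c(1, 2, 3, 4), se = 0.1, pval = c(0.5, 0.01, 0.2, 0.2)
  )
  # oracle: order by p then original position, take first per id
  oracle <- d[order(d$pval), ]
  oracle <- oracle[!duplicated(oracle$variant_id), ]
  g <- gwas_table(d, "toy")
  expect_equal(nrow(g), 2)
  expect_equal(attr(g, "drop_log")$n[5], 2)  # duplicate_id count
  expect_equal(g$beta[g$variant_id == "rs1"],
               oracle$beta[oracle$variant_id == "rs1"])
  expect_equal(g$beta[g$variant_id == "rs2"], 3)  # tie: first in file
})

test_that("harmonization follows the allele rule table", {
  # exposure is A/G throughout; outcome configurations and expected action
  cases <- tibble::tribble(
    ~ea_y, ~oa_y, ~sign, ~kept,
    "A", "G",  1, TRUE,   # identical
    "G", "A", -1, TRUE,   # swapped
    "T", "C",  1, TRUE,   # strand flip
    "C", "T", -1, TRUE,   # strand flip + swap
    "A", "C", NA, FALSE   # mismatch
  )
  for (i in seq_len(nrow(cases))) {
    ex <- make_gwas("rs1", beta = 0.1, se = 0.01)
    oy <- make_gwas("rs1", beta = 0.2, se = 0.02,
                    effect_allele = cases$ea_y[i],
                    other_allele = cases$oa_y[i], eaf = 0.3)
    if (cases$kept[i]) {
      h <- harmonize_pair(ex, oy)
      expect_equal(h$beta_y, cases$sign[i] * 0.2, info = paste("case", i))
      expect_equal(h$eaf_y, if (cases$sign[i] == 1) 0.3 else 0.7)
    } else {
      expect_error(harmonize_pair(ex, oy), class = "tmr_data_error")
    }
  }
})

test_that("palindromic variants are excluded in the ambiguity window, resolved outside it", {
  pal_ex <- function(eaf) make_gwas("rs1", beta = 0.1, se = 0.01,
                                    effect_allele = "A", other_allele = "T",
                                    eaf = eaf)
  pal_oy <- function(eaf) make_gwas("rs1", beta = 0.2, se = 0.02,
                                    effect_allele = "A", other_allele = "T",
                                    eaf = eaf)
  # eaf = 0.5: ambiguous, excluded
  expect_error(harmonize_pair(pal_ex(0.5), pal_oy(0.5)),
               class = "tmr_data_error")
  # eaf just inside the default 0.08 window: excluded
  expect_error(harmonize_pair(pal_ex(0.45), pal_oy(0.45)),
               class = "tmr_data_error")
  # missing eaf on a palindrome: excluded
  expect_error(harmonize_pair(pal_ex(NA), pal_oy(0.2)),
               class = "tmr_data_error")
  # same frequency side: kept unchanged
  h <- harmonize_pair(pal_ex(0.2), pal_oy(0.25))
  expect_equal(h$beta_y, 0.2)
  # opposite sides: the outcome measured the complementary allele
  h2 <- harmonize_pair(pal_ex(0.2), pal_oy(0.8))
  expect_equal(h2$beta_y, -0.2)
  expect_equal(h2$eaf_y, 0.2)
  # a narrower window admits the 0.45 case
  h3 <- harmonize_pair(pal_ex(0.45), pal_oy(0.45),
                       palindrome_eaf_window = 0.01)
  expect_equal(h3$beta_y, 0.2)
})

test_that("variants absent from the outcome are excluded and logged", {
  ex <- make_gwas(c("rs1", "rs2"), beta = c(0.1, 0.2), se = c(0.01, 0.01))
  oy <- make_gwas("rs1", beta = 0.3, se = 0.02)
  h <- harmonize_pair(ex, oy)
  expect_equal(h$variant_id, "rs1")
  excl <- attr(h, "exclusions")
  expect_equal(excl$variant_id, "rs2")
  expect_equal(excl$reason, "missing_in_outcome")
  expect_error(harmonize_pair(ex[2, ], oy), class = "tmr_data_error")
})

test_that("harmonization is idempotent and a double allele swap is exact", {
  ex <- make_gwas(c("rs1", "rs2"), beta = c(0.1, -0.3), se = c(0.01, 0.02),
                  effect_allele = c("A", "C"), other_allele = c("G", "T"),
                  eaf = c(0.2, 0.4))
  oy <- make_gwas(c("rs1", "rs2"), beta = c(0.2, 0.5), se = c(0.02, 0.05),
                  effect_allele = c("G", "T"), other_allele = c("A", "C"),
                  eaf = c(0.8, 0.6))
  h1 <- harmonize_pair(ex, oy)
  # rebuild the aligned outcome as a gwas table and harmonize again
  aligned <- make_gwas(h1$variant_id, beta = h1$beta_y, se = h1$se_y,
                       effect_allele = h1$effect_allele,
                       other_allele = h1$other_allele, eaf = h1$eaf_y)
  h2 <- harmonize_pair(ex, aligned)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$eaf_y, h1$eaf_y)
  # double swap: swapping the already-swapped table recovers the original
  swapped_back <- make_gwas(h1$variant_id, beta = -h1$beta_y, se = h1$se_y,
                            effect_allele = h1$other_allele,
                            other_allele = h1$effect_allele,
                            eaf = 1 - h1$eaf_y)
  h3 <- harmonize_pair(ex, swapped_back)
  expect_identical(h3$beta_y, h1$beta_y)
  expect_identical(h3$eaf_y, h1$eaf_y)
})

test_that("ld_matrix returns signed correlations with PSD structure", {
  withr::local_seed(11)
  g <- matrix(rbinom(10000 * 2, 2, 0.3), ncol = 2,
              dimnames = list(NULL, c("v1", "v2")))
  r <- ld_matrix(g)
  expect_equal(diag(r), c(v1 = 1, v2 = 1))
  expect_lt(abs(r["v1", "v2"]), 0.05)     # independent columns
  expect_true(isSymmetric(r))

  # duplicated and anti-correlated columns
  g3 <- cbind(a = g[, 1], b = g[, 1], c = -g[, 1])
  r3 <- ld_matrix(g3)
  expect_equal(r3["a", "b"], 1)
  expect_equal(r3["a", "c"], -1)
  expect_gte(min(eigen(r3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  g_bad <- cbind(g, fixed = rep(1, nrow(g)))
  expect_error(ld_matrix(g_bad), class = "tmr_data_error")
  expect_error(ld_matrix(g_bad), "fixed")
})
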