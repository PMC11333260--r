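test_that("wald_ratio arithmetic and degenerate guard", {
  w <- wald_ratio(1, 0.1, 0.5, 0.1)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(-1, 0.1, 0.5, 0.1)$beta, -0.5)
  w2 <- wald_ratio(2, 0.1, 1.0, 0.1)
  expect_equal(w2$beta, 0.5)
  expect_equal(w2$se, 0.05)
  expect_error(wald_ratio(0, 0.1, 0.5, 0.1), class = "tmr_data_error")
})

test_that("IVW pools ratio estimates with exposure-scaled outcome weights", {
  # two instruments with identical ratios: no heterogeneity
  h <- make_hset(c(1, 2), c(0.01, 0.01), c(0.5, 1.0), c(0.1, 0.1))
  fit <- ivw(h, mode = "fixed")
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$q, 0)
  expect_equal(fit$se, 1 / sqrt(500))  # weights 100 and 400

  # symmetric split ratios: beta 0.5, Q = 2 against chi-square(1)
  h2 <- make_hset(c(1, 1), c(0.01, 0.01), c(0.4, 0.6), c(0.1, 0.1))
  fit2 <- ivw(h2, mode = "fixed")
  expect_equal(fit2$beta, 0.5)
  expect_equal(fit2$q, 2)
  expect_equal(fit2$q_pval, pchisq(2, 1, lower.tail = FALSE))
  # multiplicative random effects inflates by sqrt(Q/(k-1)), floored at 1
  fit2r <- ivw(h2)
  expect_equal(fit2r$se, fit2$se * sqrt(2))
  expect_equal(ivw(h)$se, fit$se)  # floor: no deflation below fixed
  expect_error(ivw(h[1, ]), class = "tmr_data_error")
  expect_error(ivw(make_hset(c(0, 1), c(0.1, 0.1), c(0, 1), c(0.1, 0.1))),
               class = "tmr_data_error")
})

test_that("IVW reduces to the Wald ratio and is allele-flip invariant", {
  # a duplicated instrument pools to the single-instrument Wald ratio
  h <- make_hset(c(1.3, 1.3), c(0.02, 0.02), c(0.7, 0.7), c(0.09, 0.09))
  expect_equal(ivw(h, mode = "fixed")$beta, wald_ratio(1.3, 0.02, 0.7, 0.09)$beta)
  expect_equal(ivw(h, mode = "fixed")$se,
               wald_ratio(1.3, 0.02, 0.7, 0.09)$se / sqrt(2))

  withr::local_seed(8)
  h2 <- make_hset(rnorm(6, 0.1, 0.02), rep(0.01, 6),
                  rnorm(6, -0.05, 0.02), rep(0.02, 6))
  flip <- h2
  flip$beta_x[c(2, 5)] <- -flip$beta_x[c(2, 5)]
  flip$beta_y[c(2, 5)] <- -flip$beta_y[c(2, 5)]
  expect_equal(ivw(flip)$beta, ivw(h2)$beta, tolerance = 1e-12)
  expect_equal(ivw(flip)$se, ivw(h2)$se, tolerance = 1e-12)
})

test_that("MR-Egger recovers an exact line and matches normal equations", {
  h <- make_hset(c(1, 2, 3), rep(0.01, 3), 0.1 + 0.5 * c(1, 2, 3),
                 rep(0.1, 3))
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$q, 0, tolerance = 1e-16)

  # no-intercept line: intercept estimate is numerically zero
  h0 <- make_hset(c(1, 2, 3), rep(0.01, 3), 0.5 * c(1, 2, 3), rep(0.1, 3))
  expect_equal(mr_egger(h0)$egger_intercept, 0, tolerance = 1e-12)

  # random 6-instrument set against an explicit 2x2 normal-equations solve
  withr::local_seed(13)
  h6 <- make_hset(abs(rnorm(6, 0.2, 0.05)), rep(0.01, 6),
                  rnorm(6, 0.1, 0.1), runif(6, 0.05, 0.2))
  fit6 <- mr_egger(h6)
  W <- diag(1 / h6$se_y^2)
  X <- cbind(1, h6$beta_x)
  theta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% h6$beta_y)
  expect_equal(fit6$egger_intercept, theta[1], tolerance = 1e-10)
  expect_equal(fit6$beta, theta[2], tolerance = 1e-10)
  expect_error(mr_egger(h6[1:2, ]), class = "tmr_data_error")
})

test_that("MR-Egger orients instruments to non-negative exposure betas", {
  withr::local_seed(14)
  h <- make_hset(rnorm(8, 0.1, 0.1), rep(0.01, 8), rnorm(8, 0, 0.1),
                 rep(0.08, 8))
  flipped <- h
  flipped$beta_x <- -flipped$beta_x
  flipped$beta_y <- -flipped$beta_y
  expect_equal(mr_egger(flipped)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$egger_intercept, mr_egger(h)$egger_intercept,
               tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # equal weights over ratios {0.1, 0.2, 0.3}: cumulative midpoints hit 1/2
  # exactly at the middle ratio
  h <- make_hset(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.3), rep(0.1, 3))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2)
  # constant ratios
  h2 <- make_hset(c(1, 2, 4), rep(0.01, 3), c(0.3, 0.6, 1.2), rep(0.1, 3))
  expect_equal(weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.3)
  # weight concentrated on one instrument
  h3 <- make_hset(c(1, 1, 1), rep(0.01, 3), c(0.15, 0.5, 0.9),
                  c(0.01, 1, 1))
  expect_equal(weighted_median(h3, n_boot = 50, seed = 1)$beta, 0.15,
               tolerance = 0.01)
  # seeded bootstrap is reproducible
  expect_identical(weighted_median(h, n_boot = 200, seed = 42)$se,
                   weighted_median(h, n_boot = 200, seed = 42)$se)
  expect_error(weighted_median(h[1:2, ], n_boot = 50, seed = 1),
               class = "tmr_data_error")
})

test_that("the estimator suite agrees on consistent data and honours the binary flag", {
  d <- make_consistent_pair(k = 10, slope = -0.5, seed = 77)
  ins <- instrument_set(d$exposure, d$exposure_ids)
  h <- harmonize_pair(ins, d$outcome)
  suite <- run_mr_suite(h, seed = 7, n_boot = 200, n_sim = 200)
  expect_setequal(suite$method,
                  c("ivw_mre", "weighted_median", "egger", "mr_presso"))
  iv <- suite[suite$method == "ivw_mre", ]
  for (m in c("weighted_median", "egger", "mr_presso")) {
    row <- suite[suite$method == m, ]
    expect_lt(abs(row$beta - iv$beta), 2 * (row$se + iv$se))
  }
  # outcome labeled binary: odds-ratio columns populated and consistent
  expect_equal(iv$odds_ratio, exp(iv$beta))
  expect_equal(iv$or_low, exp(iv$ci_low), tolerance = 1e-12)

  # quantitative outcome: no odds-ratio fields
  hq <- harmonize_pair(ins, d$mediator)
  sq <- run_mr_suite(hq, seed = 7, n_boot = 50, include_presso = FALSE)
  expect_true(all(is.na(sq$odds_ratio)))
  expect_equal(nrow(sq), 3)
})

test_that("Egger intercept test detects directional pleiotropy, not balanced", {
  n_rep <- 120
  hits_dir <- hits_bal <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    tr_dir <- simulation_truth(theta_xm = 0, theta_my = 0,
                               theta_direct = -0.5,
                               pleiotropy_mode = "directional",
                               pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                               seed = 1000 + i)
    d <- simulate_mediation_gwas(tr_dir, k_exposure_snps = 10,
                                 k_mediator_snps = 0)
    h <- harmonize_pair(instrument_set(d$exposure, d$exposure_ids), d$outcome)
    hits_dir[i] <- mr_egger(h)$intercept_pval < 0.05

    tr_bal <- simulation_truth(theta_xm = 0, theta_my = 0,
                               theta_direct = -0.5,
                               pleiotropy_mode = "balanced",
                               pleiotropy_sd = 0.01, seed = 3000 + i)
    db <- simulate_mediation_gwas(tr_bal, k_exposure_snps = 10,
                                  k_mediator_snps = 0)
    hb <- harmonize_pair(instrument_set(db$exposure, db$exposure_ids),
                         db$outcome)
    hits_bal[i] <- mr_egger(hb)$intercept_pval < 0.05
  }
  expect_gt(mean(hits_dir), 0.5)     # power under directional pleiotropy
  expect_gte(mean(hits_bal), 0.01)   # type-I error near nominal under
  expect_lte(mean(hits_bal), 0.10)   # balanced pleiotropy
})
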