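# Config-driven end-to-end pipeline ---------------------------------------

#' Default pipeline configuration
#'
#' Materializes every tunable setting of the end-to-end run so the run
#' report alone reproduces the analysis. The default `data` block is the
#' bundled synthetic scenario; replace it with a `files` block naming
#' delimited summary-statistics tables (plus column maps) to run on real
#' data.
#'
#' @param seed Mandatory integer seed for every stochastic stage.
#' @return A nested list of class `tmr_config`.
#' @export
pipeline_config <- function(seed) {
  if (missing(seed)) abort("seed is required", class = "tmr_config_error")
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      theta_xm = 0.4, theta_my = 0.25, theta_direct = -0.9,
      pleiotropy_mode = "none", pleiotropy_sd = 0, pleiotropy_mean = 0,
      n_exposure = 344182, n_mediator = 100000, n_outcome = 100000,
      k_exposure_snps = 10, k_mediator_snps = 10,
      instrument_strength = 0.05,
      region = list(m_variants = 50, ld_rho = 0.5, n1 = 10000, n2 = 344182,
                    shared_causal = TRUE, effect_size = 0.15)
    ),
    instruments = list(profile = "sglt2", cis_window_bp = 100000L,
                       expression_p = 1e-4, weak_f_threshold = 10),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                 prior_sd1 = 0.15, prior_sd2 = 0.15, h4_threshold = 0.70),
    estimators = list(ivw_mode = "multiplicative_random",
                      n_boot = 1000, n_sim = 1000),
    screen = list(n_outcomes = 20, n_true = 1, true_effect = -0.5,
                  alpha = 0.05),
    files = NULL
  ), class = "tmr_config")
}

#' Validate a pipeline configuration
#'
#' Fails fast — before any computation — on a missing seed, unknown
#' estimator mode, or referenced files that do not exist.
#'
#' @param config A `tmr_config` list (or plain list with the same shape).
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (is.null(config$seed)) abort("config$seed is required",
                                  class = "tmr_config_error")
  if (!config$estimators$ivw_mode %in% c("multiplicative_random", "fixed")) {
    abort("unknown ivw_mode", class = "tmr_config_error")
  }
  if (!is.null(config$files)) {
    paths <- unlist(lapply(config$files, function(f) f$path))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(paste0("dataset file(s) not found: ",
                   paste(missing, collapse = ", ")),
            class = "tmr_config_error")
    }
  }
  invisible(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the [pipeline_config()] structure; omitted
#'   keys take their defaults.
#' @return A validated `tmr_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) abort("config file must set seed",
                                class = "tmr_config_error")
  config <- pipeline_config(seed = user$seed)
  config <- utils::modifyList(config, user)
  class(config) <- "tmr_config"
  validate_config(config)
  config
}

stage_counts <- function(...) tibble(quantity = names(c(...)), n = unname(c(...)))

#' Run the drug-target MR pipeline end to end
#'
#' Executes, in order and with fail-fast semantics: data generation (or
#' loading), instrument construction with F statistics, regional
#' colocalization, the outcome MR estimator suite, two-step/MVMR
#' mediation, meta-analysis of the replicate mediator datasets, and the
#' phenome-wide batch-MR screen. Every stage's settings, intermediate
#' counts and estimates land in a machine-readable report; rerunning with
#' the same config yields a byte-identical report.
#'
#' @param config A `tmr_config` (see [pipeline_config()], [read_config()]).
#' @return A list of class `tmr_report` with elements `settings` and one
#'   block per stage.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  seed <- config$seed
  simcfg <- config$simulate

  # -- stage 1: data ------------------------------------------------------
  truth <- simulation_truth(
    theta_xm = simcfg$theta_xm, theta_my = simcfg$theta_my,
    theta_direct = simcfg$theta_direct,
    pleiotropy_mode = simcfg$pleiotropy_mode,
    pleiotropy_sd = simcfg$pleiotropy_sd,
    pleiotropy_mean = simcfg$pleiotropy_mean,
    n_exposure = simcfg$n_exposure, n_mediator = simcfg$n_mediator,
    n_outcome = simcfg$n_outcome, seed = seed
  )
  dag <- simulate_mediation_gwas(truth,
                                 k_exposure_snps = simcfg$k_exposure_snps,
                                 k_mediator_snps = simcfg$k_mediator_snps,
                                 instrument_strength = simcfg$instrument_strength)
  rg <- simcfg$region
  region <- simulate_region(m_variants = rg$m_variants, ld_rho = rg$ld_rho,
                            n1 = rg$n1, n2 = rg$n2,
                            shared_causal = rg$shared_causal,
                            effect_size = rg$effect_size, seed = seed + 1L)

  # -- stage 2: instruments ----------------------------------------------
  ins <- instrument_set(dag$exposure, dag$exposure_ids)
  fs <- f_statistics(ins$beta, ins$se,
                     weak_threshold = config$instruments$weak_f_threshold)
  med_ins <- instrument_set(dag$mediator, dag$mediator_ids)
  instruments_block <- list(
    profile = config$instruments$profile,
    thresholds = selection_profile(config$instruments$profile),
    k = nrow(ins),
    f_range = range(fs$f_stat),
    n_weak = sum(fs$weak)
  )

  # -- stage 3: colocalization -------------------------------------------
  cl <- config$coloc
  coloc <- coloc_abf(region$trait1[c("beta", "se")],
                     region$trait2[c("beta", "se")],
                     p1 = cl$p1, p2 = cl$p2, p12 = cl$p12,
                     prior_sd1 = cl$prior_sd1, prior_sd2 = cl$prior_sd2,
                     h4_threshold = cl$h4_threshold)

  # -- stage 4: outcome MR ------------------------------------------------
  est <- config$estimators
  h_out <- harmonize_pair(ins, dag$outcome)
  suite <- run_mr_suite(h_out, seed = seed, ivw_mode = est$ivw_mode,
                        n_boot = est$n_boot, n_sim = est$n_sim)

  # -- stage 5: mediation -------------------------------------------------
  mediation <- two_step_mediation(ins, dag$mediator, med_ins, dag$outcome,
                                  exposure_gwas = dag$exposure, seed = seed,
                                  ivw_mode = est$ivw_mode)

  # -- stage 6: meta-analysis of replicate mediator datasets -------------
  b_rep <- ivw(harmonize_pair(ins, dag$mediator_replicate),
               mode = est$ivw_mode)
  meta <- meta_fixed(tibble(
    beta = c(mediation$beta1$beta, b_rep$beta),
    se = c(mediation$beta1$se, b_rep$se),
    label = c("mediator", "mediator_replicate")
  ))

  # -- stage 7: phenome-wide screen --------------------------------------
  sc <- config$screen
  panel <- simulate_outcome_panel(ins, n_outcomes = sc$n_outcomes,
                                  n_true = sc$n_true,
                                  true_effect = sc$true_effect,
                                  seed = seed + 2L)
  screen <- screen_outcomes(ins, panel$outcomes, alpha = sc$alpha,
                            seed = seed)

  structure(list(
    settings = unclass(config),
    data = list(truth = unclass(truth),
                n_variants = nrow(dag$exposure),
                region_variants = region$truth),
    instruments = instruments_block,
    coloc = list(pp = as.list(coloc$pp), colocalized = coloc$colocalized,
                 n_variants = coloc$n_variants),
    outcome_mr = as.data.frame(as_tibble(suite)),
    mediation = list(
      beta1 = mediation$beta1$beta, beta2 = mediation$beta2$beta,
      beta2_adj = mediation$beta2_adj, beta3 = mediation$beta3$beta,
      proportions = as.data.frame(mediation$proportions)
    ),
    meta = as.data.frame(as_tibble(meta)),
    screen = list(
      n_tests = attr(screen, "n_tests"),
      adjusted_alpha = attr(screen, "adjusted_alpha"),
      n_significant = sum(screen$significant, na.rm = TRUE),
      results = as.data.frame(as_tibble(screen))
    )
  ), class = "tmr_report")
}

#' Write a pipeline run report as JSON
#'
#' @param report A `tmr_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
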