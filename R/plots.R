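# ggplot2 displays for result objects -------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_vline geom_col labs theme_minimal scale_y_discrete
NULL

#' @export
ggplot2::autoplot

#' Forest plot of an MR estimator suite
#'
#' @param object A `tmr_mr` tibble from [run_mr_suite()] or a single
#'   estimator.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmr_mr
#' @export
autoplot.tmr_mr <- function(object, ...) {
  d <- as_tibble(object)
  d$method <- factor(d$method, levels = rev(unique(d$method)))
  ggplot(d, aes(x = .data$beta, y = .data$method)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(size = 2) +
    labs(x = "Causal estimate (beta, 95% CI)", y = NULL,
         title = paste0(attr(object, "exposure_label") %||% "exposure",
                        " → ",
                        attr(object, "outcome_label") %||% "outcome")) +
    theme_minimal()
}

#' Forest plot of a meta-analysis with its inputs
#'
#' @param object A `tmr_meta` row from [meta_fixed()] or
#'   [meta_dl_random()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmr_meta
#' @export
autoplot.tmr_meta <- function(object, ...) {
  inputs <- attr(object, "inputs")
  d <- bind_rows(
    tibble(label = inputs$label, beta = inputs$beta,
           ci_low = inputs$beta - CI_Z * inputs$se,
           ci_high = inputs$beta + CI_Z * inputs$se, pooled = FALSE),
    tibble(label = paste0("Pooled (", object$mode, ")"),
           beta = object$beta, ci_low = object$ci_low,
           ci_high = object$ci_high, pooled = TRUE)
  )
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot(d, aes(x = .data$beta, y = .data$label, shape = .data$pooled)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(size = 2, show.legend = FALSE) +
    labs(x = "Effect (beta, 95% CI)", y = NULL) +
    theme_minimal()
}

#' Posterior-probability bar chart for a colocalization result
#'
#' @param object A `tmr_coloc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmr_coloc
#' @export
autoplot.tmr_coloc <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$hypothesis, y = .data$posterior)) +
    geom_col() +
    labs(x = NULL, y = "Posterior probability") +
    theme_minimal()
}

#' Significance overview of a phenome-wide MR screen
#'
#' Plots each outcome's primary-method -log10 p-value against the
#' Bonferroni-adjusted threshold.
#'
#' @param object A `tmr_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tmr_screen
#' @export
autoplot.tmr_screen <- function(object, ...) {
  d <- as_tibble(object) %>%
    filter(.data$status == "ok", grepl("^ivw", .data$method))
  thr <- attr(object, "adjusted_alpha")
  ggplot(d, aes(x = .data$outcome, y = -log10(.data$pval))) +
    geom_point() +
    geom_vline(xintercept = NA) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        colour = "red") +
    labs(x = NULL, y = expression(-log[10](p)),
         caption = sprintf("dashed line: Bonferroni alpha/n = %.3g", thr)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
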