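#' Scatter plot of a harmonized instrument set with fitted MR lines
#'
#' SNP-outcome against SNP-exposure effects with 1-SE bars and, when
#' `methods` is non-empty, the fitted IVW (through the origin) and
#' MR-Egger (with intercept) lines.
#'
#' @param object An `mr_harmonized` tibble.
#' @param methods Lines to overlay, subset of `c("ivw", "egger")`.
#' @param seed Seed passed to estimators that need one.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_harmonized <- function(object, methods = c("ivw", "egger"),
                                   seed = 1L, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - .data$se_Gamma,
                                        ymax = .data$Gamma + .data$se_Gamma),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$gamma - .data$se_gamma,
                                         xmax = .data$gamma + .data$se_gamma),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome",
                  title = paste0(attr(object, "exposure_name"), " → ",
                                 attr(object, "outcome_name"))) +
    ggplot2::theme_minimal()
  if ("ivw" %in% methods && nrow(df) >= 2) {
    fit <- mr_ivw(object)
    p <- p + ggplot2::geom_abline(intercept = 0, slope = fit$beta,
                                  colour = "#1b6ca8")
  }
  if ("egger" %in% methods && nrow(df) >= 3) {
    fit <- mr_egger(object)
    p <- p + ggplot2::geom_abline(intercept = fit$egger_intercept,
                                  slope = fit$beta,
                                  colour = "#b0413e", linetype = "dashed")
  }
  p
}

#' Forest plot of MR results
#'
#' Odds ratios with 95% confidence intervals, one row per
#' exposure-outcome-method combination.
#'
#' @param results An `mr_result` tibble (any number of rows).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results) {
  df <- as_tibble(results)
  df$label <- paste(df$exposure, "→", df$outcome, paste0("(", df$method, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-out sensitivity plot
#'
#' Per-omission IVW estimates with 95% CIs against the full-set estimate
#' (vertical line).
#'
#' @param loo An `mr_loo` tibble from [leave_one_out()].
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  df <- as_tibble(loo)
  full <- attr(loo, "full_fit")
  zc <- qnorm(0.975)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = .data$dropped_variant_id)) +
    ggplot2::geom_vline(xintercept = full$beta, colour = "#1b6ca8") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - zc * .data$se,
                                         xmax = .data$beta + zc * .data$se),
                            height = 0.2) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "IVW estimate omitting variant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior bar chart for a colocalization result
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "#1b6ca8") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "Posterior probability", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
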