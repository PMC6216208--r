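#' Regional association plot
#'
#' Scatter of `-log10(P_trend)` against genomic position, optionally coloured
#' by LD `r2` to an index SNP — the plot for which [regional_plot_data()]
#' supplies the data.
#'
#' @param assoc An [assoc_table()] tibble.
#' @param r2_to_index Optional named `r2` vector keyed by `snp_id`.
#' @param label Label the top SNP, default `TRUE`.
#' @return A ggplot object.
#' @export
plot_regional <- function(assoc, r2_to_index = NULL, label = TRUE) {
  pd <- regional_plot_data(assoc, r2_to_index)
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$pos / 1e6,
                                        y = .data$minus_log10_p_trend))
  p <- if (all(is.na(pd$r2_to_index))) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$r2_to_index), size = 2) +
      ggplot2::scale_colour_gradient(name = expression(r^2),
                                     low = "navy", high = "red",
                                     limits = c(0, 1), na.value = "grey60")
  }
  if (label && nrow(pd)) {
    top <- pd[which.max(pd$minus_log10_p_trend), ]
    p <- p + ggplot2::annotate("text", x = top$pos / 1e6,
                               y = top$minus_log10_p_trend,
                               label = top$snp_id, vjust = -0.8, size = 3)
  }
  p + ggplot2::labs(x = "Position (Mb)",
                    y = expression(-log[10](italic(P)[trend]))) +
    ggplot2::theme_minimal()
}

#' Forest plot of a fixed-effects meta-analysis
#'
#' @param object An `fe_meta` fit.
#' @param ... Unused.
#' @return A ggplot object: per-study odds ratios with confidence intervals
#'   and the pooled estimate.
#' @method autoplot fe_meta
#' @export
autoplot.fe_meta <- function(object, ...) {
  per <- tidy(object) |> dplyr::mutate(what = "study")
  pooled <- glance(object) |>
    dplyr::transmute(study_id = "pooled", or = .data$or,
                     ci_low = .data$ci_low, ci_high = .data$ci_high,
                     what = "pooled")
  dat <- dplyr::bind_rows(per[, c("study_id", "or", "ci_low", "ci_high", "what")],
                          pooled)
  dat$study_id <- factor(dat$study_id, levels = rev(dat$study_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$study_id,
                                    colour = .data$what)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.15) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(study = "black", pooled = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Power curve plot
#'
#' @param curve A tibble from [power_curve()].
#' @return A ggplot object of rejection rate versus per-allele odds ratio.
#' @export
plot_power_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$or_per_allele,
                                      y = .data$rejection_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Per-allele odds ratio", y = "Rejection rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
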