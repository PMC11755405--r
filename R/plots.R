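#' Volcano plot of a differential-expression result
#'
#' Plots `-log10(p)` against log2 fold change, highlighting DEPs and
#' drawing the fold-change and significance thresholds used in the
#' comparison.
#'
#' @param records Tibble from [run_comparison()] or [prm_differential()].
#' @param label_top Number of top DEPs (by q) to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, label_top = 10) {
  cmp <- attr(records, "comparison")
  id_col <- if ("protein_id" %in% names(records)) "protein_id" else "peptide_id"
  records <- dplyr::mutate(records,
                           neglog10p = -log10(pmax(.data$p_value, 1e-300)))
  top <- records |>
    dplyr::filter(.data$is_dep) |>
    dplyr::slice_min(.data$q_value, n = label_top, with_ties = FALSE)
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(.data$log2fc, .data$neglog10p,
                                    colour = .data$is_dep)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "DEP") +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(p))) +
    ggplot2::theme_minimal()
  if (!is.null(cmp)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(-1, 1) * cmp$log2fc_threshold,
                          linetype = "dashed", colour = "grey40") +
      ggplot2::ggtitle(sprintf("%s vs %s", cmp$group_b, cmp$group_a))
  }
  if (nrow(top) > 0)
    p <- p + ggplot2::geom_text(
      data = top, ggplot2::aes(label = .data[[id_col]]),
      vjust = -0.6, size = 2.8, colour = "black")
  p
}

#' Plot a PRM response curve
#'
#' Per-level mean ratios with the fitted calibration line on log-log
#' axes; rejected levels are hollow, and LOD/LOQ are marked.
#'
#' @param fit A `response_curve_fit`.
#' @return A ggplot object.
#' @export
plot_response_curve <- function(fit) {
  stopifnot(inherits(fit, "response_curve_fit"))
  qc <- fit$level_qc
  qc$mean_ratio <- fit$intercept + fit$slope * qc$nominal_fmol *
    qc$accuracy_percent / 100
  p <- ggplot2::ggplot(qc, ggplot2::aes(.data$nominal_fmol,
                                        .data$mean_ratio)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "level accepted") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "nominal amount (fmol)", y = "light/heavy ratio",
                  title = sprintf("%s (r² = %.4f)", fit$peptide_id,
                                  fit$r_squared)) +
    ggplot2::theme_minimal()
  if (fit$valid) {
    line <- tibble::tibble(
      nominal_fmol = exp(seq(log(min(fit$ladder)), log(max(fit$ladder)),
                             length.out = 50)))
    line$mean_ratio <- fit$intercept + fit$slope * line$nominal_fmol
    p <- p + ggplot2::geom_line(data = line, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = c(fit$lod_fmol, fit$loq_fmol),
                          linetype = c("dotted", "dashed"),
                          colour = "grey40", na.rm = TRUE)
  }
  p
}

#' @rdname plot_response_curve
#' @param object A `response_curve_fit`.
#' @param ... Unused.
#' @export
autoplot.response_curve_fit <- function(object, ...) {
  plot_response_curve(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
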