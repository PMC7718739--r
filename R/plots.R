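#' Plot an AP expression trace
#'
#' Line plot of expression against AP position; when the trace carries
#' per-bin standard errors (a group-average trace) a SEM ribbon is shaded
#' around the mean.
#'
#' @param object a `lateral_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot lateral_trace
#' @export
autoplot.lateral_trace <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ap, y = .data$value))
  if ("sem" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sem,
                   ymax = .data$value + .data$sem),
      fill = "grey70", alpha = 0.6)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "AP position (fraction egg length)",
                  y = "expression (normalized a.u.)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot per-stain ratios with their mean
#'
#' Open circles for individual stain ratios, a filled circle for the mean,
#' and a dashed line at 1 (no difference).
#'
#' @param object a `ratio_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ratio_result
#' @export
autoplot.ratio_result <- function(object, ...) {
  df <- tidy(object)
  lab <- paste0(object$genotype_num, " / ", object$genotype_den)
  ggplot2::ggplot(df, ggplot2::aes(x = lab, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(shape = 1, size = 3,
                        position = ggplot2::position_jitter(width = 0.05)) +
    ggplot2::annotate("point", x = lab, y = object$mean_ratio, size = 4) +
    ggplot2::labs(x = NULL, y = "peak expression ratio",
                  subtitle = sprintf("mean %.2f, p = %.3g", object$mean_ratio,
                                     object$p_one_sample)) +
    ggplot2::theme_minimal()
}

#' Plot a segmented multi-stripe trace
#'
#' @param object a `stripe_set`.
#' @param trace optionally the `lateral_trace` it was segmented from, drawn
#'   underneath.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stripe_set
#' @export
autoplot.stripe_set <- function(object, trace = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_line(data = tidy(trace),
                                ggplot2::aes(x = .data$ap, y = .data$value),
                                colour = "grey40")
  }
  p +
    ggplot2::geom_vline(data = df,
                        ggplot2::aes(xintercept = .data$anterior),
                        linetype = "dotted") +
    ggplot2::geom_vline(data = df,
                        ggplot2::aes(xintercept = .data$posterior),
                        linetype = "dotted") +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(x = .data$peak_pos, y = .data$peak_level)) +
    ggplot2::labs(x = "AP position (fraction egg length)", y = "expression") +
    ggplot2::theme_minimal()
}

#' Boundary-position summary plot
#'
#' Mean anterior/posterior boundary positions per genotype with SEM error
#' bars, in the style used to compare stripe extents between constructs.
#'
#' @param metrics tibble from [stripe_metrics_by_genotype()].
#' @return A ggplot object.
#' @export
plot_boundaries <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics, dplyr::all_of(c("anterior", "posterior")),
    names_to = "boundary", values_to = "position")
  long$se <- ifelse(long$boundary == "anterior", metrics$anterior_se[
    match(long$genotype, metrics$genotype)],
    metrics$posterior_se[match(long$genotype, metrics$genotype)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$genotype,
                                     colour = .data$boundary)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$position - .data$se,
                   xmax = .data$position + .data$se), height = 0.2) +
    ggplot2::labs(x = "AP position (fraction egg length)", y = NULL) +
    ggplot2::theme_minimal()
}
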