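#' Litter-mean load distribution per organ and group
#'
#' Dot plot of litter-mean particle loads by organ, control versus exposed,
#' on a log10 axis — one point per dam.
#'
#' @param litter Litter-level table from [pool_by_dam()].
#' @return A ggplot object.
#' @export
plot_load_distribution <- function(litter) {
  ggplot2::ggplot(litter,
                  ggplot2::aes(x = .data$organ, y = .data$cp_load,
                               colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.5), size = 2, alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression(CP~load~(particles/mm^3)),
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Between-organ correlation heatmap
#'
#' Heatmap of the Spearman correlations of litter-mean loads between
#' compartments.
#'
#' @param correlation Result of [cp_correlation()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(correlation) {
  m <- attr(correlation, "matrix")
  df <- tibble::as_tibble(as.data.frame(as.table(m)))
  names(df) <- c("organ_a", "organ_b", "rho")
  ggplot2::ggplot(df, ggplot2::aes(.data$organ_a, .data$organ_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Factor maps of a fitted MFA
#'
#' `type = "individuals"`: individuals on dimensions 1-2, coloured by the
#' supplementary factor when given, with the category barycentre confidence
#' ellipses. `type = "variables"`: the correlation circle with one arrow per
#' active variable.
#'
#' @param object A `cp_mfa`.
#' @param type `"individuals"` or `"variables"`.
#' @param factor_values Optional supplementary factor for colouring and
#'   ellipses.
#' @param ellipses Draw 95% barycentre ellipses (needs `factor_values`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cp_mfa <- function(object, type = c("individuals", "variables"),
                            factor_values = NULL, ellipses = TRUE, ...) {
  type <- match.arg(type)
  lab <- sprintf("Dim %d (%.1f%%)", 1:2, object$eig$pct_inertia[1:2])
  if (type == "individuals") {
    df <- object$ind
    p <- if (is.null(factor_values)) {
      ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2)) +
        ggplot2::geom_point(alpha = 0.8)
    } else {
      f <- align_factor(object, factor_values)
      df$level <- f
      q <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                            colour = .data$level)) +
        ggplot2::geom_point(alpha = 0.8)
      if (ellipses) {
        ell <- confidence_ellipse(object, f)
        q <- q + ggplot2::geom_path(
          data = ell, ggplot2::aes(.data$x, .data$y, colour = .data$level),
          inherit.aes = FALSE)
      }
      q
    }
    p + ggplot2::geom_hline(yintercept = 0, linetype = 3) +
      ggplot2::geom_vline(xintercept = 0, linetype = 3) +
      ggplot2::labs(x = lab[1], y = lab[2]) +
      ggplot2::theme_minimal()
  } else {
    vm <- variable_factor_map(object)
    t <- seq(0, 2 * pi, length.out = 200)
    circ <- tibble::tibble(x = cos(t), y = sin(t))
    ggplot2::ggplot(vm) +
      ggplot2::geom_path(data = circ, ggplot2::aes(.data$x, .data$y),
                         colour = "grey60") +
      ggplot2::geom_segment(
        ggplot2::aes(x = 0, y = 0, xend = .data$corr_dim1,
                     yend = .data$corr_dim2, colour = .data$group),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
      ggplot2::geom_text(
        ggplot2::aes(.data$corr_dim1, .data$corr_dim2,
                     label = .data$variable, colour = .data$group),
        size = 2.6, vjust = -0.6) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = lab[1], y = lab[2]) +
      ggplot2::theme_minimal()
  }
}
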