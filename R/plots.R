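#' Plot LD decay with the critical baseline and fitted curve
#'
#' Scatter of syntenic pair `R^2` against cM distance with the loess decay
#' curve and the unlinked-pair critical-`R^2` baseline; the estimated LD
#' extent, where estimable, is marked by a vertical line.
#'
#' @param x An `ld_result` from [ld_summary()].
#' @param point_alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(x, point_alpha = 0.3) {
  stopifnot(inherits(x, "ld_result"))
  syn <- as_tibble(x$pairs) |>
    dplyr::filter(.data$linkage == "syntenic", .data$evaluable)
  p <- ggplot2::ggplot(syn, ggplot2::aes(x = .data$distance_cm,
                                         y = .data$r2)) +
    ggplot2::geom_point(alpha = point_alpha, size = 0.8) +
    ggplot2::geom_hline(yintercept = x$summary$critical_r2,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "genetic distance (cM)",
                  y = expression(R^2),
                  title = "LD decay of syntenic marker pairs") +
    ggplot2::theme_minimal()
  if (!is.null(x$extent$curve)) {
    p <- p + ggplot2::geom_line(data = x$extent$curve,
                                ggplot2::aes(x = .data$distance_cm,
                                             y = .data$r2_fit),
                                colour = "blue")
  }
  if (isTRUE(x$summary$extent_estimable)) {
    p <- p + ggplot2::geom_vline(xintercept = x$summary$extent_cm,
                                 linetype = "dotted")
  }
  p
}

#' @export
autoplot.ld_result <- function(object, ...) plot_ld_decay(object, ...)

#' Plot the gene diversity table
#'
#' Per-chromosome Nei gene diversity by group (whole collection and each
#' subspecies), the tabular diversity profile as a grouped bar chart.
#'
#' @param x A tibble from [diversity_table()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(x) {
  chrom <- x |> dplyr::filter(.data$scope_type == "chromosome")
  ggplot2::ggplot(chrom, ggplot2::aes(x = .data$scope, y = .data$h,
                                      fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "chromosome", y = "gene diversity (H)",
                  fill = NULL,
                  title = "Nei gene diversity by chromosome and group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
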