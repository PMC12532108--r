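#' Plot an aggregate chromosome map
#'
#' Heatmap of the rescaled aggregate cis or trans O/E map on a log2 color
#' scale, centromere at the axis midpoint and telomeres at the ends.
#'
#' @param agg A `hic_aggregate` from [aggregate_chromosomes()].
#' @param which `"trans"` (default) or `"cis"`.
#' @return A ggplot object.
#' @export
plot_aggregate_map <- function(agg, which = c("trans", "cis")) {
  which <- match.arg(which)
  m <- agg[[which]]
  if (is.null(m)) stop("aggregate has no ", which, " map", call. = FALSE)
  df <- tidyr::expand_grid(u = seq_len(nrow(m)), v = seq_len(ncol(m))) |>
    dplyr::mutate(log2_oe = log2(m[cbind(.data$u, .data$v)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, fill = .data$log2_oe)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "rescaled position (tel → cen → tel)",
      y = NULL, fill = "log2 O/E",
      title = paste("Aggregate", which, "map")
    ) +
    ggplot2::theme_minimal()
}

#' Plot architecture-score trajectories across a series
#'
#' @param object A `hic_series` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object: one line per score across stages.
#' @export
autoplot.hic_series <- function(object, ...) {
  df <- object$scores |>
    tidyr::pivot_longer(dplyr::all_of(c("s_cencen", "s_teltel",
                                        "s_centel_axis", "s_ct")),
                        names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$value,
                                   color = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stage", y = "score (log2)",
                  title = "Architecture scores across the series") +
    ggplot2::theme_minimal()
}

#' Plot per-stage compartmentalization strengths
#'
#' @param series A `hic_series`.
#' @return A ggplot object: strength per subcompartment label across stages.
#' @export
plot_strengths <- function(series) {
  ggplot2::ggplot(series$strengths,
                  ggplot2::aes(.data$stage, .data$strength,
                               color = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stage", y = "compartmentalization strength (log2)",
                  title = "Subcompartment strength across the series") +
    ggplot2::theme_minimal()
}
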