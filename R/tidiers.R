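#' Tidy a series result into one long tibble
#'
#' One row per stage and quantity: the four architecture scores, the
#' per-label compartmentalization strengths and the three interaction
#' fractions, ready for faceting or joining.
#'
#' @param x A `hic_series` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble: `stage`, `quantity`, `value`.
#' @export
tidy.hic_series <- function(x, ...) {
  dplyr::bind_rows(
    x$scores |>
      tidyr::pivot_longer(dplyr::all_of(c("s_cencen", "s_teltel",
                                          "s_centel_axis", "s_ct")),
                          names_to = "quantity", values_to = "value") |>
      dplyr::select("stage", "quantity", "value"),
    x$strengths |>
      dplyr::transmute(.data$stage,
                       quantity = paste0("strength_", .data$label),
                       value = .data$strength),
    x$fractions |>
      tidyr::pivot_longer(-"stage", names_to = "quantity",
                          values_to = "value")
  ) |>
    dplyr::arrange(.data$stage, .data$quantity)
}

#' One-row summary of a series result
#'
#' @param x A `hic_series`.
#' @param ... Unused.
#' @return One-row tibble: stage count, first/last territory score, the two
#'   correlation estimates and p-values.
#' @export
glance.hic_series <- function(x, ...) {
  co <- x$correlations
  tibble::tibble(
    n_stages = nrow(x$scores),
    s_ct_first = x$scores$s_ct[1],
    s_ct_last = x$scores$s_ct[nrow(x$scores)],
    r_a1_ct = co$r[co$pair == "strength_A1~s_ct"],
    p_a1_ct = co$p[co$pair == "strength_A1~s_ct"],
    r_b23_rabl = co$r[co$pair == "strength_B23~rabl"],
    p_b23_rabl = co$p[co$pair == "strength_B23~rabl"]
  )
}
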