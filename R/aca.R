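#' Rescale a chromosome's O/E block onto a common centromere-anchored axis
#'
#' Each arm is mapped linearly onto `m` rescaled bins: the P arm onto
#' positions 0..m-1 (telomere at 0, centromere at m-1) and the Q arm onto
#' m..2m-1 (centromere at m, telomere at 2m-1), using the centromere
#' interval midpoint as the anchor. Every rescaled cell is the masked,
#' fractional-overlap-weighted mean of the source cells whose bp coordinates
#' map into it, so a chromosome that already has `m` equal bins per arm
#' rescales to itself and a uniform input stays uniform.
#'
#' @param oe_block Square numeric matrix (`NA` = missing) of one
#'   chromosome's cis O/E values, or a rectangular trans block when `cols`
#'   supplies the column-side bins.
#' @param bins_of_chrom Bin-table rows of the row-side chromosome (must
#'   carry `start`, `end`, `arm`, `cen_anchor`, `chrom_length`).
#' @param m Rescaled bins per arm (>= 2).
#' @param cols Optional bin-table rows for the column side (trans blocks);
#'   defaults to `bins_of_chrom`.
#' @return `(2m) x (2m)` matrix of rescaled means (`NA` where no source cell
#'   contributes), with the contribution weight matrix attached as attribute
#'   `weight`.
#' @export
rescale_chromosome <- function(oe_block, bins_of_chrom, m, cols = NULL) {
  stopifnot(m >= 2)
  if (is.null(cols)) cols <- bins_of_chrom
  w_r <- rescale_weights(bins_of_chrom, m)
  w_c <- rescale_weights(cols, m)
  a <- oe_block
  ok <- !is.na(a)
  a[!ok] <- 0
  num <- w_r %*% a %*% t(w_c)
  den <- w_r %*% (ok + 0) %*% t(w_c)
  out <- num / den
  out[den == 0] <- NA_real_
  attr(out, "weight") <- den
  out
}

# (2m) x n_bins bp-overlap weight matrix mapping source bins onto the
# rescaled centromere-anchored axis
rescale_weights <- function(bins, m) {
  anchor <- bins$cen_anchor[1]
  len <- bins$chrom_length[1]
  n <- nrow(bins)
  edges_p <- seq(0, anchor, length.out = m + 1)          # telomere -> cen
  edges_q <- seq(anchor, len, length.out = m + 1)        # cen -> telomere
  w <- matrix(0, 2 * m, n)
  for (u in seq_len(m)) {
    w[u, ] <- pmax(0, pmin(bins$end, edges_p[u + 1]) -
                     pmax(bins$start, edges_p[u]))
    w[m + u, ] <- pmax(0, pmin(bins$end, edges_q[u + 1]) -
                         pmax(bins$start, edges_q[u]))
  }
  w / rowSums(w)
}

#' Aggregate chromosome analysis: mean rescaled cis and trans maps
#'
#' Averages centromere-anchored rescaled O/E maps over all ACA-eligible
#' (metacentric/submetacentric) chromosomes: the cis map over single
#' chromosomes, the trans map over all unordered chromosome pairs with each
#' pair's block rescaled on both axes and symmetrized. Missing cells are
#' excluded from every mean.
#'
#' @param matrix A [hic_matrix()] with the O/E layer present (see
#'   [observed_over_expected()]).
#' @param m Rescaled bins per arm.
#' @return An object of class `hic_aggregate`: list with `cis`, `trans`
#'   (`(2m) x (2m)` matrices or `NULL`), contribution counts `cis_n`,
#'   `trans_n`, and `m`.
#' @export
aggregate_chromosomes <- function(matrix, m = 20) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$oe)) stop("O/E layer missing; run observed_over_expected() first",
                               call. = FALSE)
  bins <- matrix$bins
  elig <- bins |>
    dplyr::filter(.data$eligible) |>
    dplyr::pull(.data$chrom) |>
    unique()
  # drop chromosomes with an arm having no unmasked bin
  keep <- character(0)
  for (ch in elig) {
    ix <- bins$chrom == ch
    ok_arm <- tapply(matrix$valid[ix], bins$arm[ix], any)
    if (all(ok_arm)) keep <- c(keep, ch) else
      warning("chromosome ", ch, " dropped from ACA: arm with no unmasked bin",
              call. = FALSE)
  }
  if (length(keep) < 1) stop("no ACA-eligible chromosome", call. = FALSE)
  oe <- matrix$oe
  cis_stack <- purrr::map(keep, function(ch) {
    ix <- which(bins$chrom == ch)
    rescale_chromosome(oe[ix, ix, drop = FALSE], bins[ix, ], m)
  })
  cis <- na_mean_stack(cis_stack)
  trans <- NULL
  trans_n <- NULL
  if (length(keep) >= 2) {
    pair_stack <- purrr::map(utils::combn(keep, 2, simplify = FALSE), function(p) {
      i1 <- which(bins$chrom == p[1])
      i2 <- which(bins$chrom == p[2])
      r <- rescale_chromosome(oe[i1, i2, drop = FALSE], bins[i1, ], m,
                              cols = bins[i2, ])
      (r + t(r)) / 2   # symmetrize the unordered pair
    })
    agg <- na_mean_stack(pair_stack)
    trans <- agg$mean
    trans_n <- agg$n
  }
  structure(
    list(cis = cis$mean, cis_n = cis$n, trans = trans, trans_n = trans_n,
         m = m, chromosomes = keep),
    class = "hic_aggregate"
  )
}

# elementwise NA-aware mean over a list of equal-size matrices
na_mean_stack <- function(mats) {
  num <- Reduce(`+`, lapply(mats, function(x) ifelse(is.na(x), 0, x)))
  n <- Reduce(`+`, lapply(mats, function(x) (!is.na(x)) + 0))
  out <- num / n
  out[n == 0] <- NA_real_
  list(mean = out, n = n)
}

#' @export
print.hic_aggregate <- function(x, ...) {
  cat("<hic_aggregate> m =", x$m, "bins/arm;",
      length(x$chromosomes), "chromosome(s);",
      if (is.null(x$trans)) "cis only" else "cis + trans", "\n")
  invisible(x)
}

# relative arm position (0 at centromere, 1 at telomere) of rescaled
# coordinate u in 1..2m
axis_rho <- function(m) {
  u <- seq_len(2 * m)
  ifelse(u <= m, (m - u + 0.5) / m, (u - m - 0.5) / m)
}

# CEN / TEL / ARM index sets on the rescaled axis (1-based)
axis_regions <- function(m, cen_fraction, tel_fraction) {
  k_c <- ceiling(2 * m * cen_fraction)
  k_t <- ceiling(m * tel_fraction)
  cen <- (m - ceiling(k_c / 2) + 1):(m + floor(k_c / 2))
  tel <- c(seq_len(k_t), (2 * m - k_t + 1):(2 * m))
  arm <- setdiff(seq_len(2 * m), c(cen, tel))
  list(cen = cen, tel = tel, arm = arm, k_t = k_t)
}

#' Architecture scores from an aggregate map
#'
#' Scores the three trans Rabl components on the rescaled aggregate trans
#' map. With `baseline = "matched"` (default) each region block is compared
#' to ARM x ARM cells at the same relative-arm-position offset
#' (`|delta rho|`), which isolates each component: a planted
#' centromere-to-telomere axis enriches centromere and telomere poles too
#' (both have `|delta rho| ~ 0`), and a matched baseline cancels that shared
#' axial geometry. `baseline = "global"` uses the plain ARM x ARM mean and
#' the `|u - v| <= w` diagonal band instead.
#'
#' * `s_cencen`: log2 mean trans CEN x CEN over baseline.
#' * `s_teltel`: log2 mean over the four TEL corner blocks over baseline.
#' * `s_centel_axis`: log2 ARM x ARM in-band (`|delta rho| <= tel_fraction`)
#'   over off-band.
#'
#' @param agg A `hic_aggregate` from [aggregate_chromosomes()].
#' @param cen_fraction,tel_fraction Region fractions on the rescaled axis.
#' @param baseline `"matched"` or `"global"` (see Details).
#' @param profile_correct Divide the trans aggregate by the outer product of
#'   its axial position profile (rank-1 correction) before scoring. Matrix
#'   balancing equalizes each bin's total marginal, but the cis share has a
#'   distance-decay deficit at chromosome ends, so end bins carry a
#'   multiplicative trans surplus; any such per-bin factor is exactly rank-1
#'   in the trans map and is cancelled here. The profile is estimated from
#'   cells with axial offset `|delta rho| > 2 * tel_fraction` only, where the
#'   clustering and axis kernels are negligible, so planted signals do not
#'   distort their own baseline.
#' @return One-row tibble: `s_cencen`, `s_teltel`, `s_centel_axis`
#'   (log2 units; `NA` when a contributing region is empty).
#' @export
score_aggregate <- function(agg, cen_fraction = 0.1, tel_fraction = 0.1,
                            baseline = c("matched", "global"),
                            profile_correct = TRUE) {
  stopifnot(inherits(agg, "hic_aggregate"))
  baseline <- match.arg(baseline)
  if (is.null(agg$trans)) {
    return(tibble::tibble(s_cencen = NA_real_, s_teltel = NA_real_,
                          s_centel_axis = NA_real_))
  }
  m <- agg$m
  t_map <- agg$trans
  if (profile_correct) {
    rho0 <- axis_rho(m)
    off <- abs(outer(rho0, rho0, "-")) > 2 * tel_fraction
    t_off <- t_map
    t_off[!off] <- NA_real_
    # multiplicative rank-1 fit T[u,v] ~ p_u p_v on off-band cells
    p <- rep(1, 2 * m)
    for (it in seq_len(50)) {
      pn <- rowMeans(t_off / matrix(p, 2 * m, 2 * m, byrow = TRUE),
                     na.rm = TRUE)
      pn[!is.finite(pn)] <- 1
      pn <- pn / mean(pn)
      if (max(abs(pn - p)) < 1e-12) {
        p <- pn
        break
      }
      p <- pn
    }
    t_map <- t_map / outer(p, p)
  }
  reg <- axis_regions(m, cen_fraction, tel_fraction)
  rho <- axis_rho(m)
  drho <- abs(outer(rho, rho, "-"))
  arm_cell <- matrix(FALSE, 2 * m, 2 * m)
  arm_cell[reg$arm, reg$arm] <- TRUE

  block_mean <- function(rows, cols) {
    x <- t_map[rows, cols]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  cell_mean <- function(mask) {
    x <- t_map[mask]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }

  cen_mean <- block_mean(reg$cen, reg$cen)
  tel_mean <- block_mean(reg$tel, reg$tel)
  if (baseline == "matched") {
    d_cen <- max(drho[reg$cen, reg$cen])
    d_tel <- max(drho[reg$tel[seq_len(reg$k_t)], reg$tel[seq_len(reg$k_t)]])
    base_cen <- cell_mean(arm_cell & drho <= d_cen)
    base_tel <- cell_mean(arm_cell & drho <= d_tel)
    in_band <- arm_cell & drho <= tel_fraction
    off_band <- arm_cell & drho > tel_fraction
  } else {
    base_cen <- base_tel <- block_mean(reg$arm, reg$arm)
    uv <- abs(outer(seq_len(2 * m), seq_len(2 * m), "-"))
    in_band <- uv <= reg$k_t
    off_band <- !in_band
  }
  tibble::tibble(
    s_cencen = log2(cen_mean / base_cen),
    s_teltel = log2(tel_mean / base_tel),
    s_centel_axis = log2(cell_mean(in_band) / cell_mean(off_band))
  )
}

#' Chromosome-territory score: genome-wide cis/trans contact ratio
#'
#' `log2(mean balanced cis value / mean balanced trans value)` over unmasked
#' pairs, computed on balanced counts (not O/E) so that the cis/trans ratio
#' retains its meaning. Its null value is set by distance decay, not zero;
#' compare against [expected_contact_map()] of a null parameterization.
#'
#' @param matrix A [hic_matrix()] with a balanced layer.
#' @return Scalar score (log2 units).
#' @export
cis_trans_score <- function(matrix) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$balanced)) stop("balanced layer missing; run ice_balance() first",
                                     call. = FALSE)
  v <- matrix$valid
  cis <- cis_mask(matrix$bins)
  up <- upper.tri(cis, diag = TRUE)
  ok <- outer(v, v, "&") & up
  b <- matrix$balanced
  log2(mean(b[ok & cis]) / mean(b[ok & !cis]))
}

#' Architecture scores of a contact map
#'
#' End-to-end scoring: aggregates rescaled O/E maps over eligible
#' chromosomes and returns the three Rabl scores plus the
#' chromosome-territory score.
#'
#' @param matrix A [hic_matrix()] with balanced and O/E layers.
#' @param m Rescaled bins per arm.
#' @inheritParams score_aggregate
#' @return One-row tibble: `s_cencen`, `s_teltel`, `s_centel_axis`, `s_ct`,
#'   plus the parameters used.
#' @export
architecture_scores <- function(matrix, m = 20, cen_fraction = 0.1,
                                tel_fraction = 0.1,
                                baseline = c("matched", "global"),
                                profile_correct = TRUE) {
  baseline <- match.arg(baseline)
  agg <- aggregate_chromosomes(matrix, m = m)
  sc <- score_aggregate(agg, cen_fraction, tel_fraction, baseline,
                        profile_correct = profile_correct)
  sc$s_ct <- cis_trans_score(matrix)
  sc$m <- m
  sc$cen_fraction <- cen_fraction
  sc$tel_fraction <- tel_fraction
  sc$baseline <- baseline
  sc
}
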