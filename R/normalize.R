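#' Mask low-coverage bins before balancing
#'
#' All-zero bins are always masked; additionally, bins whose marginal sum
#' falls below the `min_fraction` quantile of the nonzero marginals are
#' masked. Standard prerequisite for ICE.
#'
#' @param matrix A [hic_matrix()].
#' @param min_fraction Quantile of nonzero marginals below which bins are
#'   masked, in `[0, 1)`.
#' @return The matrix with its `valid` mask updated.
#' @export
mask_low_coverage <- function(matrix, min_fraction = 0.02) {
  stopifnot(inherits(matrix, "hic_matrix"),
            min_fraction >= 0, min_fraction < 1)
  marg <- rowSums(matrix$raw)
  valid <- marg > 0
  nz <- marg[valid]
  if (min_fraction > 0 && length(nz) > 0) {
    thr <- stats::quantile(nz, min_fraction, names = FALSE, type = 7)
    valid <- valid & marg >= thr
  }
  matrix$valid <- valid
  matrix
}

#' ICE balancing (iterative correction)
#'
#' Iteratively divides the matrix by the outer product of relative marginals
#' until every unmasked marginal matches the mean marginal within `tol`.
#' Masked bins are zeroed in the balanced layer. The per-bin bias vector `b`
#' satisfies `balanced = raw / (b_i * b_j)` on unmasked bins; it is reported
#' normalised to unit mean over unmasked bins.
#'
#' @param matrix A [hic_matrix()] with the `valid` mask set (see
#'   [mask_low_coverage()]).
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the maximum relative marginal
#'   deviation.
#' @return The matrix with `balanced` and `bias` filled and a
#'   `converged` flag in `$meta$ice`.
#' @export
ice_balance <- function(matrix, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(matrix, "hic_matrix"), max_iter >= 1, tol > 0)
  v <- matrix$valid
  n <- nrow(matrix$raw)
  m <- matrix$raw
  m[!v, ] <- 0
  m[, !v] <- 0
  bias <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  if (sum(v) > 0) {
    for (iter in seq_len(max_iter)) {
      marg <- rowSums(m)[v]
      if (any(marg == 0)) {
        warning("ICE failed to converge: unmasked bin with zero marginal ",
                "(disconnected block); mask it or lower min_fraction",
                call. = FALSE)
        break
      }
      dev <- marg / mean(marg)
      if (max(abs(dev - 1)) < tol) {
        converged <- TRUE
        break
      }
      d <- rep(1, n)
      d[v] <- dev
      m <- m / outer(d, d)
      bias <- bias * d
    }
    if (!converged && iter == max_iter) {
      warning("ICE did not converge in ", max_iter, " iterations",
              call. = FALSE)
    }
  }
  bias[!v] <- NA_real_
  mb <- mean(bias[v])
  matrix$balanced <- m
  matrix$bias <- bias / mb
  matrix$meta$ice <- list(converged = converged, iterations = iter, tol = tol)
  matrix
}

#' Expected contact profile (distance decay and trans block means)
#'
#' Cis expectation at bin distance `k` is the mean balanced value over all
#' unmasked same-chromosome pairs at `|i - j| = k`, pooled across
#' chromosomes (one shared decay curve; set `per_chromosome = TRUE` for one
#' curve per chromosome). Trans expectation is one scalar per chromosome
#' pair: the mean unmasked balanced value of that block. Distances with no
#' unmasked pairs are flagged undefined (`NA`), and O/E there is missing.
#'
#' @param matrix A [hic_matrix()] with a balanced layer.
#' @param per_chromosome Compute a separate cis curve per chromosome.
#' @return List with `cis` (tibble: `chrom` or "*", `distance` in bins,
#'   `expected`, `n_pairs`) and `trans` (tibble: `chrom1`, `chrom2`,
#'   `expected`, `n_pairs`).
#' @export
expected_profile <- function(matrix, per_chromosome = FALSE) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$balanced)) stop("balanced layer missing; run ice_balance() first",
                                     call. = FALSE)
  bins <- matrix$bins
  v <- matrix$valid
  m <- matrix$balanced
  chroms <- unique(bins$chrom)

  per_chrom_cis <- purrr::map_dfr(chroms, function(ch) {
    ix <- which(bins$chrom == ch)
    vv <- v[ix]
    sub <- m[ix, ix, drop = FALSE]
    nb <- length(ix)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    ok <- outer(vv, vv, "&") & upper.tri(d, diag = TRUE)
    tibble::tibble(chrom = ch, distance = d[ok], value = sub[ok])
  })
  if (per_chromosome) {
    cis <- per_chrom_cis |>
      dplyr::group_by(.data$chrom, .data$distance) |>
      dplyr::summarise(expected = mean(.data$value),
                       n_pairs = dplyr::n(), .groups = "drop")
  } else {
    cis <- per_chrom_cis |>
      dplyr::group_by(.data$distance) |>
      dplyr::summarise(expected = mean(.data$value),
                       n_pairs = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(chrom = "*", .before = 1)
  }

  pairs <- if (length(chroms) >= 2) {
    utils::combn(chroms, 2, simplify = FALSE)
  } else {
    list()
  }
  trans <- tibble::tibble(chrom1 = character(), chrom2 = character(),
                          expected = double(), n_pairs = integer())
  if (length(pairs) > 0) {
    trans <- purrr::map_dfr(pairs, function(p) {
      i1 <- which(bins$chrom == p[1] & v)
      i2 <- which(bins$chrom == p[2] & v)
      block <- m[i1, i2, drop = FALSE]
      tibble::tibble(chrom1 = p[1], chrom2 = p[2],
                     expected = if (length(block) > 0) mean(block) else NA_real_,
                     n_pairs = length(block))
    })
  }
  list(cis = cis, trans = trans, per_chromosome = per_chromosome)
}

#' Observed/expected transform
#'
#' Divides the balanced layer by the expectation: cis entries by the
#' distance-decay curve, trans entries by their chromosome-pair block mean.
#' Masked bins and undefined expectations become `NA` (missing values are
#' never zero-filled) so every downstream aggregate is a masked mean.
#'
#' @param matrix A [hic_matrix()] with a balanced layer.
#' @param expected Optional result of [expected_profile()]; computed if
#'   omitted.
#' @return The matrix with the `oe` layer and `$expected` filled.
#' @export
observed_over_expected <- function(matrix, expected = NULL) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$balanced)) stop("balanced layer missing; run ice_balance() first",
                                     call. = FALSE)
  if (is.null(expected)) expected <- expected_profile(matrix)
  bins <- matrix$bins
  n <- nrow(bins)
  v <- matrix$valid
  e <- matrix(NA_real_, n, n)
  chroms <- unique(bins$chrom)
  for (ch in chroms) {
    ix <- which(bins$chrom == ch)
    nb <- length(ix)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    curve <- expected$cis |>
      dplyr::filter(.data$chrom %in% c(ch, "*"))
    lut <- rep(NA_real_, nb)
    lut[curve$distance + 1L] <- curve$expected
    e[ix, ix] <- matrix(lut[d + 1L], nb, nb)
  }
  for (k in seq_len(nrow(expected$trans))) {
    i1 <- which(bins$chrom == expected$trans$chrom1[k])
    i2 <- which(bins$chrom == expected$trans$chrom2[k])
    e[i1, i2] <- expected$trans$expected[k]
    e[i2, i1] <- expected$trans$expected[k]
  }
  oe <- matrix$balanced / e
  oe[!is.finite(oe)] <- NA_real_
  oe[!v, ] <- NA_real_
  oe[, !v] <- NA_real_
  matrix$oe <- oe
  matrix$expected <- expected
  matrix
}
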