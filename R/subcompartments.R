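#' A/B compartment eigenvector with optional centromere masking
#'
#' Per chromosome, computes the Pearson correlation matrix of cis O/E rows
#' over unmasked bins and extracts its leading eigenvector. With
#' `mask_centromeres = TRUE`, bins overlapping the centromere interval
#' (extended by `cen_flank` bp) are removed before the correlation and
#' reported missing — this reduces the polarization bias that strong
#' centromere clustering exerts on compartment calling. The sign is oriented
#' so that `cor(e1, active_mark) > 0` when `tracks` are supplied; without
#' tracks the sign is arbitrary but deterministic (skewness-positive, i.e.
#' `sum(e1^3) >= 0`).
#'
#' @param matrix A [hic_matrix()] with the O/E layer.
#' @param mask_centromeres Remove centromeric bins before correlation.
#' @param cen_flank Flank (bp) added to each side of the centromere interval
#'   when masking.
#' @param tracks Optional track tibble from [simulate_tracks()] (or measured
#'   equivalents) used for sign orientation.
#' @param min_bins Chromosomes with fewer unmasked bins get `NA` e1.
#' @return Tibble: `bin`, `chrom`, `e1` (`NA` on masked bins).
#' @export
compute_e1 <- function(matrix, mask_centromeres = TRUE, cen_flank = 0,
                       tracks = NULL, min_bins = 10) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$oe)) stop("O/E layer missing; run observed_over_expected() first",
                               call. = FALSE)
  bins <- matrix$bins
  e1 <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    ix <- which(bins$chrom == ch)
    use <- matrix$valid[ix]
    if (mask_centromeres) {
      b <- bins[ix, ]
      # bins overlapping [cen_start - flank, cen_end + flank); the interval
      # is recovered from the flagged centromeric bins
      cen_bins <- b$is_cen
      cen_lo <- min(b$start[cen_bins]) - cen_flank
      cen_hi <- max(b$end[cen_bins]) + cen_flank
      use <- use & !(b$start < cen_hi & b$end > cen_lo)
    }
    if (sum(use) < min_bins) next
    sub <- matrix$oe[ix[use], ix[use], drop = FALSE]
    cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cm[!is.finite(cm)] <- 0
    ev <- eigen(cm, symmetric = TRUE)
    v <- ev$vectors[, 1]
    # orient per chromosome: each chromosome's eigenvector sign is arbitrary
    act <- if (!is.null(tracks) && "active_mark" %in% names(tracks)) {
      tracks$active_mark[match(bins$bin[ix[use]], tracks$bin)]
    } else NULL
    r <- if (!is.null(act)) suppressWarnings(stats::cor(v, act)) else NA_real_
    if (is.finite(r)) {
      if (r < 0) v <- -v
    } else {
      s <- sum(v^3)
      if (s < 0 || (s == 0 && v[1] < 0)) v <- -v
    }
    e1[ix[use]] <- v
  }
  tibble::tibble(bin = bins$bin, chrom = bins$chrom, e1 = e1)
}

# Divide trans O/E entries by their axial-position stratum mean.
# Rabl-type polarization (Cen-Cen, Tel-Tel, Cen-Tel axis) is, by
# construction, a function of the two bins' relative arm positions
# (rho = 0 at the centromere, 1 at the telomere), so binning trans pairs on
# a (rho_i, rho_j) grid and dividing by the stratum mean removes polarization
# from the trans signal, while compartment checkerboards — scattered along
# the axis — survive. The analogue, for trans contacts, of masking
# centromeric regions before compartment calling.
depolarize_trans <- function(oe, bins, n_strata = 10) {
  rho_bin <- pmin(floor(bins$r * n_strata), n_strata - 1) + 1L
  trans <- !cis_mask(bins)
  idx <- which(trans & !is.na(oe), arr.ind = TRUE)
  if (nrow(idx) == 0) return(oe)
  si <- rho_bin[idx[, 1]]
  sj <- rho_bin[idx[, 2]]
  key <- pmin(si, sj) + n_strata * pmax(si, sj)   # symmetric stratum key
  vals <- oe[idx]
  stratum_mean <- tapply(vals, key, mean)
  f <- stratum_mean[as.character(key)]
  f[!is.finite(f) | f <= 0] <- 1
  oe[idx] <- vals / f
  oe
}

#' Infer K interaction states from trans contact profiles
#'
#' Re-implementation of multi-state subcompartment inference on trans
#' contacts: each bin's profile is its trans O/E vector to all bins on other
#' chromosomes (missing-aware); the bin-bin Pearson correlation structure of
#' these profiles is reduced to its top `n_eigen` eigenvectors (scaled by the
#' square root of their eigenvalues) and clustered with k-means (`K`
#' centers, `nstart` restarts, fixed seed). To make the result equivariant
#' under permutations of bin order, clustering runs on a canonically sorted
#' copy of the embedding and bins are then assigned to the nearest centroid;
#' centroids are numbered along their first embedding coordinate.
#'
#' @param matrix A [hic_matrix()] with the O/E layer and at least two
#'   chromosomes.
#' @param K Number of states (5 for A1, A2, B1, B2, B3).
#' @param seed Integer seed for the k-means restarts.
#' @param n_eigen Number of eigenvectors retained.
#' @param nstart k-means restarts.
#' @param depolarize Divide trans O/E by its axial-position stratum mean
#'   first, so Rabl polarization does not masquerade as interaction states
#'   (the trans analogue of centromere masking in compartment calling).
#' @param n_strata Number of axial strata per side for depolarization.
#' @return Tibble: `bin`, `raw_state` (integer 1..K, `NA` on masked bins)
#'   and `score_1..score_K` (negative Euclidean distance to each centroid).
#' @export
infer_states <- function(matrix, K = 5, seed = 1L, n_eigen = 10, nstart = 20,
                         depolarize = TRUE, n_strata = 20) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$oe)) stop("O/E layer missing; run observed_over_expected() first",
                               call. = FALSE)
  bins <- matrix$bins
  if (length(unique(bins$chrom)) < 2) {
    stop("trans-profile state inference needs >= 2 chromosomes", call. = FALSE)
  }
  v <- which(matrix$valid)
  if (length(v) < K) stop("fewer unmasked bins (", length(v),
                          ") than states (", K, ")", call. = FALSE)
  oe <- if (depolarize) {
    depolarize_trans(matrix$oe, matrix$bins, n_strata = n_strata)
  } else {
    matrix$oe
  }
  prof <- oe[v, v, drop = FALSE]
  same <- outer(bins$chrom[v], bins$chrom[v], "==")
  prof[same] <- NA_real_            # trans profiles only
  cm <- suppressWarnings(stats::cor(prof, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  ev <- eigen(cm, symmetric = TRUE)
  k_eig <- min(n_eigen, ncol(ev$vectors))
  emb <- ev$vectors[, seq_len(k_eig), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k_eig)], 0)), k_eig)
  # deterministic eigenvector signs (independent of bin order)
  for (j in seq_len(ncol(emb))) {
    a <- which.max(abs(emb[, j]))
    if (emb[a, j] < 0) emb[, j] <- -emb[, j]
  }
  ord <- do.call(order, as.data.frame(emb))
  set.seed(as.integer(seed))
  km <- stats::kmeans(emb[ord, , drop = FALSE], centers = K, nstart = nstart,
                      iter.max = 100)
  centers <- km$centers[order(km$centers[, 1]), , drop = FALSE]
  d2 <- outer(rowSums(emb^2), rowSums(centers^2), "+") -
    2 * emb %*% t(centers)
  d2[d2 < 0] <- 0
  scores <- -sqrt(d2)
  state <- max.col(scores, ties.method = "first")
  out <- tibble::tibble(bin = bins$bin)
  out$raw_state <- NA_integer_
  out$raw_state[v] <- state
  sc <- matrix(NA_real_, nrow(bins), K)
  sc[v, ] <- scores
  colnames(sc) <- paste0("score_", seq_len(K))
  dplyr::bind_cols(out, tibble::as_tibble(sc))
}

#' Assign A1..B3 labels to inferred states
#'
#' Integrates the compartment eigenvector with track evidence: states whose
#' mean `e1` is positive form the A pool, the rest the B pool; pools are
#' forced to sizes (2, 3) by moving the state with mean e1 nearest zero to
#' the other pool. Within A, the state with the higher mean active mark is
#' A1, the other A2. Within B, the state with the highest polycomb mark is
#' B1; of the remaining two, the state scoring higher on repeat density
#' combined with centromere proximity is B2 (pericentromeric), the other B3
#' (telomeric). Without tracks, labels fall back to `A`/`B` only (flagged
#' with a warning).
#'
#' @param states Result of [infer_states()].
#' @param e1 Result of [compute_e1()].
#' @param tracks Track tibble (needs `active_mark`, `polycomb_mark`,
#'   `repeat_density`) or `NULL`.
#' @param bins Bin table (for centromere proximity).
#' @return Tibble `bin`, `label` (factor A1, A2, B1, B2, B3, or A/B in
#'   fallback mode); the state-by-evidence table is attached as attribute
#'   `evidence` and the state-to-label mapping as attribute `mapping`.
#' @export
label_states <- function(states, e1, tracks, bins) {
  df <- dplyr::left_join(states, e1, by = "bin") |>
    dplyr::left_join(dplyr::select(bins, "bin", "cen_dist", "chrom_length"),
                     by = "bin")
  if (!is.null(tracks)) df <- dplyr::left_join(df, tracks, by = "bin")
  ks <- sort(unique(stats::na.omit(df$raw_state)))
  ev <- df |>
    dplyr::filter(!is.na(.data$raw_state)) |>
    dplyr::group_by(.data$raw_state) |>
    dplyr::summarise(
      n_bins = dplyr::n(),
      mean_e1 = mean(.data$e1, na.rm = TRUE),
      dplyr::across(dplyr::any_of(c("active_mark", "polycomb_mark",
                                    "het_mark", "expression",
                                    "repeat_density")),
                    ~ mean(.x, na.rm = TRUE)),
      cen_proximity = -mean(.data$cen_dist / .data$chrom_length, na.rm = TRUE),
      .groups = "drop"
    )
  has_tracks <- all(c("active_mark", "polycomb_mark", "repeat_density") %in%
                      names(ev))
  in_a <- ev$mean_e1 > 0
  if (!has_tracks) {
    warning("tracks missing: labels fall back to A/B only", call. = FALSE)
    map <- ifelse(in_a, "A", "B")
  } else {
    # force pool sizes (2, 3) by moving states nearest e1 = 0
    while (sum(in_a) > 2) {
      cand <- which(in_a)
      in_a[cand[which.min(abs(ev$mean_e1[cand]))]] <- FALSE
    }
    while (sum(in_a) < 2) {
      cand <- which(!in_a)
      in_a[cand[which.min(abs(ev$mean_e1[cand]))]] <- TRUE
    }
    map <- character(nrow(ev))
    a_pool <- which(in_a)
    a_rank <- a_pool[order(-ev$active_mark[a_pool])]
    map[a_rank] <- c("A1", "A2")
    b_pool <- which(!in_a)
    b1 <- b_pool[which.max(ev$polycomb_mark[b_pool])]
    map[b1] <- "B1"
    rest <- setdiff(b_pool, b1)
    score <- rank(ev$repeat_density[rest]) + rank(ev$cen_proximity[rest])
    b2 <- rest[order(-score, -ev$repeat_density[rest])][1]
    map[b2] <- "B2"
    map[setdiff(rest, b2)] <- "B3"
  }
  names(map) <- ev$raw_state
  lv <- if (has_tracks) subcompartment_levels() else c("A", "B")
  out <- tibble::tibble(
    bin = df$bin,
    label = factor(unname(map[as.character(df$raw_state)]), levels = lv)
  )
  ev$label <- unname(map[as.character(ev$raw_state)])
  attr(out, "evidence") <- ev
  attr(out, "mapping") <- map
  out
}

#' Per-label compartmentalization strength
#'
#' `strength(s) = log2(mean O/E over pairs with both bins labeled s / mean
#' O/E over pairs with exactly one bin labeled s)`, restricted to long-range
#' cis pairs (`>= long_range_bp` apart) plus all trans pairs so that
#' distance decay does not leak into the ratio. Means are missing-aware.
#'
#' @param matrix A [hic_matrix()] with the O/E layer.
#' @param labels Label tibble from [label_states()] (columns `bin`,
#'   `label`).
#' @param long_range_bp Cis distance threshold (bp).
#' @param min_bins Labels with fewer bins get `NA` strength.
#' @param depolarize Divide trans O/E by its axial-position stratum mean
#'   first (see [infer_states()]), so that centromere/telomere clustering
#'   and axis polarization do not leak into within-state means. With
#'   `FALSE`, polarized contacts count towards compartmentalization — for
#'   B2/B3, heterochromatin states defined by pericentromeric/telomeric
#'   repeats, that is arguably part of the signal, but it makes early-stage
#'   strengths of all states hostage to label-geometry noise.
#' @return Tibble: `label`, `strength` (log2), `n_bins`.
#' @export
compartmentalization_strength <- function(matrix, labels,
                                          long_range_bp = 2e6, min_bins = 5,
                                          depolarize = TRUE) {
  stopifnot(inherits(matrix, "hic_matrix"))
  if (is.null(matrix$oe)) stop("O/E layer missing; run observed_over_expected() first",
                               call. = FALSE)
  bins <- matrix$bins
  lab <- as.character(labels$label[match(bins$bin, labels$bin)])
  oe <- if (depolarize) depolarize_trans(matrix$oe, bins) else matrix$oe
  cis <- cis_mask(bins)
  dist_bp <- abs(outer(bins$mid, bins$mid, "-"))
  eligible_pair <- (!cis | dist_bp >= long_range_bp) &
    upper.tri(oe, diag = FALSE)
  lv <- levels(labels$label)
  purrr::map_dfr(lv, function(s) {
    is_s <- !is.na(lab) & lab == s
    other <- !is.na(lab) & lab != s
    n_s <- sum(is_s)
    if (n_s < min_bins) {
      return(tibble::tibble(label = s, strength = NA_real_, n_bins = n_s))
    }
    within <- oe[eligible_pair & outer(is_s, is_s, "&")]
    cross <- oe[eligible_pair &
                  (outer(is_s, other, "&") | outer(other, is_s, "&"))]
    tibble::tibble(
      label = s,
      strength = log2(mean(within, na.rm = TRUE) / mean(cross, na.rm = TRUE)),
      n_bins = n_s
    )
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions; used to compare
#' inferred states with planted ground truth. Pairs with a missing value in
#' either labeling are dropped.
#'
#' @param x,y Vectors of equal length (factors, integers or characters).
#' @return Scalar in `[-1, 1]`, 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  tab <- table(x, y)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  n <- choose2(length(x))
  expected <- a * b / n
  max_index <- (a + b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Best-case label accuracy against ground truth
#'
#' Fraction of bins whose assigned label matches the planted state.
#'
#' @param labels Label tibble from [label_states()].
#' @param truth Bin table with planted `state`.
#' @return Scalar fraction in `[0, 1]`.
#' @export
label_accuracy <- function(labels, truth) {
  lab <- as.character(labels$label[match(truth$bin, labels$bin)])
  ok <- !is.na(lab)
  mean(lab[ok] == as.character(truth$state)[ok])
}
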