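#' Construct a binned contact matrix object
#'
#' A `hic_matrix` bundles a symmetric genome-wide count matrix with its bin
#' table and derived layers. Layers are filled in by the pipeline:
#' `raw` counts, `balanced` (after [ice_balance()]), `oe` (after
#' [observed_over_expected()]). `valid` marks bins that participate in
#' normalization; masked bins are zero in the balanced layer and missing
#' (`NA`) in O/E, and missingness propagates into every aggregate mean.
#'
#' @param counts Symmetric non-negative numeric matrix, N x N with N equal to
#'   the number of bins.
#' @param bins Bin table from [make_bins()].
#' @param meta Optional named list of metadata (sample, stage, ...).
#' @return An object of class `hic_matrix`.
#' @export
hic_matrix <- function(counts, bins, meta = list()) {
  counts <- as.matrix(counts)
  n <- nrow(bins)
  if (!is.numeric(counts) || nrow(counts) != n || ncol(counts) != n) {
    stop("`counts` must be a numeric ", n, " x ", n,
         " matrix matching the bin table", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative contact counts", call. = FALSE)
  if (max(abs(counts - t(counts))) > 1e-9) {
    stop("contact matrix is not symmetric", call. = FALSE)
  }
  structure(
    list(bins = bins, raw = counts, balanced = NULL, oe = NULL,
         bias = NULL, expected = NULL,
         valid = rep(TRUE, n), meta = meta),
    class = "hic_matrix"
  )
}

#' @export
print.hic_matrix <- function(x, ...) {
  n <- nrow(x$raw)
  layers <- c("raw",
              if (!is.null(x$balanced)) "balanced",
              if (!is.null(x$oe)) "oe")
  cat("<hic_matrix> ", n, " x ", n, " bins, ",
      length(unique(x$bins$chrom)), " chromosome(s); layers: ",
      paste(layers, collapse = ", "),
      "; valid bins: ", sum(x$valid), "/", n, "\n", sep = "")
  invisible(x)
}

# n x n logical matrix, TRUE for same-chromosome pairs
cis_mask <- function(bins) {
  outer(bins$chrom, bins$chrom, "==")
}

#' Read a sparse upper-triangle contact matrix (COO TSV)
#'
#' Expects a headerless TSV with columns `bin_i`, `bin_j`, `count`
#' (0-based global bin indices, `bin_i <= bin_j`). Duplicate records for the
#' same pair are summed. The matrix is symmetrized on load.
#'
#' @param path File path.
#' @param bins Bin table from [make_bins()]; defines N and the index space.
#' @return A [hic_matrix()] with the `raw` layer filled.
#' @export
read_coo <- function(path, bins) {
  if (!file.exists(path)) stop("contact matrix file not found: ", path, call. = FALSE)
  coo <- readr::read_tsv(path, col_names = c("bin_i", "bin_j", "count"),
                         col_types = readr::cols(readr::col_double(),
                                                 readr::col_double(),
                                                 readr::col_double()),
                         progress = FALSE)
  n <- nrow(bins)
  bad_idx <- which(coo$bin_i >= n | coo$bin_j >= n | coo$bin_i < 0 | coo$bin_j < 0)
  if (length(bad_idx) > 0) {
    stop("bin index out of range [0, ", n - 1, "] at line ", bad_idx[1],
         " of ", path, call. = FALSE)
  }
  bad_neg <- which(coo$count < 0)
  if (length(bad_neg) > 0) {
    stop("negative count at line ", bad_neg[1], " of ", path, call. = FALSE)
  }
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(coo))) {
    i <- coo$bin_i[k] + 1L
    j <- coo$bin_j[k] + 1L
    m[i, j] <- m[i, j] + coo$count[k]
  }
  m[lower.tri(m)] <- 0
  m <- m + t(m) - diag(diag(m), nrow = n)
  hic_matrix(m, bins, meta = list(source = path))
}

#' Write a contact matrix as sparse upper-triangle COO TSV
#'
#' Inverse of [read_coo()]: writes nonzero upper-triangle entries
#' (`bin_i <= bin_j`, 0-based) of the raw layer; a write/read round trip
#' reproduces the counts exactly.
#'
#' @param matrix A [hic_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coo <- function(matrix, path) {
  stopifnot(inherits(matrix, "hic_matrix"))
  m <- matrix$raw
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  readr::write_tsv(
    tibble::tibble(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                   count = m[idx]),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write a per-bin numeric track as bedGraph
#'
#' @param bins Bin table from [make_bins()].
#' @param values Numeric vector, one value per bin (`NA` rows are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, values, path) {
  stopifnot(length(values) == nrow(bins))
  keep <- !is.na(values)
  readr::write_tsv(
    tibble::tibble(chrom = bins$chrom[keep], start = bins$start[keep],
                   end = bins$end[keep],
                   value = sprintf("%.10g", values[keep])),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write per-bin state labels as BED4
#'
#' @param bins Bin table.
#' @param labels Character/factor vector per bin; `NA` rows are dropped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states_bed <- function(bins, labels, path) {
  stopifnot(length(labels) == nrow(bins))
  keep <- !is.na(labels)
  readr::write_tsv(
    tibble::tibble(chrom = bins$chrom[keep], start = bins$start[keep],
                   end = bins$end[keep], name = as.character(labels[keep])),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
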