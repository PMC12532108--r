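#' Define a genome for binned contact-map analysis
#'
#' A `genome_spec` is the coordinate authority shared by every stage of the
#' pipeline: chromosome names and lengths, one centromere interval per
#' chromosome, the bin size, and the extent from each chromosome end treated
#' as telomeric. Coordinates are 0-based half-open (BED convention).
#'
#' @param chrom_sizes Tibble/data frame with columns `chrom` and `length`
#'   (bp), in genome order.
#' @param centromeres Tibble/data frame with columns `chrom`, `start`, `end`
#'   (bp, 0-based half-open), one interval per chromosome.
#' @param bin_size Bin width in bp (> 0).
#' @param telomere_extent Distance in bp from each chromosome end treated as
#'   telomeric. Defaults to one bin.
#'
#' @return An object of class `genome_spec`: a list with a `chroms` tibble
#'   (`chrom`, `length`, `cen_start`, `cen_end`), `bin_size` and
#'   `telomere_extent`.
#' @export
#' @examples
#' gs <- genome_spec(
#'   tibble::tibble(chrom = "chr1", length = 10e6),
#'   tibble::tibble(chrom = "chr1", start = 4.9e6, end = 5.1e6),
#'   bin_size = 1e5
#' )
genome_spec <- function(chrom_sizes, centromeres, bin_size,
                        telomere_extent = bin_size) {
  stopifnot(is.numeric(bin_size), length(bin_size) == 1, bin_size > 0)
  cs <- tibble::as_tibble(chrom_sizes)
  cen <- tibble::as_tibble(centromeres)
  if (!all(c("chrom", "length") %in% names(cs))) {
    stop("`chrom_sizes` needs columns `chrom` and `length`", call. = FALSE)
  }
  if (!all(c("chrom", "start", "end") %in% names(cen))) {
    stop("`centromeres` needs columns `chrom`, `start`, `end`", call. = FALSE)
  }
  missing_cen <- setdiff(cs$chrom, cen$chrom)
  if (length(missing_cen) > 0) {
    stop("no centromere interval for chromosome(s): ",
         paste(missing_cen, collapse = ", "), call. = FALSE)
  }
  chroms <- dplyr::left_join(
    dplyr::select(cs, "chrom", "length"),
    dplyr::select(cen, "chrom", cen_start = "start", cen_end = "end"),
    by = "chrom"
  )
  short <- chroms$chrom[chroms$length < bin_size]
  if (length(short) > 0) {
    stop("chromosome(s) shorter than one bin: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  few <- chroms$chrom[ceiling(chroms$length / bin_size) < 6]
  if (length(few) > 0) {
    stop("chromosome(s) with fewer than 6 bins (cen/tel/arm regions would ",
         "be empty): ", paste(few, collapse = ", "), call. = FALSE)
  }
  bad_cen <- with(chroms, cen_start <= 0 | cen_end >= length |
                    cen_start >= cen_end |
                    cen_start < telomere_extent |
                    cen_end > length - telomere_extent)
  if (any(bad_cen)) {
    stop("centromere interval must lie strictly inside the chromosome and ",
         "clear of the telomere_extent windows: ",
         paste(chroms$chrom[bad_cen], collapse = ", "), call. = FALSE)
  }
  structure(
    list(chroms = chroms, bin_size = as.numeric(bin_size),
         telomere_extent = as.numeric(telomere_extent)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", nrow(x$chroms), " chromosome(s), bin size ",
      format(x$bin_size, big.mark = ","), " bp, telomere extent ",
      format(x$telomere_extent, big.mark = ","), " bp\n", sep = "")
  print(x$chroms)
  invisible(x)
}

#' Read a chrom.sizes table
#'
#' Two-column TSV (`name`, `length`), no header.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = readr::cols(readr::col_character(),
                                          readr::col_double()),
                  progress = FALSE)
}

#' Read centromere intervals from a BED3 file
#'
#' @param path File path to a 3-column BED (chrom, start, end), no header.
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
read_centromeres <- function(path) {
  if (!file.exists(path)) stop("centromere BED not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = readr::cols(readr::col_character(),
                                          readr::col_double(),
                                          readr::col_double()),
                  progress = FALSE)
}

#' Bin a genome and annotate arms and the centromere-telomere axis
#'
#' Tiles every chromosome into `bin_size` windows (the last bin may be short)
#' and annotates each bin with its arm, distances to the centromere anchor and
#' the nearest chromosome end, and a relative axis position `r`.
#'
#' The centromere is an interval; its midpoint is the single anchor used for
#' arm assignment and rescaling, while `is_cen` flags every bin overlapping
#' the interval itself (used for masking). A bin belongs to the P arm when its
#' midpoint lies before the anchor, otherwise to the Q arm. `r` runs from ~0
#' at the centromere edge to 1 at the telomeric end of each arm: bin midpoint
#' distances from the anchor are normalised by the arm's largest midpoint
#' distance, so the most distal bin of every arm has exactly r = 1 and `r`
#' increases monotonically with distance from the centromere.
#'
#' A chromosome is ACA-eligible (metacentric or submetacentric) when both
#' arms hold at least two bins; acrocentric chromosomes keep all annotations
#' but are flagged `eligible = FALSE` and excluded from aggregate chromosome
#' analysis.
#'
#' @param genome A [genome_spec()].
#' @return Tibble with one row per bin: `chrom`, `start`, `end`, `bin`
#'   (dense 0-based global index in genome order), `mid`, `arm` ("P"/"Q"),
#'   `cen_anchor`, `chrom_length`, `cen_dist` (bp, midpoint to anchor),
#'   `tel_dist` (bp, midpoint to nearest chromosome end), `r`, `is_cen`,
#'   `eligible`.
#' @export
make_bins <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  bs <- genome$bin_size
  bins <- purrr::pmap_dfr(genome$chroms, function(chrom, length, cen_start, cen_end) {
    starts <- seq(0, length - 1, by = bs)
    ends <- pmin(starts + bs, length)
    mid <- (starts + ends) / 2
    anchor <- (cen_start + cen_end) / 2
    arm <- ifelse(mid < anchor, "P", "Q")
    tibble::tibble(
      chrom = chrom, start = starts, end = ends, mid = mid, arm = arm,
      cen_anchor = anchor, chrom_length = length,
      cen_dist = abs(mid - anchor),
      tel_dist = pmin(mid, length - mid),
      is_cen = starts < cen_end & ends > cen_start
    )
  })
  bins$bin <- seq_len(nrow(bins)) - 1L
  bins <- bins |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::mutate(r = if (max(.data$cen_dist) > 0)
                    .data$cen_dist / max(.data$cen_dist) else 0) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(eligible = all(c("P", "Q") %in% .data$arm) &&
                    min(tapply(.data$arm, .data$arm, length)) >= 2) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "bin", "mid", "arm", "cen_anchor",
                  "chrom_length", "cen_dist", "tel_dist", "r", "is_cen",
                  "eligible")
  bins
}

#' Partition bins of ACA-eligible chromosomes into CEN, TEL and ARM regions
#'
#' Region extents are fractions of each arm's bin count: the
#' `ceiling(n_arm * cen_fraction)` bins nearest the centromere form CEN, the
#' `ceiling(n_arm * tel_fraction)` most distal bins form TEL, and the
#' remainder is ARM. The three sets partition the bins of every eligible
#' chromosome; bins of non-eligible chromosomes get `NA`.
#'
#' @param bins A bin table from [make_bins()].
#' @param cen_fraction,tel_fraction Fractions of each arm assigned to the
#'   centromeric / telomeric region; must satisfy
#'   `cen_fraction + 2 * tel_fraction < 1` per-arm non-emptiness.
#' @return The bin table with an added `region` column
#'   (factor: "CEN", "TEL", "ARM"; `NA` off eligible chromosomes).
#' @export
region_masks <- function(bins, cen_fraction = 0.1, tel_fraction = 0.1) {
  stopifnot(cen_fraction > 0, tel_fraction > 0)
  if (cen_fraction + 2 * tel_fraction >= 1) {
    stop("cen_fraction + 2*tel_fraction must be < 1 (ARM would be empty)",
         call. = FALSE)
  }
  out <- bins |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::mutate(
      .n_arm = dplyr::n(),
      .rank = rank(.data$cen_dist, ties.method = "first"),
      region = dplyr::case_when(
        !.data$eligible ~ NA_character_,
        .data$.rank <= ceiling(.data$.n_arm * cen_fraction) ~ "CEN",
        .data$.rank > .data$.n_arm - ceiling(.data$.n_arm * tel_fraction) ~ "TEL",
        TRUE ~ "ARM"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".n_arm", -".rank")
  if (any(out$eligible) &&
      !all(c("CEN", "TEL", "ARM") %in% out$region[out$eligible])) {
    stop("region fractions leave an empty region set", call. = FALSE)
  }
  out$region <- factor(out$region, levels = c("CEN", "ARM", "TEL"))
  out
}
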