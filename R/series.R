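#' Interaction-class fractions of a contact map
#'
#' Fractions of the total raw contact sum in short-range cis
#' (`< threshold_bp`), long-range cis (`>= threshold_bp`) and trans pairs.
#' Computed on raw counts: the fractions describe sequencing-signal
#' composition, not normalized signal. Each unordered pair (and the
#' diagonal) is counted once; the three fractions sum to 1.
#'
#' @param matrix A [hic_matrix()].
#' @param threshold_bp Cis short/long threshold (bp; default 2 Mb).
#' @return One-row tibble: `cis_short`, `cis_long`, `trans`.
#' @export
interaction_fractions <- function(matrix, threshold_bp = 2e6) {
  stopifnot(inherits(matrix, "hic_matrix"))
  bins <- matrix$bins
  m <- matrix$raw
  up <- upper.tri(m, diag = TRUE)
  total <- sum(m[up])
  if (total == 0) stop("empty contact matrix: fractions undefined", call. = FALSE)
  cis <- cis_mask(bins)
  dist_bp <- abs(outer(bins$mid, bins$mid, "-"))
  tibble::tibble(
    cis_short = sum(m[up & cis & dist_bp < threshold_bp]) / total,
    cis_long = sum(m[up & cis & dist_bp >= threshold_bp]) / total,
    trans = sum(m[up & !cis]) / total
  )
}

#' Correlate compartmentalization strength with architecture scores
#'
#' Across the stages of a series, Pearson correlation (exact small-n t-based
#' two-sided p) between (i) A1 compartmentalization strength and the
#' chromosome-territory score, and (ii) the mean of B2/B3 strengths and the
#' composite Rabl score (mean of the Cen-Cen, Tel-Tel and Cen-Tel axis
#' scores). Spearman is available for tiny-n robustness.
#'
#' @param series A `hic_series` object from [run_pipeline()], or a list with
#'   `scores` and `strengths` tibbles in the same shape.
#' @param method "pearson" (default, matching the usual reporting) or
#'   "spearman".
#' @return Tibble: `pair`, `r`, `p`, `n`. Constant inputs give `NA` r
#'   (reported as missing, never 0).
#' @export
correlate_series <- function(series, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- series$scores
  strengths <- series$strengths
  wide <- strengths |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      strength_a1 = .data$strength[.data$label == "A1"][1],
      strength_b23 = mean(.data$strength[.data$label %in% c("B2", "B3")],
                          na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(scores, by = "stage") |>
    dplyr::mutate(rabl_composite =
                    (.data$s_cencen + .data$s_teltel + .data$s_centel_axis) / 3)
  one <- function(pair, x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(pair = pair, r = NA_real_, p = NA_real_, n = n))
    }
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    tibble::tibble(pair = pair, r = unname(ct$estimate), p = ct$p.value, n = n)
  }
  dplyr::bind_rows(
    one("strength_A1~s_ct", wide$strength_a1, wide$s_ct),
    one("strength_B23~rabl", wide$strength_b23, wide$rabl_composite)
  )
}

#' Run the full architecture pipeline over a (simulated) series
#'
#' Per stage: low-coverage masking, ICE balancing, O/E transform, aggregate
#' chromosome analysis and architecture scores, compartment eigenvector,
#' five-state inference, A1..B3 labeling, compartmentalization strengths and
#' interaction fractions; then the cross-stage correlation table. Rerunning
#' with the same config reproduces outputs bitwise.
#'
#' @param config Named list (or path to a flat `key = value` text file).
#'   Simulation mode (`mode = "simulate"`, default) accepts `stages`,
#'   `seed`, `preset_start`, `preset_end`, `n_chrom`, `n_bins`, `bin_size`,
#'   `snr`, `m`, `cen_fraction`, `tel_fraction`. File mode
#'   (`mode = "files"`) requires `chrom_sizes`, `centromere_bed`,
#'   `bin_size` and `matrix_paths` (character vector or comma-separated
#'   string); tracks are then unavailable and labels fall back to A/B.
#' @param out_dir Optional directory: per-stage and summary TSV/BED outputs
#'   plus a `MANIFEST` are written there.
#' @return A `hic_series` object: list with `scores`, `strengths`,
#'   `fractions`, `correlations` tibbles, per-stage `stages` detail
#'   (labels, e1), `truth` (simulation mode) and `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_flat_config(config)
  cfg <- utils::modifyList(
    list(mode = "simulate", stages = 5, seed = 1, n_chrom = 3, n_bins = 100,
         bin_size = 1e5, snr = 3, m = 20, cen_fraction = 0.1,
         tel_fraction = 0.1, min_coverage_fraction = 0.02,
         mask_centromeres = TRUE, baseline = "matched"),
    config
  )
  if (cfg$mode == "simulate") {
    genome <- toy_genome(cfg$n_chrom, cfg$n_bins, cfg$bin_size)
    bins <- make_bins(genome)
    truth <- plant_states(bins, seed = cfg$seed)
    params_start <- cfg$preset_start %||% preset_params("rabl")
    params_end <- cfg$preset_end %||% preset_params("ct")
    mats <- simulate_series(genome, truth, params_start, params_end,
                            n_stages = cfg$stages, seed = cfg$seed)
  } else if (cfg$mode == "files") {
    for (need in c("chrom_sizes", "centromere_bed", "bin_size", "matrix_paths")) {
      if (is.null(cfg[[need]])) {
        stop("pipeline config missing required input: ", need, call. = FALSE)
      }
    }
    if (!file.exists(cfg$centromere_bed)) {
      stop("centromere BED not found: ", cfg$centromere_bed, call. = FALSE)
    }
    genome <- genome_spec(read_chrom_sizes(cfg$chrom_sizes),
                          read_centromeres(cfg$centromere_bed),
                          bin_size = as.numeric(cfg$bin_size))
    bins <- make_bins(genome)
    truth <- NULL
    paths <- if (length(cfg$matrix_paths) == 1)
      strsplit(cfg$matrix_paths, ",")[[1]] else cfg$matrix_paths
    mats <- purrr::imap(paths, function(p, k) {
      m <- read_coo(p, bins)
      m$meta$stage <- k
      m
    })
  } else {
    stop("unknown pipeline mode: ", cfg$mode, call. = FALSE)
  }

  stages <- purrr::imap(mats, function(m, k) {
    run_stage(m, stage = k, cfg = cfg, truth = truth)
  })
  series <- structure(
    list(
      scores = purrr::map_dfr(stages, "scores"),
      strengths = purrr::map_dfr(stages, "strengths"),
      fractions = purrr::map_dfr(stages, "fractions"),
      stages = stages,
      truth = truth,
      config = cfg
    ),
    class = "hic_series"
  )
  series$correlations <- correlate_series(series)
  if (!is.null(out_dir)) write_series(series, out_dir)
  series
}

# one pipeline stage: normalization through strengths
run_stage <- function(m, stage, cfg, truth = NULL) {
  m <- mask_low_coverage(m, cfg$min_coverage_fraction)
  m <- ice_balance(m)
  m <- observed_over_expected(m)
  sc <- architecture_scores(m, m = cfg$m, cen_fraction = cfg$cen_fraction,
                            tel_fraction = cfg$tel_fraction,
                            baseline = cfg$baseline)
  tracks <- if (!is.null(truth)) {
    simulate_tracks(truth, snr = cfg$snr, seed = cfg$seed + 1000L + stage)
  } else NULL
  e1 <- compute_e1(m, mask_centromeres = isTRUE(cfg$mask_centromeres),
                   tracks = tracks)
  states <- infer_states(m, seed = cfg$seed + 2000L + stage)
  labels <- suppressWarnings(label_states(states, e1, tracks, m$bins))
  strengths <- compartmentalization_strength(m, labels)
  list(
    scores = dplyr::mutate(sc, stage = stage, .before = 1),
    strengths = dplyr::mutate(strengths, stage = stage, .before = 1),
    fractions = dplyr::mutate(interaction_fractions(m),
                              stage = stage, .before = 1),
    e1 = e1, states = states, labels = labels, matrix = m
  )
}

#' @export
print.hic_series <- function(x, ...) {
  cat("<hic_series> ", nrow(x$scores), " stage(s)\n", sep = "")
  print(x$scores)
  cat("\nCorrelations:\n")
  print(x$correlations)
  invisible(x)
}

#' Write series outputs to a directory
#'
#' Emits `scores.tsv`, `strengths.tsv`, `fractions.tsv`,
#' `correlations.tsv`, per-stage `e1_<k>.bedGraph` and
#' `subcompartments_<k>.bed`, and a `MANIFEST` naming files and parameters.
#' Numeric formatting is fixed so identical configs reproduce identical
#' bytes.
#'
#' @param series A `hic_series`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric), ~ sprintf("%.10g", .x)))
  readr::write_tsv(fmt(series$scores), file.path(dir, "scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(fmt(series$strengths), file.path(dir, "strengths.tsv"),
                   progress = FALSE)
  readr::write_tsv(fmt(series$fractions), file.path(dir, "fractions.tsv"),
                   progress = FALSE)
  readr::write_tsv(fmt(series$correlations), file.path(dir, "correlations.tsv"),
                   progress = FALSE)
  for (st in series$stages) {
    k <- st$scores$stage[1]
    write_bedgraph(st$matrix$bins, st$e1$e1,
                   file.path(dir, sprintf("e1_stage%02d.bedGraph", k)))
    write_states_bed(st$matrix$bins,
                     st$labels$label[match(st$matrix$bins$bin, st$labels$bin)],
                     file.path(dir, sprintf("subcompartments_stage%02d.bed", k)))
  }
  cfg <- series$config
  keys <- sort(names(cfg)[vapply(cfg, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), TRUE)])
  manifest <- c(
    "hicarch series output",
    paste0("stages=", nrow(series$scores)),
    vapply(keys, function(k)
      paste0(k, "=", paste(format(cfg[[k]], scientific = FALSE),
                           collapse = ",")), ""),
    paste0("files=", paste(sort(setdiff(list.files(dir), "MANIFEST")),
                           collapse = ","))
  )
  writeLines(manifest, file.path(dir, "MANIFEST"))
  invisible(dir)
}

# flat key = value config file; numbers parsed, everything else kept as text
read_flat_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
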