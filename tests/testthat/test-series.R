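test_that("interaction fractions match brute-force strata sums exactly", {
  tg <- toy3()
  truth <- plant_states(tg$bins, seed = 4)
  m <- simulate_contact_map(tg$genome, truth,
                            arch_params(total_contacts = 1e6, seed = 4))
  fr <- interaction_fractions(m)
  expect_equal(fr$cis_short + fr$cis_long + fr$trans, 1, tolerance = 1e-9)
  # brute force over sparse triplets
  idx <- which(upper.tri(m$raw, diag = TRUE) & m$raw != 0, arr.ind = TRUE)
  b <- m$bins
  cs <- cl <- tt <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]; cnt <- m$raw[i, j]
    if (b$chrom[i] != b$chrom[j]) tt <- tt + cnt
    else if (abs(b$mid[i] - b$mid[j]) < 2e6) cs <- cs + cnt
    else cl <- cl + cnt
  }
  tot <- cs + cl + tt
  expect_identical(fr$cis_short, cs / tot)
  expect_identical(fr$cis_long, cl / tot)
  expect_identical(fr$trans, tt / tot)
})

test_that("fraction edge cases: one chromosome, diagonal-only counts", {
  b <- make_bins(ten_bin_genome())
  m <- hic_matrix(matrix(1, 10, 10), b)
  fr <- interaction_fractions(m)
  expect_identical(fr$trans, 0)
  d <- hic_matrix(diag(10) * 4, b)
  frd <- interaction_fractions(d)
  expect_identical(frd$cis_short, 1)
  empty <- hic_matrix(matrix(0, 10, 10), b)
  expect_error(interaction_fractions(empty), "undefined")
})

test_that("series correlations recover exact linear relationships", {
  fake <- list(
    scores = tibble::tibble(stage = 1:3, s_cencen = c(3, 2, 1),
                            s_teltel = c(3, 2, 1), s_centel_axis = c(3, 2, 1),
                            s_ct = c(2, 4, 6)),
    strengths = tidyr::expand_grid(stage = 1:3,
                                   label = subcompartment_levels()) |>
      dplyr::mutate(strength = ifelse(label == "A1", stage,
                                      ifelse(label %in% c("B2", "B3"),
                                             4 - stage, 1)),
                    n_bins = 50L)
  )
  co <- correlate_series(fake)
  expect_equal(co$r[co$pair == "strength_A1~s_ct"], 1)
  expect_equal(co$r[co$pair == "strength_B23~rabl"], 1)
  expect_equal(co$n, c(3L, 3L))
  # anti-ordered vectors give r = -1
  fake2 <- fake
  fake2$scores$s_ct <- c(6, 4, 2)
  co2 <- correlate_series(fake2)
  expect_equal(co2$r[1], -1)
  # constant vector: r reported missing, never 0
  fake3 <- fake
  fake3$scores$s_ct <- c(5, 5, 5)
  co3 <- correlate_series(fake3)
  expect_true(is.na(co3$r[1]))
})

test_that("the pipeline driver reruns bitwise-identically and validates input", {
  cfg <- list(stages = 3, seed = 21, n_bins = 60,
              preset_start = preset_params("rabl", total_contacts = 1e6),
              preset_end = preset_params("ct", total_contacts = 1e6))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ser1 <- run_pipeline(cfg, out_dir = d1)
  ser2 <- run_pipeline(cfg, out_dir = d2)
  files <- list.files(d1)
  expect_true(all(c("scores.tsv", "strengths.tsv", "fractions.tsv",
                    "correlations.tsv", "MANIFEST") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  expect_equal(ser1$scores, ser2$scores)
  expect_equal(nrow(ser1$scores), 3)
  expect_equal(ser1$fractions$cis_short + ser1$fractions$cis_long +
                 ser1$fractions$trans, rep(1, 3), tolerance = 1e-9)
  # missing inputs are named in the error
  expect_error(run_pipeline(list(mode = "files")), "chrom_sizes")
  expect_error(run_pipeline(list(mode = "files", chrom_sizes = "x.sizes",
                                 bin_size = 1e5, matrix_paths = "m.tsv",
                                 centromere_bed = "missing.bed")),
               "missing.bed")
})

test_that("flat config files parse keys, numbers and comments", {
  tmp <- withr::local_tempfile()
  writeLines(c("# comment", "stages = 4", "seed=2", "mode = simulate"), tmp)
  cfg <- hicarch:::read_flat_config(tmp)
  expect_identical(cfg$stages, 4)
  expect_identical(cfg$mode, "simulate")
  writeLines("oops", tmp)
  expect_error(hicarch:::read_flat_config(tmp), "bad config line")
})

test_that("tidy, glance and plots expose the series in standard shapes", {
  cfg <- list(stages = 3, seed = 8, n_bins = 60,
              preset_start = preset_params("rabl", total_contacts = 1e6),
              preset_end = preset_params("ct", total_contacts = 1e6))
  ser <- run_pipeline(cfg)
  td <- tidy(ser)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("stage", "quantity", "value"))
  expect_true(all(c("s_ct", "strength_A1", "trans") %in% td$quantity))
  gl <- glance(ser)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_stages, 3)
  p1 <- autoplot(ser)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_strengths(ser)
  expect_s3_class(p2, "ggplot")
  agg <- aggregate_chromosomes(ser$stages[[1]]$matrix, m = 10)
  p3 <- plot_aggregate_map(agg)
  expect_s3_class(p3, "ggplot")
})

test_that("null series produce calibrated correlation p-values", {
  # no interpolated change: correlations across stages are pure noise
  tg <- toy3()
  pvals <- replicate(12, NA_real_)
  for (i in seq_along(pvals)) {
    truth <- plant_states(tg$bins, seed = i)
    p0 <- arch_params(epsilon = 0.4, total_contacts = 1e6, seed = i)
    mats <- simulate_series(tg$genome, truth, p0, p0, n_stages = 4,
                            seed = 1000 + i * 7)
    stages <- lapply(seq_along(mats), function(k) {
      m <- norm_pipeline(mats[[k]])
      tk <- simulate_tracks(truth, snr = 3, seed = i * 31 + k)
      e1 <- compute_e1(m, tracks = tk)
      st <- infer_states(m, seed = i * 17 + k)
      lb <- suppressWarnings(label_states(st, e1, tk, m$bins))
      list(scores = dplyr::mutate(architecture_scores(m), stage = k),
           strengths = dplyr::mutate(compartmentalization_strength(m, lb),
                                     stage = k))
    })
    fake <- list(scores = purrr::map_dfr(stages, "scores"),
                 strengths = purrr::map_dfr(stages, "strengths"))
    pvals[i] <- correlate_series(fake)$p[1]
  }
  pvals <- pvals[!is.na(pvals)]
  expect_gte(length(pvals), 10)
  # under the null, small p-values are rare
  expect_lte(mean(pvals < 0.05), 0.25)
})
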