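test_that("rescaling is the identity when arms already have m equal bins", {
  b <- make_bins(eight_bin_genome())
  oe <- int_matrix(8)
  r <- rescale_chromosome(oe, b, m = 4)
  expect_equal(unname(r[1:8, 1:8]), unname(oe), ignore_attr = TRUE)
})

test_that("rescaling a 4-bin arm to 2 averages pairs of source bins", {
  b <- make_bins(eight_bin_genome())
  oe <- int_matrix(8)
  r <- rescale_chromosome(oe, b, m = 2)
  # brute-force oracle: each rescaled cell = mean over its 2x2 source block
  groups <- list(1:2, 3:4, 5:6, 7:8)
  oracle <- matrix(NA_real_, 4, 4)
  for (u in 1:4) for (v in 1:4) {
    oracle[u, v] <- mean(oe[groups[[u]], groups[[v]]])
  }
  expect_equal(unname(r), oracle, ignore_attr = TRUE)
  # uniform input stays uniform (mean preservation)
  ru <- rescale_chromosome(matrix(1, 8, 8), b, m = 2)
  expect_true(all(abs(ru - 1) < 1e-12))
  # a missing source cell is excluded, not zero-filled
  oe_na <- oe
  oe_na[1, 1] <- NA
  rna <- rescale_chromosome(oe_na, b, m = 2)
  expect_equal(rna[1, 1], mean(oe[1:2, 1:2][-1]), ignore_attr = TRUE)
})

test_that("aggregation equals the brute-force mean of rescaled blocks", {
  comp <- comp_map(1)
  m <- comp$m
  agg <- aggregate_chromosomes(m, m = 10)
  b <- m$bins
  chroms <- unique(b$chrom)
  # cis oracle
  cis_blocks <- lapply(chroms, function(ch) {
    ix <- which(b$chrom == ch)
    rescale_chromosome(m$oe[ix, ix], b[ix, ], 10)
  })
  cis_oracle <- apply(simplify2array(lapply(cis_blocks, unclass)), c(1, 2),
                      mean, na.rm = TRUE)
  expect_equal(unname(agg$cis), unname(cis_oracle), tolerance = 1e-12)
  # trans oracle over the 3 unordered pairs, symmetrized
  pairs <- utils::combn(chroms, 2, simplify = FALSE)
  tr_blocks <- lapply(pairs, function(p) {
    i1 <- which(b$chrom == p[1])
    i2 <- which(b$chrom == p[2])
    r <- rescale_chromosome(m$oe[i1, i2], b[i1, ], 10, cols = b[i2, ])
    (r + t(r)) / 2
  })
  tr_oracle <- apply(simplify2array(lapply(tr_blocks, unclass)), c(1, 2),
                     mean, na.rm = TRUE)
  expect_equal(unname(agg$trans), unname(tr_oracle), tolerance = 1e-12)
  # symmetric input -> symmetric aggregate
  expect_lt(max(abs(agg$cis - t(agg$cis)), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(agg$trans - t(agg$trans)), na.rm = TRUE), 1e-9)
})

test_that("a genome of identical chromosomes aggregates to the single block", {
  # two chromosomes with identical cis blocks and a constant trans block
  g <- genome_spec(
    tibble::tibble(chrom = c("c1", "c2"), length = c(8e5, 8e5)),
    tibble::tibble(chrom = c("c1", "c2"), start = 3.9e5, end = 4.1e5),
    1e5
  )
  b <- make_bins(g)
  block <- int_matrix(8)
  oe <- matrix(1, 16, 16)
  oe[1:8, 1:8] <- block
  oe[9:16, 9:16] <- block
  m <- hic_matrix(matrix(1, 16, 16), b)
  m$balanced <- m$raw
  m$oe <- oe
  agg <- aggregate_chromosomes(m, m = 4)
  expect_equal(unname(agg$cis), unname(block), ignore_attr = TRUE)
  expect_true(all(abs(agg$trans - 1) < 1e-12))
})

test_that("a uniform aggregate yields zero trans architecture scores", {
  agg <- structure(list(cis = matrix(1, 40, 40), trans = matrix(1, 40, 40),
                        cis_n = matrix(3, 40, 40), trans_n = matrix(3, 40, 40),
                        m = 20, chromosomes = c("a", "b")),
                   class = "hic_aggregate")
  for (bl in c("matched", "global")) {
    sc <- score_aggregate(agg, baseline = bl)
    expect_equal(sc$s_cencen, 0)
    expect_equal(sc$s_teltel, 0)
    expect_equal(sc$s_centel_axis, 0)
  }
})

test_that("each planted component raises its own architecture score", {
  tg <- toy3()
  truth <- plant_states(tg$bins, seed = 2)
  depth <- 5e6
  m_cc <- sim_norm(tg$genome, truth, arch_params(w_cencen = 5, seed = 2,
                                                 total_contacts = depth))
  m_tt <- sim_norm(tg$genome, truth, arch_params(w_teltel = 5, seed = 2,
                                                 total_contacts = depth))
  m_ax <- sim_norm(tg$genome, truth, arch_params(w_axis = 5, seed = 2,
                                                 total_contacts = depth))
  s_cc <- architecture_scores(m_cc)
  s_tt <- architecture_scores(m_tt)
  s_ax <- architecture_scores(m_ax)
  expect_gt(s_cc$s_cencen, 0.5)
  expect_lt(s_cc$s_teltel, 0.1)
  expect_gt(s_tt$s_teltel, 0.5)
  expect_lt(abs(s_tt$s_cencen), 0.2)
  expect_gt(s_ax$s_centel_axis, 0.5)
})

test_that("doubling the territory factor raises s_ct by about one log2 unit", {
  tg <- toy3()
  truth <- plant_states(tg$bins, seed = 3)
  deltas <- sapply(1:3, function(s) {
    m1 <- sim_norm(tg$genome, truth,
                   arch_params(seed = s, total_contacts = 2e6))
    m2 <- sim_norm(tg$genome, truth,
                   arch_params(territory_factor = 2, seed = s,
                               total_contacts = 2e6))
    cis_trans_score(m2) - cis_trans_score(m1)
  })
  expect_true(all(deltas > 0))
  expect_equal(median(deltas), 1, tolerance = 0.1)
})

test_that("acrocentric chromosomes are excluded from aggregation", {
  g <- genome_spec(
    tibble::tibble(chrom = c("meta", "acro"), length = c(8e5, 8e5)),
    tibble::tibble(chrom = c("meta", "acro"), start = c(3.9e5, 1.1e5),
                   end = c(4.1e5, 1.3e5)),
    1e5
  )
  b <- make_bins(g)
  m <- hic_matrix(matrix(1, 16, 16), b)
  m$balanced <- m$raw
  m$oe <- matrix(1, 16, 16)
  agg <- aggregate_chromosomes(m, m = 4)
  expect_equal(agg$chromosomes, "meta")
  expect_null(agg$trans)
  sc <- score_aggregate(agg)
  expect_true(is.na(sc$s_cencen))
})
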