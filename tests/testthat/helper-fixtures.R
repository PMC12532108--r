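# Shared fixtures, built in code. Expensive simulated matrices are memoized
# so several test files can reuse one normalized map.

norm_pipeline <- function(m, min_fraction = 0.02) {
  m <- mask_low_coverage(m, min_fraction)
  m <- ice_balance(m)
  observed_over_expected(m)
}

# simulate + normalize in one go
sim_norm <- function(genome, truth, params) {
  norm_pipeline(simulate_contact_map(genome, truth, params))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy3 <- function() cached("toy3", {
  g <- toy_genome()
  list(genome = g, bins = make_bins(g))
})

# all-structure-off map at full depth, normalized
null_map <- function(seed = 1) cached(paste0("null", seed), {
  tg <- toy3()
  truth <- plant_states(tg$bins, seed = seed)
  list(truth = truth,
       m = sim_norm(tg$genome, truth, arch_params(seed = seed)))
})

# strong-compartment map (epsilon = 0.8), normalized
comp_map <- function(seed = 1) cached(paste0("comp", seed), {
  tg <- toy3()
  truth <- plant_states(tg$bins, seed = seed)
  list(truth = truth,
       m = sim_norm(tg$genome, truth, arch_params(epsilon = 0.8, seed = seed)))
})

# small 1-chromosome genome for hand calculations: 10 bins of 100 kb,
# centromere anchor at 450 kb (midpoint of the interval [420, 480) kb)
ten_bin_genome <- function() {
  genome_spec(
    tibble::tibble(chrom = "chrA", length = 1e6),
    tibble::tibble(chrom = "chrA", start = 4.2e5, end = 4.8e5),
    bin_size = 1e5
  )
}

# 8-bin metacentric chromosome, anchor exactly at 400 kb: 4 bins per arm
eight_bin_genome <- function() {
  genome_spec(
    tibble::tibble(chrom = "chrA", length = 8e5),
    tibble::tibble(chrom = "chrA", start = 3.9e5, end = 4.1e5),
    bin_size = 1e5
  )
}

# symmetric integer test matrix
int_matrix <- function(n) {
  m <- outer(seq_len(n), seq_len(n), function(i, j) i + 2 * j)
  (m + t(m)) / 2
}
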