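#' Parameters of the synthetic contact-map generator
#'
#' The generator plants the architecture signatures seen in embryonic Hi-C —
#' power-law distance decay, cis Rabl "wings" perpendicular to the main
#' diagonal, trans centromere (Cen-Cen) and telomere (Tel-Tel) clustering,
#' centromere-to-telomere axis polarization, a cis-enriching territory
#' factor, and a five-state compartment checkerboard — each controlled by a
#' single weight so monotonicity checks are meaningful. The expected rate for
#' a bin pair is
#' `mu_ij = Z * base_ij * comp_ij * arch_ij`, with cis
#' `base = (|mid_i - mid_j| + s0)^(-alpha) * t`, trans `base = b_t`,
#' `comp = 1 + epsilon * (affinity[s_i, s_j] - mean(affinity))`, and
#' `arch` holding a Gaussian same-|d| wing on opposite arms in cis and
#' exponential centromere/telomere clustering kernels plus a Gaussian
#' relative-axis-position kernel in trans. Each architecture factor is
#' normalised to unit mean over its own pair set, so a clustering weight
#' redistributes contacts towards the poles without changing the genome-wide
#' cis/trans composition — only `territory_factor` moves that. Counts are
#' Poisson.
#'
#' @param alpha Distance-decay exponent (> 0).
#' @param s0 Decay offset in bp; default one 100-kb bin.
#' @param b_t Trans base rate; default `(mean chromosome length / 2)^(-alpha)`
#'   at simulation time (`NULL`).
#' @param w_wing,w_cencen,w_teltel,w_axis Non-negative component weights.
#' @param sigma_wing Length scale (bp) of the cis wing kernel.
#' @param lambda_clust Length scale (bp) of the Cen-Cen / Tel-Tel clustering
#'   kernels.
#' @param sigma_axis Length scale (relative-arm-position units) of the
#'   Cen-Tel axis kernel.
#' @param territory_factor Multiplies every cis rate; >= 1.
#' @param epsilon Compartment contrast (>= 0).
#' @param state_affinity Symmetric 5x5 affinity matrix with unit diagonal
#'   (states A1, A2, B1, B2, B3).
#' @param total_contacts Expected genome-wide count sum.
#' @param seed Integer seed for the Poisson draw.
#' @return An object of class `arch_params` (named list).
#' @export
arch_params <- function(alpha = 1, s0 = 1e5, b_t = NULL,
                        w_wing = 0, w_cencen = 0, w_teltel = 0, w_axis = 0,
                        sigma_wing = 1e6, lambda_clust = 5e5, sigma_axis = 0.1,
                        territory_factor = 1, epsilon = 0,
                        state_affinity = default_affinity(),
                        total_contacts = 1e7, seed = 1L) {
  stopifnot(alpha > 0, s0 > 0, is.null(b_t) || b_t > 0,
            w_wing >= 0, w_cencen >= 0, w_teltel >= 0, w_axis >= 0,
            sigma_wing > 0, lambda_clust > 0, sigma_axis > 0,
            territory_factor >= 1, epsilon >= 0, total_contacts > 0)
  a <- as.matrix(state_affinity)
  if (nrow(a) != 5 || ncol(a) != 5 || max(abs(a - t(a))) > 1e-9 ||
      max(abs(diag(a) - 1)) > 1e-9) {
    stop("state_affinity must be a symmetric 5x5 matrix with unit diagonal",
         call. = FALSE)
  }
  structure(
    list(alpha = alpha, s0 = s0, b_t = b_t, w_wing = w_wing,
         w_cencen = w_cencen, w_teltel = w_teltel, w_axis = w_axis,
         sigma_wing = sigma_wing, lambda_clust = lambda_clust,
         sigma_axis = sigma_axis, territory_factor = territory_factor,
         epsilon = epsilon, state_affinity = a,
         total_contacts = total_contacts, seed = as.integer(seed)),
    class = "arch_params"
  )
}

#' Default subcompartment affinity matrix
#'
#' Same-state contact propensity is 1 for every state; cross-state values
#' encode the A/B split (A1/A2 mix with each other more than with B states)
#' and the stronger segregation of A1, which makes A1 the most
#' self-associating state — the planted analogue of A1-A1 strengthening in
#' differentiated tissue.
#'
#' @return Symmetric 5x5 matrix, states A1, A2, B1, B2, B3.
#' @export
default_affinity <- function() {
  a <- matrix(c(
    1.0, 0.5, 0.1, 0.1, 0.1,
    0.5, 1.0, 0.3, 0.3, 0.3,
    0.1, 0.3, 1.0, 0.5, 0.5,
    0.1, 0.3, 0.5, 1.0, 0.6,
    0.1, 0.3, 0.5, 0.6, 1.0
  ), 5, 5, byrow = TRUE)
  dimnames(a) <- list(subcompartment_levels(), subcompartment_levels())
  a
}

#' Early-embryo-like affinity matrix
#'
#' The counterpart of [default_affinity()] for early stages: A1 is only
#' weakly segregated from the other states (compartmentalization of active
#' chromatin has not yet sharpened) while B2/B3 — pericentromeric and
#' telomeric heterochromatin — mix tightly with each other and stand apart,
#' reflecting heterochromatin-driven early compartments. Interpolating from
#' this matrix to the default across a series emulates the developmental
#' strengthening of A1-A1 interactions.
#'
#' @return Symmetric 5x5 matrix, states A1, A2, B1, B2, B3.
#' @export
early_affinity <- function() {
  a <- matrix(c(
    1.00, 0.70, 0.45, 0.30, 0.30,
    0.70, 1.00, 0.50, 0.35, 0.35,
    0.45, 0.50, 1.00, 0.55, 0.55,
    0.30, 0.35, 0.55, 1.00, 0.80,
    0.30, 0.35, 0.55, 0.80, 1.00
  ), 5, 5, byrow = TRUE)
  dimnames(a) <- list(subcompartment_levels(), subcompartment_levels())
  a
}

#' @rdname arch_params
#' @param preset One of "rabl" (early-embryo-like: strong Cen-Cen/Tel-Tel/axis
#'   and cis wings, no territory enrichment, weak compartments), "ct"
#'   (late-stage-like: clustering off, territory factor 3, strong
#'   compartments) or "mixed" (territory features with residual Cen-Cen, as
#'   in differentiated fly tissue).
#' @param ... Overrides passed on to [arch_params()].
#' @export
preset_params <- function(preset = c("rabl", "ct", "mixed"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    rabl = list(w_wing = 4, w_cencen = 5, w_teltel = 5, w_axis = 5,
                territory_factor = 1, epsilon = 0.6,
                state_affinity = early_affinity()),
    ct = list(w_wing = 0, w_cencen = 0, w_teltel = 0, w_axis = 0,
              territory_factor = 3, epsilon = 0.8,
              state_affinity = default_affinity()),
    mixed = list(w_wing = 1, w_cencen = 3, w_teltel = 0.5, w_axis = 0.5,
                 territory_factor = 2, epsilon = 0.7,
                 state_affinity = (early_affinity() + default_affinity()) / 2)
  )
  do.call(arch_params, utils::modifyList(base, list(...)))
}

#' Subcompartment state names
#' @return Character vector `c("A1","A2","B1","B2","B3")`.
#' @export
subcompartment_levels <- function() c("A1", "A2", "B1", "B2", "B3")

#' Desk-scale synthetic genome
#'
#' Metacentric chromosomes with the centromere interval centred
#' mid-chromosome; convenient ground for simulation and tests.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_bins Bins per chromosome.
#' @param bin_size Bin width (bp).
#' @return A [genome_spec()].
#' @export
toy_genome <- function(n_chrom = 3, n_bins = 100, bin_size = 1e5) {
  len <- n_bins * bin_size
  genome_spec(
    tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)), length = len),
    tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)),
                   start = len / 2 - bin_size / 2,
                   end = len / 2 + bin_size / 2),
    bin_size = bin_size
  )
}

#' Plant ground-truth subcompartment states along the genome
#'
#' States are laid down in contiguous blocks whose lengths are geometric with
#' mean `block_len`. Each block's state is drawn from `proportions`, with B2
#' up-weighted (`cen_multiplier`) when the block starts in the centromeric
#' region and B3 up-weighted (`tel_multiplier`) in the telomeric region,
#' emulating pericentromeric-B2 and telomeric-B3 association.
#'
#' @param bins Bin table from [make_bins()].
#' @param proportions Length-5 state probabilities (A1, A2, B1, B2, B3);
#'   must sum to 1 within 1e-9.
#' @param block_len Mean block length in bins (>= 1).
#' @param seed Integer seed.
#' @param cen_multiplier,tel_multiplier Probability multipliers (>= 1) for B2
#'   in CEN and B3 in TEL regions.
#' @return The bin table with an added `state` factor column (the ground
#'   truth); planting parameters attached as attribute `planting`.
#' @export
plant_states <- function(bins, proportions = rep(0.2, 5), block_len = 5,
                         seed = 1L, cen_multiplier = 3, tel_multiplier = 3) {
  stopifnot(length(proportions) == 5, block_len >= 1,
            cen_multiplier >= 1, tel_multiplier >= 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  }
  lv <- subcompartment_levels()
  regions <- region_masks(bins)$region
  set.seed(as.integer(seed))
  state <- character(nrow(bins))
  for (ch in unique(bins$chrom)) {
    ix <- which(bins$chrom == ch)
    pos <- 1L
    while (pos <= length(ix)) {
      len <- stats::rgeom(1, prob = 1 / block_len) + 1L
      p <- proportions
      reg <- regions[ix[pos]]
      if (!is.na(reg) && reg == "CEN") p[4] <- p[4] * cen_multiplier
      if (!is.na(reg) && reg == "TEL") p[5] <- p[5] * tel_multiplier
      s <- sample(lv, 1, prob = p / sum(p))
      state[ix[pos:min(pos + len - 1L, length(ix))]] <- s
      pos <- pos + len
    }
  }
  out <- dplyr::mutate(bins, state = factor(state, levels = lv))
  attr(out, "planting") <- list(proportions = proportions,
                                block_len = block_len, seed = seed,
                                cen_multiplier = cen_multiplier,
                                tel_multiplier = tel_multiplier)
  out
}

# expected contact rate matrix mu (dense, symmetric), Z-scaled so that the
# upper triangle (incl. diagonal) sums to total_contacts
contact_intensity <- function(genome, truth, params) {
  stopifnot(inherits(params, "arch_params"))
  if (!"state" %in% names(truth)) {
    stop("`truth` must carry a `state` column (see plant_states())",
         call. = FALSE)
  }
  b <- truth
  n <- nrow(b)
  cis <- outer(b$chrom, b$chrom, "==")
  dist_bp <- abs(outer(b$mid, b$mid, "-"))
  b_t <- params$b_t %||% (mean(genome$chroms$length) / 2)^(-params$alpha)
  base <- ifelse(cis,
                 (dist_bp + params$s0)^(-params$alpha) * params$territory_factor,
                 b_t)
  a <- params$state_affinity
  s <- as.integer(b$state)
  comp <- 1 + params$epsilon * (a[cbind(rep(s, n), rep(s, each = n))] - mean(a))
  comp <- matrix(comp, n, n)
  # architecture factors are normalised to unit mean over their own pair set
  # (cis for the wing, trans for the clustering/axis kernels), so each weight
  # redistributes contacts within its compartment of the map without changing
  # the genome-wide cis/trans composition; only territory_factor moves that.
  wing <- cis & outer(b$arm, b$arm, "!=")
  arch <- matrix(1, n, n)
  if (params$w_wing > 0) {
    dd <- outer(b$cen_dist, b$cen_dist, "-")
    f_cis <- 1 + ifelse(wing,
                        params$w_wing * exp(-dd^2 / (2 * params$sigma_wing^2)),
                        0)
    arch[cis] <- f_cis[cis] / mean(f_cis[cis])
  }
  if (params$w_cencen > 0 || params$w_teltel > 0 || params$w_axis > 0) {
    dsum <- outer(b$cen_dist, b$cen_dist, "+")
    esum <- outer(b$tel_dist, b$tel_dist, "+")
    dr <- outer(b$r, b$r, "-")
    f_trans <- 1 + params$w_cencen * exp(-dsum / params$lambda_clust) +
      params$w_teltel * exp(-esum / params$lambda_clust) +
      params$w_axis * exp(-dr^2 / (2 * params$sigma_axis^2))
    if (any(!cis)) arch[!cis] <- f_trans[!cis] / mean(f_trans[!cis])
  }
  mu <- base * comp * arch
  mu <- (mu + t(mu)) / 2
  z <- params$total_contacts / sum(mu[upper.tri(mu, diag = TRUE)])
  mu * z
}

#' Simulate a contact map with planted architecture
#'
#' Draws Poisson counts around the expected rate surface described in
#' [arch_params()] and returns a symmetric raw-count matrix.
#'
#' @param genome A [genome_spec()].
#' @param truth Bin table with a planted `state` column from
#'   [plant_states()].
#' @param params An [arch_params()].
#' @return A [hic_matrix()] with the raw layer filled; the parameters are
#'   stored in `$meta$params`.
#' @export
simulate_contact_map <- function(genome, truth, params) {
  mu <- contact_intensity(genome, truth, params)
  n <- nrow(mu)
  set.seed(params$seed)
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), mu[up])
  counts <- counts + t(counts) - diag(diag(counts), nrow = n)
  m <- hic_matrix(counts, truth, meta = list(params = params))
  m
}

#' Expected (noise-free) contact map
#'
#' The Poisson rate surface itself, as a `hic_matrix` raw layer. Useful as
#' the analytic reference for null calibration, e.g. the null value of the
#' cis/trans territory score.
#'
#' @inheritParams simulate_contact_map
#' @return A [hic_matrix()] whose raw layer holds expected rates.
#' @export
expected_contact_map <- function(genome, truth, params) {
  mu <- contact_intensity(genome, truth, params)
  hic_matrix(mu, truth, meta = list(params = params, expected_rates = TRUE))
}

#' Simulate per-bin epigenetic and sequence tracks
#'
#' Five tracks (`active_mark`, `polycomb_mark`, `het_mark`, `expression`,
#' `repeat_density`) drawn as `state_mean[state] + Normal(0, state_sd/snr)`.
#' Default state means follow the biological ordering: active mark and
#' expression highest in A1 then A2; polycomb mark highest in B1; het mark
#' and repeat density highest in B2/B3 (B2 the more repeat-dense,
#' pericentromeric one).
#'
#' @param truth Bin table with a `state` column.
#' @param snr Signal-to-noise ratio (> 0); `Inf` gives noise-free tracks.
#' @param seed Integer seed.
#' @param state_means 5x5 numeric matrix (rows: tracks; cols: states) or
#'   `NULL` for the default.
#' @param state_sd Common state standard deviation before division by `snr`.
#' @return Tibble: `bin` plus the five track columns.
#' @export
simulate_tracks <- function(truth, snr = 3, seed = 1L, state_means = NULL,
                            state_sd = 1) {
  stopifnot(snr > 0)
  if (is.null(state_means)) state_means <- default_state_means()
  s <- as.integer(truth$state)
  n <- nrow(truth)
  set.seed(as.integer(seed))
  noise_sd <- if (is.finite(snr)) state_sd / snr else 0
  out <- tibble::tibble(bin = truth$bin)
  for (tr in rownames(state_means)) {
    out[[tr]] <- state_means[tr, s] +
      (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  }
  out
}

#' @rdname simulate_tracks
#' @export
default_state_means <- function() {
  m <- rbind(
    active_mark    = c(3.0, 2.0, 0.5, 0.3, 0.3),
    polycomb_mark  = c(0.5, 1.0, 3.0, 0.5, 0.5),
    het_mark       = c(0.3, 0.5, 1.0, 2.5, 2.2),
    expression     = c(3.0, 2.0, 0.5, 0.2, 0.2),
    repeat_density = c(0.5, 0.5, 0.8, 3.0, 2.5)
  )
  colnames(m) <- subcompartment_levels()
  m
}

#' Simulate a developmental series of contact maps
#'
#' Linearly interpolates every component weight, the territory factor, the
#' compartment contrast and the state affinity matrix between two parameter
#' sets across `n_stages`, drawing each stage with a distinct seed. With the
#' default presets this emulates the Rabl-to-territory transition: clustering
#' weights fall while the territory factor rises and A1 affinity sharpens
#' (heterochromatin-driven early compartments giving way to A1-A1
#' segregation).
#'
#' @param genome A [genome_spec()].
#' @param truth Planted bin table from [plant_states()] (shared by all
#'   stages; only the interaction parameters change).
#' @param params_start,params_end [arch_params()] at the first / last stage.
#' @param n_stages Number of stages (>= 2).
#' @param seed Base seed; stage k uses `seed + k - 1`.
#' @return List of [hic_matrix()] objects with `$meta$stage` set.
#' @export
simulate_series <- function(genome, truth,
                            params_start = preset_params("rabl"),
                            params_end = preset_params("ct"),
                            n_stages = 5, seed = 1L) {
  stopifnot(n_stages >= 2)
  purrr::map(seq_len(n_stages), function(k) {
    p <- interpolate_params(params_start, params_end,
                            frac = (k - 1) / (n_stages - 1))
    p$seed <- as.integer(seed + k - 1L)
    m <- simulate_contact_map(genome, truth, p)
    m$meta$stage <- k
    m
  })
}

#' @rdname simulate_series
#' @param frac Interpolation fraction in `[0, 1]`.
#' @export
interpolate_params <- function(params_start, params_end, frac) {
  stopifnot(frac >= 0, frac <= 1)
  p <- params_start
  for (f in c("w_wing", "w_cencen", "w_teltel", "w_axis",
              "territory_factor", "epsilon")) {
    p[[f]] <- (1 - frac) * params_start[[f]] + frac * params_end[[f]]
  }
  p$state_affinity <- (1 - frac) * params_start$state_affinity +
    frac * params_end$state_affinity
  p
}
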