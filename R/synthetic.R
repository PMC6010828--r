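#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulated study system: a smooth environmental
#' landscape with one causal layer, demes at sampling sites exchanging
#' migrants according to a dispersal kernel in landscape resistance,
#' Wright-Fisher drift, and presence points drawn from a suitability
#' function of the causal layer. Defaults describe a desk-scale version of
#' a microsatellite landscape-genetics study: 15 sites, 20 diploid
#' individuals each, 16 loci with up to 10 alleles, deme size 200, 400
#' generations of drift-migration balance, producing pairwise F_ST roughly
#' in 0-0.15 with isolation by distance plus a causal environmental signal.
#'
#' @param seed integer master seed; all outputs are deterministic given it.
#' @param grid_shape raster rows/cols (1 km cells).
#' @param n_sites number of sampling sites (>= 5).
#' @param n_loci,n_alleles microsatellite loci and alleles per locus.
#' @param Ne deme effective size.
#' @param G generations simulated.
#' @param m0 total per-generation emigration fraction of the best-connected
#'   deme, in [0, 1). Migration of every other deme scales down with its
#'   landscape resistance, so poorly connected demes drift.
#' @param causal_token name of the causal layer (default `"PSN"`).
#' @param gradient strength of the broad west-east ramp in the causal layer
#'   relative to its patchy component.
#' @param patch_scale patchiness length-scale of the causal field, in cells.
#' @param decoy_scale length-scale of the decoy fields (finer than the
#'   causal field so decoys do not inherit its broad spatial structure and
#'   act as genuine null predictors).
#' @param noise_sd sd of the perturbation that makes the collinear layer.
#' @param cost_contrast resistance of the worst habitat relative to the
#'   best on the migration surface (mild by design: the environmental
#'   effect modulates, but does not dominate, isolation by distance -
#'   mirroring a system where the environmental signal is detectable yet
#'   marginal).
#' @param kernel_steepness dispersal-kernel decay: migration is
#'   `exp(-R / R_scale)` with `R_scale` the median nearest-neighbor
#'   effective resistance divided by this constant. Larger values localize
#'   dispersal and strengthen isolation by distance.
#' @param suit_steepness,suit_midpoint logistic presence-habitat response:
#'   true suitability is `plogis(steepness * (scaled_causal - midpoint))`,
#'   concentrating presences in the best habitat so the above-cutoff
#'   connectivity pockets away from the main belt are rare and well
#'   separated (the fragmented-margin regime the patch stage targets).
#' @param n_per_site diploid individuals sampled per site.
#' @param migration `"resistance"` (kernel above) or `"uniform"`
#'   (island model; useful as a panmixia control).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, grid_shape = c(56L, 56L), n_sites = 15L,
                       n_loci = 16L, n_alleles = 10L, Ne = 200L, G = 400L,
                       m0 = 0.25, causal_token = "PSN", gradient = 1.0,
                       patch_scale = 6, decoy_scale = 2, noise_sd = 0.25,
                       cost_contrast = 4, kernel_steepness = 4,
                       suit_steepness = 10, suit_midpoint = 0.65,
                       n_per_site = 20L,
                       migration = c("resistance", "uniform")) {
  migration <- match.arg(migration)
  if (m0 < 0 || m0 >= 1) stop("m0 must be in [0, 1)")
  if (n_sites < 5L) stop("need n_sites >= 5")
  stopifnot(n_loci >= 1L, n_alleles >= 2L, Ne >= 2L, G >= 1L, n_per_site >= 1L)
  structure(list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 n_sites = as.integer(n_sites), n_loci = as.integer(n_loci),
                 n_alleles = as.integer(n_alleles), Ne = as.integer(Ne),
                 G = as.integer(G), m0 = m0, causal_token = causal_token,
                 gradient = gradient, patch_scale = patch_scale,
                 decoy_scale = decoy_scale, noise_sd = noise_sd,
                 cost_contrast = cost_contrast,
                 kernel_steepness = kernel_steepness,
                 suit_steepness = suit_steepness,
                 suit_midpoint = suit_midpoint,
                 n_per_site = as.integer(n_per_site), migration = migration),
            class = "sim_config")
}

# Smooth zero-mean unit-sd random field: white noise convolved with a
# Gaussian kernel on the torus (FFT), then standardized.
smooth_field <- function(nr, nc, scale) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * scale^2))
  f <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / sd(f)
}

# Synthetic frame: 1 km cells at a low-latitude origin.
SYN_CELLSIZE_DEG <- 0.0089932
SYN_ORIGIN <- c(lat = 3.6, lon = 31.5)

#' Generate a synthetic environmental stack
#'
#' One causal layer (a broad west-east ramp plus a patchy smooth random
#' field), two decoy layers statistically independent of it (finer-grained,
#' see [sim_config()]), and one layer collinear with the causal one (the
#' causal field plus small smooth noise, pairwise |R| > 0.9) to exercise
#' the covariation filter. All layers share a 1 km frame and are
#' standardized.
#'
#' @param cfg a [sim_config()].
#' @return named list of [raster_grid] layers; the causal layer carries
#'   `cfg$causal_token`, the collinear one is `"GPP"`, decoys `"DST"` and
#'   `"NDVI"`. Deterministic given `cfg$seed`.
#' @export
generate_landscape <- function(cfg) {
  set.seed(cfg$seed)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  ramp <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  causal <- cfg$gradient * ramp + smooth_field(nr, nc, cfg$patch_scale)
  causal <- (causal - mean(causal)) / sd(causal)
  collinear <- causal + cfg$noise_sd * smooth_field(nr, nc, cfg$patch_scale)
  decoy1 <- smooth_field(nr, nc, cfg$decoy_scale)
  decoy2 <- smooth_field(nr, nc, cfg$decoy_scale)
  mk <- function(v) raster_grid(v, SYN_CELLSIZE_DEG, SYN_ORIGIN["lat"],
                                SYN_ORIGIN["lon"])
  out <- list(mk(causal), mk(collinear), mk(decoy1), mk(decoy2))
  names(out) <- c(cfg$causal_token, "GPP", "DST", "NDVI")
  out
}

#' Place sampling sites on the synthetic frame
#'
#' Sites follow a jittered regular grid (inset from the frame edge), the
#' way field campaigns space trap clusters to cover a region evenly; one
#' site per chosen cell.
#'
#' @param cfg a [sim_config()].
#' @param stack output of [generate_landscape()] (provides the frame).
#' @return a `site_table` with ids `S01`, `S02`, ...
#' @export
sim_sites <- function(cfg, stack) {
  set.seed(cfg$seed + 1L)
  frame <- stack[[1]]
  nr <- nrow(frame$values); nc <- ncol(frame$values)
  g <- ceiling(sqrt(cfg$n_sites))
  rs <- round(seq(3, nr - 3, length.out = g))
  cs <- round(seq(3, nc - 3, length.out = g))
  pts <- expand.grid(row = rs, col = cs)
  pts <- pts[sample.int(nrow(pts), cfg$n_sites), ]
  pts$row <- pmin(pmax(pts$row + sample(-2:2, cfg$n_sites, TRUE), 1L), nr)
  pts$col <- pmin(pmax(pts$col + sample(-2:2, cfg$n_sites, TRUE), 1L), nc)
  cc <- cell_center(frame, pts$row, pts$col)
  site_table(sprintf("S%02d", seq_len(cfg$n_sites)), cc$lat, cc$lon,
             n = rep(cfg$n_per_site, cfg$n_sites))
}

# Migration surface of the generator: habitat cost falls linearly from
# `cost_contrast` (worst) to 1 (best) as the causal variable rises. Mild on
# purpose - see sim_config(cost_contrast).
migration_cost_surface <- function(stack, cfg) {
  g <- stack[[cfg$causal_token]]
  v <- g$values
  s <- (v - min(v, na.rm = TRUE)) / (max(v, na.rm = TRUE) - min(v, na.rm = TRUE))
  raster_grid(1 + (cfg$cost_contrast - 1) * (1 - s), g$cellsize_deg,
              g$origin_lat, g$origin_lon, g$nodata_flag)
}

# Deme-to-deme migration matrix: exponential dispersal kernel in effective
# resistance on the causal migration surface, scaled so the best-connected
# deme exports m0 per generation (rows always sum to 1; the diagonal
# absorbs the remainder, so poorly connected demes receive little).
migration_matrix <- function(stack, sites, cfg) {
  n_demes <- nrow(sites)
  if (cfg$migration == "uniform" || cfg$m0 == 0) {
    W <- matrix(1, n_demes, n_demes); diag(W) <- 0
  } else {
    R <- unclass(resistance_matrix(build_graph(migration_cost_surface(stack, cfg)),
                                   sites, mode = "effective"))
    if (any(!is.finite(R[upper.tri(R)])))
      stop("disconnected demes on the migration surface")
    Rnn <- R; diag(Rnn) <- Inf
    r_scale <- median(apply(Rnn, 1, min)) / cfg$kernel_steepness
    W <- exp(-R / r_scale); diag(W) <- 0
  }
  M <- matrix(0, n_demes, n_demes)
  if (cfg$m0 > 0) M <- cfg$m0 * W / max(rowSums(W))
  diag(M) <- 1 - rowSums(M)
  if (any(diag(M) < 0) || any(abs(rowSums(M) - 1) > 1e-9))
    stop("migration matrix failed row-stochasticity after normalization")
  M
}

#' Forward-time simulation of site genotypes
#'
#' Demes sit at the sampling sites. Each generation, allele frequencies mix
#' through a row-stochastic migration matrix derived from the causal
#' landscape: migration between two demes decays exponentially with the
#' effective resistance between them on a mild cost surface of the causal
#' variable (see [sim_config()]), scaled so the best-connected deme
#' exchanges `m0` of its genes per generation. Wright-Fisher drift then
#' resamples `2*Ne` genes per deme per locus. Initial frequencies are a
#' shared ancestral Dirichlet(1) draw; there is no mutation. Finally
#' `n_per_site` diploid individuals are sampled per site under
#' Hardy-Weinberg. Allele size labels are 150, 152, ... mimicking
#' microsatellite repeat lengths.
#'
#' @param stack output of [generate_landscape()].
#' @param sites a `site_table` on the stack's frame.
#' @param cfg a [sim_config()].
#' @return a `genotype_table`. Deterministic given `cfg$seed`.
#' @export
simulate_genotypes <- function(stack, sites, cfg) {
  M <- migration_matrix(stack, sites, cfg)
  n_demes <- nrow(sites)
  set.seed(cfg$seed + 2L)
  K <- cfg$n_alleles; L <- cfg$n_loci
  init <- matrix(0, L, K)
  for (l in seq_len(L)) {
    g <- rgamma(K, 1)
    init[l, ] <- g / sum(g)
  }
  # P: demes x (loci*alleles), column blocks per locus
  P <- matrix(rep(t(init), each = n_demes), n_demes, L * K)
  two_ne <- 2L * cfg$Ne
  for (gen in seq_len(cfg$G)) {
    P <- M %*% P
    for (d in seq_len(n_demes)) for (l in seq_len(L)) {
      cols <- ((l - 1L) * K + 1L):(l * K)
      P[d, cols] <- rmultinom(1L, two_ne, P[d, cols]) / two_ne
    }
  }
  alleles <- 150L + 2L * (seq_len(K) - 1L)
  recs <- vector("list", n_demes * L)
  k <- 0L
  for (d in seq_len(n_demes)) {
    ind_ids <- sprintf("%s_i%02d", sites$id[d], seq_len(cfg$n_per_site))
    for (l in seq_len(L)) {
      cols <- ((l - 1L) * K + 1L):(l * K)
      pr <- P[d, cols]
      a <- sample(alleles, cfg$n_per_site, replace = TRUE, prob = pr)
      b <- sample(alleles, cfg$n_per_site, replace = TRUE, prob = pr)
      k <- k + 1L
      recs[[k]] <- data.frame(site = sites$id[d], individual = ind_ids,
                              locus = l, a = a, b = b,
                              stringsAsFactors = FALSE)
    }
  }
  genotype_table(do.call(rbind, recs), n_loci = L)
}

#' Ground-truth suitability surface of the synthetic landscape
#'
#' The presence process of the simulated species: a steep logistic response
#' of the min-max-scaled causal layer (habitat quality rises with the
#' causal variable, consistent with the migration model where high values
#' conduct; see [sim_config()] for the response parameters).
#'
#' @param stack output of [generate_landscape()].
#' @param cfg a [sim_config()].
#' @return a `surface_raster`.
#' @export
true_suitability <- function(stack, cfg) {
  g <- stack[[cfg$causal_token]]
  v <- g$values
  s <- (v - min(v, na.rm = TRUE)) / (max(v, na.rm = TRUE) - min(v, na.rm = TRUE))
  s <- plogis(cfg$suit_steepness * (s - cfg$suit_midpoint))
  out <- raster_grid(s, g$cellsize_deg, g$origin_lat, g$origin_lon)
  attr(out, "role") <- "suitability"
  class(out) <- c("surface_raster", class(out))
  out
}

#' Draw presence points from a suitability surface
#'
#' `n` distinct cells sampled without replacement with probability
#' proportional to suitability; returned coordinates are cell centers
#' (trap clusters snapped to the 1 km grid).
#'
#' @param suitability a `surface_raster` with values in [0, 1].
#' @param n number of presence points.
#' @param seed integer seed.
#' @return a `presence_set`.
#' @export
sample_presences <- function(suitability, n, seed = 1L) {
  v <- suitability$values
  pos <- which(!is.na(v) & v > 0)
  if (n > length(pos))
    stop("n exceeds the number of positive-suitability cells (",
         length(pos), ")")
  set.seed(as.integer(seed))
  pick <- sample(pos, n, prob = v[pos])
  rc <- arrayInd(pick, dim(v))
  cc <- cell_center(suitability, rc[, 1], rc[, 2])
  presence_set(cc$lat, cc$lon)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing everything the pipeline consumes, with
#' known ground truth: the environmental stack, sites, genotypes, presence
#' points (drawn from the true suitability), and the causal variable token.
#'
#' @param cfg a [sim_config()].
#' @param n_presences presence points to draw (default 150).
#' @return list with `stack`, `sites`, `genotypes`, `presences`,
#'   `suitability`, `causal`, `cfg`.
#' @export
synthetic_dataset <- function(cfg = sim_config(), n_presences = 150L) {
  stack <- generate_landscape(cfg)
  sites <- sim_sites(cfg, stack)
  genotypes <- simulate_genotypes(stack, sites, cfg)
  suit <- true_suitability(stack, cfg)
  presences <- sample_presences(suit, n_presences, seed = cfg$seed + 3L)
  list(stack = stack, sites = sites, genotypes = genotypes,
       presences = presences, suitability = suit,
       causal = cfg$causal_token, cfg = cfg)
}
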