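# Per-site, per-locus sufficient statistics for the Weir-Cockerham estimator:
# sample size, allele frequencies, and per-allele heterozygote frequencies.
# theta for any pair of sites depends only on these, so they are computed once.
site_locus_stats <- function(genotypes) {
  n_loci <- attr(genotypes, "n_loci")
  g <- genotypes[!is.na(genotypes$a), ]
  split_site <- split(g, g$site)
  lapply(split_site, function(gs) {
    by_locus <- split(gs, factor(gs$locus, levels = seq_len(n_loci)))
    lapply(by_locus, function(gl) {
      n <- nrow(gl)
      if (n == 0L) return(NULL)
      alleles <- c(gl$a, gl$b)
      p <- table(alleles) / (2 * n)
      het <- gl$a != gl$b
      h <- vapply(names(p), function(u) {
        u <- as.integer(u)
        sum(het & (gl$a == u | gl$b == u)) / n
      }, numeric(1))
      list(n = n, p = p, h = h)
    })
  })
}

# Weir-Cockerham (1984) variance components for one pair of populations at
# one locus; returns c(a, b, c) summed over alleles. r = 2 populations.
wc_components <- function(s1, s2) {
  n1 <- s1$n; n2 <- s2$n
  if (n1 + n2 <= 2L) return(c(0, 0, 0))
  alleles <- union(names(s1$p), names(s2$p))
  p1 <- setNames(numeric(length(alleles)), alleles); p1[names(s1$p)] <- s1$p
  p2 <- setNames(numeric(length(alleles)), alleles); p2[names(s2$p)] <- s2$p
  h1 <- setNames(numeric(length(alleles)), alleles); h1[names(s1$h)] <- s1$h
  h2 <- setNames(numeric(length(alleles)), alleles); h2[names(s2$h)] <- s2$h
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(sum(a), sum(b), sum(cc))
}

# Multilocus theta: components summed over loci (and alleles) before the ratio.
theta_pair <- function(stats1, stats2, n_loci) {
  acc <- c(0, 0, 0)
  for (l in seq_len(n_loci)) {
    s1 <- stats1[[l]]; s2 <- stats2[[l]]
    if (is.null(s1) || is.null(s2)) next
    acc <- acc + wc_components(s1, s2)
  }
  denom <- sum(acc)
  if (denom == 0) return(NA_real_)   # no shared polymorphic locus
  acc[1] / denom
}

#' Pairwise multilocus Weir-Cockerham F_ST
#'
#' Computes the Weir-Cockerham (1984) theta estimator for every pair of
#' sampling sites, summing the a/b/c variance components over loci (and
#' alleles) before taking the ratio. Missing genotypes are handled
#' locus-wise: each locus contributes the individuals typed at it in both
#' sites. Significance per pair is assessed by relabeling individuals between
#' the two sites and recomputing theta, with the +1 permutation correction.
#'
#' @param genotypes a `genotype_table` (see [read_genotypes()]).
#' @param sites a `site_table`; its id order fixes the matrix order. Sites
#'   absent from the genotype data are an error.
#' @param n_perm individual-relabeling permutations per pair (0 skips
#'   p-values).
#' @param seed integer seed for the permutations.
#' @return a [pairwise_matrix] of kind `"fst"`. Negative estimates are
#'   reported as computed (clamping to zero happens in [linearize_fst()]).
#'   Attributes: `p_values` (matrix, `NA` off-permutation), `undefined`
#'   (logical matrix flagging pairs with no shared typed polymorphic locus).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fst_matrix <- function(genotypes, sites, n_perm = 0L, seed = 1L) {
  ids <- sites$id
  if (length(ids) < 2L) stop("need at least two sites")
  missing_sites <- setdiff(ids, unique(genotypes$site))
  if (length(missing_sites))
    stop("no genotypes for site(s): ", paste(missing_sites, collapse = ", "))
  n_loci <- attr(genotypes, "n_loci")
  stats <- site_locus_stats(genotypes)
  n <- length(ids)
  theta <- matrix(0, n, n)
  pmat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  undef <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n_perm > 0L) set.seed(as.integer(seed))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    t_obs <- theta_pair(stats[[ids[i]]], stats[[ids[j]]], n_loci)
    if (is.na(t_obs)) { undef[i, j] <- undef[j, i] <- TRUE; next }
    theta[i, j] <- theta[j, i] <- t_obs
    if (n_perm > 0L) {
      gp <- genotypes[genotypes$site %in% ids[c(i, j)], ]
      inds <- unique(gp$individual)
      sizes <- c(sum(unique(gp[, c("site", "individual")])$site == ids[i]))
      hits <- 0L
      for (k in seq_len(n_perm)) {
        lab1 <- sample(inds, sizes)
        gp$site_perm <- ifelse(gp$individual %in% lab1, "A", "B")
        gq <- gp; gq$site <- gq$site_perm
        st <- site_locus_stats(genotype_table(gq, n_loci = n_loci))
        t_star <- theta_pair(st[["A"]], st[["B"]], n_loci)
        if (!is.na(t_star) && t_star >= t_obs) hits <- hits + 1L
      }
      pmat[i, j] <- pmat[j, i] <- (1 + hits) / (n_perm + 1)
    }
  }
  out <- pairwise_matrix(ids, theta, "fst")
  attr(out, "p_values") <- pmat
  attr(out, "undefined") <- undef
  out
}

#' Linearize F_ST as F/(1-F)
#'
#' Rousset's adjustment for finite populations: linearized F_ST grows
#' approximately linearly with distance under equilibrium isolation by
#' distance. Negative estimates are clamped to zero before the transform
#' (the estimator's negative values mean "no differentiation").
#'
#' @param fst a [pairwise_matrix] of kind `"fst"` with all values < 1.
#' @return a [pairwise_matrix] of kind `"linearized_fst"`. Pairs at exactly
#'   F = 1 become `Inf`.
#' @export
linearize_fst <- function(fst) {
  if (attr(fst, "kind") != "fst") stop("input must be a kind='fst' matrix")
  v <- unclass(fst)
  if (any(v > 1, na.rm = TRUE)) stop("F_ST > 1 is not a valid input")
  v <- pmax(v, 0)
  out <- v / (1 - v)
  out[v == 1] <- Inf
  pairwise_matrix(rownames(fst), out, "linearized_fst")
}

#' Per-site diversity statistics
#'
#' Allelic richness (plain mean observed allele count per locus, no
#' rarefaction - note unequal sample sizes inflate AR for larger samples),
#' observed heterozygosity, unbiased expected heterozygosity
#' \eqn{(2n/(2n-1))(1 - \sum p_i^2)}, and the fixation index
#' \eqn{F_{IS} = 1 - H_O/H_E}.
#'
#' @param genotypes a `genotype_table`.
#' @return data.frame with columns `site`, `AR`, `H_O`, `H_E`, `F_IS`
#'   (`F_IS` is `NA` for monomorphic sites where `H_E = 0`).
#' @export
diversity_stats <- function(genotypes) {
  n_loci <- attr(genotypes, "n_loci")
  stats <- site_locus_stats(genotypes)
  rows <- lapply(names(stats), function(s) {
    per_locus <- stats[[s]]
    typed <- !vapply(per_locus, is.null, logical(1))
    if (!any(typed)) return(NULL)
    ar <- mean(vapply(per_locus[typed], function(x) length(x$p), numeric(1)))
    ho <- mean(vapply(per_locus[typed], function(x) sum(x$h) / 2, numeric(1)))
    he <- mean(vapply(per_locus[typed], function(x) {
      n <- x$n
      if (2 * n <= 1) return(0)
      (2 * n / (2 * n - 1)) * (1 - sum(x$p^2))
    }, numeric(1)))
    fis <- if (he > 0) 1 - ho / he else NA_real_
    data.frame(site = s, AR = ar, H_O = ho, H_E = he, F_IS = fis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Haversine great-circle distance between two points
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return distance in km on a sphere of radius 6371.0088 km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Pairwise great-circle distance matrix
#' @param sites a `site_table`.
#' @return a [pairwise_matrix] of kind `"distance_km"`.
#' @export
distance_matrix_km <- function(sites) {
  pts <- cbind(sites$lon, sites$lat)
  d <- geosphere::distm(pts, fun = function(x, y)
    geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM))
  pairwise_matrix(sites$id, d, "distance_km")
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation of the unfolded lower triangles of a genetic and a
#' geographic distance matrix, with significance from joint row/column
#' permutation of the genetic matrix (one-sided, r* >= r, +1 correction).
#'
#' @param genetic,geographic [pairwise_matrix] objects sharing the same id
#'   order.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_ibd <- function(genetic, geographic, n_perm = 10000L, seed = 1L) {
  check_same_ids(genetic, geographic)
  n <- nrow(genetic)
  if (n < 4L) stop("Mantel test needs at least 4 sites")
  x <- lower_triangle(genetic)
  y <- lower_triangle(geographic)
  if (sd(x) == 0 || sd(y) == 0) stop("constant matrix: Mantel r undefined")
  r_obs <- cor(x, y)
  set.seed(as.integer(seed))
  g <- unclass(genetic)
  hits <- 0L
  lt <- lower.tri(g)
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_star <- cor(g[idx, idx][lt], y)
    if (r_star >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

check_same_ids <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1]])
  for (m in mats[-1])
    if (!identical(rownames(m), ids))
      stop("matrices do not share the same site id order")
  invisible(ids)
}
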