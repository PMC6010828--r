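# Shared fixtures and independent oracles. Everything here is deliberately
# written as simple, direct computation so it can disagree with the package's
# (more optimized) implementations.

# -- coordinate convention shared by every fixture: degrees, latitude first,
#    cell centers; ~1 km cells at a low-latitude test frame.
FIX_CS <- 0.0089932
FIX_LAT <- 3.0
FIX_LON <- 31.0

fix_grid <- function(values) {
  raster_grid(as.matrix(values), FIX_CS, FIX_LAT, FIX_LON)
}

# Sites placed on cell centers (row/col 1-based) of a fix_grid frame.
fix_sites <- function(rows, cols, ids = sprintf("s%02d", seq_along(rows))) {
  lat <- FIX_LAT - (rows - 1) * FIX_CS
  lon <- FIX_LON + (cols - 1) * FIX_CS
  site_table(ids, lat, lon)
}

# Long-format genotype builder: alleles is a list (one element per
# individual) of per-locus c(a, b) pairs stored as a 2 x L matrix.
toy_genotypes <- function(site, alleles_by_ind, n_loci) {
  recs <- list()
  for (i in seq_along(alleles_by_ind)) {
    m <- alleles_by_ind[[i]]
    recs[[i]] <- data.frame(site = site,
                            individual = sprintf("%s_i%d", site, i),
                            locus = seq_len(n_loci),
                            a = m[1, ], b = m[2, ])
  }
  do.call(rbind, recs)
}

# ---- Weir-Cockerham (1984) single-pair oracle ------------------------------
# Direct transliteration of the published component formulas, organized
# around explicit per-individual genotype lists (not the package's
# sufficient-statistics path). r = 2 populations.
wc_theta_oracle <- function(geno1, geno2) {
  # genoX: list of c(a, b) integer pairs (one per individual), NA = missing
  acc_a <- acc_b <- acc_c <- 0
  g1 <- Filter(function(g) !any(is.na(g)), geno1)
  g2 <- Filter(function(g) !any(is.na(g)), geno2)
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0 || n2 == 0 || n1 + n2 <= 2) return(NA_real_)
  alleles <- unique(c(unlist(g1), unlist(g2)))
  r <- 2
  nbar <- (n1 + n2) / 2
  nC <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  for (u in alleles) {
    p1 <- sum(unlist(g1) == u) / (2 * n1)
    p2 <- sum(unlist(g2) == u) / (2 * n2)
    h1 <- mean(vapply(g1, function(g) g[1] != g[2] && u %in% g, logical(1)))
    h2 <- mean(vapply(g2, function(g) g[1] != g[2] && u %in% g, logical(1)))
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nC) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    acc_a <- acc_a + a; acc_b <- acc_b + b; acc_c <- acc_c + cc
  }
  acc_a / (acc_a + acc_b + acc_c)
}

# Multilocus version: components summed across loci before the ratio.
wc_theta_oracle_multi <- function(loci1, loci2) {
  # lociX: list over loci; each element a list of c(a,b) per individual
  num <- den <- 0
  for (l in seq_along(loci1)) {
    g1 <- Filter(function(g) !any(is.na(g)), loci1[[l]])
    g2 <- Filter(function(g) !any(is.na(g)), loci2[[l]])
    n1 <- length(g1); n2 <- length(g2)
    if (n1 == 0 || n2 == 0 || n1 + n2 <= 2) next
    alleles <- unique(c(unlist(g1), unlist(g2)))
    r <- 2; nbar <- (n1 + n2) / 2
    nC <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (u in alleles) {
      p1 <- sum(unlist(g1) == u) / (2 * n1)
      p2 <- sum(unlist(g2) == u) / (2 * n2)
      h1 <- mean(vapply(g1, function(g) g[1] != g[2] && u %in% g, logical(1)))
      h2 <- mean(vapply(g2, function(g) g[1] != g[2] && u %in% g, logical(1)))
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      num <- num + (nbar / nC) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      den <- den + (nbar / nC) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1)) +
        (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                 (2 * nbar - 1) / (4 * nbar) * hbar) +
        hbar / 2
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Random two-site genotype table plus the nested-list form the oracle eats.
random_pair_dataset <- function(seed, n1 = 6, n2 = 9, n_loci = 3,
                                n_alleles = 4, miss_rate = 0.1) {
  set.seed(seed)
  alle <- 150L + 2L * (seq_len(n_alleles) - 1L)
  draw <- function(n) {
    lapply(seq_len(n_loci), function(l) {
      lapply(seq_len(n), function(i) {
        if (runif(1) < miss_rate) return(c(NA_integer_, NA_integer_))
        sort(sample(alle, 2, replace = TRUE))
      })
    })
  }
  l1 <- draw(n1); l2 <- draw(n2)
  to_df <- function(site, loci, n) {
    do.call(rbind, lapply(seq_len(n_loci), function(l) {
      data.frame(site = site, individual = sprintf("%s_i%d", site, seq_len(n)),
                 locus = l,
                 a = vapply(loci[[l]], `[`, integer(1), 1),
                 b = vapply(loci[[l]], `[`, integer(1), 2))
    }))
  }
  gt <- genotype_table(rbind(to_df("A", l1, n1), to_df("B", l2, n2)),
                       n_loci = n_loci)
  list(gt = gt, loci1 = l1, loci2 = l2,
       sites = fix_sites(c(1, 5), c(1, 5), ids = c("A", "B")))
}

# ---- dense Laplacian pseudo-inverse oracle ---------------------------------
effective_resistance_oracle <- function(n, edges) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; g <- edges$conductance[k]
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
  }
  Lp <- solve(L + 1 / n) - 1 / n          # Moore-Penrose inverse of L
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    R[i, j] <- Lp[i, i] + Lp[j, j] - 2 * Lp[i, j]
  R
}

# Random connected graph with <= n_max nodes; returns a conductance_graph
# whose raster is a 1 x n strip (so focal mapping works) but whose edges are
# arbitrary.
random_graph <- function(seed, n_max = 15) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  grid <- fix_grid(matrix(1, 1, n))
  g <- build_graph(grid, 4)               # guarantees a connected backbone
  extra <- t(combn(n, 2))
  extra <- extra[sample(nrow(extra), min(n, nrow(extra))), , drop = FALSE]
  edges <- rbind(g$edges,
                 data.frame(i = extra[, 1], j = extra[, 2],
                            conductance = runif(nrow(extra), 0.1, 2)))
  g$edges <- edges
  g
}

graph_sites <- function(graph, nodes, ids = sprintf("f%d", seq_along(nodes))) {
  rows <- graph$nodes$row[match(nodes, graph$nodes$id)]
  cols <- graph$nodes$col[match(nodes, graph$nodes$id)]
  cc <- cell_center(graph$grid, rows, cols)
  site_table(ids, cc$lat, cc$lon)
}

# ---- recursive flood-fill labeling oracle ----------------------------------
flood_fill_oracle <- function(fg, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  cur <- 0L
  for (sr in seq_len(nr)) for (sc in seq_len(nc)) {
    if (!fg[sr, sc] || lab[sr, sc] != 0L) next
    cur <- cur + 1L
    stack <- list(c(sr, sc))
    lab[sr, sc] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && fg[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Canonical relabeling so two labelings compare as partitions.
canonical_labels <- function(lab) {
  ord <- unique(lab[lab > 0])
  out <- lab
  for (k in seq_along(ord)) out[lab == ord[k]] <- k
  out
}

# ---- random symmetric matrices for permutation-null experiments ------------
random_pairwise <- function(n, ids = sprintf("s%02d", seq_len(n)),
                            kind = "resistance") {
  m <- matrix(rnorm(n * n), n, n)
  m <- m + t(m); diag(m) <- 0
  pairwise_matrix(ids, m, kind)
}
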