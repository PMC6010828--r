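surface_from <- function(vals) {
  g <- fix_grid(vals)
  attr(g, "role") <- "connectivity"
  class(g) <- c("surface_raster", class(g))
  g
}

test_that("patch extraction: strict cutoff, minimum size, flood-fill agreement", {
  v <- matrix(0, 8, 8)
  v[2:3, 2:3] <- 0.9          # blob of 4
  v[6, 6] <- 0.8              # singleton, below min size
  v[5, 2] <- 0.5              # exactly at the cutoff: background
  ps <- extract_patches(surface_from(v), cutoff = 0.5, min_size = 4)
  expect_equal(nrow(ps$table), 1L)
  expect_equal(ps$table$pixels, 4L)
  expect_equal(ps$labels$values[5, 2], 0L)

  # two 8-connected blobs of 5 and 3 pixels, min_size 4 -> one patch of 5
  v2 <- matrix(0, 8, 8)
  v2[cbind(c(1, 2, 2, 3, 3), c(1, 1, 2, 2, 3))] <- 1   # 8-connected chain of 5
  v2[cbind(c(6, 7, 7), c(6, 6, 7))] <- 1               # blob of 3
  ps2 <- extract_patches(surface_from(v2), min_size = 4)
  expect_equal(nrow(ps2$table), 1L)
  expect_equal(ps2$table$pixels, 5L)

  # empty foreground is an empty patch set, not an error
  ps0 <- extract_patches(surface_from(matrix(0.2, 4, 4)))
  expect_equal(nrow(ps0$table), 0L)
})

test_that("component labeling equals the recursive flood-fill oracle", {
  set.seed(31)
  for (rep in 1:8) {
    nr <- sample(5:50, 1); nc <- sample(5:50, 1)
    fg <- matrix(runif(nr * nc) < 0.45, nr, nc)
    for (conn in c(4, 8)) {
      mine <- isopatch:::label_components(fg, conn)
      oracle <- flood_fill_oracle(fg, conn)
      expect_identical(canonical_labels(mine), canonical_labels(oracle))
    }
  }
})

test_that("patch structure is monotone: min-size count, foreground, nesting", {
  set.seed(32)
  v <- plogis(2 * isopatch:::smooth_field(40, 40, 3))
  # count is non-increasing in the minimum mapping unit at every cutoff
  for (ct in seq(0.35, 0.65, by = 0.1)) {
    counts_ms <- sapply(2:7, function(ms)
      nrow(extract_patches(surface_from(v), cutoff = ct, min_size = ms)$table))
    expect_true(all(diff(counts_ms) <= 0))
  }
  # raising the cutoff shrinks the foreground and nests the patches:
  # every higher-cutoff patch pixel lies inside some lower-cutoff patch
  # (the count itself can rise when a blob splits, so it is not asserted)
  labs <- lapply(seq(0.35, 0.65, by = 0.05), function(ct)
    extract_patches(surface_from(v), cutoff = ct, min_size = 1)$labels$values)
  fg <- vapply(labs, function(l) sum(l > 0), numeric(1))
  expect_true(all(diff(fg) <= 0))
  for (k in seq_along(labs)[-1])
    expect_true(all(labs[[k - 1]][labs[[k]] > 0] > 0))
})

test_that("gap-distance clustering: thresholds and single-linkage transitivity", {
  # 1 km cells; patches in one row with controlled gaps
  v <- matrix(0, 3, 30)
  v[2, 1:2] <- 1         # patch A (cols 1-2)
  v[2, 6:7] <- 1         # patch B: gap 3 cells (~3 km) from A
  v[2, 14:15] <- 1       # patch C: gap 6 cells (~6 km) from B
  ps <- cluster_patches(extract_patches(surface_from(v), min_size = 2),
                        range_km = 5)
  tab <- ps$table[order(ps$table$centroid_lon), ]
  expect_equal(tab$cluster[1], tab$cluster[2])   # A-B merged (3 km < 5)
  expect_false(tab$cluster[2] == tab$cluster[3]) # B-C split (6 km > 5)

  # chain A-B 4, B-C 4, A-C 8 -> one cluster by single linkage
  v2 <- matrix(0, 3, 30)
  v2[2, 1:2] <- 1; v2[2, 7:8] <- 1; v2[2, 13:14] <- 1
  ps2 <- cluster_patches(extract_patches(surface_from(v2), min_size = 2),
                         range_km = 5)
  expect_equal(length(unique(ps2$table$cluster)), 1L)
})

test_that("clustering is invariant to patch label permutation", {
  set.seed(33)
  v <- matrix(0, 20, 20)
  v[2:3, 2:4] <- 1; v[10:12, 10] <- 1; v[14:15, 12:13] <- 1  # last two merge
  ps <- cluster_patches(extract_patches(surface_from(v), min_size = 2),
                        range_km = 5)
  # permute labels manually and re-cluster
  ps_perm <- extract_patches(surface_from(v), min_size = 2)
  lab <- ps_perm$labels$values
  perm <- c(3L, 1L, 2L)
  lab[lab > 0] <- perm[lab[lab > 0]]
  ps_perm$labels$values <- lab
  ps_perm$table$patch <- perm[ps_perm$table$patch]
  ps_perm <- cluster_patches(ps_perm, range_km = 5)
  part1 <- split(ps$table$patch, ps$table$cluster)
  # translate permuted ids back to the original labels before comparing
  inv <- order(perm)
  part2 <- split(inv[ps_perm$table$patch], ps_perm$table$cluster)
  norm <- function(p) sort(sapply(unname(lapply(p, sort)), paste, collapse = ","))
  expect_identical(norm(part1), norm(part2))
})

test_that("isolation selection applies belt, edge and suitability rules", {
  # frame large enough that interior patches are > 5 km from the edge
  v <- matrix(0, 24, 24)
  v[10:14, 2:10] <- 1      # big belt patch (touches the 5 km edge zone too)
  v[8:9, 16:17] <- 1       # candidate, interior
  v[17:18, 16:17] <- 1     # candidate, interior
  v[1:2, 20:21] <- 1       # touches the frame edge zone
  suit_vals <- matrix(0.9, 24, 24)
  suit_vals[17:18, 16:17] <- 0.2   # unsuitable cluster
  suit <- surface_from(suit_vals)
  ps <- cluster_patches(extract_patches(surface_from(v), min_size = 2),
                        range_km = 5)
  ps <- select_isolated(ps, suit, suit_cutoff = 0.25, edge_km = 5)
  tab <- ps$table
  belt <- tab[which.max(tab$pixels), ]
  expect_true(belt$main_belt)
  expect_false(belt$isolated)
  edge_patch <- tab[tab$centroid_lat == max(tab$centroid_lat), ]
  expect_true(edge_patch$edge_excluded)
  iso <- tab[tab$isolated, ]
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$pixels, 4L)
  expect_true(iso$suitable)
  # single patch -> main belt, nothing isolated
  v1 <- matrix(0, 24, 24); v1[10:12, 10:12] <- 1
  ps1 <- cluster_patches(extract_patches(surface_from(v1), min_size = 2), 5)
  ps1 <- select_isolated(ps1, suit)
  expect_true(all(ps1$table$main_belt))
  expect_equal(sum(ps1$table$isolated), 0L)
  # mean-suitability rule: clusters at 0.2 vs 0.3 -> exactly one isolated
  v2 <- matrix(0, 30, 30)
  v2[14:16, 3:8] <- 1      # belt
  v2[9:10, 20:21] <- 1
  v2[20:21, 20:21] <- 1
  sv <- matrix(0, 30, 30)
  sv[9:10, 20:21] <- 0.3; sv[20:21, 20:21] <- 0.2
  ps2 <- cluster_patches(extract_patches(surface_from(v2), min_size = 2), 5)
  ps2 <- select_isolated(ps2, surface_from(sv), suit_cutoff = 0.25, edge_km = 5)
  expect_equal(sum(ps2$table$isolated), 1L)
})
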