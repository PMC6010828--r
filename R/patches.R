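#' Extract discrete patches from a connectivity surface
#'
#' Thresholds the surface at `cutoff` (strictly greater; nodata and water
#' count as background), labels connected components under the chosen
#' neighborhood, and discards components smaller than `min_size` pixels (the
#' minimum mapping unit).
#'
#' @param surface a `surface_raster` with values in [0, 1].
#' @param cutoff foreground threshold (default 0.5, strict `>`).
#' @param min_size minimum component size in pixels (default 4).
#' @param connectivity 4 or 8 (default 8: diagonal pixels connect).
#' @return a `patch_set`: `labels` ([raster_grid] of patch ids, 0 =
#'   background), `table` (data.frame: patch, pixels, centroid_lat,
#'   centroid_lon), `surface_frame`. Labels are 1..k in decreasing size
#'   order. An empty foreground yields an empty (zero-row) patch set.
#' @export
extract_patches <- function(surface, cutoff = 0.5, min_size = 4L,
                            connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- surface$values
  fg <- !is.na(v) & v > cutoff
  lab <- label_components(fg, connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_size)
    relab <- integer(length(sizes))
    keep <- keep[order(-sizes[keep], keep)]
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  ids <- seq_len(max(lab))
  rows <- lapply(ids, function(p) {
    px <- which(lab == p, arr.ind = TRUE)
    cc <- cell_center(surface, px[, 1], px[, 2])
    data.frame(patch = p, pixels = nrow(px),
               centroid_lat = mean(cc$lat), centroid_lon = mean(cc$lon))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch = integer(0), pixels = integer(0),
               centroid_lat = numeric(0), centroid_lon = numeric(0))
  labels <- raster_grid(lab, surface$cellsize_deg, surface$origin_lat,
                        surface$origin_lon, surface$nodata_flag)
  structure(list(labels = labels, table = tab), class = "patch_set")
}

# Two-pass union-find connected-component labeling on a logical matrix.
label_components <- function(fg, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  n_fg <- sum(fg)
  if (n_fg == 0L) return(lab)
  lab[fg] <- seq_len(n_fg)                 # provisional: one label per pixel
  parent <- seq_len(n_fg)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    both <- which(a > 0L & b > 0L)
    for (k in both) unite(a[k], b[k])
  }
  roots <- vapply(seq_len(n_fg), find, integer(1))
  lab[fg] <- match(roots, sort(unique(roots)))
  lab
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches\n", nrow(x$table)))
  print(head(x$table, 8), row.names = FALSE)
  invisible(x)
}

# Minimum pixel-center-to-pixel-center distance (km) between two patches,
# with a bounding-box lower bound to skip distant pairs cheaply.
patch_gap_km <- function(pix_a, pix_b, skip_above = Inf) {
  if (is.finite(skip_above)) {
    dlat <- max(0, max(min(pix_a$lat) - max(pix_b$lat),
                       min(pix_b$lat) - max(pix_a$lat)))
    dlon <- max(0, max(min(pix_a$lon) - max(pix_b$lon),
                       min(pix_b$lon) - max(pix_a$lon)))
    lb <- KM_PER_DEG * sqrt(dlat^2 + (dlon * cos(mean(pix_a$lat) * pi / 180))^2)
    if (lb > skip_above * 1.5) return(Inf)
  }
  d <- geosphere::distm(cbind(pix_a$lon, pix_a$lat), cbind(pix_b$lon, pix_b$lat),
                        fun = function(x, y)
                          geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM))
  min(d)
}

patch_pixels <- function(patches, p) {
  px <- which(patches$labels$values == p, arr.ind = TRUE)
  cc <- cell_center(patches$labels, px[, 1], px[, 2])
  data.frame(row = px[, 1], col = px[, 2], lat = cc$lat, lon = cc$lon)
}

#' Group nearby patches into clusters
#'
#' Single-linkage clustering on the minimum edge-to-edge inter-patch
#' distance (pixel centers, haversine): patches closer than `range_km` - the
#' organism's short-range dispersal ability - belong to one cluster and are
#' treated as a single unit in the isolation accounting.
#'
#' @param patches a `patch_set`.
#' @param range_km clustering range in km (default 5).
#' @return the `patch_set` with a `cluster` column added to its table.
#' @export
cluster_patches <- function(patches, range_km = 5.0) {
  tab <- patches$table
  np <- nrow(tab)
  if (np == 0L) { tab$cluster <- integer(0); patches$table <- tab; return(patches) }
  pix <- lapply(tab$patch, patch_pixels, patches = patches)
  edges <- matrix(integer(0), ncol = 2)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) for (j in seq.int(i + 1L, np)) {
      if (patch_gap_km(pix[[i]], pix[[j]], skip_above = range_km) <= range_km)
        edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(np, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  tab$cluster <- as.integer(memb)
  patches$table <- tab
  patches
}

#' Flag isolated patches within suitable habitat
#'
#' Applies the final selection criteria: the largest patch (with its whole
#' cluster) is the "main habitat belt" and never isolated; clusters with any
#' pixel closer than `edge_km` to the raster frame boundary are excluded
#' (they may connect to habitat outside the frame); the remaining clusters
#' are isolated, and suitable when their suitability (cluster-mean by
#' default, or any-pixel) exceeds `suit_cutoff`.
#'
#' @param patches a clustered `patch_set` (see [cluster_patches()]).
#' @param suitability a `surface_raster` on the same frame.
#' @param suit_cutoff suitability threshold (default 0.25, strict `>`).
#' @param edge_km frame-edge exclusion distance in km (default 5).
#' @param suit_mode `"mean"` (cluster-mean suitability) or `"any"` (any
#'   pixel above the cutoff).
#' @return the `patch_set` with logical columns `main_belt`,
#'   `edge_excluded`, `suitable`, `isolated` added.
#' @export
select_isolated <- function(patches, suitability, suit_cutoff = 0.25,
                            edge_km = 5.0, suit_mode = c("mean", "any")) {
  suit_mode <- match.arg(suit_mode)
  tab <- patches$table
  if (is.null(tab$cluster)) stop("run cluster_patches() first")
  np <- nrow(tab)
  tab$main_belt <- tab$edge_excluded <- tab$suitable <- tab$isolated <-
    logical(np)
  if (np == 0L) { patches$table <- tab; return(patches) }
  if (!identical(dim(suitability$values), dim(patches$labels$values)))
    stop("suitability surface is not on the patch frame")
  lab <- patches$labels$values
  nr <- nrow(lab); nc <- ncol(lab)
  ckm <- cell_size_km(patches$labels)
  belt_cluster <- tab$cluster[which.max(tab$pixels)]
  tab$main_belt <- tab$cluster == belt_cluster
  for (cl in unique(tab$cluster)) {
    sel <- tab$cluster == cl
    px <- which(matrix(lab %in% tab$patch[sel], nr, nc), arr.ind = TRUE)
    edge_dist <- pmin(px[, 1] - 0.5, nr - px[, 1] + 0.5,
                      px[, 2] - 0.5, nc - px[, 2] + 0.5) * ckm
    if (min(edge_dist) < edge_km) tab$edge_excluded[sel] <- TRUE
    sv <- suitability$values[px]
    ok_suit <- if (suit_mode == "mean") mean(sv, na.rm = TRUE) > suit_cutoff
               else any(sv > suit_cutoff, na.rm = TRUE)
    tab$suitable[sel] <- isTRUE(ok_suit)
  }
  tab$isolated <- !tab$main_belt & !tab$edge_excluded & tab$suitable
  patches$table <- tab
  patches
}
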