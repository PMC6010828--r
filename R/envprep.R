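# Resistance-cost bin ladders: 11 classes over the variable's range.
RESIST_BINS <- list(
  linear_1_100 = c(1, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100),
  exp_1_500    = c(1, 25, 50, 75, 100, 150, 200, 250, 325, 400, 500))

# Supercover traversal: every cell whose square extent the segment a->b
# intersects, endpoint cells included. Works in continuous cell coordinates
# where integer (row, col) are cell centers and cell edges sit at +-0.5.
# Segment crossings of row/column boundary lines split [0,1] into intervals;
# each interval midpoint identifies one traversed cell. A crossing exactly
# through a cell corner yields the diagonal cell only (measure-zero case).
supercover_cells <- function(r0, c0, r1, c1) {
  tbreaks <- c(0, 1)
  for (b in seq(floor(min(r0, r1) - 0.5) + 0.5, ceiling(max(r0, r1) + 0.5) - 0.5))
    if (r1 != r0) {
      t <- (b - r0) / (r1 - r0)
      if (t > 0 && t < 1) tbreaks <- c(tbreaks, t)
    }
  for (b in seq(floor(min(c0, c1) - 0.5) + 0.5, ceiling(max(c0, c1) + 0.5) - 0.5))
    if (c1 != c0) {
      t <- (b - c0) / (c1 - c0)
      if (t > 0 && t < 1) tbreaks <- c(tbreaks, t)
    }
  tbreaks <- sort(unique(tbreaks))
  tm <- (tbreaks[-1] + tbreaks[-length(tbreaks)]) / 2
  cells <- unique(data.frame(row = round(r0 + tm * (r1 - r0)),
                             col = round(c0 + tm * (c1 - c0))))
  cells
}

# Continuous (row, col) position of a lat/lon point on the grid.
continuous_cell <- function(grid, lat, lon) {
  list(row = (grid$origin_lat - lat) / grid$cellsize_deg + 1,
       col = (lon - grid$origin_lon) / grid$cellsize_deg + 1)
}

#' Mean raster value along the straight path between two points
#'
#' Unweighted mean over all non-nodata cells whose area the segment from `a`
#' to `b` intersects (supercover traversal; both endpoint cells included).
#'
#' @param grid a [raster_grid].
#' @param a,b points as `c(lat, lon)` or lists with `lat`/`lon`, inside the
#'   raster frame.
#' @return the mean (scalar); `NA` with a warning when every traversed cell
#'   is nodata.
#' @export
straight_path_mean <- function(grid, a, b) {
  pa <- as_point(a); pb <- as_point(b)
  ca <- continuous_cell(grid, pa$lat, pa$lon)
  cb <- continuous_cell(grid, pb$lat, pb$lon)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (min(ca$row, cb$row) < 0.5 - 1e-9 || max(ca$row, cb$row) > nr + 0.5 + 1e-9 ||
      min(ca$col, cb$col) < 0.5 - 1e-9 || max(ca$col, cb$col) > nc + 0.5 + 1e-9)
    stop("straight_path_mean: endpoint outside the raster frame")
  cells <- supercover_cells(ca$row, ca$col, cb$row, cb$col)
  cells <- cells[cells$row >= 1 & cells$row <= nr &
                 cells$col >= 1 & cells$col <= nc, ]
  vals <- grid$values[cbind(cells$row, cells$col)]
  if (all(is.na(vals))) {
    warning("straight_path_mean: all traversed cells are nodata")
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

as_point <- function(p) {
  if (is.list(p)) list(lat = p$lat, lon = p$lon)
  else list(lat = p[[1]], lon = p[[2]])
}

# Straight-path-mean vector over all site pairs (lower-triangle order).
straight_path_pair_vector <- function(grid, sites) {
  n <- nrow(sites)
  out <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (j in seq_len(n - 1L)) for (i in seq.int(j + 1L, n)) {
    k <- k + 1L
    out[k] <- straight_path_mean(grid,
                                 c(sites$lat[i], sites$lon[i]),
                                 c(sites$lat[j], sites$lon[j]))
  }
  out
}

#' Covariation filter for an environmental stack
#'
#' Reduces a stack of environmental rasters to a non-covarying subset, the
#' way a practitioner screens remote-sensing layers before resistance
#' modeling. For each variable the straight-path mean between every pair of
#' sampling sites is computed; variables whose pair-vectors correlate with
#' |R| above `r_drop` are grouped (single linkage), and each group is
#' represented by the member with the largest absolute loading on the first
#' principal component of the standardized pair-vectors (lexicographically
#' first token on ties). `r_flag` only flags pairs in the report.
#'
#' @param stack named list of [raster_grid] layers on one frame.
#' @param sites a `site_table`.
#' @param r_flag report-level correlation threshold (default 0.80).
#' @param r_drop grouping threshold (default 0.85).
#' @return list with `selected` (character tokens), `pairs` (data.frame:
#'   var1, var2, R, p, flagged), `loadings` (PC1 loadings), `var_explained`
#'   (proportion of variance per component), `groups` (list of tokens).
#' @export
covariation_filter <- function(stack, sites, r_flag = 0.80, r_drop = 0.85) {
  tokens <- names(stack)
  if (length(tokens) < 2L) stop("need at least two variables")
  vecs <- vapply(stack, straight_path_pair_vector, numeric(nrow(sites) * (nrow(sites) - 1) / 2),
                 sites = sites)
  if (nrow(vecs) < 3L) stop("need at least 3 site pairs")
  if (nrow(vecs) < length(tokens))
    warning("fewer site pairs than variables: PCA is rank deficient")
  R <- cor(vecs)
  npair <- nrow(vecs)
  pc <- prcomp(vecs, scale. = TRUE)
  loadings <- pc$rotation[, 1]
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  cmb <- t(combn(length(tokens), 2))
  rv <- R[cmb]
  tstat <- rv * sqrt((npair - 2) / pmax(1 - rv^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = npair - 2)
  pairs <- data.frame(var1 = tokens[cmb[, 1]], var2 = tokens[cmb[, 2]],
                      R = rv, p = pval, flagged = abs(rv) > r_flag,
                      stringsAsFactors = FALSE)
  adj <- abs(R) > r_drop
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  groups <- split(tokens, comp)
  selected <- vapply(groups, function(g) {
    ld <- abs(loadings[g])
    g[order(-ld, g)][1]
  }, character(1))
  selected <- sort(unname(selected))
  list(selected = selected, pairs = pairs, loadings = loadings,
       var_explained = var_explained, groups = unname(groups))
}

#' Build a binned resistance surface from an environmental variable
#'
#' The variable's range is split into 11 equal-width classes; class k
#' (1-indexed from the low end, maximum value in class 11) receives the k-th
#' cost of the scheme's bin ladder: linear costs 1,10,20,...,100 or
#' exponential costs 1,25,50,75,100,150,200,250,325,400,500. With
#' `direction = "decreasing"` the ladder is reversed, so high variable values
#' cost 1 (the variable aids movement). Four surfaces per variable span the
#' two schemes times the two directions.
#'
#' @param variable a [raster_grid] with a non-degenerate finite range.
#' @param direction `"increasing"` (high variable value = high cost) or
#'   `"decreasing"`.
#' @param scheme `"linear_1_100"` or `"exp_1_500"`.
#' @param token variable name recorded in the provenance.
#' @return a `resistance_surface`: a [raster_grid] of costs with a
#'   `provenance` attribute `(variable, direction, scheme)`.
#' @export
make_resistance_surface <- function(variable,
                                    direction = c("increasing", "decreasing"),
                                    scheme = c("linear_1_100", "exp_1_500"),
                                    token = "env") {
  direction <- match.arg(direction)
  scheme <- match.arg(scheme)
  v <- variable$values
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("constant or non-finite raster: no resistance classes")
  breaks <- seq(rng[1], rng[2], length.out = 12L)
  cls <- findInterval(v, breaks, rightmost.closed = TRUE)
  bins <- RESIST_BINS[[scheme]]
  if (direction == "decreasing") bins <- rev(bins)
  costs <- matrix(bins[cls], nrow(v), ncol(v))
  costs[is.na(v)] <- NA_real_
  out <- raster_grid(costs, variable$cellsize_deg, variable$origin_lat,
                     variable$origin_lon, variable$nodata_flag)
  attr(out, "provenance") <- list(variable = token, direction = direction,
                                  scheme = scheme)
  class(out) <- c("resistance_surface", class(out))
  out
}

#' All four resistance surfaces for one variable
#' @param variable a [raster_grid].
#' @param token variable name recorded in the provenance.
#' @return named list of four `resistance_surface` objects, names like
#'   `"PSN|decreasing|exp_1_500"`.
#' @export
resistance_surfaces <- function(variable, token = "env") {
  out <- list()
  for (dir in c("increasing", "decreasing"))
    for (sch in names(RESIST_BINS)) {
      key <- paste(token, dir, sch, sep = "|")
      out[[key]] <- make_resistance_surface(variable, dir, sch, token = token)
    }
  out
}
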