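#' Build a conductance graph from a resistance surface
#'
#' Raster cells become graph nodes (nodata cells are excluded); neighboring
#' cells are joined by an edge whose conductance is the reciprocal of the
#' average of the two cell resistances, `1 / ((r_i + r_j) / 2)`, the
#' Circuitscape convention. With the 8-neighborhood, diagonal edges are
#' scaled by `1/sqrt(2)` to account for the longer step.
#'
#' @param surface a `resistance_surface` (or any [raster_grid] of positive
#'   costs).
#' @param neighborhood 4 (rook) or 8 (queen, default).
#' @return a `conductance_graph`: list with `nodes` (data.frame id/row/col),
#'   `edges` (data.frame i/j/conductance, undirected), `node_of` (matrix
#'   mapping cells to node ids, 0 = nodata), `grid` (the input raster, used
#'   for focal mapping and the straight-path matrix mode).
#' @export
build_graph <- function(surface, neighborhood = 8) {
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  v <- surface$values
  if (any(v <= 0, na.rm = TRUE)) stop("resistances must be positive")
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 non-nodata cells")
  node_of <- matrix(0L, nr, nc)
  node_of[ok] <- seq_len(sum(ok))
  idx <- which(ok, arr.ind = TRUE)
  nodes <- data.frame(id = node_of[ok], row = idx[, 1], col = idx[, 2])
  nodes <- nodes[order(nodes$id), ]

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  ei <- integer(0); ej <- integer(0); cond <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a_rows <- rep(r1, times = length(c1)); a_cols <- rep(c1, each = length(r1))
    b_rows <- a_rows + dr; b_cols <- a_cols + dc
    ia <- node_of[cbind(a_rows, a_cols)]
    ib <- node_of[cbind(b_rows, b_cols)]
    keep <- ia > 0L & ib > 0L
    if (!any(keep)) next
    ra <- v[cbind(a_rows, a_cols)][keep]
    rb <- v[cbind(b_rows, b_cols)][keep]
    g <- 1 / ((ra + rb) / 2)
    if (dr != 0L && dc != 0L) g <- g / sqrt(2)
    ei <- c(ei, ia[keep]); ej <- c(ej, ib[keep]); cond <- c(cond, g)
  }
  structure(list(nodes = nodes,
                 edges = data.frame(i = ei, j = ej, conductance = cond),
                 node_of = node_of, grid = surface),
            class = "conductance_graph")
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("<conductance_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Sparse graph Laplacian L = D - W.
graph_laplacian <- function(graph) {
  e <- graph$edges
  n <- nrow(graph$nodes)
  W <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

# Connected-component membership of graph nodes.
graph_components <- function(graph) {
  g <- igraph::graph_from_edgelist(as.matrix(graph$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(graph$nodes) - igraph::vcount(g)))
  igraph::components(g)$membership
}

# Map sites to graph node ids; errors (naming the site) on nodata cells.
resolve_focals <- function(graph, sites) {
  cells <- point_to_cell(graph$grid, sites$lat, sites$lon)
  node <- graph$node_of[cbind(cells$row, cells$col)]
  if (any(node == 0L))
    stop("site(s) on nodata cells: ",
         paste(sites$id[node == 0L], collapse = ", "))
  setNames(node, sites$id)
}

# Grounded-inverse columns for a set of focal nodes within one component.
# Ground node's row/column are removed (potential fixed at 0); the reduced
# Laplacian is SPD and factorized once, then solved for every focal
# injection. Returns an n x k matrix of node potentials for unit injection
# at each focal (extraction at the ground); the ground focal's column is 0.
grounded_potentials <- function(L, focals, ground) {
  keep <- setdiff(seq_len(nrow(L)), ground)
  Lg <- L[keep, keep, drop = FALSE]
  uo <- unique(focals[focals != ground])
  X <- matrix(0, nrow(L), length(focals))
  colnames(X) <- names(focals)
  if (length(uo)) {
    E <- Matrix::sparseMatrix(i = match(uo, keep), j = seq_along(uo),
                              x = 1, dims = c(length(keep), length(uo)))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE, perm = TRUE)
    Z <- as.matrix(Matrix::solve(ch, E, system = "A"))
    for (t in seq_along(focals))
      if (focals[t] != ground) X[keep, t] <- Z[, match(focals[t], uo)]
  }
  X
}

#' Pairwise resistance matrix between sampling sites
#'
#' `mode = "effective"` computes two-point effective resistance by solving
#' the graph Laplacian (ground one focal node, inject unit current at the
#' other; the resistance is the potential difference). `mode =
#' "straightpath_surface"` instead averages the cost raster along the
#' straight path between the sites (see [straight_path_mean()]); both
#' constructions of the landscape-distance matrix are in use in the
#' literature. Pairs whose focal nodes fall in different graph components get
#' `Inf`.
#'
#' @param graph a `conductance_graph`.
#' @param sites a `site_table`; all sites must map to non-nodata cells.
#' @param mode `"effective"` (default) or `"straightpath_surface"`.
#' @return a [pairwise_matrix] of kind `"resistance"`.
#' @export
resistance_matrix <- function(graph, sites,
                              mode = c("effective", "straightpath_surface")) {
  mode <- match.arg(mode)
  if (mode == "straightpath_surface") {
    n <- nrow(sites)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- straight_path_mean(
        graph$grid, c(sites$lat[i], sites$lon[i]), c(sites$lat[j], sites$lon[j]))
    }
    return(pairwise_matrix(sites$id, m, "resistance"))
  }
  focals <- resolve_focals(graph, sites)
  L <- graph_laplacian(graph)
  comp <- graph_components(graph)
  k <- length(focals)
  R <- matrix(Inf, k, k)
  diag(R) <- 0
  for (cmp in unique(comp[focals])) {
    sel <- which(comp[focals] == cmp)
    if (length(sel) < 2L) next
    f <- focals[sel]
    ground <- f[1]
    X <- grounded_potentials(L, f, ground)
    # Y_ab = potential at focal a under unit injection at focal b (ground ref)
    Y <- X[f, , drop = FALSE]
    for (a in seq_along(sel)) for (b in seq_along(sel)) {
      if (a < b) {
        val <- Y[a, a] + Y[b, b] - 2 * Y[a, b]
        R[sel[a], sel[b]] <- R[sel[b], sel[a]] <- val
      }
    }
  }
  if (any(is.infinite(R[upper.tri(R)])))
    warning("focal pairs in disconnected components: infinite resistance")
  pairwise_matrix(sites$id, R, "resistance")
}

#' Cumulative current map over all focal pairs
#'
#' For every unordered pair of focal sites a unit current is injected at one
#' and extracted at the other; per-node current is half the sum of absolute
#' currents on incident edges (the two focal nodes carry the full injected
#' current, 1). The cumulative map sums these over all pairs and is written
#' back onto the raster frame; it highlights predicted movement corridors.
#'
#' @param graph a `conductance_graph`.
#' @param sites a `site_table` with >= 2 sites.
#' @return a [raster_grid] of cumulative current (nodata off-graph).
#' @export
current_map <- function(graph, sites) {
  focals <- resolve_focals(graph, sites)
  if (length(focals) < 2L) stop("need at least 2 focal sites")
  L <- graph_laplacian(graph)
  comp <- graph_components(graph)
  e <- graph$edges
  node_current <- numeric(nrow(graph$nodes))
  for (cmp in unique(comp[focals])) {
    sel <- which(comp[focals] == cmp)
    if (length(sel) < 2L) next
    f <- focals[sel]
    X <- grounded_potentials(L, f, f[1])
    for (a in seq_along(f)) for (b in seq_along(f)) {
      if (a >= b) next
      v <- X[, a] - X[, b]
      iedge <- e$conductance * (v[e$i] - v[e$j])
      absI <- abs(iedge)
      n_nodes <- nrow(graph$nodes)
      flow <- (tapply_add(e$i, absI, n_nodes) +
               tapply_add(e$j, absI, n_nodes)) / 2
      flow[f[c(a, b)]] <- 1
      node_current <- node_current + flow
    }
  }
  if (length(unique(comp[focals])) > 1L)
    warning("focal sites span disconnected components; cross-component pairs ",
            "contribute no current")
  out <- graph$grid$values
  out[] <- NA_real_
  out[cbind(graph$nodes$row, graph$nodes$col)] <- node_current
  raster_grid(out, graph$grid$cellsize_deg, graph$grid$origin_lat,
              graph$grid$origin_lon, graph$grid$nodata_flag)
}

tapply_add <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Geographic-distance-only control matrix
#'
#' The isolation-by-distance control used alongside the environment-specific
#' resistance matrices: either the great-circle distance matrix itself, or
#' effective resistance on an all-cost-1 surface (a "flat" landscape with the
#' same frame and nodata mask).
#'
#' @param sites a `site_table`.
#' @param frame a [raster_grid] providing the frame and nodata mask
#'   (required for `uniform_effective`).
#' @param mode `"greatcircle"` or `"uniform_effective"`.
#' @param neighborhood passed to [build_graph()] for the uniform surface.
#' @return a [pairwise_matrix] (kind `"distance_km"` or `"resistance"`).
#' @export
geographic_control_matrix <- function(sites, frame = NULL,
                                      mode = c("greatcircle", "uniform_effective"),
                                      neighborhood = 8) {
  mode <- match.arg(mode)
  if (mode == "greatcircle") return(distance_matrix_km(sites))
  if (is.null(frame)) stop("uniform_effective mode needs a raster frame")
  u <- frame
  u$values[!is.na(u$values)] <- 1
  resistance_matrix(build_graph(u, neighborhood), sites, mode = "effective")
}
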