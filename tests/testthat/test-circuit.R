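# Manually built triangle of unit resistors on a 1x3 frame.
triangle_graph <- function() {
  g <- build_graph(fix_grid(matrix(1, 1, 3)), 4)
  g$edges <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3), conductance = 1)
  g
}

test_that("graph construction follows the average-resistance edge rule", {
  # 2x1 grid, costs (2, 4) -> single edge, conductance 1/3
  g <- build_graph(fix_grid(matrix(c(2, 4), 2, 1)), 4)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$conductance, 1 / 3)

  # 2x2 grid, 8-neighborhood -> 4 orthogonal + 2 diagonal edges
  g8 <- build_graph(fix_grid(matrix(1, 2, 2)), 8)
  expect_equal(nrow(g8$edges), 6L)
  diag_edges <- g8$edges[abs(g8$nodes$row[g8$edges$i] - g8$nodes$row[g8$edges$j]) == 1 &
                         abs(g8$nodes$col[g8$edges$i] - g8$nodes$col[g8$edges$j]) == 1, ]
  expect_equal(nrow(diag_edges), 2L)
  expect_equal(diag_edges$conductance, rep(1 / sqrt(2), 2))

  # nodata cell and its incident edges are absent
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  gm <- build_graph(fix_grid(v), 4)
  expect_equal(nrow(gm$nodes), 8L)
  expect_false(any(gm$node_of == 0 & !is.na(v)))
  expect_equal(nrow(gm$edges), 8L)   # the ring of 8 cells, 4-connected
})

test_that("effective resistance reproduces series and triangle closed forms", {
  chain <- build_graph(fix_grid(matrix(1, 1, 3)), 4)   # two unit resistors
  s <- fix_sites(c(1, 1), c(1, 3), ids = c("a", "b"))
  expect_equal(resistance_matrix(chain, s)["a", "b"], 2, tolerance = 1e-12)

  tri <- triangle_graph()
  st <- fix_sites(c(1, 1, 1), c(1, 2, 3), ids = c("x", "y", "z"))
  R <- resistance_matrix(tri, st)
  expect_equal(lower_triangle(unclass(R)), rep(2 / 3, 3), tolerance = 1e-12)
})

test_that("effective resistance matches the Laplacian pseudo-inverse oracle", {
  for (seed in c(1, 2, 3, 12, 31)) {
    g <- random_graph(seed)
    n <- nrow(g$nodes)
    focal_nodes <- sort(sample(seq_len(n), min(5, n)))
    s <- graph_sites(g, focal_nodes)
    R <- resistance_matrix(g, s)
    Rexp <- effective_resistance_oracle(n, g$edges)[focal_nodes, focal_nodes]
    expect_equal(unclass(R), Rexp, ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("effective resistance is a metric and obeys Rayleigh monotonicity", {
  set.seed(77)
  for (rep in 1:5) {
    g <- random_graph(rep + 40)
    n <- nrow(g$nodes)
    s <- graph_sites(g, seq_len(min(6, n)))
    R <- unclass(resistance_matrix(g, s))
    expect_equal(R, t(R), tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(diag(R) == 0))
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
      expect_lte(R[i, k], R[i, j] + R[j, k] + 1e-9)
    # raise one conductance: no effective resistance may increase
    g2 <- g
    e <- sample(nrow(g2$edges), 1)
    g2$edges$conductance[e] <- g2$edges$conductance[e] * 3
    R2 <- unclass(resistance_matrix(g2, s))
    expect_true(all(R2 <= R + 1e-9))
  }
})

test_that("current maps satisfy Kirchhoff balance and match a dense solve", {
  # 3-cell chain, focals at the ends: every node carries the full current
  chain <- build_graph(fix_grid(matrix(1, 1, 3)), 4)
  s <- fix_sites(c(1, 1), c(1, 3), ids = c("a", "b"))
  cm <- current_map(chain, s)
  expect_equal(as.vector(cm$values), c(1, 1, 1))

  # 2x3 grid, one focal pair: compare against a brute-force Kirchhoff solve
  g <- build_graph(fix_grid(matrix(c(1, 2, 3, 4, 5, 6), 2, 3)), 8)
  sp <- fix_sites(c(1, 2), c(1, 3), ids = c("p", "q"))
  cm2 <- current_map(g, sp)
  n <- nrow(g$nodes)
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]; c0 <- g$edges$conductance[k]
    L[i, j] <- L[i, j] - c0; L[j, i] <- L[j, i] - c0
    L[i, i] <- L[i, i] + c0; L[j, j] <- L[j, j] + c0
  }
  f <- isopatch:::resolve_focals(g, sp)
  rhs <- numeric(n); rhs[f[1]] <- 1; rhs[f[2]] <- -1
  v <- c(solve(L[-1, -1], rhs[-1]))
  v <- c(0, v)
  iedge <- g$edges$conductance * (v[g$edges$i] - v[g$edges$j])
  # Kirchhoff: signed currents balance at non-focal nodes
  for (nd in setdiff(seq_len(n), f)) {
    net <- sum(iedge[g$edges$i == nd]) - sum(iedge[g$edges$j == nd])
    expect_lt(abs(net), 1e-8)
  }
  node_cur <- sapply(seq_len(n), function(nd)
    (sum(abs(iedge[g$edges$i == nd])) + sum(abs(iedge[g$edges$j == nd]))) / 2)
  node_cur[f] <- 1
  expected <- matrix(NA_real_, 2, 3)
  expected[cbind(g$nodes$row, g$nodes$col)] <- node_cur
  expect_equal(cm2$values, expected, tolerance = 1e-8)
})

test_that("mirror-symmetric focal pairs give mirror-symmetric current maps", {
  g <- build_graph(fix_grid(matrix(1, 3, 5)), 4)
  s <- fix_sites(c(2, 2), c(1, 5), ids = c("a", "b"))
  cm <- current_map(g, s)
  expect_equal(cm$values, cm$values[, 5:1], tolerance = 1e-9)
  expect_equal(cm$values, cm$values[3:1, ], tolerance = 1e-9)
})

test_that("disconnected focal pairs are flagged as infinite resistance", {
  v <- matrix(1, 1, 5); v[1, 3] <- NA
  g <- build_graph(fix_grid(v), 4)
  s <- fix_sites(c(1, 1), c(1, 5), ids = c("a", "b"))
  expect_warning(R <- resistance_matrix(g, s), "disconnected")
  expect_true(is.infinite(R["a", "b"]))
  expect_error(resolve <- isopatch:::resolve_focals(g, fix_sites(1, 3, "bad")),
               "bad")
})

test_that("geographic control: great-circle delegation and uniform-surface behavior", {
  s <- fix_sites(c(2, 2, 2), c(2, 5, 9))
  frame <- fix_grid(matrix(runif(30), 3, 10))
  expect_identical(unclass(geographic_control_matrix(s, mode = "greatcircle")),
                   unclass(distance_matrix_km(s)))
  # uniform surface on a 1xN strip: resistance grows with separation
  strip <- fix_grid(matrix(5, 1, 12))
  sl <- fix_sites(c(1, 1, 1, 1), c(1, 4, 8, 12))
  Ru <- geographic_control_matrix(sl, strip, mode = "uniform_effective",
                                  neighborhood = 4)
  r1 <- Ru["s01", "s02"]; r2 <- Ru["s01", "s03"]; r3 <- Ru["s01", "s04"]
  expect_true(r1 < r2 && r2 < r3)
  # ladder oracle: on an all-cost-1 strip each step adds one unit resistor
  expect_equal(r1, 3, tolerance = 1e-10)
  # two focals in the same cell -> zero resistance
  s_same <- site_table(c("u", "v"), rep(FIX_LAT, 2), rep(FIX_LON, 2))
  R0 <- geographic_control_matrix(s_same, strip, mode = "uniform_effective")
  expect_equal(R0["u", "v"], 0)
})
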