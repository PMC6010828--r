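test_that("straight-path mean: constant field, row transect, degenerate segment", {
  g <- fix_grid(matrix(7, 6, 6))
  a <- c(FIX_LAT, FIX_LON)
  b <- c(FIX_LAT - 4 * FIX_CS, FIX_LON + 5 * FIX_CS)
  expect_equal(straight_path_mean(g, a, b), 7)

  row5 <- fix_grid(matrix(1:5, 1, 5, byrow = TRUE))
  ends <- list(c(FIX_LAT, FIX_LON), c(FIX_LAT, FIX_LON + 4 * FIX_CS))
  expect_equal(straight_path_mean(row5, ends[[1]], ends[[2]]), 3)

  onecell <- straight_path_mean(row5, c(FIX_LAT, FIX_LON + 2 * FIX_CS),
                                c(FIX_LAT, FIX_LON + 2 * FIX_CS + FIX_CS / 4))
  expect_equal(onecell, 3)   # both endpoints inside cell 3
})

test_that("straight-path mean is symmetric and matches a dense sampling oracle", {
  set.seed(21)
  for (rep in 1:6) {
    vals <- matrix(runif(12 * 12), 12, 12)
    g <- fix_grid(vals)
    rc <- runif(4, 1, 12)     # two continuous endpoints inside the frame
    a <- c(FIX_LAT - (rc[1] - 1) * FIX_CS, FIX_LON + (rc[2] - 1) * FIX_CS)
    b <- c(FIX_LAT - (rc[3] - 1) * FIX_CS, FIX_LON + (rc[4] - 1) * FIX_CS)
    expect_equal(straight_path_mean(g, a, b), straight_path_mean(g, b, a))
    # oracle: dense point sampling along the segment, snapped to cells
    t <- seq(0, 1, length.out = 20001)
    rr <- round(rc[1] + t * (rc[3] - rc[1]))
    cc <- round(rc[2] + t * (rc[4] - rc[2]))
    cells <- unique(cbind(rr, cc))
    expect_equal(straight_path_mean(g, a, b), mean(vals[cells]),
                 tolerance = 1e-12)
  }
})

test_that("straight-path mean flags all-nodata transects", {
  g <- fix_grid(matrix(NA_real_, 3, 3))
  expect_warning(v <- straight_path_mean(g, c(FIX_LAT, FIX_LON),
                                         c(FIX_LAT, FIX_LON + 2 * FIX_CS)),
                 "nodata")
  expect_true(is.na(v))
  expect_error(straight_path_mean(fix_grid(matrix(1, 2, 2)),
                                  c(FIX_LAT + 1, FIX_LON), c(FIX_LAT, FIX_LON)),
               "outside")
})

test_that("covariation filter keeps one of a duplicated pair and all independent layers", {
  set.seed(3)
  sites <- fix_sites(c(2, 9, 3, 8, 5), c(2, 3, 9, 8, 5))
  a <- fix_grid(matrix(runif(100), 10, 10))
  stack_dup <- list(A = a, B = a, C = fix_grid(matrix(runif(100), 10, 10)))
  res <- covariation_filter(stack_dup, sites)
  expect_length(intersect(res$selected, c("A", "B")), 1L)
  expect_true("C" %in% res$selected)
  dup_row <- res$pairs[res$pairs$var1 == "A" & res$pairs$var2 == "B", ]
  expect_equal(abs(dup_row$R), 1, tolerance = 1e-12)
  expect_true(dup_row$flagged)

  # independent noise layers: all retained
  noise <- lapply(1:4, function(i) fix_grid(matrix(runif(100), 10, 10)))
  names(noise) <- c("w", "x", "y", "z")
  res2 <- covariation_filter(noise, sites)
  expect_setequal(res2$selected, c("w", "x", "y", "z"))
})

test_that("covariation filter groups near-duplicates by PC1 loading, order-invariantly", {
  set.seed(14)
  base <- matrix(runif(100), 10, 10)
  stack <- list(A = fix_grid(base),
                B = fix_grid(base + matrix(rnorm(100, sd = 0.02), 10, 10)),
                C = fix_grid(matrix(runif(100), 10, 10)))
  sites <- fix_sites(c(2, 9, 3, 8, 5), c(2, 3, 9, 8, 5))
  res <- covariation_filter(stack, sites)
  # exhaustive grouping oracle on 3 variables
  vecs <- sapply(stack, function(g) {
    out <- c()
    for (i in 2:5) for (j in 1:(i - 1))
      out <- c(out, straight_path_mean(g, c(sites$lat[i], sites$lon[i]),
                                       c(sites$lat[j], sites$lon[j])))
    out
  })
  R <- cor(vecs)
  expect_gt(abs(R["A", "B"]), 0.9)
  expect_lt(max(abs(R["A", "C"]), abs(R["B", "C"])), 0.85)
  ld <- abs(prcomp(vecs, scale. = TRUE)$rotation[, 1])
  rep_ab <- c("A", "B")[which.max(ld[c("A", "B")])]
  expect_setequal(res$selected, c(rep_ab, "C"))
  # order invariance
  res_rev <- covariation_filter(rev(stack), sites)
  expect_setequal(res_rev$selected, res$selected)
})

test_that("resistance binning assigns the documented costs", {
  v <- fix_grid(matrix(seq(0, 10, length.out = 36), 6, 6))
  inc_lin <- make_resistance_surface(v, "increasing", "linear_1_100")
  expect_equal(inc_lin$values[v$values == 0], 1)     # minimum -> cost 1
  expect_equal(inc_lin$values[v$values == 10], 100)  # maximum -> cost 100
  expect_true(all(inc_lin$values %in% c(1, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100)))

  # class 6 of 11 under the exponential scheme costs 150
  mid <- 0 + (5.5 / 11) * 10                         # midpoint of class 6
  inc_exp <- make_resistance_surface(v, "increasing", "exp_1_500")
  cls6_val <- v$values[abs(v$values - mid) == min(abs(v$values - mid))][1]
  expect_equal(unique(inc_exp$values[v$values == cls6_val]), 150)
  expect_true(all(inc_exp$values %in% c(1, 25, 50, 75, 100, 150, 200, 250, 325, 400, 500)))

  # decreasing is the cellwise bin reversal of increasing
  dec_lin <- make_resistance_surface(v, "decreasing", "linear_1_100")
  bins <- c(1, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  expect_equal(dec_lin$values,
               matrix(rev(bins)[match(inc_lin$values, bins)], 6, 6))
  expect_error(make_resistance_surface(fix_grid(matrix(5, 3, 3)), "increasing",
                                       "linear_1_100"), "constant")
  # nodata propagates
  v2 <- v; v2$values[2, 2] <- NA
  s <- make_resistance_surface(v2, "increasing", "linear_1_100")
  expect_true(is.na(s$values[2, 2]))
  # four surfaces per variable
  expect_length(resistance_surfaces(v, "PSN"), 4L)
})
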