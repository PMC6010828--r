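maxent_toy <- function(seed = 1, nr = 12, nc = 12) {
  set.seed(seed)
  stack <- list(ENV = fix_grid(matrix(runif(nr * nc), nr, nc)))
  feats <- feature_expand(stack)
  list(stack = stack, feats = feats)
}

presences_at <- function(grid, rows, cols) {
  cc <- cell_center(grid, rows, cols)
  presence_set(cc$lat, cc$lon)
}

test_that("feature expansion hits the documented endpoints", {
  toy <- maxent_toy(2)
  F <- toy$feats$matrix
  v <- toy$stack$ENV$values[cbind(toy$feats$cells$row, toy$feats$cells$col)]
  lin <- F[, "ENV_linear"]
  expect_equal(lin[which.min(v)], 0)
  expect_equal(lin[which.max(v)], 1)
  expect_equal(F[, "ENV_quadratic"], lin^2)
  # hinge with knot 0.4 at scaled value 0.3 -> 0
  h4 <- F[, "ENV_hinge_0.40"]
  expect_equal(h4[abs(lin - 0.3) < 0.05], rep(0, sum(abs(lin - 0.3) < 0.05)))
  expect_equal(h4, pmax(0, (lin - 0.4) / 0.6), tolerance = 1e-12)
  # constant variable -> dropped with warning
  stack2 <- list(A = fix_grid(matrix(1, 4, 4)), B = fix_grid(matrix(runif(16), 4, 4)))
  expect_warning(f2 <- feature_expand(stack2), "constant")
  expect_false(any(grepl("^A_", colnames(f2$matrix))))
})

test_that("uniform presences give a near-uniform fitted distribution", {
  toy <- maxent_toy(3)
  set.seed(3)
  n <- nrow(toy$feats$cells)
  idx <- sample(n, 60)
  pres <- presences_at(toy$stack$ENV, toy$feats$cells$row[idx],
                       toy$feats$cells$col[idx])
  model <- fit_maxent(toy$feats, pres)
  expect_lt(max(abs(model$raw - 1 / n)), 2 / n)
  # KKT box condition holds for every feature
  Eq <- drop(crossprod(toy$feats$matrix, model$raw))
  expect_true(all(abs(Eq - model$presence_means) <= model$beta + 1e-6))
})

test_that("presences in the top decile produce a monotone positive response", {
  toy <- maxent_toy(4)
  v <- toy$stack$ENV$values[cbind(toy$feats$cells$row, toy$feats$cells$col)]
  top <- which(v >= quantile(v, 0.9))
  pres <- presences_at(toy$stack$ENV, toy$feats$cells$row[top],
                       toy$feats$cells$col[top])
  feats_lin <- feature_expand(toy$stack, classes = "linear")
  model <- fit_maxent(feats_lin, pres)
  expect_gt(model$weights["ENV_linear"], 0)
  ord <- order(v)
  expect_true(all(diff(model$raw[ord]) >= -1e-12))
})

test_that("total shrinkage drives all weights to zero and predictions to tau", {
  toy <- maxent_toy(5)
  set.seed(5)
  idx <- sample(nrow(toy$feats$cells), 30)
  pres <- presences_at(toy$stack$ENV, toy$feats$cells$row[idx],
                       toy$feats$cells$col[idx])
  model <- fit_maxent(toy$feats, pres,
                      beta = c(linear = 1e6, quadratic = 1e6, hinge = 1e6))
  expect_true(all(model$weights == 0))
  surf <- predict_logistic(model, toy$stack)
  expect_equal(unique(round(as.vector(surf$values), 10)), 0.5)
})

test_that("fitted distribution matches a 1-feature Lagrangian oracle (beta = 0)", {
  set.seed(6)
  stack <- list(ENV = fix_grid(matrix(runif(16), 4, 4)))
  feats <- feature_expand(stack, classes = "linear")
  f <- feats$matrix[, 1]
  pres <- presences_at(stack$ENV, feats$cells$row[f > 0.6],
                       feats$cells$col[f > 0.6])
  model <- fit_maxent(feats, pres, beta = c(linear = 0), tol = 1e-8)
  s <- mean(f[f > 0.6])
  # oracle: with an exact moment constraint the max-entropy solution is the
  # Gibbs distribution whose multiplier solves E_q[f] = s
  wstar <- uniroot(function(w) {
    q <- exp(w * f); q <- q / sum(q); sum(q * f) - s
  }, c(-50, 50), tol = 1e-12)$root
  qstar <- exp(wstar * f); qstar <- qstar / sum(qstar)
  expect_equal(model$raw, qstar, tolerance = 1e-6)
  expect_equal(unname(model$weights[1]), wstar, tolerance = 1e-4)
  # and its entropy is maximal among feasible perturbations
  expect_gte(model$entropy_H + 1e-6, -sum(qstar * log(qstar)))
})

test_that("logistic output is in [0,1], water-masked cells are exactly 0", {
  toy <- maxent_toy(7)
  v <- toy$stack$ENV$values[cbind(toy$feats$cells$row, toy$feats$cells$col)]
  top <- which(v >= quantile(v, 0.75))   # informative presences
  pres <- presences_at(toy$stack$ENV, toy$feats$cells$row[top],
                       toy$feats$cells$col[top])
  model <- fit_maxent(toy$feats, pres)
  mask_vals <- matrix(0, 12, 12); mask_vals[3, ] <- 1
  mask <- fix_grid(mask_vals)
  surf <- predict_logistic(model, toy$stack, water_mask = mask)
  expect_true(all(surf$values >= 0 & surf$values <= 1, na.rm = TRUE))
  expect_equal(unique(surf$values[3, ]), 0)
  # monotone in the linear predictor
  eta <- drop(toy$feats$matrix %*% model$weights)
  p <- surf$values[cbind(toy$feats$cells$row, toy$feats$cells$col)]
  keep <- mask_vals[cbind(toy$feats$cells$row, toy$feats$cells$col)] == 0
  expect_gt(cor(eta[keep], p[keep], method = "spearman"), 0.999)
})

test_that("merge_max is a commutative cellwise maximum with nodata pass-through", {
  a_vals <- matrix(c(0.2, NA, 0.6, 0.1), 2, 2)
  b_vals <- matrix(c(0.7, 0.3, NA, 0.1), 2, 2)
  mk <- function(v) {
    g <- fix_grid(v); attr(g, "role") <- "suitability"
    class(g) <- c("surface_raster", class(g)); g
  }
  m <- merge_max(mk(a_vals), mk(b_vals))
  expect_equal(m$values, matrix(c(0.7, 0.3, 0.6, 0.1), 2, 2))
  m2 <- merge_max(mk(b_vals), mk(a_vals))
  expect_equal(m2$values, m$values)
  zero <- mk(matrix(0, 2, 2))
  b <- mk(matrix(c(0.7, 0.3, 0.2, 0.1), 2, 2))
  expect_equal(merge_max(zero, b)$values, b$values)
  both_na <- merge_max(mk(matrix(NA_real_, 2, 2)), mk(matrix(NA_real_, 2, 2)))
  expect_true(all(is.na(both_na$values)))
})

test_that("presence points off the background are rejected", {
  toy <- maxent_toy(8)
  pres <- presence_set(FIX_LAT + 0.5, FIX_LON)
  expect_error(fit_maxent(toy$feats, pres), "outside")
  few <- presences_at(toy$stack$ENV, 1:3, 1:3)
  expect_error(fit_maxent(toy$feats, few), "at least 5")
})
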