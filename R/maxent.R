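#' Expand an environmental stack into MaxEnt feature columns
#'
#' Each variable is min-max scaled to [0, 1] over the background cells;
#' feature classes are `linear` (the scaled value), `quadratic` (its
#' square), and `hinge` (`max(0, (v - k)/(1 - k))` at `n_hinge_knots` evenly
#' spaced knots `k = 0, 1/n, ..., (n-1)/n` on the scaled axis). The scaling
#' constants and knots are stored so the same transform applies bit-for-bit
#' at prediction time (values outside the training range are clamped).
#'
#' @param stack named list of [raster_grid] layers on one frame.
#' @param cells optional data.frame(row, col) of background cells; default
#'   all cells with data in every layer.
#' @param classes subset of `c("linear", "quadratic", "hinge")`.
#' @param n_hinge_knots hinge knots per variable (default 10).
#' @return a `maxent_features` object: `defs` (per-feature variable, class,
#'   knot, vmin, vmax), `matrix` (cells x features), `cells`, `grid`
#'   (frame of the first layer, used to map coordinates to cells).
#' @export
feature_expand <- function(stack, cells = NULL,
                           classes = c("linear", "quadratic", "hinge"),
                           n_hinge_knots = 10L) {
  classes <- match.arg(classes, several.ok = TRUE)
  frame <- stack[[1]]
  ok <- Reduce(`&`, lapply(stack, function(g) !is.na(g$values)))
  if (is.null(cells)) {
    idx <- which(ok, arr.ind = TRUE)
    cells <- data.frame(row = idx[, 1], col = idx[, 2])
  }
  defs <- list()
  for (tok in names(stack)) {
    v <- stack[[tok]]$values[cbind(cells$row, cells$col)]
    vmin <- min(v); vmax <- max(v)
    if (vmax == vmin) {
      warning("constant variable '", tok, "': features dropped")
      next
    }
    if ("linear" %in% classes)
      defs[[length(defs) + 1L]] <- list(variable = tok, class = "linear",
                                        knot = NA_real_, vmin = vmin, vmax = vmax)
    if ("quadratic" %in% classes)
      defs[[length(defs) + 1L]] <- list(variable = tok, class = "quadratic",
                                        knot = NA_real_, vmin = vmin, vmax = vmax)
    if ("hinge" %in% classes)
      for (k in seq(0, 1 - 1 / n_hinge_knots, length.out = n_hinge_knots))
        defs[[length(defs) + 1L]] <- list(variable = tok, class = "hinge",
                                          knot = k, vmin = vmin, vmax = vmax)
  }
  if (!length(defs)) stop("no usable features")
  F <- apply_features(defs, stack, cells)
  structure(list(defs = defs, matrix = F, cells = cells, grid = frame),
            class = "maxent_features")
}

# Evaluate stored feature definitions on a set of cells of a stack.
apply_features <- function(defs, stack, cells) {
  F <- matrix(0, nrow(cells), length(defs))
  colnames(F) <- vapply(defs, function(d)
    if (d$class == "hinge") sprintf("%s_hinge_%.2f", d$variable, d$knot)
    else paste(d$variable, d$class, sep = "_"), character(1))
  for (k in seq_along(defs)) {
    d <- defs[[k]]
    x <- stack[[d$variable]]$values[cbind(cells$row, cells$col)]
    v <- pmin(pmax((x - d$vmin) / (d$vmax - d$vmin), 0), 1)
    F[, k] <- switch(d$class,
                     linear = v,
                     quadratic = v^2,
                     hinge = pmax(0, (v - d$knot) / (1 - d$knot)))
  }
  F
}

#' Fit a maximum-entropy presence-only model
#'
#' Fits the Gibbs distribution \eqn{q(x) \propto \exp(w \cdot f(x))} over the
#' background cells by maximizing the penalized presence log-likelihood
#' \deqn{\frac{1}{m}\sum_{presences} w \cdot f(x) - \log Z(w) - \sum_f \beta_f |w_f|,}
#' a convex problem solved by proximal gradient descent (FISTA with
#' backtracking). At the optimum every feature satisfies the KKT box
#' condition \eqn{|E_q[f] - \bar f_{presence}| \le \beta_f}, with equality on
#' active features - the defining property of L1-regularized MaxEnt.
#'
#' Per-class regularization constants are scaled by the presence count as
#' \eqn{\beta_{class}/\sqrt{m}}, so constraints tighten with more data.
#'
#' @param features a `maxent_features` object.
#' @param presences a `presence_set`; every point must fall on a background
#'   cell.
#' @param beta named per-class base constants (default linear/quadratic/hinge
#'   all 1).
#' @param max_iter iteration cap (error on non-convergence).
#' @param tol KKT violation tolerance.
#' @return a `maxent_model`: `defs`, `weights`, `beta` (per feature),
#'   `entropy_H`, `raw` (fitted background distribution), `log_Z`,
#'   `presence_means`, `cells`, `grid`, `n_background`.
#' @export
fit_maxent <- function(features, presences,
                       beta = c(linear = 1, quadratic = 1, hinge = 1),
                       max_iter = 2000L, tol = 1e-6) {
  F <- features$matrix
  n <- nrow(F)
  pc <- point_to_cell(features$grid, presences$lat, presences$lon)
  key <- paste(features$cells$row, features$cells$col)
  pidx <- match(paste(pc$row, pc$col), key)
  if (any(is.na(pidx)))
    stop(sum(is.na(pidx)), " presence point(s) fall outside the background")
  m <- length(pidx)
  if (m < 5L) stop("need at least 5 presence cells")
  s <- colMeans(F[pidx, , drop = FALSE])
  cls <- vapply(features$defs, `[[`, "", "class")
  bf <- unname(beta[cls]) / sqrt(m)
  if (any(is.na(bf))) stop("beta must name every feature class in use")

  smooth_grad <- function(w) {
    eta <- drop(F %*% w)
    mx <- max(eta)
    q <- exp(eta - mx); q <- q / sum(q)
    list(q = q, grad = drop(crossprod(F, q)) - s,
         val = log(sum(exp(eta - mx))) + mx - sum(s * w))
  }
  # value of the smooth part at w given precomputed pieces is recomputed
  # cheaply inside the backtracking loop
  soft <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

  w <- numeric(ncol(F)); wv <- w
  tprev <- 1
  L <- 1
  g0 <- smooth_grad(w)
  fv <- g0$val
  for (it in seq_len(max_iter)) {
    gv <- smooth_grad(wv)
    repeat {
      w_new <- soft(wv - gv$grad / L, bf / L)
      gnew <- smooth_grad(w_new)
      dd <- w_new - wv
      if (gnew$val <= gv$val + sum(gv$grad * dd) + L / 2 * sum(dd^2) + 1e-12)
        break
      L <- L * 2
      if (L > 1e12) stop("MaxEnt line search failed (Lipschitz blow-up)")
    }
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    wv <- w_new + (tprev - 1) / tnew * (w_new - w)
    w <- w_new; tprev <- tnew
    L <- max(L / 2, 1e-3)
    gw <- smooth_grad(w)
    kkt <- ifelse(w == 0, pmax(abs(gw$grad) - bf, 0), abs(gw$grad + bf * sign(w)))
    if (max(kkt) <= tol) break
    if (it == max_iter)
      stop(sprintf("MaxEnt did not converge in %d iterations (KKT violation %.3g)",
                   max_iter, max(kkt)))
  }
  gw <- smooth_grad(w)
  q <- gw$q
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(list(defs = features$defs, weights = setNames(w, colnames(F)),
                 beta = setNames(bf, colnames(F)), entropy_H = H, raw = q,
                 log_Z = gw$val + sum(s * w), presence_means = s,
                 cells = features$cells, grid = features$grid,
                 n_background = n),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features over %d background cells, H = %.3f\n",
              length(x$weights), x$n_background, x$entropy_H))
  act <- x$weights[x$weights != 0]
  if (length(act)) print(round(act, 4))
  invisible(x)
}

#' Logistic-output prediction surface
#'
#' Converts the fitted raw distribution to the 0-1 logistic score
#' \eqn{c\,q(x) e^H / (1 + c\,q(x) e^H)} with \eqn{c = \tau/(1-\tau)} and
#' prevalence constant \eqn{\tau = 0.5} by default, so a completely
#' uninformative model scores every cell at \eqn{\tau}. Cells flagged by the
#' water mask are forced to 0 after the transform (open water is treated as
#' a hard barrier).
#'
#' @param model a `maxent_model`.
#' @param stack named list of [raster_grid] layers including every variable
#'   the model uses.
#' @param water_mask optional [raster_grid]; cells with a nonzero,
#'   non-missing value are water.
#' @param tau prevalence constant (default 0.5).
#' @param role tag recorded on the output (`"connectivity"` or
#'   `"suitability"`).
#' @return a `surface_raster`: [raster_grid] with values in [0, 1].
#' @export
predict_logistic <- function(model, stack, water_mask = NULL, tau = 0.5,
                             role = "connectivity") {
  toks <- unique(vapply(model$defs, `[[`, "", "variable"))
  if (!all(toks %in% names(stack)))
    stop("stack is missing variable(s): ",
         paste(setdiff(toks, names(stack)), collapse = ", "))
  ok <- Reduce(`&`, lapply(stack[toks], function(g) !is.na(g$values)))
  idx <- which(ok, arr.ind = TRUE)
  cells <- data.frame(row = idx[, 1], col = idx[, 2])
  F <- apply_features(model$defs, stack, cells)
  eta <- drop(F %*% model$weights)
  logq <- eta - model$log_Z
  odds <- exp(logq + model$entropy_H) * tau / (1 - tau)
  p <- odds / (1 + odds)
  frame <- stack[[toks[1]]]
  out <- frame$values
  out[] <- NA_real_
  out[cbind(cells$row, cells$col)] <- p
  if (!is.null(water_mask)) {
    water <- !is.na(water_mask$values) & water_mask$values != 0
    out[water & !is.na(out)] <- 0
  }
  sr <- raster_grid(out, frame$cellsize_deg, frame$origin_lat,
                    frame$origin_lon, frame$nodata_flag)
  attr(sr, "role") <- role
  class(sr) <- c("surface_raster", class(sr))
  sr
}

#' Cellwise maximum of two surfaces
#'
#' Used to merge a newly fitted suitability model with an existing (prior)
#' one: each pixel takes the larger of the two scores; where one layer is
#' nodata the other's value carries through.
#'
#' @param a,b `surface_raster` (or [raster_grid]) objects on the same frame.
#' @return a `surface_raster`.
#' @export
merge_max <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("surfaces are not on the same frame")
  va <- a$values; vb <- b$values
  out <- pmax(va, vb, na.rm = TRUE)   # nodata in one layer -> the other's value
  sr <- raster_grid(out, a$cellsize_deg, a$origin_lat, a$origin_lon,
                    a$nodata_flag)
  attr(sr, "role") <- attr(a, "role") %||% "suitability"
  class(sr) <- c("surface_raster", class(sr))
  sr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
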