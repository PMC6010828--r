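#' Multiple matrix regression with randomization (MMRR)
#'
#' Regresses an unfolded distance matrix on one or more unfolded predictor
#' matrices. All vectors are standardized to zero mean and unit variance so
#' coefficients are comparable across predictor surfaces. Significance of
#' each coefficient comes from jointly permuting the rows and columns of the
#' response matrix, refitting, and counting `|t*| >= |t|` with the +1
#' correction (Wang's randomization scheme).
#'
#' Pairs with a non-finite value in any predictor (disconnected focal pairs)
#' are dropped listwise from all matrices; the count is reported in the
#' result.
#'
#' @param y response [pairwise_matrix].
#' @param xs named list of predictor [pairwise_matrix] objects (a single
#'   matrix is accepted).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `mmrr_result`: `coefficients` (data.frame with
#'   predictor, beta, t_stat, p_perm), `r_squared`, `n_perm`, `seed`,
#'   `n_dropped_pairs`.
#' @references Wang, I.J. (2013) Examining the full effects of landscape
#'   heterogeneity on spatial genetic variation. Evolution 67:3403-3411.
#' @export
mmrr <- function(y, xs, n_perm = 10000L, seed = 1L) {
  if (inherits(xs, "pairwise_matrix")) xs <- list(x = xs)
  if (is.null(names(xs)) || any(!nzchar(names(xs))))
    names(xs) <- paste0("x", seq_along(xs))
  do.call(check_same_ids, c(list(y), xs))
  n <- nrow(y)
  if (n < 5L) stop("MMRR needs at least 5 sites")
  lt <- lower.tri(unclass(y))
  yv_raw <- unclass(y)[lt]
  if (any(!is.finite(yv_raw))) stop("non-finite entries in the response matrix")
  xmat <- vapply(xs, function(m) unclass(m)[lt], numeric(sum(lt)))
  keep <- rowSums(!is.finite(xmat)) == 0L
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("MMRR: dropping ", n_drop, " pair(s) with non-finite predictor values")
  z <- function(v) {
    s <- sd(v)
    if (s == 0) stop("constant vector cannot be standardized (predictor or response)")
    (v - mean(v)) / s
  }
  Xs <- apply(xmat[keep, , drop = FALSE], 2, z)
  yz <- z(yv_raw[keep])
  X <- cbind(`(Intercept)` = 1, Xs)
  XtX <- crossprod(X)
  cn <- kappa(XtX, exact = TRUE)
  if (cn > 1e10) {
    cx <- cor(Xs)
    diag(cx) <- 0
    worst <- which(abs(cx) == max(abs(cx)), arr.ind = TRUE)[1, ]
    stop(sprintf("collinear predictors (condition number %.3g): %s vs %s",
                 cn, colnames(Xs)[worst[1]], colnames(Xs)[worst[2]]))
  }
  XtX_inv <- solve(XtX)
  H <- XtX_inv %*% t(X)
  df <- sum(keep) - ncol(X)
  fit_t <- function(yv) {
    beta <- drop(H %*% yv)
    res <- yv - drop(X %*% beta)
    rss <- sum(res^2)
    se <- sqrt(rss / df * diag(XtX_inv))
    list(beta = beta, t = beta / se, rss = rss)
  }
  obs <- fit_t(yz)
  tss <- sum(yz^2)
  r2 <- 1 - obs$rss / tss
  kcoef <- ncol(Xs)
  hits <- numeric(kcoef)
  set.seed(as.integer(seed))
  ymat <- unclass(y)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    yp <- ymat[idx, idx][lt][keep]
    tstar <- fit_t(yp)$t[-1]
    hits <- hits + (abs(tstar) >= abs(obs$t[-1]))
  }
  coefs <- data.frame(predictor = colnames(Xs),
                      beta = unname(obs$beta[-1]),
                      t_stat = unname(obs$t[-1]),
                      p_perm = (1 + hits) / (n_perm + 1),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, r_squared = r2, n_perm = n_perm,
                 seed = seed, n_dropped_pairs = n_drop),
            class = "mmrr_result")
}

#' @export
print.mmrr_result <- function(x, ...) {
  cat(sprintf("<mmrr> R^2 = %.4f, %d permutations\n", x$r_squared, x$n_perm))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Two-step IBD-residual scan of resistance surfaces
#'
#' Step 1 regresses the unfolded F_ST matrix on the geographic control
#' (isolation by distance) and refolds the residuals. Step 2 runs a
#' single-predictor [mmrr()] of the residual matrix on each candidate
#' resistance matrix. The environmental signal tested is therefore the
#' differentiation that *exceeds* the IBD expectation. No multiple-testing
#' correction is applied when flagging surfaces at `alpha` (each surface is a
#' competing hypothesis for the same signal); a Holm-adjusted column is
#' reported alongside for transparency.
#'
#' @param fst F_ST [pairwise_matrix].
#' @param geo_control geographic control matrix (great-circle distance or
#'   uniform-surface effective resistance).
#' @param env_resistances named list of resistance [pairwise_matrix] objects;
#'   names like `"PSN|decreasing|exp_1_500"` are split into variable /
#'   direction / scheme columns.
#' @param n_perm permutations per surface.
#' @param seed integer seed (each surface uses `seed + its index`).
#' @param alpha significance threshold for the `selected` flag.
#' @return list of class `scan_result`: `table` (one row per surface:
#'   surface, variable, direction, scheme, beta, t_stat, p_mmrr, p_holm,
#'   selected), `residual_matrix`, `ibd_fit` (beta and R^2 of step 1).
#' @export
ibd_residual_scan <- function(fst, geo_control, env_resistances,
                              n_perm = 10000L, seed = 1L, alpha = 0.05) {
  do.call(check_same_ids, c(list(fst, geo_control), env_resistances))
  lt <- lower.tri(unclass(fst))
  yv <- unclass(fst)[lt]
  gv <- unclass(geo_control)[lt]
  if (any(!is.finite(yv)) || any(!is.finite(gv)))
    stop("non-finite entries in F_ST or control matrix")
  fit <- lm(yv ~ gv)
  resid_m <- fold_matrix(resid(fit), rownames(fst), "resistance")
  rows <- lapply(seq_along(env_resistances), function(k) {
    m <- mmrr(resid_m, env_resistances[k], n_perm = n_perm,
              seed = as.integer(seed) + k)
    co <- m$coefficients
    data.frame(surface = names(env_resistances)[k], beta = co$beta,
               t_stat = co$t_stat, p_mmrr = co$p_perm,
               r_squared = m$r_squared, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  parts <- strsplit(tab$surface, "|", fixed = TRUE)
  tab$variable <- vapply(parts, `[`, "", 1)
  tab$direction <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  tab$scheme <- vapply(parts, function(p) if (length(p) > 2) p[3] else NA_character_, "")
  tab$p_holm <- stats::p.adjust(tab$p_mmrr, method = "holm")
  tab$selected <- tab$p_mmrr <= alpha
  tab <- tab[order(tab$p_mmrr, -abs(tab$t_stat)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, residual_matrix = resid_m,
                 ibd_fit = list(beta = unname(coef(fit)[2]),
                                r_squared = summary(fit)$r.squared)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<ibd_residual_scan> IBD R^2 = %.3f; %d surfaces, %d selected\n",
              x$ibd_fit$r_squared, nrow(x$table), sum(x$table$selected)))
  print(head(x$table[, c("surface", "beta", "t_stat", "p_mmrr", "selected")], 10),
        row.names = FALSE)
  invisible(x)
}

#' Partial Mantel test
#'
#' Correlation of matrices `a` and `b` after removing the effect of `c`:
#' Pearson correlation of the residuals of `a ~ c` and `b ~ c` on the
#' unfolded lower triangles. Significance by joint row/column permutation of
#' `a` (one-sided, `r* >= r`, +1 correction), the convention of the
#' landscape-genetics literature.
#'
#' @param a,b,c [pairwise_matrix] objects sharing id order.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list with `r_partial`, `p`, `n_perm`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 10000L, seed = 1L) {
  check_same_ids(a, b, c)
  lt <- lower.tri(unclass(a))
  av <- unclass(a)[lt]; bv <- unclass(b)[lt]; cv <- unclass(c)[lt]
  res_b <- resid(lm(bv ~ cv))
  res_a <- resid(lm(av ~ cv))
  if (sd(res_a) < 1e-14 || sd(res_b) < 1e-14)
    stop("constant residuals: partial Mantel r undefined")
  r_obs <- cor(res_a, res_b)
  set.seed(as.integer(seed))
  amat <- unclass(a)
  n <- nrow(amat)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    ra <- resid(lm(amat[idx, idx][lt] ~ cv))
    if (cor(ra, res_b) >= r_obs) hits <- hits + 1L
  }
  list(r_partial = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}
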