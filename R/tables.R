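#' Symmetric site-by-site matrix
#'
#' The common currency of the pipeline: pairwise F_ST, linearized F_ST,
#' great-circle distance, or landscape resistance between sampling sites.
#' Enforces symmetry (within 1e-12 of the larger magnitude), a zero diagonal,
#' and dimension/id agreement. `Inf` entries are permitted and mark pairs in
#' disconnected graph components.
#'
#' @param ids character vector of site ids (ordered).
#' @param values square numeric matrix matching `ids`.
#' @param kind one of `"fst"`, `"linearized_fst"`, `"distance_km"`,
#'   `"resistance"`.
#' @return a `pairwise_matrix` (numeric matrix with dimnames and a `kind`
#'   attribute).
#' @export
pairwise_matrix <- function(ids, values, kind = c("fst", "linearized_fst",
                                                  "distance_km", "resistance")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  values <- as.matrix(values)
  if (anyDuplicated(ids)) stop("site ids must be unique")
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop("matrix dimensions do not match the id list")
  fin <- is.finite(values) & is.finite(t(values))
  if (any(abs(values - t(values))[fin] > 1e-12 * pmax(1, abs(values))[fin]))
    stop("matrix is not symmetric")
  if (any(abs(diag(values)) > 1e-12, na.rm = TRUE))
    stop("diagonal must be zero")
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix kind=%s> %d sites\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Unfold the lower triangle of a pairwise matrix
#' @param m square matrix.
#' @return numeric vector, column-major order of the strict lower triangle.
#' @export
lower_triangle <- function(m) m[lower.tri(m)]

#' Refold a lower-triangle vector into a symmetric zero-diagonal matrix
#' @param v vector as produced by [lower_triangle()].
#' @param ids site ids giving the dimension.
#' @param kind passed to [pairwise_matrix()].
#' @export
fold_matrix <- function(v, ids, kind = "resistance") {
  n <- length(ids)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  pairwise_matrix(ids, m, kind)
}

#' Write / read a pairwise matrix as CSV with id header row and column
#' @param m a [pairwise_matrix].
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @param kind matrix kind tag for the object read back.
#' @export
read_matrix_csv <- function(path, kind = "resistance") {
  df <- read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  pairwise_matrix(ids, vals, kind)
}

#' Read a site coordinate table
#'
#' CSV with at least columns `id`, `lat`, `lon` (an `n` column with per-site
#' sample sizes is kept when present). Ids must be unique and coordinates
#' geographic degrees.
#'
#' @param path file path.
#' @return data.frame with class `site_table`.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  site_table(df$id, df$lat, df$lon, n = df$n)
}

#' Construct a site table
#' @param id site identifiers (unique tokens).
#' @param lat,lon coordinates in decimal degrees.
#' @param n optional individual counts.
#' @export
site_table <- function(id, lat, lon, n = NULL) {
  if (is.null(id) || is.null(lat) || is.null(lon))
    stop("site table needs id, lat and lon")
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate site ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("site coordinates must be geographic degrees")
  df <- data.frame(id = id, lat = as.numeric(lat), lon = as.numeric(lon),
                   stringsAsFactors = FALSE)
  if (!is.null(n)) df$n <- as.integer(n)
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a diploid microsatellite genotype table
#'
#' CSV layout: columns `site`, `individual`, then two columns per locus with
#' integer allele sizes. `0`, blank, or `NA` marks a missing allele call; a
#' genotype is treated as missing unless both calls are present.
#'
#' @param path file path.
#' @return a `genotype_table`: long data.frame with columns `site`,
#'   `individual`, `locus` (integer index), `a`, `b` (allele sizes, `NA` when
#'   missing); attribute `n_loci`.
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4L) stop("genotype CSV needs site, individual and >=1 locus pair")
  allele_cols <- ncol(df) - 2L
  if (allele_cols %% 2L != 0L)
    stop("genotype CSV has an odd number of allele columns (", allele_cols, ")")
  if (anyDuplicated(df[[2]]))
    stop("duplicate individual ids: ",
         paste(unique(df[[2]][duplicated(df[[2]])]), collapse = ", "))
  n_loci <- allele_cols %/% 2L
  to_int <- function(x) {
    x <- suppressWarnings(as.integer(as.character(x)))
    x[!is.na(x) & x == 0L] <- NA_integer_
    x
  }
  recs <- lapply(seq_len(n_loci), function(l) {
    a <- to_int(df[[2L + 2L * l - 1L]])
    b <- to_int(df[[2L + 2L * l]])
    miss <- is.na(a) | is.na(b)
    data.frame(site = as.character(df[[1]]), individual = as.character(df[[2]]),
               locus = l,
               a = ifelse(miss, NA_integer_, a), b = ifelse(miss, NA_integer_, b),
               stringsAsFactors = FALSE)
  })
  genotype_table(do.call(rbind, recs), n_loci = n_loci)
}

#' Construct a genotype table from long records
#' @param df data.frame with columns site, individual, locus, a, b.
#' @param n_loci locus count (inferred from `locus` when missing).
#' @export
genotype_table <- function(df, n_loci = max(df$locus)) {
  need <- c("site", "individual", "locus", "a", "b")
  if (!all(need %in% names(df))) stop("genotype records need columns ",
                                      paste(need, collapse = ", "))
  if (any(xor(is.na(df$a), is.na(df$b))))
    stop("half-missing genotypes: both alleles must be present or both missing")
  df <- df[order(df$site, df$individual, df$locus), need]
  rownames(df) <- NULL
  attr(df, "n_loci") <- as.integer(n_loci)
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Write a genotype table back to the wide CSV layout
#' @param g a `genotype_table`.
#' @param path file path.
#' @export
write_genotypes <- function(g, path) {
  n_loci <- attr(g, "n_loci")
  inds <- unique(g[, c("site", "individual")])
  wide <- inds
  for (l in seq_len(n_loci)) {
    gl <- g[g$locus == l, ]
    i <- match(inds$individual, gl$individual)
    a <- gl$a[i]; b <- gl$b[i]
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
    wide[[sprintf("L%02d_a", l)]] <- a
    wide[[sprintf("L%02d_b", l)]] <- b
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read presence-point records
#' @param path CSV with columns `lat`, `lon`.
#' @return data.frame of class `presence_set`.
#' @export
read_presences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  presence_set(df$lat, df$lon)
}

#' @rdname read_presences
#' @param lat,lon trap coordinates in degrees.
#' @export
presence_set <- function(lat, lon) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("presence coordinates must be geographic degrees")
  df <- data.frame(lat = as.numeric(lat), lon = as.numeric(lon))
  class(df) <- c("presence_set", "data.frame")
  df
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers when they look numeric. Command-line flags are expected to
#' override config values on conflict.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
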