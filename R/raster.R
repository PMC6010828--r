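#' @importFrom stats setNames sd cor pt lm coef resid rnorm rgamma rmultinom
#'   prcomp fft median plogis quantile var t.test uniroot
#' @importFrom utils read.csv write.csv head combn
NULL

# Spherical Earth radius (km) used for every degree->km conversion in the
# package; matches the haversine distances in distance_matrix_km().
EARTH_RADIUS_KM <- 6371.0088

KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180

#' Single-band georeferenced raster grid
#'
#' The one carrier type for environmental layers, resistance surfaces, current
#' maps, connectivity and suitability surfaces. Values are stored as a numeric
#' matrix whose first row is the northernmost; missing cells are `NA`. The
#' georeference is the latitude/longitude of the *center* of the top-left cell
#' plus a square cell size in decimal degrees.
#'
#' @param values numeric matrix (row 1 = north). `NA` marks nodata cells.
#' @param cellsize_deg positive cell edge length in decimal degrees.
#' @param origin_lat,origin_lon coordinates (degrees) of the center of the
#'   top-left cell.
#' @param nodata_flag sentinel written to file for missing cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cellsize_deg, origin_lat, origin_lon,
                        nodata_flag = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize_deg) || length(cellsize_deg) != 1L || cellsize_deg <= 0)
    stop("cellsize_deg must be a single positive number")
  if (abs(origin_lat) > 90 || abs(origin_lon) > 180)
    stop("origin must be geographic degrees (|lat|<=90, |lon|<=180)")
  structure(
    list(values = values, cellsize_deg = cellsize_deg,
         origin_lat = origin_lat, origin_lon = origin_lon,
         nodata_flag = nodata_flag),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %.6g deg (~%.3f km), origin (%.4f, %.4f)\n",
              nrow(v), ncol(v), x$cellsize_deg, cell_size_km(x),
              x$origin_lat, x$origin_lon))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Cell edge length in kilometers
#'
#' Converts the degree cell size to km on a sphere of radius 6371.0088 km,
#' averaging the meridian arc and the parallel arc at the grid's mean
#' latitude. At low latitudes this is within a fraction of a percent of the
#' plain meridian arc (one degree = 111.195 km).
#'
#' @param grid a [raster_grid].
#' @return cell size in km (scalar).
#' @export
cell_size_km <- function(grid) {
  mean_lat <- grid$origin_lat - (nrow(grid$values) - 1) / 2 * grid$cellsize_deg
  grid$cellsize_deg * KM_PER_DEG * (1 + cos(mean_lat * pi / 180)) / 2
}

#' Latitude/longitude of cell centers
#' @param grid a [raster_grid].
#' @param row,col 1-based cell indices (row 1 = north).
#' @return list with numeric `lat`, `lon`.
#' @export
cell_center <- function(grid, row, col) {
  list(lat = grid$origin_lat - (row - 1) * grid$cellsize_deg,
       lon = grid$origin_lon + (col - 1) * grid$cellsize_deg)
}

#' Map a point to its containing cell
#'
#' Points are snapped to the cell whose center is nearest (equivalently, the
#' cell whose square extent contains the point). Errors if the point falls
#' outside the raster frame.
#'
#' @param grid a [raster_grid].
#' @param lat,or numeric vectors of point coordinates in degrees.
#' @param lon see `lat`.
#' @return data.frame with columns `row`, `col`.
#' @export
point_to_cell <- function(grid, lat, lon) {
  row <- round((grid$origin_lat - lat) / grid$cellsize_deg) + 1
  col <- round((lon - grid$origin_lon) / grid$cellsize_deg) + 1
  bad <- row < 1 | row > nrow(grid$values) | col < 1 | col > ncol(grid$values)
  if (any(bad))
    stop(sprintf("%d point(s) fall outside the raster frame (first: lat=%.4f lon=%.4f)",
                 sum(bad), lat[which(bad)[1]], lon[which(bad)[1]]))
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read a single-band raster
#'
#' Two dialects are supported. `esri_ascii` is parsed directly (header keys
#' `ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, optional `NODATA_value`). `geotiff` reads pixel values through
#' the \pkg{tiff} package and takes the geotransform from an ESRI world file
#' (`.tfw`) next to the image; a missing world file is an error because the
#' grid would have no georeference.
#'
#' @param path file path.
#' @param dialect `"esri_ascii"` or `"geotiff"`; default guessed from the
#'   file extension.
#' @return a [raster_grid]. Nodata cells are `NA`.
#' @export
read_raster <- function(path, dialect = c("auto", "esri_ascii", "geotiff")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("tif", "tiff")) "geotiff" else "esri_ascii"
  }
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (dialect == "esri_ascii") read_esri_ascii(path) else read_geotiff(path)
}

read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  repeat {
    if (i > length(lines)) stop("ESRI ASCII parse error: no data rows in ", path)
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1])) {
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val))
        stop(sprintf("ESRI ASCII parse error at line %d: '%s'", i, lines[i]))
      hdr[[tolower(parts[1])]] <- val
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII parse error: header missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (is.null(hdr$xllcorner) && is.null(hdr$xllcenter))
    stop("ESRI ASCII parse error: header missing xllcorner/xllcenter")
  if (is.null(hdr$yllcorner) && is.null(hdr$yllcenter))
    stop("ESRI ASCII parse error: header missing yllcorner/yllcenter")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop(sprintf("ESRI ASCII parse error: expected %d values, found %d",
                 nc * nr, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cs / 2
  yll <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cs / 2
  origin_lat <- yll + (nr - 1) * cs   # from lower-left center to top-left center
  if (abs(origin_lat) > 90 || abs(xll) > 180)
    warning("raster coordinates do not look like geographic degrees; ",
            "distances derived from this grid will be wrong")
  raster_grid(m, cs, origin_lat, xll, nodata_flag = nodata)
}

read_geotiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading GeoTIFF requires the 'tiff' package")
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  wf <- paste0(tools::file_path_sans_ext(path), ".tfw")
  if (!file.exists(wf))
    stop("GeoTIFF '", path, "' has no world file (", basename(wf),
         "); cannot georeference")
  w <- scan(wf, quiet = TRUE)
  if (length(w) != 6L) stop("malformed world file: ", wf)
  # world file lines: x-size, rot, rot, y-size(negative), x-center, y-center
  if (abs(abs(w[4]) - abs(w[1])) > 1e-9 * abs(w[1]))
    stop("non-square cells in world file: ", wf)
  m[is.nan(m)] <- NA_real_
  raster_grid(m, abs(w[1]), origin_lat = w[6], origin_lon = w[5],
              nodata_flag = NaN)
}

#' Write a single-band raster
#'
#' `esri_ascii` output round-trips bit-exactly through [read_raster()] (values
#' are printed with 17 significant digits). `geotiff` writes a 32-bit float
#' TIFF plus a `.tfw` world file; use the ASCII dialect when exact
#' reproduction matters.
#'
#' @param grid a [raster_grid].
#' @param path output path.
#' @param dialect `"esri_ascii"` or `"geotiff"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, dialect = c("auto", "esri_ascii", "geotiff")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("tif", "tiff")) "geotiff" else "esri_ascii"
  }
  m <- grid$values
  nr <- nrow(m); nc <- ncol(m)
  if (dialect == "esri_ascii") {
    nodata <- grid$nodata_flag
    if (is.na(nodata) || is.nan(nodata)) nodata <- -9999
    hdr <- c(sprintf("ncols %d", nc),
             sprintf("nrows %d", nr),
             sprintf("xllcenter %.17g", grid$origin_lon),
             sprintf("yllcenter %.17g", grid$origin_lat - (nr - 1) * grid$cellsize_deg),
             sprintf("cellsize %.17g", grid$cellsize_deg),
             sprintf("NODATA_value %.17g", nodata))
    m[is.na(m)] <- nodata
    rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(c(hdr, rows), path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing GeoTIFF requires the 'tiff' package")
    m[is.na(m)] <- NaN
    tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = TRUE)
    wf <- paste0(tools::file_path_sans_ext(path), ".tfw")
    writeLines(sprintf("%.17g", c(grid$cellsize_deg, 0, 0, -grid$cellsize_deg,
                                  grid$origin_lon, grid$origin_lat)), wf)
  }
  invisible(path)
}
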