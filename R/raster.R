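#' In-memory georeferenced raster grid
#'
#' A light container for the rasters the pipeline moves around: a numeric
#' array (rows x cols x bands), the world coordinates of the top-left
#' corner, and a square pixel size. The local frame is metric and north-up:
#' x grows eastward (with column index), y grows southward (with row
#' index), matching image row order. Pixel centers sit at
#' `origin + (index - 0.5) * gsd_m`.
#'
#' @param values numeric matrix (single band) or rows x cols x bands array.
#' @param origin numeric length-2, world (x, y) of the top-left raster
#'   corner in meters.
#' @param gsd_m pixel size in meters (square pixels).
#' @param bands optional character vector of band names; defaults to
#'   `c("R","G","B")` for 3-band values, `"B1"..` otherwise.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), gsd_m, bands = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a matrix or a 3-d array", call. = FALSE)
  if (!is.numeric(gsd_m) || length(gsd_m) != 1L || gsd_m <= 0)
    stop("`gsd_m` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric length 2", call. = FALSE)
  nb <- dim(values)[3L]
  if (is.null(bands))
    bands <- if (nb == 3L) c("R", "G", "B") else paste0("B", seq_len(nb))
  if (length(bands) != nb)
    stop("band names do not match band count", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 gsd_m = gsd_m, bands = bands),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d x %d px, %d band(s) [%s]\n",
              d[1], d[2], d[3], paste(x$bands, collapse = ",")))
  cat(sprintf("  origin (%.3f, %.3f) m, gsd %.4f m/px\n",
              x$origin[1], x$origin[2], x$gsd_m))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Extract one band of a raster as a plain matrix
#' @param x a `grid_raster`.
#' @param band band name or index.
#' @return numeric matrix.
#' @export
raster_band <- function(x, band) {
  stopifnot(inherits(x, "grid_raster"))
  if (is.character(band)) {
    i <- match(band, x$bands)
    if (is.na(i)) stop("no band named '", band, "'", call. = FALSE)
  } else i <- as.integer(band)
  d <- dim(x$values)
  matrix(x$values[, , i], d[1], d[2])
}

#' World coordinates of pixel centers
#'
#' @param x a `grid_raster` (or any object with `origin`, `gsd_m`, raster
#'   dims).
#' @return list with vectors `x` (per column) and `y` (per row), meters.
#' @export
pixel_centers <- function(x) {
  d <- dim(x$values)
  list(x = x$origin[1] + (seq_len(d[2]) - 0.5) * x$gsd_m,
       y = x$origin[2] + (seq_len(d[1]) - 0.5) * x$gsd_m)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values)[1:2] == dim(b$values)[1:2]) &&
    max(abs(a$origin - b$origin)) < tol && abs(a$gsd_m - b$gsd_m) < tol
}

#' Logical mask of pixels whose centers fall inside a polygon
#'
#' The single geometry convention of the package: a pixel belongs to a
#' region of interest iff its center lies inside (or on the boundary of)
#' the polygon. Evaluation is restricted to the polygon's bounding box.
#'
#' @param x a `grid_raster` supplying the grid geometry.
#' @param polygon two-column matrix of world (x, y) vertices, meters; an
#'   open ring is closed implicitly.
#' @return logical matrix with the raster's row/col dimensions.
#' @export
pixels_in_polygon <- function(x, polygon) {
  stopifnot(inherits(x, "grid_raster"))
  polygon <- as.matrix(polygon)
  d <- dim(x$values)
  ctr <- pixel_centers(x)
  mask <- matrix(FALSE, d[1], d[2])
  cr <- range(polygon[, 1]); rr <- range(polygon[, 2])
  cols <- which(ctr$x >= cr[1] - x$gsd_m & ctr$x <= cr[2] + x$gsd_m)
  rows <- which(ctr$y >= rr[1] - x$gsd_m & ctr$y <= rr[2] + x$gsd_m)
  if (!length(cols) || !length(rows)) return(mask)
  px <- rep(ctr$x[cols], each = length(rows))
  py <- rep(ctr$y[rows], times = length(cols))
  inside <- pracma::inpolygon(px, py, polygon[, 1], polygon[, 2],
                              boundary = TRUE)
  mask[rows, cols] <- matrix(inside, length(rows), length(cols))
  mask
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a raster to disk as TIFF plus a georeferencing sidecar
#'
#' The pixel grid goes into a plain TIFF; the affine transform (origin,
#' gsd), band names, dtype and the value scaling are recorded in a JSON
#' sidecar `<path>.aux.json`. Integer dtypes (`uint8`, `uint16`) store DN
#' exactly; `float32` data are mapped into `[0, 1]` with a power-of-two
#' scale and offset and stored as 32-bit samples, so continuous rasters
#' round-trip to about 1 part in 4e9 of their value span.
#'
#' @param x a `grid_raster`. Values must be finite.
#' @param path output file path (`.tif`).
#' @param dtype one of `"float32"`, `"uint8"`, `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, dtype = c("float32", "uint8", "uint16")) {
  stopifnot(inherits(x, "grid_raster"))
  dtype <- match.arg(dtype)
  v <- x$values
  if (any(!is.finite(v)))
    stop("raster contains non-finite values; mask them before writing",
         call. = FALSE)
  if (dtype %in% c("uint8", "uint16")) {
    top <- if (dtype == "uint8") 255 else 65535
    if (any(v < 0 | v > top | v != round(v)))
      stop("values do not fit dtype ", dtype, call. = FALSE)
    tiff::writeTIFF(v / top, path,
                    bits.per.sample = if (dtype == "uint8") 8L else 16L)
    scale <- top; offset <- 0
  } else {
    lo <- min(v); hi <- max(v)
    # power-of-two offset and scale keep the mapping exact in binary, so
    # the only loss is the single double -> float32 rounding per pixel
    offset <- if (lo >= 0) 0 else -2^ceiling(log2(-lo))
    span <- hi - offset
    scale <- if (span <= 0) 1 else 2^ceiling(log2(span))
    tiff::writeTIFF((v - offset) / scale, path, bits.per.sample = 32L)
  }
  meta <- list(driver = "uavpheno-tiff", origin = x$origin, gsd_m = x$gsd_m,
               bands = x$bands, dtype = dtype, scale = scale,
               offset = offset, dim = dim(v))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path path to the TIFF.
#' @param expected_bands optional band count to enforce.
#' @return a `grid_raster`.
#' @export
read_raster <- function(path, expected_bands = NULL) {
  if (!file.exists(path)) stop("no such raster: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("raster '", path, "' has no georeferencing sidecar (",
         basename(sc), " missing)", call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$origin) || is.null(meta$gsd_m))
    stop("sidecar of '", path, "' lacks an affine transform", call. = FALSE)
  v <- tiff::readTIFF(path)
  if (is.matrix(v)) v <- array(v, c(dim(v), 1L))
  # integer dtypes are stored normalized by `scale`; undo it exactly
  v <- if (meta$dtype %in% c("uint8", "uint16")) round(v * meta$scale)
  else v * meta$scale + meta$offset
  if (!is.null(expected_bands) && dim(v)[3L] != expected_bands)
    stop("expected ", expected_bands, " band(s), found ", dim(v)[3L],
         " in ", path, call. = FALSE)
  grid_raster(v, origin = meta$origin, gsd_m = meta$gsd_m,
              bands = meta$bands)
}
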