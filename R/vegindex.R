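#' Chromatic coordinates of an RGB reflectance raster
#'
#' Normalizes each band by the band sum: `r = R/(R+G+B)` and likewise for
#' g and b, removing overall brightness. Pixels with `R+G+B = 0` are
#' marked invalid (excluded from downstream indices, means and
#' histograms) rather than propagated as NaN.
#'
#' @param x 3-band reflectance `grid_raster`.
#' @return object of class `chromatic_image`: matrices `r`, `g`, `b`,
#'   logical `valid`, and the grid geometry (`origin`, `gsd_m`).
#' @export
chromatic_coords <- function(x) {
  stopifnot(inherits(x, "grid_raster"))
  if (dim(x)[3] != 3L)
    stop("chromatic coordinates need exactly 3 bands", call. = FALSE)
  R <- raster_band(x, "R"); G <- raster_band(x, "G"); B <- raster_band(x, "B")
  s <- R + G + B
  valid <- is.finite(s) & s > 0
  s[!valid] <- 1  # placeholder; masked out
  structure(list(r = R / s, g = G / s, b = B / s, valid = valid,
                 origin = x$origin, gsd_m = x$gsd_m),
            class = "chromatic_image")
}

#' Compute the six RGB vegetation indices
#'
#' From chromatic coordinates (r, g, b summing to 1 per pixel):
#' EXG = 2g - r - b, EXR = 1.4r - g, EXGR = 3g - 2.4r - b (= EXG - EXR),
#' NDI = (g - r)/(g + r), GLI = (2g - b - r)/(2g + b + r),
#' VARI = (g - r)/(g + r - b). Indices are computed only on valid pixels;
#' pixels where a denominator vanishes are invalidated for that index
#' only (`valid_ndi`, `valid_vari`).
#'
#' @param chroma a `chromatic_image`.
#' @return object of class `vi_stack`: matrices `exg`, `exgr`, `exr`,
#'   `ndi`, `gli`, `vari`, masks `valid`, `valid_ndi`, `valid_vari`,
#'   and grid geometry.
#' @export
compute_vis <- function(chroma) {
  stopifnot(inherits(chroma, "chromatic_image"))
  r <- chroma$r; g <- chroma$g; b <- chroma$b; valid <- chroma$valid
  exg <- 2 * g - r - b
  exr <- 1.4 * r - g
  exgr <- 3 * g - 2.4 * r - b
  dn_ndi <- g + r
  dn_vari <- g + r - b
  valid_ndi <- valid & dn_ndi != 0
  valid_vari <- valid & dn_vari != 0
  ndi <- gli <- vari <- matrix(NA_real_, nrow(r), ncol(r))
  ndi[valid_ndi] <- ((g - r) / dn_ndi)[valid_ndi]
  # 2g + b + r = 1 + g > 0 always on valid pixels
  gli[valid] <- ((2 * g - b - r) / (2 * g + b + r))[valid]
  vari[valid_vari] <- ((g - r) / dn_vari)[valid_vari]
  exg[!valid] <- exr[!valid] <- exgr[!valid] <- NA_real_
  structure(list(exg = exg, exgr = exgr, exr = exr, ndi = ndi, gli = gli,
                 vari = vari, valid = valid, valid_ndi = valid_ndi,
                 valid_vari = valid_vari, origin = chroma$origin,
                 gsd_m = chroma$gsd_m),
            class = "vi_stack")
}

vi_names <- function() c("exg", "exgr", "exr", "ndi", "gli", "vari")

#' Otsu's threshold over a collection of values
#'
#' Builds a fixed-bin histogram spanning the observed range (256 bins by
#' default) and returns the interior bin edge maximizing the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2`. Deterministic: ties
#' are broken toward the lowest edge.
#'
#' @param values numeric vector (e.g. EXG over plot ROIs); non-finite
#'   entries are dropped.
#' @param bins number of histogram bins.
#' @return list with `threshold`, `between_class_variance`, `counts`,
#'   `breaks`.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("degenerate input: Otsu needs at least 2 distinct values",
         call. = FALSE)
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  n <- sum(counts)
  w0 <- cumsum(counts)[-bins]
  w1 <- n - w0
  m0 <- cumsum(counts * mids)[-bins]
  mu0 <- m0 / w0
  mu1 <- (sum(counts * mids) - m0) / w1
  sb2 <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sb2[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(sb2)  # first maximum -> lowest edge
  list(threshold = breaks[k + 1L], between_class_variance = sb2[k],
       counts = counts, breaks = breaks)
}

#' Canopy mask by EXG thresholding over regions of interest
#'
#' A pixel is canopy iff it is valid, its center lies inside at least one
#' ROI polygon, and its EXG exceeds the threshold. With
#' `scope = "global"` (default) one Otsu threshold is computed over the
#' union of ROIs; `"per-plot"` thresholds each ROI independently. A
#' numeric `threshold` overrides Otsu.
#'
#' @param vis a `vi_stack` (its `exg` and `valid` are used), or a
#'   single-band `grid_raster` of EXG values.
#' @param rois list of `plot_roi` objects.
#' @param scope `"global"` or `"per-plot"`.
#' @param threshold optional fixed EXG threshold (may be `-Inf`).
#' @param bins histogram bins for Otsu.
#' @return logical canopy matrix with attributes `threshold` (named per
#'   plot for per-plot scope) and `roi_mask` (the ROI union coverage).
#' @export
vegetation_mask <- function(vis, rois, scope = c("global", "per-plot"),
                            threshold = NULL, bins = 256L) {
  scope <- match.arg(scope)
  if (inherits(vis, "grid_raster")) {
    exg <- raster_band(vis, 1L); valid <- is.finite(exg)
    geom <- vis
  } else {
    stopifnot(inherits(vis, "vi_stack"))
    exg <- vis$exg; valid <- vis$valid
    geom <- grid_raster(exg, origin = vis$origin, gsd_m = vis$gsd_m,
                        bands = "EXG")
  }
  if (!length(rois)) stop("empty ROI union", call. = FALSE)
  roi_masks <- lapply(rois, function(r) pixels_in_polygon(geom, r$polygon))
  union <- Reduce(`|`, roi_masks)
  if (!any(union)) stop("empty ROI union", call. = FALSE)
  canopy <- matrix(FALSE, nrow(exg), ncol(exg))
  if (scope == "global") {
    thr <- threshold %||% otsu_threshold(exg[union & valid], bins)$threshold
    canopy <- valid & union & !is.na(exg) & exg > thr
    thrs <- thr
  } else {
    thrs <- numeric(length(rois))
    for (i in seq_along(rois)) {
      m <- roi_masks[[i]] & valid
      thrs[i] <- threshold %||% otsu_threshold(exg[m], bins)$threshold
      canopy <- canopy | (m & !is.na(exg) & exg > thrs[i])
    }
    names(thrs) <- vapply(rois, function(r) r$plot_id, "")
  }
  attr(canopy, "threshold") <- thrs
  attr(canopy, "roi_mask") <- union
  canopy
}
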