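#' Per-plant canopy surface area of a plot
#'
#' Canopy pixels inside the plot ROI are counted, converted to cm² with
#' the ground sampling distance, and divided by the plot's stand count.
#' A stand count of 0 marks a non-germinated plot: the function returns
#' `NA` (with a message) rather than failing, so callers can drop the
#' plot downstream.
#'
#' @param canopy_mask logical canopy matrix (from [vegetation_mask()]).
#' @param roi a `plot_roi`.
#' @param geom `grid_raster` supplying the grid geometry.
#' @param gsd_cm pixel size in cm (defaults to `geom$gsd_m * 100`).
#' @param n_plants stand count override; defaults to `roi$n_plants`.
#' @return per-plant area in cm², with attribute `n_canopy_px`.
#' @export
plot_surface_area <- function(canopy_mask, roi, geom, gsd_cm = NULL,
                              n_plants = NULL) {
  stopifnot(inherits(roi, "plot_roi"), inherits(geom, "grid_raster"))
  gsd_cm <- gsd_cm %||% (geom$gsd_m * 100)
  if (gsd_cm <= 0) stop("`gsd_cm` must be positive", call. = FALSE)
  n_plants <- n_plants %||% roi$n_plants
  px <- sum(canopy_mask & pixels_in_polygon(geom, roi$polygon))
  if (n_plants == 0) {
    message("plot '", roi$plot_id, "' has no plants; excluded from area")
    return(structure(NA_real_, n_canopy_px = px))
  }
  structure(px * gsd_cm^2 / n_plants, n_canopy_px = px)
}

#' Estimated plant height of a plot from DSM minus DTM
#'
#' The canopy height model is the per-pixel difference between the
#' digital surface model and the digital terrain model; negative
#' differences (reconstruction noise) are floored at 0 before taking the
#' plot maximum, which is returned in millimeters.
#'
#' @param dsm single-band `grid_raster`, elevation in meters.
#' @param dtm single-band `grid_raster` on the same grid.
#' @param roi a `plot_roi` covering at least one pixel center.
#' @return height in mm.
#' @export
estimate_height <- function(dsm, dtm, roi) {
  stopifnot(inherits(dsm, "grid_raster"), inherits(dtm, "grid_raster"),
            inherits(roi, "plot_roi"))
  if (!same_geometry(dsm, dtm))
    stop("DSM and DTM are not co-registered", call. = FALSE)
  mask <- pixels_in_polygon(dsm, roi$polygon)
  if (!any(mask))
    stop("ROI '", roi$plot_id, "' covers no pixel centers", call. = FALSE)
  chm <- pmax(raster_band(dsm, 1L) - raster_band(dtm, 1L), 0)
  max(chm[mask]) * 1000
}

#' Mean vegetation indices over a plot
#'
#' Arithmetic mean of each of the six indices over the selected pixels:
#' all valid ROI pixels (`mode = "all-roi"`) or only canopy pixels inside
#' the ROI (`mode = "canopy-only"`). Pixels invalid for NDI or VARI are
#' excluded from those two means only. If no pixel qualifies, all six
#' means are `NA` and a message is logged.
#'
#' @param vis a `vi_stack`.
#' @param roi a `plot_roi`.
#' @param mode `"all-roi"` or `"canopy-only"`.
#' @param canopy_mask logical canopy matrix; required for canopy-only.
#' @return named numeric vector `exg`, `exgr`, `exr`, `ndi`, `gli`,
#'   `vari`, with attribute `n_pixels`.
#' @export
plot_vi_means <- function(vis, roi, mode = c("all-roi", "canopy-only"),
                          canopy_mask = NULL) {
  stopifnot(inherits(vis, "vi_stack"), inherits(roi, "plot_roi"))
  mode <- match.arg(mode)
  geom <- grid_raster(vis$exg, origin = vis$origin, gsd_m = vis$gsd_m)
  sel <- pixels_in_polygon(geom, roi$polygon) & vis$valid
  if (mode == "canopy-only") {
    if (is.null(canopy_mask))
      stop("canopy-only mode needs `canopy_mask`", call. = FALSE)
    sel <- sel & canopy_mask
  }
  if (!any(sel)) {
    message("plot '", roi$plot_id, "': no pixels selected for VI means")
    return(structure(setNames(rep(NA_real_, 6), vi_names()), n_pixels = 0L))
  }
  out <- vapply(vi_names(), function(v) {
    m <- sel
    if (v == "ndi") m <- m & vis$valid_ndi
    if (v == "vari") m <- m & vis$valid_vari
    mean(vis[[v]][m])
  }, numeric(1))
  structure(out, n_pixels = sum(sel))
}

#' Extract image traits for every plot of one acquisition
#'
#' Convenience wrapper running canopy segmentation, per-plant area,
#' height estimation and VI means across a list of plot ROIs.
#'
#' @param refl 3-band reflectance `grid_raster`.
#' @param dsm,dtm elevation `grid_raster`s co-registered with `refl`.
#' @param plot_rois list of `plot_roi`.
#' @param otsu_scope threshold scope for [vegetation_mask()].
#' @param vi_mode pixel selection for [plot_vi_means()].
#' @param gsd_cm pixel size in cm; defaults from the raster.
#' @return data.frame, one row per plot: `plot_id`, `entry`, `rep`,
#'   `n_plants`, `sur_cm2`, `eph_mm`, the six VI means, `n_canopy_px`.
#' @export
extract_plot_traits <- function(refl, dsm, dtm, plot_rois,
                                otsu_scope = "global",
                                vi_mode = "all-roi", gsd_cm = NULL) {
  stopifnot(inherits(refl, "grid_raster"))
  chroma <- chromatic_coords(refl)
  vis <- compute_vis(chroma)
  canopy <- vegetation_mask(vis, plot_rois, scope = otsu_scope)
  gsd_cm <- gsd_cm %||% (refl$gsd_m * 100)
  rows <- lapply(plot_rois, function(roi) {
    sur <- plot_surface_area(canopy, roi, refl, gsd_cm = gsd_cm)
    vim <- plot_vi_means(vis, roi, mode = vi_mode, canopy_mask = canopy)
    data.frame(plot_id = roi$plot_id, entry = roi$entry,
               rep = roi$replicate, n_plants = roi$n_plants,
               sur_cm2 = as.numeric(sur),
               eph_mm = estimate_height(dsm, dtm, roi),
               t(vim), n_canopy_px = attr(sur, "n_canopy_px"))
  })
  do.call(rbind, rows)
}

#' Assemble the per-plot trait table across acquisition sets
#'
#' Stacks image-derived traits from the acquisition sets and joins the
#' optional manual measurements (stem diameter `sd_mm`, node count `nn`)
#' on `(plot_id, set)`. Plots with a stand count of 0 (non-germinated
#' entries) are dropped with a log message; unmatched manual rows are
#' reported.
#'
#' @param image_traits named list of data.frames from
#'   [extract_plot_traits()]; names are the set labels (e.g. `"1"`,
#'   `"2"`).
#' @param manual optional data.frame with columns `plot_id`, `set`,
#'   `sd_mm`, `nn`.
#' @return data.frame with columns `plot_id`, `set`, `entry`, `rep`,
#'   `sur_cm2`, `eph_mm`, `sd_mm`, `nn`, the six VI means,
#'   `n_canopy_px`.
#' @export
build_trait_table <- function(image_traits, manual = NULL) {
  stopifnot(is.list(image_traits), length(image_traits) >= 1L)
  if (is.null(names(image_traits)))
    names(image_traits) <- seq_along(image_traits)
  tab <- do.call(rbind, lapply(names(image_traits), function(s) {
    cbind(set = as.integer(s), image_traits[[s]])
  }))
  if (anyDuplicated(tab[, c("plot_id", "set")]))
    stop("duplicate (plot_id, set) rows in image traits", call. = FALSE)
  dropped <- tab$n_plants == 0
  if (any(dropped)) {
    message("dropping ", sum(dropped), " row(s) from non-germinated plots: ",
            paste(unique(tab$plot_id[dropped]), collapse = ", "))
    tab <- tab[!dropped, ]
  }
  tab$sd_mm <- NA_real_; tab$nn <- NA_real_
  if (!is.null(manual)) {
    stopifnot(all(c("plot_id", "set") %in% names(manual)))
    if (anyDuplicated(manual[, c("plot_id", "set")]))
      stop("duplicate (plot_id, set) rows in manual table", call. = FALSE)
    key <- paste(tab$plot_id, tab$set)
    mkey <- paste(manual$plot_id, manual$set)
    hit <- match(key, mkey)
    if ("sd_mm" %in% names(manual)) tab$sd_mm <- manual$sd_mm[hit]
    if ("nn" %in% names(manual)) tab$nn <- manual$nn[hit]
    orphan <- !(mkey %in% key)
    if (any(orphan))
      message(sum(orphan), " manual row(s) had no matching plot/set: ",
              paste(head(mkey[orphan], 5), collapse = "; "))
  }
  cols <- c("plot_id", "set", "entry", "rep", "sur_cm2", "eph_mm",
            "sd_mm", "nn", vi_names(), "n_canopy_px")
  rownames(tab) <- NULL
  tab[, cols]
}

#' Write / read a trait table as CSV
#'
#' Plain CSV round trip used by the pipeline; [read_trait_table()] is the
#' exact inverse of [write_trait_table()].
#'
#' @param tab trait table data.frame.
#' @param path CSV path.
#' @return the path / the table.
#' @export
write_trait_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
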