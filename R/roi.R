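#' Plot and calibration-panel regions of interest
#'
#' A plot ROI carries the polygon delimiting one trial plot plus its
#' metadata: entry (genotype) label, replicate number and the stand count
#' used to divide plot canopy area into per-plant area. A stand count of 0
#' marks a non-germinated plot; it keeps its ROI but is excluded from
#' trait tables. A panel ROI carries the polygon of one ground calibration
#' panel and its standard reflectance fraction.
#'
#' @param polygon two-column matrix of world (x, y) vertices in meters;
#'   the ring may be open (it is closed implicitly) and must be simple.
#' @param plot_id unique plot identifier.
#' @param entry genotype / accession label.
#' @param replicate replicate number (1-based).
#' @param n_plants number of established plants in the plot (>= 0).
#' @return an object of class `plot_roi`.
#' @export
plot_roi <- function(polygon, plot_id, entry, replicate, n_plants) {
  polygon <- check_polygon(polygon, label = plot_id)
  if (!is.numeric(n_plants) || n_plants < 0 || n_plants != round(n_plants))
    stop("`n_plants` must be a non-negative integer", call. = FALSE)
  structure(list(polygon = polygon, plot_id = as.character(plot_id),
                 entry = as.character(entry),
                 replicate = as.integer(replicate),
                 n_plants = as.integer(n_plants)),
            class = c("plot_roi", "roi"))
}

#' @rdname plot_roi
#' @param panel_id panel identifier.
#' @param reflectance standard reflectance fraction in (0, 1].
#' @export
panel_roi <- function(polygon, panel_id, reflectance) {
  polygon <- check_polygon(polygon, label = panel_id)
  if (!is.numeric(reflectance) || reflectance <= 0 || reflectance > 1)
    stop("panel `reflectance` must lie in (0, 1]", call. = FALSE)
  structure(list(polygon = polygon, panel_id = as.character(panel_id),
                 reflectance = reflectance),
            class = c("panel_roi", "roi"))
}

# Validate a polygon ring: >= 3 distinct vertices, closed, simple (no
# proper self-intersection between non-adjacent edges).
check_polygon <- function(polygon, label = "polygon") {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || !is.numeric(polygon))
    stop("polygon must be a numeric two-column matrix (", label, ")",
         call. = FALSE)
  # drop explicit closure for the vertex count, re-close canonically
  n <- nrow(polygon)
  if (n >= 2L && all(polygon[1, ] == polygon[n, ]))
    polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3L)
    stop("polygon must have at least 3 vertices (", label, ")",
         call. = FALSE)
  if (polygon_self_intersects(polygon))
    stop("self-intersecting polygon for feature '", label, "'",
         call. = FALSE)
  rbind(polygon, polygon[1, ])
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_cross(v[i, ], v[idx(i + 1L), ],
                         v[j, ], v[idx(j + 1L), ])) return(TRUE)
    }
  }
  FALSE
}

roi_feature <- function(roi) {
  coords <- lapply(seq_len(nrow(roi$polygon)),
                   function(i) as.numeric(roi$polygon[i, ]))
  props <- if (inherits(roi, "plot_roi")) {
    list(kind = "plot", plot_id = roi$plot_id, entry = roi$entry,
         replicate = roi$replicate, n_plants = roi$n_plants)
  } else {
    list(kind = "panel", panel_id = roi$panel_id,
         panel_reflectance = roi$reflectance)
  }
  list(type = "Feature",
       geometry = list(type = "Polygon", coordinates = list(coords)),
       properties = props)
}

#' Write ROIs to a GeoJSON FeatureCollection
#'
#' @param rois list of `plot_roi` / `panel_roi` objects.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(all(vapply(rois, inherits, TRUE, "roi")))
  fc <- list(type = "FeatureCollection",
             features = lapply(rois, roi_feature))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ROIs from a GeoJSON FeatureCollection
#'
#' Features with `properties.kind == "plot"` must carry `plot_id`, `entry`,
#' `replicate` and `n_plants`; `kind == "panel"` features must carry
#' `panel_id` and `panel_reflectance`. Polygons are validated (simple,
#' >= 3 vertices) with the offending feature named on failure.
#'
#' @param path path to a GeoJSON file.
#' @return list of `plot_roi` / `panel_roi` objects.
#' @export
read_rois <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection") || is.null(fc$features))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  if (!length(fc$features))
    stop("empty FeatureCollection: ", path, call. = FALSE)
  lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("unsupported geometry type '", f$geometry$type, "'",
           call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) unlist(p)[1:2]))
    p <- f$properties
    kind <- p$kind %||% "plot"
    if (kind == "panel") {
      need <- setdiff(c("panel_id", "panel_reflectance"), names(p))
      if (length(need))
        stop("panel feature missing propert", if (length(need) > 1) "ies "
             else "y ", paste(need, collapse = ", "), call. = FALSE)
      panel_roi(poly, p$panel_id, p$panel_reflectance)
    } else {
      need <- setdiff(c("plot_id", "entry", "replicate", "n_plants"),
                      names(p))
      if (length(need))
        stop("plot feature missing propert", if (length(need) > 1) "ies "
             else "y ", paste(need, collapse = ", "), call. = FALSE)
      plot_roi(poly, p$plot_id, p$entry, p$replicate, p$n_plants)
    }
  })
}

#' Split ROIs by kind
#' @param rois list of ROI objects.
#' @return list with elements `plots` and `panels`.
#' @export
split_rois <- function(rois) {
  list(plots = Filter(function(r) inherits(r, "plot_roi"), rois),
       panels = Filter(function(r) inherits(r, "panel_roi"), rois))
}
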