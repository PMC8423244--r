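#' Camera model for nominal ground sampling distance
#'
#' Geometry of the nadir-looking RGB camera: angular fields of view, sensor
#' pixel counts and flight altitude.
#'
#' @param horizontal_fov,vertical_fov angular field of view in degrees,
#'   in (0, 180).
#' @param image_width,image_height sensor size in pixels.
#' @param altitude_m flight altitude above ground, meters.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(horizontal_fov = 72.3, vertical_fov = 57.5,
                         image_width = 4000, image_height = 3000,
                         altitude_m = 40) {
  vals <- c(horizontal_fov, vertical_fov, image_width, image_height,
            altitude_m)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all camera parameters must be positive", call. = FALSE)
  if (horizontal_fov >= 180 || vertical_fov >= 180)
    stop("field of view must be below 180 degrees", call. = FALSE)
  structure(list(horizontal_fov = horizontal_fov,
                 vertical_fov = vertical_fov,
                 image_width = image_width, image_height = image_height,
                 altitude_m = altitude_m),
            class = "camera_model")
}

#' Nominal ground sampling distance of a nadir camera
#'
#' The ground footprint width is `2 * altitude * tan(hfov / 2)`; dividing
#' by the sensor width in pixels gives the per-pixel ground distance,
#' returned in cm/pixel. Strictly increasing in altitude and field of
#' view, strictly decreasing in image width.
#'
#' @param camera a `camera_model`.
#' @return ground sampling distance in cm per pixel.
#' @export
nominal_gsd <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  if (camera$altitude_m <= 0 || camera$image_width <= 0)
    stop("altitude and image width must be positive", call. = FALSE)
  100 * 2 * camera$altitude_m *
    tan(camera$horizontal_fov / 2 * pi / 180) / camera$image_width
}

#' Field trial layout for the synthetic generator
#'
#' Describes the randomized block design the generator renders: entries x
#' replicates rectangular plots on a grid, each plot holding a regular
#' grid of plants at fixed spacing on dark plastic mulch, with a row of
#' four calibration panels at the top of the field. Entries listed in
#' `dropout_entries` emulate accessions that never germinated: their
#' plots keep their ROIs but have a stand count of 0.
#'
#' @param n_entries number of entries (genotypes).
#' @param n_replicates replicates per entry.
#' @param plants_per_plot seeds per plot (>= 1).
#' @param plant_spacing_cm within-plot plant spacing, cm.
#' @param plant_grid c(cols, rows) of the within-plot planting grid;
#'   must hold `plants_per_plot`.
#' @param plot_margin_cm margin between outer plant centers and the plot
#'   ROI edge, cm.
#' @param alley_cm alley between neighbouring plots, cm.
#' @param plot_cols plots per field row.
#' @param field_margin_m margin around the whole field, m.
#' @param entries entry labels (defaults to E01..).
#' @param dropout_entries entries with zero germination.
#' @param mulch_reflectance background reflectance (all bands).
#' @param panel_reflectances standard reflectances of the calibration
#'   panels.
#' @param panel_size_m calibration panel side length, m.
#' @return object of class `field_layout`.
#' @export
field_layout <- function(n_entries = 24, n_replicates = 3,
                         plants_per_plot = 15, plant_spacing_cm = 25,
                         plant_grid = c(5, 3), plot_margin_cm = 25,
                         alley_cm = 30, plot_cols = 12,
                         field_margin_m = 0.5,
                         entries = sprintf("E%02d", seq_len(n_entries)),
                         dropout_entries = "E02",
                         mulch_reflectance = 0.04,
                         panel_reflectances = c(0.03, 0.12, 0.36, 0.56),
                         panel_size_m = 1.2) {
  if (plants_per_plot < 1) stop("plants_per_plot must be >= 1", call. = FALSE)
  if (prod(plant_grid) < plants_per_plot)
    stop("plant_grid cannot hold plants_per_plot plants", call. = FALSE)
  if (length(entries) != n_entries)
    stop("need exactly n_entries entry labels", call. = FALSE)
  if (!all(dropout_entries %in% entries))
    stop("dropout_entries must be a subset of entries", call. = FALSE)
  n_plots <- n_entries * n_replicates
  structure(list(n_entries = n_entries, n_replicates = n_replicates,
                 n_plots = n_plots, plants_per_plot = plants_per_plot,
                 plant_spacing_cm = plant_spacing_cm,
                 plant_grid = plant_grid, plot_margin_cm = plot_margin_cm,
                 alley_cm = alley_cm, plot_cols = plot_cols,
                 plot_rows = ceiling(n_plots / plot_cols),
                 field_margin_m = field_margin_m, entries = entries,
                 dropout_entries = dropout_entries,
                 mulch_reflectance = mulch_reflectance,
                 panel_reflectances = panel_reflectances,
                 panel_size_m = panel_size_m),
            class = "field_layout")
}

# Plot footprint and field extents, all in meters.
layout_geometry <- function(layout) {
  ext_x <- (layout$plant_grid[1] - 1) * layout$plant_spacing_cm / 100
  ext_y <- (layout$plant_grid[2] - 1) * layout$plant_spacing_cm / 100
  plot_w <- ext_x + 2 * layout$plot_margin_cm / 100
  plot_h <- ext_y + 2 * layout$plot_margin_cm / 100
  pitch_x <- plot_w + layout$alley_cm / 100
  pitch_y <- plot_h + layout$alley_cm / 100
  panel_strip <- layout$panel_size_m + 0.4
  width <- 2 * layout$field_margin_m + layout$plot_cols * pitch_x
  height <- 2 * layout$field_margin_m + panel_strip +
    layout$plot_rows * pitch_y
  list(plot_w = plot_w, plot_h = plot_h, pitch_x = pitch_x,
       pitch_y = pitch_y, panel_strip = panel_strip, width = width,
       height = height)
}

#' Default growth parameters of the synthetic trial
#'
#' Per acquisition set, each plot-level trait (plant height mm, canopy
#' radius cm, stem diameter mm, node count, canopy green chromatic
#' fraction) is `mu + load * u + sd * e`, where `u` is a latent growth
#' factor shared by all traits of a plot (entry effect plus replicate
#' noise) and `e` is independent standard normal noise. Set 1 (early
#' stage) uses near-zero loadings so traits are nearly uncorrelated; set
#' 2 (late stage) uses loading-to-noise ratios around 1.4, giving
#' population correlations of roughly 0.55-0.75 among traits, with the
#' green fraction loading positively so green-emphasizing indices rise
#' with growth.
#'
#' @return nested list of `c(mu, load, sd)` per trait per set, plus
#'   `rep_noise`, the replicate-level standard deviation of the latent
#'   factor.
#' @export
default_growth_params <- function() {
  list(
    set1 = list(height = c(mu = 800, load = 30, sd = 100),
                radius = c(mu = 9, load = 0.3, sd = 1.0),
                stem = c(mu = 8, load = 0.3, sd = 1.0),
                nodes = c(mu = 8, load = 0.3, sd = 1.6),
                g = c(mu = 0.42, load = 0.004, sd = 0.012)),
    set2 = list(height = c(mu = 2500, load = 300, sd = 220),
                radius = c(mu = 16, load = 2.2, sd = 1.6),
                stem = c(mu = 18, load = 2.8, sd = 2.0),
                nodes = c(mu = 25, load = 3.5, sd = 2.5),
                g = c(mu = 0.48, load = 0.020, sd = 0.012)),
    rep_noise = 0.3
  )
}

#' Generate ground-truth plot traits for both acquisition sets
#'
#' Draws one latent growth factor per entry (plus replicate noise),
#' assigns entries to plots at random, and generates all plot-level
#' traits from the latent-factor model of [default_growth_params()].
#' Canopy area is filled in later by [generate_scene()] from the
#' rendered mask. Identical `(layout, growth, seed)` give identical
#' tables.
#'
#' @param layout a `field_layout`.
#' @param growth growth parameters (see [default_growth_params()]).
#' @param seed integer seed.
#' @return data.frame: `plot_id`, `set`, `entry`, `rep`, `n_plants`,
#'   `height_mm`, `area_cm2` (NA until rendered), `sd_mm`, `nn`,
#'   `g_frac`, `radius_cm`.
#' @export
generate_truth_traits <- function(layout, growth = default_growth_params(),
                                  seed = 1) {
  stopifnot(inherits(layout, "field_layout"))
  sds <- unlist(lapply(growth[c("set1", "set2")],
                       function(s) vapply(s, function(p) p[["sd"]], 0)))
  if (any(sds < 0) || growth$rep_noise < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  with_seed(seed, {
    n <- layout$n_plots
    plot_id <- sprintf("P%02d", seq_len(n))
    assign <- sample(rep(layout$entries, layout$n_replicates))
    rep_no <- stats::ave(seq_len(n), assign, FUN = seq_along)
    u_entry <- setNames(rnorm(layout$n_entries), layout$entries)
    u_plot <- u_entry[assign] + growth$rep_noise * rnorm(n)
    n_plants <- ifelse(assign %in% layout$dropout_entries, 0L,
                       layout$plants_per_plot)
    draw <- function(p, u) p[["mu"]] + p[["load"]] * u +
      p[["sd"]] * rnorm(length(u))
    out <- lapply(c(1, 2), function(set) {
      gp <- growth[[paste0("set", set)]]
      data.frame(plot_id = plot_id, set = set, entry = assign,
                 rep = rep_no, n_plants = n_plants,
                 height_mm = pmax(draw(gp$height, u_plot), 50),
                 area_cm2 = NA_real_,
                 sd_mm = pmax(draw(gp$stem, u_plot), 0.5),
                 nn = pmax(round(draw(gp$nodes, u_plot)), 0),
                 g_frac = pmin(pmax(draw(gp$g, u_plot), 0.36), 0.62),
                 radius_cm = pmin(pmax(draw(gp$radius, u_plot), 3), 22))
    })
    out <- do.call(rbind, out)
    blank <- out$n_plants == 0
    out[blank, c("height_mm", "sd_mm", "nn", "g_frac", "radius_cm")] <- NA
    rownames(out) <- NULL
    out
  })
}

#' Default empirical-line truth coefficients per acquisition set
#'
#' Per-band exponential DN-to-reflectance coefficients used by the
#' generator to invert reflectance into digital numbers, one model per
#' acquisition (the calibration is refitted per flight).
#'
#' @param set acquisition set, 1 (early) or 2 (late).
#' @return an `elm_model`.
#' @export
default_elm_truth <- function(set = 1) {
  if (set == 1)
    elm_model(A = c(R = 0.0095, G = 0.0066, B = 0.0043),
              B = c(R = 0.0165, G = 0.0178, B = 0.0192))
  else
    elm_model(A = c(R = 0.0042, G = 0.0043, B = 0.0037),
              B = c(R = 0.0211, G = 0.0210, B = 0.0217))
}

#' Render one synthetic acquisition of the trial field
#'
#' Renders plants as soft-edged overlapping disks of green-dominated
#' reflectance on dark mulch, four calibration panels at their standard
#' reflectances, a smooth low-amplitude terrain, and a DSM equal to the
#' terrain plus a per-plant dome whose apex equals the plot's true
#' height. Reflectance is inverted to digital numbers through the
#' per-band exponential empirical line model, optionally perturbed by
#' Gaussian DN noise and quantized to the configured bit depth. The
#' truth table's `area_cm2` is filled from the rendered hard-disk mask
#' clipped to the plot ROI.
#'
#' @param layout a `field_layout`.
#' @param camera a `camera_model` (sets the ground sampling distance).
#' @param elm_truth an `elm_model` used to invert reflectance to DN.
#' @param truth truth table from [generate_truth_traits()].
#' @param set acquisition set to render (1 or 2).
#' @param noise list with `dn_sd` (DN units) and `dsm_sd_m` (meters).
#' @param bit_depth DN bit depth, 8 (default) or 16.
#' @param quantize_dn round DN to integers (disable for exact
#'   radiometric validation scenes).
#' @param dtm_amplitude_m total relief of the terrain gradient, m.
#' @param canopy_total_reflectance summed R+G+B reflectance of canopy
#'   interior pixels.
#' @param soft_edge_cm width of the soft canopy edge, cm.
#' @param seed integer seed.
#' @return object of class `synthetic_scene`: `dn`, `dsm`, `dtm`
#'   (`grid_raster`s), `panel_rois`, `plot_rois`, `truth` (this set's
#'   rows, `area_cm2` filled), `gsd_cm`, `set`, `elm_truth`,
#'   `bit_depth`, `seed`.
#' @export
generate_scene <- function(layout, camera = camera_model(),
                           elm_truth = default_elm_truth(set), truth,
                           set = 1,
                           noise = list(dn_sd = 1, dsm_sd_m = 0.005),
                           bit_depth = 8, quantize_dn = TRUE,
                           dtm_amplitude_m = 0.3,
                           canopy_total_reflectance = 0.30,
                           soft_edge_cm = 2, seed = 1) {
  stopifnot(inherits(layout, "field_layout"),
            inherits(camera, "camera_model"),
            inherits(elm_truth, "elm_model"))
  if (!bit_depth %in% c(8, 16))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  truth_set <- truth[truth$set == set, ]
  if (nrow(truth_set) != layout$n_plots)
    stop("truth table does not match layout for set ", set, call. = FALSE)
  gsd_cm <- nominal_gsd(camera)
  gsd <- gsd_cm / 100
  geo <- layout_geometry(layout)
  nc <- ceiling(geo$width / gsd)
  nr <- ceiling(geo$height / gsd)
  with_seed(seed, {
    xs <- (seq_len(nc) - 0.5) * gsd
    ys <- (seq_len(nr) - 0.5) * gsd
    # terrain: smooth planar gradient plus a gentle swell
    dtm_m <- outer(ys, xs, function(y, x) {
      dtm_amplitude_m * (0.6 * x / geo$width + 0.3 * y / geo$height +
                           0.1 * sin(2 * pi * x / geo$width) *
                           sin(pi * y / geo$height))
    })
    mul <- layout$mulch_reflectance
    R <- matrix(mul, nr, nc); G <- matrix(mul, nr, nc)
    B <- matrix(mul, nr, nc)
    chm_m <- matrix(0, nr, nc)
    base <- grid_raster(array(0, c(nr, nc, 1)), origin = c(0, 0),
                        gsd_m = gsd)
    # calibration panels along the top strip
    panel_rois <- vector("list", length(layout$panel_reflectances))
    for (i in seq_along(layout$panel_reflectances)) {
      px0 <- layout$field_margin_m + (i - 1) * (layout$panel_size_m + 0.4)
      py0 <- layout$field_margin_m
      cset <- which(xs >= px0 & xs <= px0 + layout$panel_size_m)
      rset <- which(ys >= py0 & ys <= py0 + layout$panel_size_m)
      refl <- layout$panel_reflectances[i]
      R[rset, cset] <- refl; G[rset, cset] <- refl; B[rset, cset] <- refl
      ins <- 0.15
      panel_rois[[i]] <- panel_roi(
        rbind(c(px0 + ins, py0 + ins),
              c(px0 + layout$panel_size_m - ins, py0 + ins),
              c(px0 + layout$panel_size_m - ins,
                py0 + layout$panel_size_m - ins),
              c(px0 + ins, py0 + layout$panel_size_m - ins)),
        panel_id = sprintf("panel_%02d", i), reflectance = refl)
    }
    # plots
    y0p <- layout$field_margin_m + geo$panel_strip
    plot_rois <- vector("list", layout$n_plots)
    edge <- soft_edge_cm / 100
    for (k in seq_len(layout$n_plots)) {
      tr <- truth_set[k, ]
      fi <- (k - 1) %/% layout$plot_cols   # field row
      fj <- (k - 1) %% layout$plot_cols    # field col
      x0 <- layout$field_margin_m + fj * geo$pitch_x
      y0 <- y0p + fi * geo$pitch_y
      poly <- rbind(c(x0, y0), c(x0 + geo$plot_w, y0),
                    c(x0 + geo$plot_w, y0 + geo$plot_h),
                    c(x0, y0 + geo$plot_h))
      plot_rois[[k]] <- plot_roi(poly, tr$plot_id, tr$entry, tr$rep,
                                 tr$n_plants)
      if (tr$n_plants == 0) next
      # plant centers on the within-plot grid, snapped to pixel centers
      sp <- layout$plant_spacing_cm / 100
      gx <- x0 + layout$plot_margin_cm / 100 +
        (seq_len(layout$plant_grid[1]) - 1) * sp
      gy <- y0 + layout$plot_margin_cm / 100 +
        (seq_len(layout$plant_grid[2]) - 1) * sp
      centers <- expand.grid(x = gx, y = gy)[seq_len(tr$n_plants), ]
      apex <- ceiling(tr$n_plants / 2)
      g_p <- tr$g_frac
      ct <- canopy_total_reflectance
      cG <- ct * g_p; cR <- ct * (1 - g_p) * 0.55
      cB <- ct * (1 - g_p) * 0.45
      plot_mask <- matrix(FALSE, nr, nc)
      for (p in seq_len(tr$n_plants)) {
        cx <- (round(centers$x[p] / gsd + 0.5) - 0.5) * gsd
        cy <- (round(centers$y[p] / gsd + 0.5) - 0.5) * gsd
        r_m <- (if (p == apex) tr$radius_cm else
          tr$radius_cm * runif(1, 0.9, 1.1)) / 100
        h_m <- (if (p == apex) tr$height_mm else
          tr$height_mm * runif(1, 0.82, 0.97)) / 1000
        ci <- which(xs >= cx - r_m - edge & xs <= cx + r_m + edge)
        ri <- which(ys >= cy - r_m - edge & ys <= cy + r_m + edge)
        if (!length(ci) || !length(ri)) next
        d <- sqrt(outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, `+`))
        # blend ramp centered on the disk boundary: w = 0.5 at d = r
        w <- pmin(pmax((r_m - d) / edge + 0.5, 0), 1)
        R[ri, ci] <- w * cR + (1 - w) * R[ri, ci]
        G[ri, ci] <- w * cG + (1 - w) * G[ri, ci]
        B[ri, ci] <- w * cB + (1 - w) * B[ri, ci]
        dome <- h_m * sqrt(pmax(1 - (d / r_m)^2, 0))
        chm_m[ri, ci] <- pmax(chm_m[ri, ci], dome)
        plot_mask[ri, ci] <- plot_mask[ri, ci] | (d <= r_m)
      }
      in_roi <- pixels_in_polygon(base, poly)
      truth_set$area_cm2[k] <- sum(plot_mask & in_roi) * gsd_cm^2
    }
    # reflectance -> DN through the inverse ELM
    dn <- array(0, c(nr, nc, 3))
    bands <- list(R = R, G = G, B = B)
    top <- 2^bit_depth - 1
    for (b in c("R", "G", "B")) {
      refl <- bands[[b]]
      if (any(refl <= 0))
        stop("reflectance outside the invertible range of the ELM ",
             "for band ", b, call. = FALSE)
      v <- log(refl / elm_truth$A[[b]]) / elm_truth$B[[b]]
      if (noise$dn_sd > 0) v <- v + rnorm(length(v), sd = noise$dn_sd)
      if (quantize_dn) {
        v <- round(v)
        if (any(v > top))
          warning("DN clipped at the top of the ", bit_depth,
                  "-bit range in band ", b, call. = FALSE)
        v <- pmin(pmax(v, 0), top)
      }
      dn[, , match(b, c("R", "G", "B"))] <- v
    }
    dsm_m <- dtm_m + chm_m
    if (noise$dsm_sd_m > 0)
      dsm_m <- dsm_m + matrix(rnorm(nr * nc, sd = noise$dsm_sd_m), nr, nc)
    structure(list(
      dn = grid_raster(dn, origin = c(0, 0), gsd_m = gsd),
      dsm = grid_raster(dsm_m, origin = c(0, 0), gsd_m = gsd,
                        bands = "DSM"),
      dtm = grid_raster(dtm_m, origin = c(0, 0), gsd_m = gsd,
                        bands = "DTM"),
      panel_rois = panel_rois, plot_rois = plot_rois,
      truth = truth_set, gsd_cm = gsd_cm, set = set,
      elm_truth = elm_truth, bit_depth = bit_depth, seed = seed),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> set %d: %d x %d px at %.3f cm/px, %d plots, %d panels\n",
              x$set, dim(x$dn)[1], dim(x$dn)[2], x$gsd_cm,
              length(x$plot_rois), length(x$panel_rois)))
  invisible(x)
}

#' Simulate the full two-acquisition study
#'
#' Generates the ground-truth trait table and renders both acquisition
#' sets (early and late stage), each with its own per-flight calibration
#' coefficients. Fully deterministic given the seed.
#'
#' @param layout a `field_layout`.
#' @param camera a `camera_model`.
#' @param elm_truth list of two `elm_model`s, one per set.
#' @param growth growth parameters (see [default_growth_params()]).
#' @param noise list with `dn_sd`, `dsm_sd_m`.
#' @param bit_depth DN bit depth.
#' @param quantize_dn round DN to integers.
#' @param seed integer seed; sub-seeds are derived per stage.
#' @return list with `scenes` (named list `"1"`, `"2"`), `truth` (both
#'   sets, areas filled), `layout`, `camera`.
#' @export
simulate_study <- function(layout = field_layout(),
                           camera = camera_model(),
                           elm_truth = list(default_elm_truth(1),
                                            default_elm_truth(2)),
                           growth = default_growth_params(),
                           noise = list(dn_sd = 1, dsm_sd_m = 0.005),
                           bit_depth = 8, quantize_dn = TRUE, seed = 1) {
  truth <- generate_truth_traits(layout, growth, seed = seed)
  scenes <- lapply(c(1, 2), function(s)
    generate_scene(layout, camera, elm_truth[[s]], truth, set = s,
                   noise = noise, bit_depth = bit_depth,
                   quantize_dn = quantize_dn, seed = seed + s))
  names(scenes) <- c("1", "2")
  truth <- do.call(rbind, lapply(scenes, function(sc) sc$truth))
  rownames(truth) <- NULL
  list(scenes = scenes, truth = truth, layout = layout, camera = camera)
}

#' Write a synthetic scene to disk
#'
#' Orthoimage (integer DN), DSM and DTM (float32) as TIFF with
#' georeferencing sidecars, and plot plus panel ROIs as one GeoJSON
#' FeatureCollection.
#'
#' @param scene a `synthetic_scene`.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_scene <- function(scene, outdir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- scene$set
  dtype <- if (scene$bit_depth == 8) "uint8" else "uint16"
  paths <- c(
    ortho = file.path(outdir, sprintf("ortho_set%d.tif", s)),
    dsm = file.path(outdir, sprintf("dsm_set%d.tif", s)),
    dtm = file.path(outdir, sprintf("dtm_set%d.tif", s)),
    rois = file.path(outdir, sprintf("rois_set%d.geojson", s)))
  if (all(scene$dn$values == round(scene$dn$values)))
    write_raster(scene$dn, paths["ortho"], dtype = dtype)
  else write_raster(scene$dn, paths["ortho"], dtype = "float32")
  write_raster(scene$dsm, paths["dsm"], dtype = "float32")
  write_raster(scene$dtm, paths["dtm"], dtype = "float32")
  write_rois(c(scene$plot_rois, scene$panel_rois), paths["rois"])
  invisible(paths)
}

#' Write / derive tables from the ground truth
#'
#' `write_truth()` stores the truth table as CSV with the canonical
#' header `plot_id,set,entry,rep,height_mm,area_cm2,sd_mm,nn,g_frac`.
#' `truth_manual_table()` extracts the columns that play the role of the
#' manual measurements (stem diameter and node count) for joining into
#' trait tables.
#'
#' @param truth truth data.frame from [simulate_study()].
#' @param path output CSV path.
#' @return the path / a data.frame.
#' @export
write_truth <- function(truth, path) {
  cols <- c("plot_id", "set", "entry", "rep", "height_mm", "area_cm2",
            "sd_mm", "nn", "g_frac")
  write.csv(truth[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
truth_manual_table <- function(truth) {
  out <- truth[truth$n_plants > 0, c("plot_id", "set", "sd_mm", "nn")]
  rownames(out) <- NULL
  out
}
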