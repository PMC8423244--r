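#' Exponential empirical-line model
#'
#' The empirical line method maps raw digital numbers (DN) to surface
#' reflectance using ground panels of known reflectance. The model here is
#' exponential, `r_k = A_k * exp(B_k * DN)` per band k, fitted flight by
#' flight. `elm_model()` builds a model directly from coefficients (e.g. a
#' published table, or the generator's truth); [fit_elm()] estimates one
#' from panel samples.
#'
#' @param A named numeric vector of per-band scale coefficients (> 0);
#'   names must be `R`, `G`, `B`. `A` is the reflectance at DN = 0.
#' @param B named numeric vector of per-band rate coefficients (per DN).
#' @param r2 optional per-band goodness of fit in `[0, 1]`.
#' @param n_samples optional per-band sample count.
#' @return an object of class `elm_model`.
#' @export
elm_model <- function(A, B, r2 = rep(NA_real_, 3), n_samples = rep(NA_integer_, 3)) {
  bands <- c("R", "G", "B")
  A <- unlist(A); B <- unlist(B)
  if (is.null(names(A))) names(A) <- bands
  if (is.null(names(B))) names(B) <- bands
  if (!setequal(names(A), bands) || !setequal(names(B), bands))
    stop("ELM model needs exactly the three bands R, G, B", call. = FALSE)
  if (any(A[bands] <= 0)) stop("coefficients A must be > 0", call. = FALSE)
  if (!all(is.na(r2)) && any(r2 < -1e-12 | r2 > 1 + 1e-12, na.rm = TRUE))
    stop("r2 must lie in [0, 1]", call. = FALSE)
  structure(list(A = A[bands], B = B[bands],
                 r2 = setNames(as.numeric(r2), bands),
                 n_samples = setNames(as.integer(n_samples), bands)),
            class = "elm_model")
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model> r = A * exp(B * DN)\n")
  print(data.frame(band = names(x$A), A = x$A, B = x$B, r2 = x$r2,
                   n = x$n_samples, row.names = NULL))
  invisible(x)
}

#' Invert the ELM: digital number at a given reflectance
#'
#' @param model an `elm_model`.
#' @param reflectance reflectance fraction(s), must be > 0.
#' @param band one of `"R"`, `"G"`, `"B"`.
#' @return DN value(s) (real-valued, not quantized).
#' @export
invert_elm <- function(model, reflectance, band) {
  stopifnot(inherits(model, "elm_model"))
  band <- match.arg(band, c("R", "G", "B"))
  if (any(reflectance <= 0))
    stop("reflectance outside the invertible range of the ELM for band ",
         band, call. = FALSE)
  log(reflectance / model$A[[band]]) / model$B[[band]]
}

#' Extract calibration samples from panel regions
#'
#' For each panel ROI and each band, averages the DN of pixels whose
#' centers fall inside the panel polygon and pairs the mean with the
#' panel's standard reflectance. Pixels at the extremes of the sensor
#' range (0 or `dn_max`) violate the exponential model and are excluded
#' (with a message) when `exclude_extremes` is on.
#'
#' @param dn_raster 3-band `grid_raster` of digital numbers.
#' @param panel_rois list of `panel_roi` objects.
#' @param dn_max top of the sensor range (e.g. 255); `NULL` disables the
#'   saturation screen.
#' @param exclude_extremes drop saturated / zero pixels from panel means.
#' @return data.frame with columns `panel_id`, `band`, `dn`, `reflectance`.
#' @export
extract_panel_samples <- function(dn_raster, panel_rois, dn_max = NULL,
                                  exclude_extremes = TRUE) {
  stopifnot(inherits(dn_raster, "grid_raster"))
  if (dim(dn_raster)[3] != 3L)
    stop("DN raster must have 3 bands", call. = FALSE)
  if (!length(panel_rois)) stop("no panel ROIs supplied", call. = FALSE)
  out <- list()
  for (p in panel_rois) {
    mask <- pixels_in_polygon(dn_raster, p$polygon)
    if (!any(mask))
      stop("panel ROI '", p$panel_id, "' covers no pixel centers",
           call. = FALSE)
    for (b in c("R", "G", "B")) {
      v <- raster_band(dn_raster, b)[mask]
      if (exclude_extremes && !is.null(dn_max)) {
        bad <- v <= 0 | v >= dn_max
        if (any(bad)) {
          message(sum(bad), " extreme-DN pixel(s) excluded from panel '",
                  p$panel_id, "' band ", b)
          v <- v[!bad]
        }
        if (!length(v))
          stop("panel '", p$panel_id, "' band ", b,
               " has only extreme DN values", call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        panel_id = p$panel_id, band = b, dn = mean(v),
        reflectance = p$reflectance)
    }
  }
  do.call(rbind, out)
}

#' Fit the exponential empirical-line model
#'
#' Per band, ordinary least squares on the log scale:
#' `ln(r) = ln(A) + B * DN`, which is closed-form, deterministic, and
#' recovers `(A, B)` exactly when samples lie on the model. `r2` is the
#' coefficient of determination of that log-linear regression.
#'
#' @param samples data.frame with columns `band`, `dn`, `reflectance`
#'   (as from [extract_panel_samples()]).
#' @return an `elm_model`.
#' @export
fit_elm <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("band", "dn", "reflectance") %in% names(samples)))
  bands <- c("R", "G", "B")
  A <- B <- r2 <- setNames(numeric(3), bands)
  n <- setNames(integer(3), bands)
  for (b in bands) {
    s <- samples[samples$band == b, ]
    if (length(unique(s$dn)) < 2L)
      stop("underdetermined fit: band ", b,
           " has fewer than 2 distinct DN values", call. = FALSE)
    if (any(s$reflectance <= 0))
      stop("non-positive reflectance in band ", b,
           " cannot be log-transformed", call. = FALSE)
    fit <- lm(log(reflectance) ~ dn, data = s)
    A[b] <- exp(coef(fit)[1]); B[b] <- coef(fit)[2]
    sst <- sum((log(s$reflectance) - mean(log(s$reflectance)))^2)
    r2[b] <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
    n[b] <- nrow(s)
  }
  elm_model(A, B, r2 = r2, n_samples = n)
}

#' Apply a fitted ELM to a DN raster
#'
#' Elementwise `r = A_k * exp(B_k * DN)` per band, clipped to `[0, 1]`.
#' The number of clipped pixels is attached as attribute `n_clipped` and
#' reported with a message when non-zero.
#'
#' @param model an `elm_model` with all three bands fitted.
#' @param dn_raster 3-band `grid_raster` of digital numbers.
#' @return 3-band reflectance `grid_raster` (fractions).
#' @export
apply_elm <- function(model, dn_raster) {
  stopifnot(inherits(model, "elm_model"), inherits(dn_raster, "grid_raster"))
  if (dim(dn_raster)[3] != 3L || !setequal(dn_raster$bands, c("R", "G", "B")))
    stop("DN raster bands do not match the 3-band ELM model", call. = FALSE)
  if (any(!is.finite(model$A)) || any(!is.finite(model$B)))
    stop("ELM model is not fitted for all three bands", call. = FALSE)
  out <- dn_raster
  clipped <- 0L
  for (b in c("R", "G", "B")) {
    i <- match(b, dn_raster$bands)
    r <- model$A[[b]] * exp(model$B[[b]] * dn_raster$values[, , i])
    clipped <- clipped + sum(r < 0 | r > 1)
    out$values[, , i] <- pmin(pmax(r, 0), 1)
  }
  out$bands <- dn_raster$bands
  if (clipped > 0)
    message(clipped, " reflectance value(s) clipped to [0, 1]")
  attr(out, "n_clipped") <- clipped
  out
}
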