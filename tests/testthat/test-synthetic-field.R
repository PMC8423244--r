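test_that("nominal GSD follows the pinhole footprint formula", {
  cam <- camera_model()   # 72.3 deg HFOV, 4000 px, 40 m
  gsd <- nominal_gsd(cam)
  expect_equal(gsd, 100 * 2 * 40 * tan(72.3 / 2 * pi / 180) / 4000)
  expect_equal(trunc(gsd * 10) / 10, 1.4)
  # linear in altitude
  expect_equal(nominal_gsd(camera_model(altitude_m = 20)), gsd / 2)
  # tan(45 deg) = 1 with a 2-px sensor at 1 m -> 1 m/px
  expect_equal(nominal_gsd(camera_model(horizontal_fov = 90,
                                        image_width = 2, altitude_m = 1)),
               100)
})

test_that("camera invariants are enforced", {
  expect_error(camera_model(altitude_m = 0), "positive")
  expect_error(camera_model(image_width = -1), "positive")
  expect_error(camera_model(horizontal_fov = 181), "180")
})

test_that("GSD is monotone in altitude and fov, antitone in image width", {
  g <- function(...) nominal_gsd(camera_model(...))
  alts <- c(10, 20, 40, 80)
  expect_true(all(diff(vapply(alts, function(a) g(altitude_m = a), 0)) > 0))
  fovs <- c(30, 60, 90, 120)
  expect_true(all(diff(vapply(fovs, function(f) g(horizontal_fov = f), 0)) > 0))
  ws <- c(1000, 2000, 4000)
  expect_true(all(diff(vapply(ws, function(w) g(image_width = w), 0)) < 0))
})

test_that("identical seeds reproduce scenes and truth bit for bit", {
  a <- tiny_study(seed = 7)
  b <- tiny_study(seed = 7)
  expect_identical(a$truth, b$truth)
  expect_identical(a$scenes[["1"]]$dn$values, b$scenes[["1"]]$dn$values)
  expect_identical(a$scenes[["2"]]$dsm$values, b$scenes[["2"]]$dsm$values)
  c <- tiny_study(seed = 8)
  expect_false(identical(a$scenes[["1"]]$dn$values,
                         c$scenes[["1"]]$dn$values))
})

test_that("layout controls the number of plot ROIs and stand counts", {
  study <- tiny_study(seed = 5)
  sc <- study$scenes[["1"]]
  expect_length(sc$plot_rois, 4 * 3)
  stand <- vapply(sc$plot_rois, function(r) r$n_plants, 0L)
  entry <- vapply(sc$plot_rois, function(r) r$entry, "")
  expect_true(all(stand[entry == "E02"] == 0))
  expect_true(all(stand[entry != "E02"] == 6))
})

test_that("rendered canopy area matches the disk-area oracle", {
  # 1 cm/px camera; a single plant of fixed 20 cm radius
  cam <- camera_model(horizontal_fov = 90, image_width = 8000,
                      altitude_m = 40)
  expect_equal(nominal_gsd(cam), 1)
  layout <- field_layout(n_entries = 1, n_replicates = 1,
                         plants_per_plot = 1, plant_grid = c(1, 1),
                         plot_margin_cm = 30, plot_cols = 1,
                         dropout_entries = character(0))
  growth <- default_growth_params()
  growth$set1$radius <- c(mu = 20, load = 0, sd = 0)
  truth <- generate_truth_traits(layout, growth, seed = 2)
  sc <- generate_scene(layout, cam, truth = truth, set = 1,
                       noise = list(dn_sd = 0, dsm_sd_m = 0), seed = 3)
  expect_lt(abs(sc$truth$area_cm2[1] - pi * 20^2) / (pi * 20^2), 0.05)
})

test_that("panels render at their exact inverted DN when noise is off", {
  layout <- tiny_layout()
  truth <- generate_truth_traits(layout, seed = 4)
  sc <- generate_scene(layout, tiny_camera(), truth = truth, set = 1,
                       noise = list(dn_sd = 0, dsm_sd_m = 0), seed = 5)
  samples <- extract_panel_samples(sc$dn, sc$panel_rois,
                                   exclude_extremes = FALSE)
  for (b in c("R", "G", "B")) {
    got <- samples$dn[samples$band == b]
    want <- round(invert_elm(sc$elm_truth, c(0.03, 0.12, 0.36, 0.56), b))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the canopy height model is 0 off-canopy and exact at the apex", {
  layout <- tiny_layout()
  truth <- generate_truth_traits(layout, seed = 6)
  sc <- generate_scene(layout, tiny_camera(), truth = truth, set = 2,
                       noise = list(dn_sd = 0, dsm_sd_m = 0), seed = 7)
  chm <- sc$dsm$values[, , 1] - sc$dtm$values[, , 1]
  expect_true(all(chm >= 0))
  for (k in seq_along(sc$plot_rois)) {
    roi <- sc$plot_rois[[k]]
    if (roi$n_plants == 0) next
    h <- max(chm[pixels_in_polygon(sc$dsm, roi$polygon)]) * 1000
    expect_equal(h, sc$truth$height_mm[k], tolerance = 1e-9)
  }
  # outside all plot ROIs and panels the surface equals the terrain
  outside <- !Reduce(`|`, lapply(sc$plot_rois, function(r)
    pixels_in_polygon(sc$dsm, r$polygon)))
  expect_lt(max(chm[outside]), 1e-12)
})

test_that("latent-factor loadings control trait correlations", {
  layout <- field_layout(n_entries = 20, n_replicates = 3,
                         plot_cols = 10, dropout_entries = character(0))
  # zero loadings: traits are independent -> rho within chance bounds
  g0 <- default_growth_params()
  for (tr in names(g0$set2)) g0$set2[[tr]]["load"] <- 0
  t0 <- generate_truth_traits(layout, g0, seed = 9)
  s2 <- t0[t0$set == 2, ]
  rho <- cor(s2[, c("height_mm", "sd_mm", "nn", "g_frac")],
             method = "spearman")
  crit <- stats::qnorm(0.995) / sqrt(nrow(s2) - 1)  # 1% two-sided bound
  expect_lt(max(abs(rho[upper.tri(rho)])), crit)
  # strong loadings, vanishing noise: a common monotone factor -> rho ~ 1
  g1 <- default_growth_params()
  for (tr in names(g1$set2)) g1$set2[[tr]]["sd"] <- 1e-9
  g1$rep_noise <- 0
  t1 <- generate_truth_traits(layout, g1, seed = 10)
  s2 <- t1[t1$set == 2, ]
  rho <- cor(s2[, c("height_mm", "sd_mm", "g_frac")], method = "spearman")
  expect_true(all(rho > 0.995))   # clipping can introduce a few ties
})

test_that("sample correlations match a Monte-Carlo population oracle", {
  gp <- default_growth_params()
  # population Spearman for height vs stem under the set-2 model,
  # by brute-force Monte Carlo at n = 1e6
  set.seed(123)
  n <- 1e6
  u <- rnorm(n) + gp$rep_noise * rnorm(n)
  h <- gp$set2$height[["mu"]] + gp$set2$height[["load"]] * u +
    gp$set2$height[["sd"]] * rnorm(n)
  s <- gp$set2$stem[["mu"]] + gp$set2$stem[["load"]] * u +
    gp$set2$stem[["sd"]] * rnorm(n)
  rho_pop <- cor(h, s, method = "spearman")
  layout <- field_layout(n_entries = 20, n_replicates = 3,
                         plot_cols = 10, dropout_entries = character(0))
  rhos <- vapply(1:200, function(seed) {
    tt <- generate_truth_traits(layout, gp, seed = seed)
    s2 <- tt[tt$set == 2, ]
    cor(s2$height_mm, s2$sd_mm, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos) - rho_pop), 0.1)
})

test_that("negative noise parameters are rejected", {
  g <- default_growth_params()
  g$set1$height["sd"] <- -1
  expect_error(generate_truth_traits(tiny_layout(), g, seed = 1),
               "non-negative")
})

test_that("truth CSV uses the canonical header and round-trips", {
  study <- tiny_study(seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(study$truth, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("plot_id", "set", "entry", "rep", "height_mm",
                     "area_cm2", "sd_mm", "nn", "g_frac"))
  expect_equal(nrow(back), 2 * 12)
})
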