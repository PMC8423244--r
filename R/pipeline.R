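#' Default pipeline configuration
#'
#' A plain named list validated by [read_config()]. Keys: `seed`,
#' `bit_depth`, `otsu_scope` (`"global"` / `"per-plot"`), `vi_mode`
#' (`"all-roi"` / `"canopy-only"`), `alpha`, `dn_noise_sd`,
#' `dsm_noise_sd_m`, and the layout fields `n_entries`, `n_replicates`,
#' `plants_per_plot`, `dropout_entries`.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(seed = 1, bit_depth = 8, otsu_scope = "global",
       vi_mode = "all-roi", alpha = 0.05, dn_noise_sd = 1,
       dsm_noise_sd_m = 0.005, n_entries = 24, n_replicates = 3,
       plants_per_plot = 15, dropout_entries = "E02")
}

#' Read and validate a pipeline configuration file
#'
#' YAML file of key-value pairs; unknown keys are rejected with the
#' offending key named, and values override [default_config()].
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(user)] <- user
  }
  stopifnot(cfg$otsu_scope %in% c("global", "per-plot"),
            cfg$vi_mode %in% c("all-roi", "canopy-only"),
            cfg$alpha > 0, cfg$alpha < 1, cfg$bit_depth %in% c(8, 16))
  cfg
}

#' Run the whole pipeline: simulate, calibrate, index, extract, test
#'
#' End-to-end orchestration on a synthetic trial: render both
#' acquisition sets, refit the empirical-line model from the rendered
#' calibration panels, convert DN to reflectance, compute vegetation
#' indices and the canopy mask, extract per-plot traits (joining the
#' ground-truth stem diameter and node count as the "manual"
#' measurements), and run the statistical layer. Every stage writes its
#' artifacts under `outdir`; rerunning with the same configuration and
#' seed reproduces them byte for byte.
#'
#' @param config configuration list from [read_config()].
#' @param outdir output directory.
#' @return list with `elm` (per set), `traits` (trait table), `stats`,
#'   `truth`, `outdir`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  layout <- field_layout(n_entries = config$n_entries,
                         n_replicates = config$n_replicates,
                         plants_per_plot = config$plants_per_plot,
                         dropout_entries = config$dropout_entries)
  study <- simulate_study(layout = layout,
                          noise = list(dn_sd = config$dn_noise_sd,
                                       dsm_sd_m = config$dsm_noise_sd_m),
                          bit_depth = config$bit_depth,
                          seed = config$seed)
  write_truth(study$truth, file.path(outdir, "truth.csv"))
  image_traits <- list()
  elms <- list()
  for (s in names(study$scenes)) {
    scene <- study$scenes[[s]]
    write_scene(scene, outdir)
    samples <- extract_panel_samples(scene$dn, scene$panel_rois,
                                     dn_max = 2^scene$bit_depth - 1)
    elm <- fit_elm(samples)
    elms[[s]] <- elm
    jsonlite::write_json(
      list(set = as.integer(s), A = as.list(elm$A), B = as.list(elm$B),
           r2 = as.list(elm$r2), n = as.list(elm$n_samples)),
      file.path(outdir, sprintf("elm_set%s.json", s)),
      auto_unbox = TRUE, digits = NA)
    refl <- apply_elm(elm, scene$dn)
    write_raster(refl, file.path(outdir, sprintf("reflectance_set%s.tif", s)),
                 dtype = "float32")
    image_traits[[s]] <- extract_plot_traits(
      refl, scene$dsm, scene$dtm, scene$plot_rois,
      otsu_scope = config$otsu_scope, vi_mode = config$vi_mode)
  }
  manual <- truth_manual_table(study$truth)
  traits <- build_trait_table(image_traits, manual = manual)
  trait_path <- file.path(outdir, "traits.csv")
  write_trait_table(traits, trait_path)
  write_sidecar(trait_path, config)
  stats_dir <- file.path(outdir, "stats")
  st <- run_stats(traits, outdir = stats_dir, alpha = config$alpha)
  for (f in list.files(stats_dir, pattern = "\\.csv$", full.names = TRUE))
    write_sidecar(f, config)
  write_sidecar(file.path(outdir, "truth.csv"), config)
  jsonlite::write_json(
    list(package = "uavpheno",
         version = as.character(utils::packageVersion("uavpheno")),
         seed = config$seed, config = config,
         stages = c("simulate", "calibrate", "indices", "traits", "stats")),
    file.path(outdir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(elm = elms, traits = traits, stats = st,
                 truth = study$truth, outdir = outdir))
}

# Per-file provenance sidecar: configuration hash and seed.
write_sidecar <- function(path, config) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  h <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  jsonlite::write_json(list(config_md5 = h, seed = config$seed,
                            generator = "uavpheno"),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
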