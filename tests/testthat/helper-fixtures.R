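# Shared fixtures: small synthetic scenes built in code, plus a cache so
# expensive scenes are rendered once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A coarse camera (higher altitude) keeps test rasters small.
tiny_camera <- function(altitude_m = 80) {
  camera_model(altitude_m = altitude_m)
}

tiny_layout <- function(n_entries = 4, n_replicates = 3,
                        plants_per_plot = 6, dropout = "E02") {
  field_layout(n_entries = n_entries, n_replicates = n_replicates,
               plants_per_plot = plants_per_plot, plant_grid = c(3, 2),
               plot_cols = 4, dropout_entries = dropout)
}

tiny_study <- function(seed = 7, noise = list(dn_sd = 1, dsm_sd_m = 0.005),
                       ...) {
  layout <- tiny_layout(...)
  simulate_study(layout = layout, camera = tiny_camera(), noise = noise,
                 seed = seed)
}

# Noise-free, unquantized single scene for exact radiometric checks.
clean_scene <- function(set = 1, seed = 11, layout = tiny_layout()) {
  truth <- generate_truth_traits(layout, seed = seed)
  generate_scene(layout, tiny_camera(), default_elm_truth(set), truth,
                 set = set, noise = list(dn_sd = 0, dsm_sd_m = 0),
                 quantize_dn = FALSE, seed = seed + 1)
}

# The full-size study at default settings; rendered once and shared by
# the acceptance checks.
default_study <- function() {
  cached("default_study", simulate_study(seed = 1))
}

# Independent mid-rank computation (O(n^2), no calls to rank()).
hand_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Independent tie-corrected Kruskal-Wallis from the formula.
hand_kw <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- hand_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H / C
}

# Exhaustive Otsu oracle: loop over every interior bin edge, recompute
# class weights and means directly from the counts.
oracle_otsu <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  n <- sum(counts)
  best <- -Inf; best_k <- NA
  for (k in seq_len(bins - 1L)) {
    w0 <- sum(counts[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / w1
    sb2 <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (sb2 > best) { best <- sb2; best_k <- k }
  }
  list(threshold = breaks[best_k + 1L], between_class_variance = best)
}

# Check the compact-letter-display contract against a significance matrix.
cld_contract_ok <- function(letters_vec, sig) {
  g <- length(letters_vec)
  for (i in seq_len(g - 1)) for (j in seq(i + 1, g)) {
    shared <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                               strsplit(letters_vec[j], "")[[1]])) > 0
    if (sig[i, j] && shared) return(FALSE)
    if (!sig[i, j] && !shared) return(FALSE)
  }
  TRUE
}
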