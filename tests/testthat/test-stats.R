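test_that("Shapiro-Wilk screen behaves under null and skewed alternatives", {
  set.seed(51)
  p_norm <- vapply(1:200, function(i) shapiro_normality(rnorm(500))$p, 0)
  expect_gte(mean(p_norm > 0.01), 0.95)
  p_exp <- vapply(1:200, function(i) shapiro_normality(rexp(500))$p, 0)
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(shapiro_normality(rep(1, 10)), "degenerate")
  expect_error(shapiro_normality(c(1, 2)), "insufficient")
})

test_that("Kruskal-Wallis reproduces the hand-ranked example and oracle", {
  kt <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kt$H, 7.2, tolerance = 1e-12)
  expect_equal(kt$df, 2)
  # identical groups: zero statistic, p = 1, no error
  k0 <- kruskal_wallis(list(rep(2, 4), rep(2, 5), rep(2, 3)))
  expect_equal(k0$H, 0)
  expect_equal(k0$p, 1)
  # tie-laden random data matches an independent rank implementation
  set.seed(53)
  for (i in 1:10) {
    groups <- lapply(1:4, function(g) sample(1:6, 8, replace = TRUE))
    expect_equal(kruskal_wallis(groups)$H, hand_kw(groups),
                 tolerance = 1e-12)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(55)
  groups <- lapply(1:5, function(g) rnorm(6, mean = g / 3))
  f <- function(x) exp(3 * x) + 5
  expect_equal(kruskal_wallis(groups)$H,
               kruskal_wallis(lapply(groups, f))$H, tolerance = 1e-12)
  d1 <- dunn_bonferroni(groups)
  d2 <- dunn_bonferroni(lapply(groups, f))
  expect_equal(d1$z, d2$z, tolerance = 1e-12)
})

test_that("the chi-square Kruskal-Wallis test is valid (if conservative) at 20 x 3", {
  set.seed(57)
  rej <- vapply(1:1000, function(i) {
    kruskal_wallis(split(rnorm(60), rep(1:20, 3)))$p < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.065)   # never anti-conservative
})

test_that("Dunn z statistics match a from-scratch oracle with ties", {
  set.seed(59)
  groups <- lapply(1:3, function(g) sample(seq(0, 3, 0.5), 7, replace = TRUE))
  d <- dunn_bonferroni(groups)
  x <- unlist(groups); N <- length(x)
  rk <- hand_ranks(x)
  idx <- rep(1:3, lengths(groups))
  mr <- tapply(rk, idx, mean)
  tie <- table(x)
  s2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  z12 <- (mr[1] - mr[2]) / sqrt(s2 * (1 / 7 + 1 / 7))
  expect_equal(d$z[d$group1 == "1" & d$group2 == "2"], unname(z12),
               tolerance = 1e-12)
  expect_equal(d$p_adj, pmin(1, d$p_raw * 3), tolerance = 1e-12)
})

test_that("Dunn handles identical groups and the Bonferroni cap", {
  d <- dunn_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d$z, 0)
  expect_equal(d$p_adj, 1)
  # 20 groups: 190 comparisons, so p_raw = 0.01 caps at 1
  set.seed(61)
  groups <- lapply(1:20, function(g) rnorm(3, mean = g / 10))
  d20 <- dunn_bonferroni(groups)
  expect_equal(nrow(d20), 190)
  expect_equal(d20$p_adj, pmin(1, d20$p_raw * 190), tolerance = 1e-12)
  expect_true(all(d20$p_adj[d20$p_raw >= 1 / 190] == 1))
  expect_error(dunn_bonferroni(list(1:3, numeric(0))), "empty group")
})

test_that("compact letters satisfy the display contract on canonical cases", {
  none <- matrix(FALSE, 3, 3)
  expect_equal(unname(compact_letters(none)), c("a", "a", "a"))
  all_sig <- matrix(TRUE, 3, 3); diag(all_sig) <- FALSE
  expect_equal(unname(compact_letters(all_sig)), c("a", "b", "c"))
  # chain: A~B, B~C but A vs C significant -> a, ab, b
  chain <- matrix(FALSE, 3, 3)
  chain[1, 3] <- chain[3, 1] <- TRUE
  expect_equal(unname(compact_letters(chain)), c("a", "ab", "b"))
  asym <- matrix(FALSE, 3, 3); asym[1, 2] <- TRUE
  expect_error(compact_letters(asym), "symmetric")
})

test_that("compact letters honor the contract for every 4-group pattern", {
  pairs <- utils::combn(4, 2)
  for (bits in 0:(2^6 - 1)) {
    sig <- matrix(FALSE, 4, 4)
    for (k in 1:6) {
      if (bitwAnd(bits, bitwShiftL(1L, k - 1L)) != 0) {
        i <- pairs[1, k]; j <- pairs[2, k]
        sig[i, j] <- sig[j, i] <- TRUE
      }
    }
    lt <- compact_letters(sig)
    expect_true(cld_contract_ok(lt, sig),
                info = paste("pattern", bits))
  }
})

test_that("Spearman matrices agree with the closed form and handle ties", {
  expect_equal(spearman_matrix(data.frame(x = 1:3, y = 3:1))$rho["x", "y"],
               -1)
  set.seed(63)
  x <- sample(100, 30); y <- sample(200, 30)  # no ties
  d <- rank(x) - rank(y)
  closed <- 1 - 6 * sum(d^2) / (30 * (30^2 - 1))
  m <- spearman_matrix(data.frame(x = x, y = y))
  expect_equal(m$rho["x", "y"], closed, tolerance = 1e-12)
  expect_equal(m$rho, t(m$rho))
  expect_equal(unname(diag(m$rho)), c(1, 1))
  # zero-variance columns degrade to NA with a message
  expect_message(z <- spearman_matrix(data.frame(x = x, y = y, c = 1)),
                 "zero-variance")
  expect_true(all(is.na(z$rho["c", ])))
  expect_false(anyNA(z$rho[c("x", "y"), c("x", "y")]))
})

test_that("pairwise-complete observations are used per cell", {
  df <- data.frame(x = c(1:8, NA, NA), y = c(2, 1, 4, 3, 6, 5, 8, 7, 1, 2),
                   z = c(NA, NA, 1:8))
  m <- spearman_matrix(df)
  expect_equal(m$n["x", "y"], 8)
  expect_equal(m$n["x", "z"], 6)
  expect_equal(m$rho["x", "y"],
               cor(df$x[1:8], df$y[1:8], method = "spearman"),
               tolerance = 1e-12)
})

test_that("PCA matches an independent eigendecomposition to 1e-9", {
  set.seed(65)
  n <- 40
  df <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(df) <- c("sur_cm2", "eph_mm", "sd_mm", "nn",
                 "exg", "exgr", "exr", "ndi", "gli", "vari")
  p <- pca_traits(df, variable_set = "gt_vi", abs_exr = FALSE)
  x <- as.matrix(df)
  e <- eigen(cor(x), symmetric = TRUE)
  expect_equal(unname(p$explained_pct),
               unname(100 * e$values / sum(e$values)), tolerance = 1e-9)
  for (k in 1:10) {
    v <- e$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(p$loadings[, k]), unname(v), tolerance = 1e-9)
  }
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(p$explained_pct) <= 1e-12))
  # loading columns are orthonormal
  expect_equal(unname(crossprod(p$loadings)), diag(10), tolerance = 1e-9)
})

test_that("PCA conventions: rank-1 tables, |EXR|, variable permutations", {
  df <- data.frame(sur_cm2 = 1:10, eph_mm = 2 * (1:10) + 3,
                   sd_mm = 11:20, nn = 3 * (1:10))
  p <- pca_traits(df, variable_set = "gt")
  expect_equal(p$explained_pct[1], 100, tolerance = 1e-9)
  set.seed(67)
  vi <- as.data.frame(matrix(rnorm(120), 20, 6))
  names(vi) <- c("exg", "exgr", "exr", "ndi", "gli", "vari")
  vi$exr <- -abs(vi$exr)   # all negative, as in practice
  p_abs <- pca_traits(vi, variable_set = "vi", abs_exr = TRUE)
  vi_neg <- vi; vi_neg$exr <- -vi_neg$exr
  p_neg <- pca_traits(vi_neg, variable_set = "vi", abs_exr = FALSE)
  expect_equal(p_abs$loadings, p_neg$loadings, tolerance = 1e-12)
  # permuting observations does not change explained variance
  p_perm <- pca_traits(vi[sample(20), ], variable_set = "vi")
  p_base <- pca_traits(vi, variable_set = "vi")
  expect_equal(p_perm$explained_pct, p_base$explained_pct,
               tolerance = 1e-9)
  cst <- vi; cst$vari <- 1
  expect_warning(pca_traits(cst, variable_set = "vi"), "constant")
})

test_that("the full statistical layer runs and writes its report", {
  study <- tiny_study(seed = 69)
  traits <- lapply(study$scenes, function(sc) {
    refl <- apply_elm(sc$elm_truth, sc$dn)
    extract_plot_traits(refl, sc$dsm, sc$dtm, sc$plot_rois)
  })
  tab <- suppressMessages(
    build_trait_table(traits, manual = truth_manual_table(study$truth)))
  outdir <- withr::local_tempdir()
  res <- run_stats(tab, outdir = outdir)
  expect_true(all(c("kw_tests.csv", "dunn_pairs.csv", "letters.csv",
                    "spearman_set1.csv", "spearman_set2.csv",
                    "pca_loadings.csv", "pca_variance.csv",
                    "summary.txt") %in% list.files(outdir)))
  expect_true(all(res$kw$H >= 0))
  expect_true(all(res$kw$source %in% c("entry", "rep")))
  # letters cover every tested entry
  expect_setequal(unique(res$letters$entry),
                  setdiff(unique(tab$entry), character(0)))
})
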