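#' Shapiro-Wilk normality screen
#'
#' Reported as a gate only: whatever the outcome, the pipeline proceeds
#' nonparametrically (rank tests), since plot-trial traits routinely fail
#' normality at some stage.
#'
#' @param values numeric vector, 3 <= n <= 5000 after NA removal.
#' @return list with `W` and `p`.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3)
    stop("insufficient data: Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (length(values) > 5000)
    stop("Shapiro-Wilk is defined for n <= 5000", call. = FALSE)
  if (var(values) == 0)
    stop("degenerate input: all values identical", call. = FALSE)
  s <- shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) stop("pass a list of numeric vectors")
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  groups
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-square tail probability on
#' `g - 1` degrees of freedom. If every observation is identical the
#' statistic is 0 with p = 1 (not an error).
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need at least 2 non-empty groups", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1, n = length(x)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(x))
}

#' Dunn post hoc comparisons with Bonferroni adjustment
#'
#' All pairwise z tests on mean ranks after a Kruskal-Wallis test, with
#' the tie-corrected standard error
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))`,
#' two-sided normal p-values, and Bonferroni adjustment over all
#' `g(g-1)/2` comparisons capped at 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @param labels optional group labels (defaults to list names or
#'   indices).
#' @return data.frame: `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_bonferroni <- function(groups, labels = NULL) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0))
    stop("invalid input: empty group", call. = FALSE)
  labels <- labels %||% names(groups) %||% as.character(seq_along(groups))
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)  # mid-ranks for ties
  idx <- rep(seq_along(groups), lengths(groups))
  mean_rank <- tapply(rk, idx, mean)
  n_i <- lengths(groups)
  tie <- table(x)
  tie_term <- sum(tie^3 - tie) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  cmb <- utils::combn(length(groups), 2)
  m <- ncol(cmb)
  z <- p_raw <- numeric(m)
  for (k in seq_len(m)) {
    i <- cmb[1, k]; j <- cmb[2, k]
    se <- sqrt(s2 * (1 / n_i[i] + 1 / n_i[j]))
    z[k] <- if (se == 0) 0 else (mean_rank[i] - mean_rank[j]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = labels[cmb[1, ]], group2 = labels[cmb[2, ]],
             z = z, p_raw = p_raw, p_adj = pmin(1, p_raw * m))
}

#' Compact letter display from pairwise significance
#'
#' Insert-and-absorb letter assignment: starting from a single set
#' holding all groups, each significant pair splits every set containing
#' both; sets contained in others are absorbed. The result satisfies the
#' display contract exactly: two groups share at least one letter iff
#' their difference is not significant. Letters are assigned in group
#' order, so the output is deterministic.
#'
#' @param significant logical g x g matrix, `TRUE` where the pair
#'   differs significantly; must be symmetric with a `FALSE`/ignored
#'   diagonal. Row/col names are used as group labels.
#' @param labels optional group labels.
#' @return named character vector of letter strings.
#' @export
compact_letters <- function(significant, labels = NULL) {
  stopifnot(is.matrix(significant), nrow(significant) == ncol(significant))
  g <- nrow(significant)
  diag(significant) <- FALSE
  if (!isTRUE(all(significant == t(significant))))
    stop("significance relation must be symmetric", call. = FALSE)
  labels <- labels %||% rownames(significant) %||% as.character(seq_len(g))
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      if (!significant[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb: drop sets contained in another set
      keep <- vapply(seq_along(new_sets), function(a) {
        !any(vapply(seq_along(new_sets), function(b) {
          b != a && all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[b]]) > length(new_sets[[a]]) || b < a)
        }, TRUE))
      }, TRUE)
      sets <- new_sets[keep]
    }
  }
  # deterministic ordering: by smallest member, then lexicographically
  ord <- order(vapply(sets, min, 0L),
               vapply(sets, function(s) paste(sprintf("%04d", s),
                                              collapse = ","), ""))
  sets <- sets[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- setNames(rep("", g), labels)
  for (k in seq_along(sets))
    for (m in sets[[k]]) out[m] <- paste0(out[m], letters_pool[k])
  out
}

#' Compact letters for a Dunn-Bonferroni result
#'
#' @param dunn data.frame from [dunn_bonferroni()].
#' @param groups character vector of all group labels, in display order.
#' @param alpha significance threshold on adjusted p-values.
#' @return named character vector of letters.
#' @export
dunn_letters <- function(dunn, groups, alpha = 0.05) {
  g <- length(groups)
  sig <- matrix(FALSE, g, g, dimnames = list(groups, groups))
  for (k in seq_len(nrow(dunn))) {
    i <- match(dunn$group1[k], groups); j <- match(dunn$group2[k], groups)
    if (is.na(i) || is.na(j)) stop("dunn table names unknown group")
    sig[i, j] <- sig[j, i] <- dunn$p_adj[k] < alpha
  }
  compact_letters(sig, labels = groups)
}

#' Spearman correlation matrix with pairwise-complete observations
#'
#' Tie-aware Spearman rho (Pearson correlation of mid-ranks) for every
#' pair of trait columns, with p-values from the t approximation on
#' `n - 2` degrees of freedom. Zero-variance columns get NA rows/columns
#' (with a message) rather than failing.
#'
#' @param data data.frame holding the trait columns.
#' @param traits character vector of column names to correlate.
#' @return object of class `correlation_matrix`: `rho`, `p`, `n`
#'   matrices and `traits`.
#' @export
spearman_matrix <- function(data, traits = NULL) {
  traits <- traits %||% names(data)[vapply(data, is.numeric, TRUE)]
  stopifnot(all(traits %in% names(data)))
  x <- as.matrix(data[, traits, drop = FALSE])
  k <- length(traits)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- is.finite(x[, i]) & is.finite(x[, j])
    n[i, j] <- sum(ok)
    if (n[i, j] < 3) next
    if (var(x[ok, i]) == 0 || var(x[ok, j]) == 0) next
    rho[i, j] <- cor(x[ok, i], x[ok, j], method = "spearman")
    if (i == j) { p[i, j] <- 0; next }
    r <- rho[i, j]
    if (abs(r) >= 1) p[i, j] <- 0
    else {
      tstat <- r * sqrt((n[i, j] - 2) / (1 - r^2))
      p[i, j] <- 2 * pt(-abs(tstat), df = n[i, j] - 2)
    }
  }
  degenerate <- traits[vapply(seq_len(k), function(i) is.na(rho[i, i]), TRUE)]
  if (length(degenerate))
    message("zero-variance column(s) left NA: ",
            paste(degenerate, collapse = ", "))
  structure(list(rho = rho, p = p, n = n, traits = traits),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix> Spearman rho:\n")
  print(round(x$rho, digits))
  invisible(x)
}

gt_trait_names <- function() c("sur_cm2", "eph_mm", "sd_mm", "nn")

#' Principal component analysis of the trait table
#'
#' Correlation-matrix PCA (variables standardized) of the growth traits
#' and/or vegetation indices, after replacing EXR by its absolute value
#' when `abs_exr` is on (EXR carries the opposite sign of the other
#' indices). Listwise-complete observations; constant variables are
#' dropped with a warning. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param data trait table (rows = plot x set observations).
#' @param variable_set `"gt_vi"` (growth traits + indices), `"gt"`, or
#'   `"vi"`.
#' @param abs_exr replace EXR by `|EXR|` before standardization.
#' @param scale. standardize variables (correlation PCA, default) or not
#'   (covariance PCA).
#' @return object of class `pca_result`: `loadings` (variables x
#'   components), `explained_pct`, `scores`, `variable_set`, `n`.
#' @export
pca_traits <- function(data, variable_set = c("gt_vi", "gt", "vi"),
                       abs_exr = TRUE, scale. = TRUE) {
  variable_set <- match.arg(variable_set)
  vars <- switch(variable_set,
                 gt = gt_trait_names(),
                 vi = vi_names(),
                 gt_vi = c(gt_trait_names(), vi_names()))
  stopifnot(all(vars %in% names(data)))
  x <- as.matrix(data[, vars, drop = FALSE])
  if (abs_exr && "exr" %in% colnames(x))
    x[, "exr"] <- abs(x[, "exr"])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete observations",
                        call. = FALSE)
  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 variables", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  load <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, k])), k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(loadings = load, explained_pct = 100 * ev / sum(ev),
                 scores = scores, variable_set = variable_set,
                 n = nrow(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %s, n = %d\n", x$variable_set, x$n))
  cat("explained %:", paste(sprintf("%.2f", x$explained_pct),
                            collapse = " "), "\n")
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "NS")))
}

#' Run the whole statistical layer over a trait table
#'
#' Per trait and acquisition set: Shapiro-Wilk screen, Kruskal-Wallis
#' tests on entries and (separately) on replicates, Dunn-Bonferroni
#' pairwise comparisons with compact letters; per set: Spearman matrix
#' over all traits and the three PCA variable sets. Results are written
#' as CSV files plus a plain-text summary when `outdir` is given.
#'
#' @param traits trait table from [build_trait_table()].
#' @param outdir optional output directory for the report files.
#' @param alpha significance threshold.
#' @return list with `kw`, `dunn`, `letters`, `shapiro`, `spearman`
#'   (per set), `pca` (per set x variable set).
#' @export
run_stats <- function(traits, outdir = NULL, alpha = 0.05) {
  trait_cols <- c(gt_trait_names(), vi_names())
  trait_cols <- trait_cols[trait_cols %in% names(traits)]
  sets <- sort(unique(traits$set))
  kw_rows <- list(); dunn_rows <- list(); letter_rows <- list()
  shapiro_rows <- list()
  for (s in sets) {
    ds <- traits[traits$set == s, ]
    for (tr in trait_cols) {
      v <- ds[[tr]]
      ok <- is.finite(v)
      if (sum(ok) < 3 || var(v[ok]) == 0) next
      sw <- shapiro_normality(v[ok])
      shapiro_rows[[length(shapiro_rows) + 1L]] <- data.frame(
        trait = tr, set = s, W = sw$W, p = sw$p)
      for (src in c("entry", "rep")) {
        gl <- split(v[ok], ds[[src]][ok])
        gl <- gl[lengths(gl) > 0]
        if (length(gl) < 2) next
        kt <- kruskal_wallis(gl)
        kw_rows[[length(kw_rows) + 1L]] <- data.frame(
          trait = tr, set = s, source = src, df = kt$df, H = kt$H,
          p = kt$p, signif = significance_stars(kt$p))
        if (src == "entry") {
          dn <- dunn_bonferroni(gl, labels = names(gl))
          dunn_rows[[length(dunn_rows) + 1L]] <- cbind(
            trait = tr, set = s, dn)
          let <- dunn_letters(dn, names(gl), alpha = alpha)
          letter_rows[[length(letter_rows) + 1L]] <- data.frame(
            trait = tr, set = s, entry = names(let), letters = unname(let))
        }
      }
    }
  }
  spearman <- lapply(sets, function(s)
    spearman_matrix(traits[traits$set == s, ], traits = trait_cols))
  names(spearman) <- paste0("set", sets)
  pca <- lapply(sets, function(s) {
    ds <- traits[traits$set == s, ]
    lapply(c(gt_vi = "gt_vi", gt = "gt", vi = "vi"), function(vs)
      tryCatch(pca_traits(ds, variable_set = vs),
               error = function(e) NULL))
  })
  names(pca) <- paste0("set", sets)
  res <- list(kw = do.call(rbind, kw_rows),
              dunn = do.call(rbind, dunn_rows),
              letters = do.call(rbind, letter_rows),
              shapiro = do.call(rbind, shapiro_rows),
              spearman = spearman, pca = pca, alpha = alpha)
  if (!is.null(outdir)) write_stats_report(res, outdir)
  res
}

write_stats_report <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$kw, file.path(outdir, "kw_tests.csv"), row.names = FALSE)
  write.csv(res$dunn, file.path(outdir, "dunn_pairs.csv"),
            row.names = FALSE)
  write.csv(res$letters, file.path(outdir, "letters.csv"),
            row.names = FALSE)
  write.csv(res$shapiro, file.path(outdir, "shapiro.csv"),
            row.names = FALSE)
  for (s in names(res$spearman)) {
    write.csv(res$spearman[[s]]$rho,
              file.path(outdir, sprintf("spearman_%s.csv", s)))
  }
  load_rows <- list(); var_rows <- list()
  for (s in names(res$pca)) for (vs in names(res$pca[[s]])) {
    p <- res$pca[[s]][[vs]]
    if (is.null(p)) next
    ld <- as.data.frame(p$loadings[, 1:min(2, ncol(p$loadings)),
                                   drop = FALSE])
    names(ld) <- paste0("PC", seq_len(ncol(ld)))
    load_rows[[paste(s, vs)]] <- cbind(set = s, variables = vs,
                                       variable = rownames(ld), ld)
    var_rows[[paste(s, vs)]] <- data.frame(
      set = s, variables = vs,
      component = seq_along(p$explained_pct),
      explained_pct = p$explained_pct)
  }
  if (length(load_rows))
    write.csv(do.call(rbind, load_rows),
              file.path(outdir, "pca_loadings.csv"), row.names = FALSE)
  if (length(var_rows))
    write.csv(do.call(rbind, var_rows),
              file.path(outdir, "pca_variance.csv"), row.names = FALSE)
  smry <- file.path(outdir, "summary.txt")
  con <- file(smry, "w"); on.exit(close(con))
  writeLines(c("uavpheno statistical report",
               sprintf("alpha = %g", res$alpha), "",
               "Kruskal-Wallis tests:"), con)
  if (!is.null(res$kw))
    writeLines(utils::capture.output(print(res$kw, row.names = FALSE)),
               con)
  invisible(outdir)
}
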