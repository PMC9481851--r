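## Dissimilarity, distance-based redundancy analysis, Moran's I, rank
## correlation, contingency tests and bootstrap group comparisons.

#' Pairwise community dissimilarity between plots
#'
#' Jaccard dissimilarity on presence/absence (1 - shared/total), or
#' Bray-Curtis on quantitative cover, via [vegan::vegdist()].
#'
#' @param mat plot-by-entity (species, molecule or protein-family)
#'   non-negative matrix; rows are plots.
#' @param method `"jaccard"` or `"bray_curtis"`.
#' @return A `dist` object over plots.
#' @export
dissimilarity <- function(mat, method = c("jaccard", "bray_curtis")) {
  method <- match.arg(method)
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop_field("need at least 2 plots")
  if (anyNA(mat) || any(mat < 0)) stop_field("matrix values must be >= 0")
  empty <- rowSums(mat) == 0
  if (any(empty)) {
    stop_field("empty communities make pairwise dissimilarity undefined: %s",
               paste(rownames(mat)[empty] %||% which(empty), collapse = ", "))
  }
  if (method == "jaccard") {
    vegan::vegdist(mat > 0, method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(mat, method = "bray")
  }
}

#' Distance-based redundancy analysis with a permutation test
#'
#' Constrained ordination of a dissimilarity matrix on explanatory
#' variables: the matrix is Gower-centred (-1/2 D^2, double-centred),
#' eigendecomposed, the positive-eigenvalue principal-coordinate axes are
#' retained, and the retained coordinates are regressed on the predictors.
#' R2 is the fitted share of the total sum of squares over retained axes,
#' and the pseudo-F statistic is tested by seeded permutations of the
#' predictor rows.
#'
#' @param D distance matrix (`dist` or symmetric matrix).
#' @param X predictor data frame/matrix or a single vector; each column
#'   must have positive variance.
#' @param n_perm number of row permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return Object of class `dbrda_result`: `r2`, `pseudo_f`, `p_perm`,
#'   `n_perm`, `n_axes_retained`, `eigenvalues`.
#' @export
dbrda_analysis <- function(D, X, n_perm = 999, seed = NULL) {
  Dm <- as.matrix(D)
  n <- nrow(Dm)
  if (n < 3) stop_field("need at least 3 plots")
  if (is.null(dim(X))) X <- data.frame(x = X)
  X <- as.matrix(as.data.frame(X))
  if (nrow(X) != n) stop_field("predictor rows must match distance matrix")
  if (any(apply(X, 2, var) == 0)) stop_field("constant predictor")

  A <- -0.5 * Dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tol
  if (!any(pos)) stop_field("no positive eigenvalues in the Gower-centred matrix")
  Y <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  ss_total <- sum(eig$values[pos])
  q <- ncol(X)

  f_stat <- function(Xp) {
    fitq <- lm.fit(cbind(1, Xp), Y)
    fitted <- Y - fitq$residuals
    fitted <- sweep(fitted, 2, colMeans(fitted))  # centred fitted values
    ss_fit <- sum(fitted^2)
    (ss_fit / q) / ((ss_total - ss_fit) / (n - q - 1))
  }
  fitq <- lm.fit(cbind(1, X), Y)
  fitted <- Y - fitq$residuals
  fitted <- sweep(fitted, 2, colMeans(fitted))
  ss_fit <- sum(fitted^2)
  r2 <- ss_fit / ss_total
  f_obs <- (ss_fit / q) / ((ss_total - ss_fit) / (n - q - 1))

  p_perm <- with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) {
      f_stat(X[sample.int(n), , drop = FALSE])
    }, numeric(1))
    (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  })

  structure(list(
    r2 = r2, pseudo_f = f_obs, p_perm = p_perm, n_perm = n_perm,
    n_axes_retained = sum(pos), eigenvalues = eig$values
  ), class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: r2 = %.4f, pseudo-F = %.3f, P = %.4g (%d permutations, %d axes)\n",
              x$r2, x$pseudo_f, x$p_perm, x$n_perm, x$n_axes_retained))
  invisible(x)
}

#' Moran's I spatial autocorrelation
#'
#' Moran's I with inverse-Euclidean-distance weights, row-standardised,
#' tested against the null expectation -1/(n-1) with the
#' randomisation-variance normal approximation (two-sided).
#'
#' @param values numeric vector (e.g. model residuals), non-constant.
#' @param coords two-column matrix/data frame of planar coordinates; no
#'   coincident points.
#' @return Object of class `moran_result`: `observed_i`, `expected_i`,
#'   `sd`, `p`.
#' @export
morans_i <- function(values, coords) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 3) stop_field("need n >= 3")
  if (nrow(coords) != n) stop_field("coords must have one row per value")
  if (var(values) == 0) stop_field("constant values")
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] == 0)) stop_field("coincident coordinates (distance 0)")
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)

  z <- values - mean(values)
  s0 <- sum(w)
  obs <- (n / s0) * sum(w * outer(z, z)) / sum(z^2)
  ei <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  kurt <- (sum(z^4) / n) / (sum(z^2) / n)^2
  vari <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
             kurt * (n * (n - 1) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  sdi <- sqrt(vari)
  p <- 2 * pnorm(-abs((obs - ei) / sdi))
  structure(list(observed_i = obs, expected_i = ei, sd = sdi,
                 p = min(max(p, .Machine$double.xmin), 1)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f), P = %.4g\n",
              x$observed_i, x$expected_i, x$sd, x$p))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with the asymptotic t-approximation
#' p-value.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return List `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_field("need n >= 3 complete pairs")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Likelihood-ratio (G) test of independence
#'
#' G = 2 sum O ln(O/E) over non-zero cells, df = (r-1)(c-1), chi-square
#' p-value.
#'
#' @param tab matrix of non-negative integer counts.
#' @return List `g`, `df`, `p`.
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_field("counts must be non-negative integers")
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  nz <- tab > 0
  g <- 2 * sum(tab[nz] * log(tab[nz] / E[nz]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(g = g, df = df, p = pchisq(g, df, lower.tail = FALSE))
}

#' Contingency-table tests
#'
#' For a 2x2 table, the Fisher exact test (conditional maximum-likelihood
#' odds ratio, hypergeometric p); for any table, the G-test of
#' independence. Infinite odds ratios (a zero cell on the off-diagonal) are
#' flagged with `odds_ratio_bounded = TRUE`.
#'
#' @param tab matrix of non-negative integer counts.
#' @return List with `g` (see [g_test()]) and, for 2x2 tables, `fisher`:
#'   `odds_ratio`, `p`, `odds_ratio_bounded`.
#' @export
contingency_tests <- function(tab) {
  tab <- as.matrix(tab)
  out <- list(g = g_test(tab))
  if (all(dim(tab) == c(2, 2))) {
    ft <- fisher.test(tab)
    out$fisher <- list(
      odds_ratio = unname(ft$estimate),
      p = ft$p.value,
      odds_ratio_bounded = !is.finite(unname(ft$estimate)) ||
        unname(ft$estimate) == 0)
  }
  out
}

## compact letter display: maximal cliques of the "not significantly
## different" graph, letters ordered by group mean
cld_letters <- function(same, means) {
  g <- nrow(same)
  groups <- seq_len(g)
  ## enumerate maximal cliques by brute force (few groups)
  subsets <- lapply(seq_len(2^g - 1), function(b) groups[bitwAnd(b, 2^(groups - 1)) > 0])
  is_clique <- vapply(subsets, function(s) all(same[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) {
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o)
    }, logical(1)))
  }, logical(1))
  cliques <- cliques[maximal]
  cliques <- cliques[order(vapply(cliques, function(s) min(means[s]), numeric(1)))]
  lab <- rep("", g)
  for (i in seq_along(cliques)) {
    lab[cliques[[i]]] <- paste0(lab[cliques[[i]]], letters[i])
  }
  lab
}

#' Bootstrap comparison of group means
#'
#' Stratified bootstrap of per-group means: each group is resampled with
#' replacement `n_boot` times, giving percentile confidence intervals for
#' the group means and for all pairwise mean differences. Groups whose
#' pairwise-difference interval excludes zero are assigned distinct
#' letters (compact letter display).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length; every group needs at
#'   least 2 values.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param ci_level confidence level for the percentile intervals
#'   (default 0.90).
#' @return Data frame `group, n, mean, lower, upper, letters`, with the
#'   pairwise comparison table in attribute `"pairwise"`.
#' @export
bootstrap_group_compare <- function(values, groups, n_boot = 1000, seed = NULL,
                                    ci_level = 0.90) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop_field("need at least 2 groups")
  if (any(sizes < 2)) {
    stop_field("group(s) with fewer than 2 values: %s",
               paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  lv <- levels(groups)
  idx <- split(seq_along(values), groups)
  boot <- with_seed(seed, {
    vapply(lv, function(g) {
      v <- values[idx[[g]]]
      vapply(seq_len(n_boot), function(b) mean(sample(v, replace = TRUE)),
             numeric(1))
    }, numeric(n_boot))
  })
  alpha <- (1 - ci_level) / 2
  means <- vapply(lv, function(g) mean(values[idx[[g]]]), numeric(1))
  ci <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha))

  g <- length(lv)
  same <- matrix(TRUE, g, g, dimnames = list(lv, lv))
  pw <- list()
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      diffs <- boot[, i] - boot[, j]
      dlo <- quantile(diffs, alpha); dhi <- quantile(diffs, 1 - alpha)
      distinct <- dlo > 0 || dhi < 0
      same[i, j] <- same[j, i] <- !distinct
      pw[[length(pw) + 1L]] <- data.frame(
        group1 = lv[i], group2 = lv[j], diff = means[i] - means[j],
        lower = unname(dlo), upper = unname(dhi), distinct = distinct,
        stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(
    group = lv, n = as.integer(sizes[lv]), mean = unname(means),
    lower = ci[1, ], upper = ci[2, ],
    letters = cld_letters(same, means),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pairwise") <- do.call(rbind, pw)
  out
}
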