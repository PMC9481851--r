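test_that("AICc formula and limits", {
  expect_equal(aicc(-10, 2, 10), 20 + 4 + 12 / 7)
  ## large-n limit is plain AIC
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)
  ## extra parameter at equal likelihood strictly increases AICc
  expect_gt(aicc(-10, 3, 20), aicc(-10, 2, 20))
  expect_error(aicc(-10, 9, 10), "must exceed")
})

test_that("intercept-only Poisson recovers the log mean and gaussian matches OLS", {
  r <- fit_glm(c(2, 4, 6), NULL, "poisson")
  expect_equal(unname(r$coefficients[1, "estimate"]), log(4))
  x <- c(0.1, 0.5, 0.9, 1.4, 2.2, 3.0)
  y <- c(1.0, 1.8, 2.1, 3.9, 4.4, 6.1)
  g <- fit_glm(y, data.frame(x = x), "gaussian")
  ols <- lm(y ~ x)
  expect_equal(unname(g$coefficients[, "estimate"]), unname(coef(ols)))
})

test_that("Poisson IRLS coefficients match a numeric likelihood optimum", {
  x <- c(-1.2, -0.6, -0.1, 0.3, 0.8, 1.1, 1.7, 2.3)
  y <- c(0L, 1L, 1L, 2L, 3L, 2L, 6L, 9L)
  fit <- fit_glm(y, data.frame(x = x), "poisson")
  nll <- function(b) -sum(dpois(y, exp(b[1] + b[2] * x), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  ## polish the numeric optimum with Newton steps on the log-likelihood
  b <- opt$par
  for (i in 1:50) {
    mu <- exp(b[1] + b[2] * x)
    grad <- c(sum(y - mu), sum((y - mu) * x))
    hess <- -rbind(c(sum(mu), sum(mu * x)), c(sum(mu * x), sum(mu * x^2)))
    b <- b - solve(hess, grad)
  }
  expect_lt(nll(b), nll(opt$par) + 1e-12)  # a genuine improvement step
  expect_equal(unname(fit$coefficients[, "estimate"]), b, tolerance = 1e-6)
})

test_that("quasi-binomial inference scales binomial errors by the dispersion", {
  set.seed(5)
  n <- 40; trials <- rep(25, n)
  x <- runif(n)
  p <- plogis(-0.5 + 1.5 * x)
  ## overdispersed proportions via a beta-binomial draw
  y <- rbinom(n, trials, rbeta(n, p * 8, (1 - p) * 8)) / trials
  q <- fit_glm(y, data.frame(x = x), "quasibinomial", weights = trials)
  b <- suppressWarnings(fit_glm(y, data.frame(x = x), "binomial",
                                weights = trials))
  expect_gt(q$dispersion, 1)
  expect_equal(unname(q$coefficients[, "estimate"]),
               unname(b$coefficients[, "estimate"]))
  expect_equal(unname(q$coefficients[, "se"]),
               unname(b$coefficients[, "se"]) * sqrt(q$dispersion),
               tolerance = 1e-8)
  expect_true(q$lrt_p > 0 && q$lrt_p <= 1)
})

test_that("Nagelkerke pseudo-R2 is 0 for the null and rises with signal", {
  set.seed(2)
  y <- rpois(60, 5)
  r0 <- fit_glm(y, NULL, "poisson")
  expect_equal(r0$nagelkerke_r2, 0)
  x <- seq(0, 2, length.out = 60)
  y1 <- rpois(60, exp(0.5 + 1.2 * x))
  r1 <- fit_glm(y1, data.frame(x = x), "poisson")
  expect_gt(r1$nagelkerke_r2, 0.3)
  expect_lte(r1$nagelkerke_r2, 1)
  expect_lt(r1$lrt_p, 1e-4)
})

test_that("negative binomial fit approaches Poisson for equidispersed data", {
  set.seed(3)
  x <- runif(80)
  y <- rpois(80, exp(1 + 0.8 * x))
  nb <- fit_glm(y, data.frame(x = x), "negative_binomial")
  po <- fit_glm(y, data.frame(x = x), "poisson")
  expect_gt(nb$theta, 100)  # little overdispersion to absorb
  expect_equal(unname(nb$coefficients[, "estimate"]),
               unname(po$coefficients[, "estimate"]), tolerance = 1e-3)
  ## the likelihood limit at huge theta
  mu <- fitted(po$fit)
  expect_lt(abs(sum(dnbinom(y, size = 1e6, mu = mu, log = TRUE)) -
                  sum(dpois(y, mu, log = TRUE))), 0.1)
})

test_that("model selection follows the AICc-vs-null rule and tie-breaks", {
  set.seed(4)
  n <- 200
  urb <- runif(n, 0, 100); neo <- runif(n)
  ## pure-noise response: the null must win
  noise <- rnorm(n)
  sel <- select_model(noise, urb, neo, "gaussian")
  expect_equal(sel$chosen, "null")
  ## strong interaction: the interaction model wins in most seeded runs
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    u <- runif(n, 0, 100); v <- runif(n)
    y <- 0.5 + 0.002 * u + 0.3 * v + 0.08 * u * v + rnorm(n, 0, 1)
    if (select_model(y, u, v, "gaussian")$chosen ==
        "urbanisation*neophyte_prop") hits <- hits + 1
  }
  expect_gte(hits / 40, 0.9)
})

test_that("dissimilarities satisfy the set-arithmetic identities", {
  m <- rbind(p1 = c(1, 1, 1, 0), p2 = c(0, 1, 1, 1), p3 = c(1, 1, 1, 0),
             p4 = c(0, 0, 0, 2))
  colnames(m) <- letters[1:4]
  d <- as.matrix(dissimilarity(m, "jaccard"))
  expect_equal(d["p1", "p2"], 0.5)      # 1 - 2/4
  expect_equal(d["p1", "p3"], 0)        # identical plots
  expect_equal(d["p1", "p4"], 1)        # disjoint plots
  bc <- as.matrix(dissimilarity(m, "bray_curtis"))
  expect_equal(bc["p1", "p4"], 1)
  expect_equal(bc["p1", "p2"], 2 / 6)   # sum|x-y| / sum(x+y)
  m0 <- rbind(m, p5 = c(0, 0, 0, 0))
  expect_error(dissimilarity(m0, "jaccard"), "p5")
})

test_that("dbRDA equals the explicit PCoA-then-regression oracle", {
  set.seed(10)
  n <- 8
  m <- matrix(rbinom(n * 12, 1, 0.5), n, dimnames = list(paste0("p", 1:n), NULL))
  m[1, ] <- 1  # no empty plots
  D <- dissimilarity(m, "jaccard")
  x <- rnorm(n)
  res <- dbrda_analysis(D, x, n_perm = 99, seed = 1)
  ## oracle: stats::cmdscale PCoA, positive axes, per-axis OLS
  pc <- suppressWarnings(cmdscale(D, k = n - 1, eig = TRUE))
  pos <- pc$eig > max(pc$eig) * 1e-10
  Y <- pc$points[, seq_len(sum(pos)), drop = FALSE]
  ss_fit <- sum(vapply(seq_len(ncol(Y)), function(j) {
    f <- lm(Y[, j] ~ x)
    sum((fitted(f) - mean(Y[, j]))^2)
  }, numeric(1)))
  expect_equal(res$r2, ss_fit / sum(pc$eig[pos]), tolerance = 1e-8)
  expect_equal(res$n_axes_retained, sum(pos))
})

test_that("dbRDA r2 is invariant to affine predictor rescaling and exact for collinear gradients", {
  set.seed(11)
  n <- 10
  x <- rnorm(n)
  D <- dist(x)  # Euclidean distance of a variable collinear with x
  r <- dbrda_analysis(D, x, n_perm = 49, seed = 2)
  expect_equal(r$r2, 1, tolerance = 1e-10)
  m <- matrix(rbinom(n * 15, 1, 0.5), n); m[, 1] <- 1
  D2 <- dissimilarity(m, "jaccard")
  a <- dbrda_analysis(D2, x, n_perm = 49, seed = 3)
  b <- dbrda_analysis(D2, 100 - 3 * x, n_perm = 49, seed = 3)
  expect_equal(a$r2, b$r2, tolerance = 1e-12)
  ## seeded permutation p is reproducible bit-exact
  expect_identical(a$p_perm,
                   dbrda_analysis(D2, x, n_perm = 49, seed = 3)$p_perm)
  expect_error(dbrda_analysis(D2, rep(1, n), n_perm = 9), "constant")
})

test_that("Moran's I matches a hand-expanded double sum on four points", {
  vals <- c(1, 2, 3, 4)
  coords <- cbind(1:4, 0)
  res <- morans_i(vals, coords)
  expect_equal(res$expected_i, -1 / 3)
  ## independent oracle: explicit loops over the definition
  d <- as.matrix(dist(coords)); w <- 1 / d; diag(w) <- 0
  w <- w / rowSums(w)
  z <- vals - mean(vals)
  num <- 0
  for (i in 1:4) for (j in 1:4) num <- num + w[i, j] * z[i] * z[j]
  I_hand <- (4 / sum(w)) * num / sum(z^2)
  expect_equal(res$observed_i, I_hand, tolerance = 1e-12)
  ## cross-check against the cited reference implementation
  if (requireNamespace("ape", quietly = TRUE)) {
    ref <- ape::Moran.I(vals, w)
    expect_equal(res$observed_i, ref$observed, tolerance = 1e-12)
    expect_equal(res$sd, ref$sd, tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(morans_i(vals, cbind(c(1, 1, 2, 3), 0)), "coincident")
  expect_error(morans_i(rep(2, 4), coords), "constant")
})

test_that("Spearman correlation handles ties through midranks", {
  x <- c(1, 2, 2, 3, 5, 6)
  y <- c(2, 1, 4, 4, 7, 9)
  s <- spearman_test(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)))
  expect_equal(spearman_test(1:8, 1:8)$rho, 1)
  expect_equal(spearman_test(1:8, 8:1)$rho, -1)
})

test_that("contingency tests: Fisher odds ratio and hand-computed G", {
  perfect <- matrix(c(10, 0, 0, 10), 2)
  ct <- contingency_tests(perfect)
  expect_true(ct$fisher$odds_ratio_bounded)
  expect_lt(ct$fisher$p, 1e-4)
  ## independence: G = 0
  ind <- matrix(c(10, 20, 5, 10), 2)
  expect_equal(g_test(ind)$g, 0, tolerance = 1e-12)
  ## 2x3 table against manually expanded O*ln(O/E) sums
  tab <- matrix(c(12, 5, 7, 9, 3, 14), 2, 3)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g_hand <- 2 * sum(tab * log(tab / E))
  gt <- g_test(tab)
  expect_equal(gt$g, g_hand, tolerance = 1e-10)
  expect_equal(gt$df, 2)
  expect_error(g_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("bootstrap group comparison separates and letters groups sensibly", {
  set.seed(20)
  v <- c(rnorm(50, 0), rnorm(50, 5))
  g <- rep(c("a", "b"), each = 50)
  bc <- bootstrap_group_compare(v, g, n_boot = 500, seed = 1)
  expect_false(bc$letters[1] == bc$letters[2])
  ## identical groups share a letter
  v2 <- rep(c(1, 2, 3), 4)
  g2 <- rep(c("x", "y"), each = 6)
  bc2 <- bootstrap_group_compare(v2, g2, n_boot = 500, seed = 2)
  expect_equal(bc2$letters[1], bc2$letters[2])
  ## seeded determinism and input validation
  expect_identical(bootstrap_group_compare(v, g, 200, seed = 9),
                   bootstrap_group_compare(v, g, 200, seed = 9))
  expect_error(bootstrap_group_compare(c(1, 2, 3), c("a", "a", "b"), 100),
               "fewer than 2")
})

test_that("bootstrap CIs approximately cover the true group mean", {
  cover <- 0
  nsim <- 200
  for (s in 1:nsim) {
    set.seed(s)
    v <- rnorm(30, 1, 1)
    g <- rep(c("a", "b"), each = 15)
    bc <- bootstrap_group_compare(v, g, n_boot = 300, seed = s,
                                  ci_level = 0.90)
    cover <- cover + (bc$lower[1] <= 1 && 1 <= bc$upper[1])
  }
  expect_gt(cover / nsim, 0.80)
  expect_lt(cover / nsim, 0.98)
})
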