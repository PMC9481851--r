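## Generalised linear models with AICc, Nagelkerke pseudo-R2 and
## likelihood-ratio tests, plus AICc-based model selection over the
## urbanisation and invasion predictors.

GLM_FAMILIES <- c("gaussian", "poisson", "negative_binomial", "binomial",
                  "quasibinomial")

#' Second-order corrected AIC
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param loglik log-likelihood of the fitted model.
#' @param k_params number of estimated parameters (including dispersion-type
#'   parameters where applicable).
#' @param n number of observations; must exceed `k_params + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k_params, n) {
  if (n <= k_params + 1) {
    stop_field("AICc undefined: n (%d) must exceed k + 1 (%d)", n, k_params + 1)
  }
  -2 * loglik + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

## Nagelkerke pseudo-R2 from null and full log-likelihoods
nagelkerke_r2 <- function(ll0, ll1, n) {
  cs <- 1 - exp((2 / n) * (ll0 - ll1))
  max_cs <- 1 - exp(2 * ll0 / n)
  if (max_cs <= 0) return(0)
  min(max(cs / max_cs, 0), 1)
}

#' Fit a generalised linear model with allergenicity-pipeline conventions
#'
#' Wraps maximum-likelihood (or quasi-likelihood) GLM fitting for the five
#' response families used along the urbanisation/invasion gradients:
#' `gaussian` (cover, PAV means), `poisson` (species counts, family
#' richness), `negative_binomial` (allergen molecule richness; theta
#' estimated by maximum likelihood), `binomial` and `quasibinomial`
#' (species proportions; supply the number of trials through `weights`).
#' Reports coefficients with standard errors (dispersion-scaled for the
#' quasi family), the log-likelihood (for the quasi family, that of the
#' underlying binomial fit), AICc, Nagelkerke pseudo-R2 and a test against
#' the intercept-only model: likelihood-ratio chi-square, or an F-type
#' drop-in-deviance test for the quasi family.
#'
#' @param y response vector (counts, proportions in \[0,1\], or continuous).
#' @param X data frame of predictors, or `NULL` for an intercept-only model.
#' @param family one of `r paste0('"', GLM_FAMILIES, '"', collapse = ", ")`.
#' @param weights binomial denominators (number of trials) for the
#'   (quasi)binomial families.
#' @return Object of class `glm_result`: list with elements `family`,
#'   `coefficients` (matrix: estimate, se, statistic, p), `dispersion`,
#'   `theta`, `loglik`, `df_resid`, `n`, `k`, `aicc`, `nagelkerke_r2`,
#'   `lrt_p`, and the underlying `fit`.
#' @export
fit_glm <- function(y, X = NULL, family = GLM_FAMILIES, weights = NULL) {
  family <- match.arg(family)
  if (is.null(X)) X <- data.frame(row.names = seq_along(y))
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop_field("length(y) must equal nrow(X)")
  ok <- !is.na(y) & complete.cases(X)
  if (!is.null(weights)) ok <- ok & !is.na(weights) & weights > 0
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[ok]
  n <- length(y)
  if (n < 3) stop_field("too few complete observations (n = %d)", n)
  if (var(y) == 0) stop_field("zero-variance response: %s", deparse(y[1]))
  if (family %in% c("poisson", "negative_binomial") &&
      (any(y < 0) || any(y != round(y)))) {
    stop_field("%s family requires non-negative integer counts", family)
  }
  if (family %in% c("binomial", "quasibinomial")) {
    if (any(y < 0 | y > 1)) stop_field("proportions must lie in [0, 1]")
    if (is.null(w)) stop_field("(quasi)binomial proportions need trial weights")
  }

  d <- cbind(data.frame(.y = y), X)
  rhs <- if (ncol(X)) paste(sprintf("`%s`", names(X)), collapse = " + ") else "1"
  fml <- as.formula(paste(".y ~", rhs))
  null_fml <- .y ~ 1

  fit_one <- function(f, fam_obj) {
    if (family == "negative_binomial") {
      suppressWarnings(MASS::glm.nb(f, data = d, control = stats::glm.control(maxit = 100, epsilon = 1e-12)))
    } else {
      suppressWarnings(glm(f, data = d, family = fam_obj, weights = w,
                           control = stats::glm.control(maxit = 100, epsilon = 1e-12)))
    }
  }
  fam_obj <- switch(family,
    gaussian = gaussian(), poisson = poisson(),
    binomial = binomial(), quasibinomial = quasibinomial(),
    negative_binomial = NULL)
  fit <- fit_one(fml, fam_obj)
  fit0 <- fit_one(null_fml, fam_obj)
  if (!fit$converged) {
    stop_field("GLM (%s) did not converge after %d IRLS iterations; deviance %.4g",
               family, fit$iter, fit$deviance)
  }

  sm <- summary(fit)
  coefs <- sm$coefficients
  colnames(coefs) <- c("estimate", "se", "statistic", "p")
  dispersion <- if (family %in% c("quasibinomial", "gaussian")) sm$dispersion else 1
  theta <- if (family == "negative_binomial") fit$theta else NA_real_

  if (family == "quasibinomial") {
    ## quasi-likelihood has no true likelihood: take the underlying binomial
    ## fit for loglik / pseudo-R2, and an F-type drop-in-deviance test
    bfit <- suppressWarnings(glm(fml, data = d, family = binomial(), weights = w))
    bfit0 <- suppressWarnings(glm(null_fml, data = d, family = binomial(), weights = w))
    ll1 <- as.numeric(logLik(bfit)); ll0 <- as.numeric(logLik(bfit0))
    k <- attr(logLik(bfit), "df") + 1  # + dispersion
    df_diff <- fit0$df.residual - fit$df.residual
    lrt_p <- if (df_diff > 0) {
      Fstat <- ((fit0$deviance - fit$deviance) / df_diff) / dispersion
      pf(Fstat, df_diff, fit$df.residual, lower.tail = FALSE)
    } else 1
  } else {
    ll1 <- as.numeric(logLik(fit)); ll0 <- as.numeric(logLik(fit0))
    k <- attr(logLik(fit), "df")
    df_diff <- length(coef(fit)) - length(coef(fit0))
    lrt_p <- if (df_diff > 0) {
      pchisq(2 * (ll1 - ll0), df_diff, lower.tail = FALSE)
    } else 1
  }

  structure(list(
    family = family,
    coefficients = coefs,
    dispersion = dispersion,
    theta = theta,
    loglik = ll1,
    df_resid = fit$df.residual,
    n = n,
    k = k,
    aicc = aicc(ll1, k, n),
    nagelkerke_r2 = if (df_diff > 0) nagelkerke_r2(ll0, ll1, n) else 0,
    lrt_p = min(max(lrt_p, .Machine$double.xmin), 1),
    fit = fit
  ), class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("GLM (%s), n = %d, df_resid = %d\n", x$family, x$n, x$df_resid))
  print(round(x$coefficients, 4))
  cat(sprintf("AICc = %.2f  Nagelkerke R2 = %.3f  LRT p = %.4g\n",
              x$aicc, x$nagelkerke_r2, x$lrt_p))
  invisible(x)
}

#' AICc model selection over the urbanisation and invasion predictors
#'
#' Fits the candidate set (intercept-only; urbanisation; neophyte
#' proportion; both; both plus their interaction) and picks the model with
#' the lowest AICc, breaking ties toward fewer parameters. Under the default
#' rule the winner must beat the intercept-only model by at least 2 AICc
#' units, otherwise the null model is reported; `"simplest_within_2"`
#' instead returns the most parsimonious candidate within 2 AICc units of
#' the minimum. For the quasi-binomial family, selection uses QAICc with the
#' overdispersion estimated from the richest candidate.
#'
#' @param y response vector.
#' @param urbanisation,neophyte_prop predictor vectors.
#' @param family GLM family (see [fit_glm()]).
#' @param weights binomial trials where applicable.
#' @param aicc_rule `"beat_null"` (default) or `"simplest_within_2"`.
#' @return List with `chosen` (candidate name), `result` (the chosen
#'   [fit_glm()] result) and `table` (candidate, k, aicc, delta_aicc,
#'   chosen flag).
#' @export
select_model <- function(y, urbanisation, neophyte_prop, family = GLM_FAMILIES,
                         weights = NULL,
                         aicc_rule = c("beat_null", "simplest_within_2")) {
  family <- match.arg(family)
  aicc_rule <- match.arg(aicc_rule)
  preds <- list(
    null = NULL,
    urbanisation = data.frame(urbanisation = urbanisation),
    neophyte_prop = data.frame(neophyte_prop = neophyte_prop),
    `urbanisation+neophyte_prop` =
      data.frame(urbanisation = urbanisation, neophyte_prop = neophyte_prop),
    `urbanisation*neophyte_prop` =
      data.frame(urbanisation = urbanisation, neophyte_prop = neophyte_prop,
                 urbanisation_x_neophyte_prop = urbanisation * neophyte_prop)
  )
  fits <- lapply(names(preds), function(nm) {
    tryCatch(fit_glm(y, preds[[nm]], family, weights),
             error = function(e) {
               warning(sprintf("candidate '%s' failed: %s", nm, conditionMessage(e)),
                       call. = FALSE)
               NULL
             })
  })
  names(fits) <- names(preds)
  ok <- !vapply(fits, is.null, logical(1))
  if (!ok["null"]) stop_field("null model failed to fit; cannot select")
  fits <- fits[ok]

  crit <- vapply(fits, function(f) f$aicc, numeric(1))
  if (family == "quasibinomial") {
    ## QAICc with a common c-hat taken from the richest fitted candidate
    c_hat <- fits[[length(fits)]]$dispersion
    crit <- vapply(fits, function(f) {
      aicc(f$loglik / c_hat, f$k, f$n)
    }, numeric(1))
  }
  ks <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(crit, ks)          # ties go to fewer parameters
  best <- names(fits)[ord[1]]
  chosen <- if (aicc_rule == "beat_null") {
    if (crit[best] <= crit["null"] - 2) best else "null"
  } else {
    within <- names(fits)[crit - min(crit) < 2]
    within[which.min(ks[within])]
  }
  tab <- data.frame(
    candidate = names(fits), k = ks, aicc = crit,
    delta_aicc = crit - min(crit),
    chosen = names(fits) == chosen,
    row.names = NULL, stringsAsFactors = FALSE)
  list(chosen = chosen, result = fits[[chosen]], table = tab)
}
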