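## Community-level allergenicity metrics computed per plot, overall and by
## introduction status.

SUBSET_LEVELS <- c("all", "native", "archaeophyte", "neophyte", "non-native")

#' Validate and coerce a plot-by-species cover matrix
#'
#' @param x matrix or wide data frame (first column `plot_id` when a data
#'   frame) of per-cent cover values. Row sums may exceed 100 (layered
#'   vegetation).
#' @return Numeric matrix with plot ids as row names and species as column
#'   names.
#' @export
as_cover_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (names(x)[1] != "plot_id") {
      stop_field("wide cover table must have 'plot_id' as its first column")
    }
    m <- as.matrix(x[-1])
    rownames(m) <- as.character(x$plot_id)
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) stop_field("cover must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_field("cover matrix needs plot row names and species column names")
  }
  if (anyDuplicated(rownames(x))) stop_field("duplicate plot ids in cover matrix")
  if (anyNA(x) || any(x < 0)) stop_field("cover values must be >= 0 and non-missing")
  x
}

#' Species present in a plot
#'
#' @param cover cover matrix (see [as_cover_matrix()]).
#' @param plot plot id.
#' @return Character vector of species with cover strictly above zero.
#' @export
presence <- function(cover, plot) {
  cover <- as_cover_matrix(cover)
  if (!plot %in% rownames(cover)) stop_field("unknown plot id: %s", plot)
  colnames(cover)[cover[plot, ] > 0]
}

## rows of the annotated table in a status subset
subset_mask <- function(annotated, subset) {
  switch(subset,
    "all" = rep(TRUE, nrow(annotated)),
    "native" = annotated$status == "native",
    "archaeophyte" = annotated$status == "archaeophyte",
    "neophyte" = annotated$status == "neophyte",
    "non-native" = annotated$status %in% c("archaeophyte", "neophyte"),
    stop_field("unknown subset: %s", subset)
  )
}

## metric vector for one plot and one subset; NA where undefined
plot_subset_metrics <- function(annotated, cover, plot, subset) {
  pres <- cover[plot, ] > 0
  keep <- pres[annotated$species] & subset_mask(annotated, subset)
  sub <- annotated[keep, , drop = FALSE]
  covers <- cover[plot, sub$species]
  richness <- nrow(sub)
  al <- sub$is_allergenic
  al_rich <- sum(al)
  mols <- unique(unlist(sub$molecules[al], use.names = FALSE))
  fams <- unique(unlist(sub$families[al], use.names = FALSE))
  c(
    richness = richness,
    allergenic_richness = al_rich,
    allergenic_prop = if (richness > 0) al_rich / richness else NA_real_,
    allergenic_cover = if (al_rich > 0) sum(covers[al]) else 0,
    mean_pav = if (richness > 0) mean(sub$pav) else NA_real_,
    cwm_pav = if (richness > 0) sum(covers * sub$pav) / sum(covers) else NA_real_,
    molecule_richness = length(mols),
    family_richness = length(fams)
  )
}

#' Per-plot community allergenicity profile
#'
#' For every plot and status subset (all species, natives, archaeophytes,
#' neophytes, and non-natives = archaeophytes plus neophytes) computes:
#' species richness, allergenic richness, the proportion of allergenic
#' species, their cumulative per-cent cover, the unweighted community mean
#' PAV (all present species, non-allergenics contributing 0), the
#' cover-weighted mean PAV (CWM, the herbaceous-layer equivalent of the
#' iUGZA index), and the number of unique allergen molecules and protein
#' families carried by present species.
#'
#' @param annotated annotated species table from [annotate_species()].
#' @param cover cover matrix (see [as_cover_matrix()]).
#' @param subsets subsets to compute; default all five.
#' @return Tidy data frame with columns `plot_id`, `subset`, `metric`,
#'   `value`. Metrics undefined on empty subsets are `NA`.
#' @export
community_profile <- function(annotated, cover, subsets = SUBSET_LEVELS) {
  cover <- as_cover_matrix(cover)
  unknown <- setdiff(colnames(cover), annotated$species)
  if (length(unknown)) {
    stop_field("cover matrix species absent from trait table: %s",
               paste(unknown, collapse = ", "))
  }
  annotated <- annotated[annotated$species %in% colnames(cover), , drop = FALSE]
  res <- list()
  for (plot in rownames(cover)) {
    for (s in subsets) {
      v <- plot_subset_metrics(annotated, cover, plot, s)
      res[[length(res) + 1L]] <- data.frame(
        plot_id = plot, subset = s, metric = names(v), value = unname(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Proportion of neophytes per plot
#'
#' @param annotated annotated (or at least status-bearing) species table.
#' @param cover cover matrix.
#' @return Named numeric vector per plot: present neophytes / present
#'   species; `NA` for empty plots.
#' @export
neophyte_proportion <- function(annotated, cover) {
  cover <- as_cover_matrix(cover)
  status <- setNames(annotated$status, annotated$species)
  vapply(rownames(cover), function(p) {
    sp <- colnames(cover)[cover[p, ] > 0]
    if (!length(sp)) return(NA_real_)
    mean(status[sp] == "neophyte")
  }, numeric(1))
}

#' Rarefaction of allergen protein families
#'
#' Expected number of unique allergen protein families contributed by `k`
#' allergenic species drawn uniformly without replacement from a pool.
#' Offers a seeded Monte-Carlo mode (mean and standard deviation across
#' draws, plus the full rarefaction curve over 1..k) and an exact
#' combinatorial mode: E\[families at k\] =
#' sum over families f of 1 - C(n - m_f, k) / C(n, k), where m_f is the
#' number of pool species carrying family f.
#'
#' @param family_sets named list: species -> character vector of protein
#'   families (empty vectors allowed).
#' @param k subsample size, 1 <= k <= pool size.
#' @param n_draws Monte-Carlo replicates (default 1000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param mode `"montecarlo"` or `"exact"`.
#' @return List with `mean`, `sd` (0 in exact mode), and `curve`, a data
#'   frame with columns `k`, `mean`, `sd`, `exact`.
#' @export
rarefy_allergen_families <- function(family_sets, k, n_draws = 1000,
                                     seed = NULL,
                                     mode = c("montecarlo", "exact")) {
  mode <- match.arg(mode)
  n <- length(family_sets)
  if (n < 1) stop_field("empty species pool")
  if (k < 1 || k > n) stop_field("k must lie in 1..pool size (%d)", n)
  fams <- unique(unlist(family_sets, use.names = FALSE))
  m_f <- vapply(fams, function(f) {
    sum(vapply(family_sets, function(s) f %in% s, logical(1)))
  }, numeric(1))
  exact_at <- function(j) {
    sum(1 - exp(lchoose(n - m_f, j) - lchoose(n, j)))
  }
  exact_curve <- vapply(seq_len(k), exact_at, numeric(1))
  if (mode == "exact") {
    curve <- data.frame(k = seq_len(k), mean = exact_curve, sd = 0,
                        exact = exact_curve)
    return(list(mean = exact_curve[k], sd = 0, curve = curve))
  }
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(r) {
      idx <- sample.int(n, k)
      seen <- character(0)
      out <- numeric(k)
      for (j in seq_len(k)) {
        seen <- unique(c(seen, family_sets[[idx[j]]]))
        out[j] <- length(seen)
      }
      out
    }, numeric(k))
  })
  draws <- matrix(draws, nrow = k)
  mc_mean <- rowMeans(draws)
  mc_sd <- apply(draws, 1, sd)
  curve <- data.frame(k = seq_len(k), mean = mc_mean, sd = mc_sd,
                      exact = exact_curve)
  list(mean = mc_mean[k], sd = mc_sd[k], curve = curve)
}
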