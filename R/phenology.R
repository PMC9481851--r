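## Month-resolved flowering structure: monthly allergenicity profiles,
## allergy-season bounds and peaks, urbanisation clusters, and flowering
## summaries by introduction status.

MONTHLY_METRICS <- c("allergenic_richness", "allergenic_cover",
                     "molecule_richness", "family_richness")

#' Monthly flowering incidence matrix
#'
#' @param table species table with validated `flower_first`/`flower_last`.
#' @return Logical species-by-12 matrix, `TRUE` for months within the
#'   flowering period (inclusive).
#' @export
monthly_flowering_matrix <- function(table) {
  table <- validate_species_table(table)
  m <- outer(table$flower_first, 1:12, "<=") & outer(table$flower_last, 1:12, ">=")
  dimnames(m) <- list(table$species, 1:12)
  m
}

#' Monthly allergenicity profile of one plot
#'
#' For each calendar month, computes the chosen metric over the allergenic
#' species of the subset that are present in the plot and in flower that
#' month: a species count, a cover sum, or the cardinality of the union of
#' allergen molecules or protein families. `mean_monthly` averages the 12
#' monthly values, making it proportional to the area under the monthly
#' flowering curve.
#'
#' @param annotated annotated species table ([annotate_species()]).
#' @param cover cover matrix.
#' @param plot plot id.
#' @param subset status subset (see [community_profile()]).
#' @param metric one of `"allergenic_richness"`, `"allergenic_cover"`,
#'   `"molecule_richness"`, `"family_richness"`.
#' @return List with `values` (length-12 numeric) and `mean_monthly`.
#' @export
monthly_profile <- function(annotated, cover, plot, subset = "all",
                            metric = MONTHLY_METRICS) {
  metric <- match.arg(metric)
  cover <- as_cover_matrix(cover)
  if (!plot %in% rownames(cover)) stop_field("unknown plot id: %s", plot)
  keep <- (cover[plot, ] > 0)[annotated$species] &
    subset_mask(annotated, subset) & annotated$is_allergenic
  sub <- annotated[keep, , drop = FALSE]
  values <- numeric(12)
  if (nrow(sub)) {
    flow <- monthly_flowering_matrix(sub)
    covers <- cover[plot, sub$species]
    for (m in 1:12) {
      idx <- flow[, m]
      values[m] <- switch(metric,
        allergenic_richness = sum(idx),
        allergenic_cover = sum(covers[idx]),
        molecule_richness =
          length(unique(unlist(sub$molecules[idx], use.names = FALSE))),
        family_richness =
          length(unique(unlist(sub$families[idx], use.names = FALSE))))
    }
  }
  list(values = values, mean_monthly = mean(values))
}

#' Monthly profiles for all plots in tidy form
#'
#' @inheritParams monthly_profile
#' @param subsets,metrics vectors of subsets and metrics to compute.
#' @return Data frame `plot_id, subset, metric, month, value`.
#' @export
monthly_profiles <- function(annotated, cover, subsets = SUBSET_LEVELS,
                             metrics = MONTHLY_METRICS) {
  cover <- as_cover_matrix(cover)
  res <- list()
  for (plot in rownames(cover)) {
    for (s in subsets) {
      for (met in metrics) {
        pr <- monthly_profile(annotated, cover, plot, s, met)
        res[[length(res) + 1L]] <- data.frame(
          plot_id = plot, subset = s, metric = met, month = 1:12,
          value = pr$values, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Allergy-season bounds and flowering peak of a plot
#'
#' Season bounds are the first and last month with at least one allergenic
#' species in flower; the peak is the earliest month attaining the maximum
#' allergenic richness. Plots without allergenic species return `NA`.
#'
#' @inheritParams monthly_profile
#' @return For `season_bounds`: named numeric `c(first, last)`; for
#'   `peak_month`: a month or `NA`.
#' @export
season_bounds <- function(annotated, cover, plot, subset = "all") {
  v <- monthly_profile(annotated, cover, plot, subset, "allergenic_richness")$values
  on <- which(v > 0)
  if (!length(on)) return(c(first = NA_real_, last = NA_real_))
  c(first = min(on), last = max(on))
}

#' @rdname season_bounds
#' @export
peak_month <- function(annotated, cover, plot, subset = "all") {
  v <- monthly_profile(annotated, cover, plot, subset, "allergenic_richness")$values
  if (all(v == 0)) return(NA_real_)
  which.max(v)  # earliest month attaining the maximum
}

#' Urbanisation clusters from imperviousness
#'
#' Classifies plots into three urbanisation clusters by the percentage of
#' impervious surfaces in the surrounding buffer: near rural below 7,
#' low urban between 7 and 30 (bounds inclusive), high urban above 30.
#'
#' @param impervious_pct numeric vector in \[0, 100\].
#' @return Factor with levels `near_rural`, `low_urban`, `high_urban`.
#' @export
urbanisation_clusters <- function(impervious_pct) {
  if (anyNA(impervious_pct) || any(impervious_pct < 0 | impervious_pct > 100)) {
    stop_field("impervious_pct must lie in [0, 100]")
  }
  lab <- ifelse(impervious_pct < 7, "near_rural",
                ifelse(impervious_pct <= 30, "low_urban", "high_urban"))
  factor(lab, levels = c("near_rural", "low_urban", "high_urban"))
}

#' Cluster-level monthly flowering curves
#'
#' For each urbanisation cluster, status subset and month, counts the unique
#' allergenic species present anywhere in the cluster's plots and in flower
#' that month, together with the unique allergen protein families they
#' carry.
#'
#' @param annotated annotated species table.
#' @param cover cover matrix.
#' @param env plot environment table with `plot_id` and `impervious_pct`.
#' @return Data frame `cluster, subset, month, unique_species,
#'   unique_families`.
#' @export
cluster_monthly_curves <- function(annotated, cover, env,
                                   subsets = SUBSET_LEVELS) {
  cover <- as_cover_matrix(cover)
  env <- env[match(rownames(cover), env$plot_id), , drop = FALSE]
  cl <- urbanisation_clusters(env$impervious_pct)
  flow <- monthly_flowering_matrix(annotated)
  res <- list()
  for (g in levels(cl)) {
    plots <- rownames(cover)[cl == g]
    pres <- if (length(plots)) {
      colnames(cover)[colSums(cover[plots, , drop = FALSE] > 0) > 0]
    } else character()
    for (s in subsets) {
      keep <- annotated$species %in% pres & subset_mask(annotated, s) &
        annotated$is_allergenic
      sub <- annotated[keep, , drop = FALSE]
      for (m in 1:12) {
        idx <- if (nrow(sub)) flow[sub$species, m] else logical(0)
        res[[length(res) + 1L]] <- data.frame(
          cluster = g, subset = s, month = m,
          unique_species = sum(idx),
          unique_families = length(unique(unlist(sub$families[idx],
                                                 use.names = FALSE))),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flowering summaries by introduction status
#'
#' Per-species first flowering month, last flowering month and flowering
#' duration (months), grouped by introduction status; the natural input for
#' [bootstrap_group_compare()].
#'
#' @param table species trait table.
#' @return Data frame `species, status, first, last, duration`.
#' @export
flowering_stats_by_status <- function(table) {
  table <- validate_species_table(table)
  data.frame(
    species = table$species,
    status = factor(table$status, levels = STATUS_LEVELS),
    first = table$flower_first,
    last = table$flower_last,
    duration = table$flower_last - table$flower_first + 1,
    stringsAsFactors = FALSE)
}
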