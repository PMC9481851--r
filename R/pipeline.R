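## End-to-end pipeline: input reading/validation, the full gradient
## analysis (Table-1/2-shaped GLM report, AICc selection, dbRDA turnover,
## Moran's I diagnostics, phenology statistics) and report writing.

## family mapping used throughout the report
METRIC_FAMILY <- c(
  richness = "poisson",
  allergenic_richness = "poisson",
  allergenic_prop = "quasibinomial",
  allergenic_cover = "gaussian",
  mean_pav = "gaussian",
  cwm_pav = "gaussian",
  molecule_richness = "negative_binomial",
  family_richness = "poisson",
  mean_monthly_allergenic_richness = "gaussian",
  mean_monthly_allergenic_cover = "gaussian",
  mean_monthly_molecule_richness = "gaussian",
  mean_monthly_family_richness = "gaussian")

#' Read and validate study inputs from CSV files
#'
#' Expects the five plain-text inputs written by [write_study()]:
#' `species.csv`, `catalog.csv`, `direct_hits.csv`, `cover.csv` (wide,
#' first column `plot_id`) and `environment.csv`. Cross-file consistency is
#' enforced: every cover column must appear in the species table, plot ids
#' must be unique and shared with the environment table.
#'
#' @param dir directory holding the five CSVs.
#' @return List `species`, `catalog`, `cover`, `env` (and `truth` when a
#'   `truth.json` sidecar is present).
#' @export
read_study <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_field("missing input file: %s", p)
    p
  }
  species <- utils::read.csv(path("species.csv"), stringsAsFactors = FALSE)
  species <- validate_species_table(species)
  catalog <- read_allergen_catalog(path("catalog.csv"), path("direct_hits.csv"))
  wide <- utils::read.csv(path("cover.csv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(wide) == 0 || ncol(wide) < 2) stop_field("empty cover matrix")
  cover <- as_cover_matrix(wide)
  unknown <- setdiff(colnames(cover), species$species)
  if (length(unknown)) {
    stop_field("cover.csv species absent from species.csv: %s",
               paste(unknown, collapse = ", "))
  }
  env <- utils::read.csv(path("environment.csv"), stringsAsFactors = FALSE)
  need <- c("plot_id", "impervious_pct", "x", "y")
  miss <- setdiff(need, names(env))
  if (length(miss)) {
    stop_field("environment.csv lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(env$plot_id)) stop_field("duplicate plot ids in environment.csv")
  if (!setequal(env$plot_id, rownames(cover))) {
    stop_field("plot ids differ between cover.csv and environment.csv")
  }
  if (any(env$impervious_pct < 0 | env$impervious_pct > 100)) {
    stop_field("impervious_pct must lie in [0, 100]")
  }
  out <- list(species = species, catalog = catalog, cover = cover, env = env)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}

## wide metric table: plots x metrics for one subset
subset_metric_table <- function(profile, monthly, subset) {
  pr <- profile[profile$subset == subset, ]
  wide <- stats::reshape(pr[c("plot_id", "metric", "value")],
                         idvar = "plot_id", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  mm <- monthly[monthly$subset == subset, ]
  agg <- stats::aggregate(value ~ plot_id + metric, mm, mean)
  for (met in unique(agg$metric)) {
    sub_a <- agg[agg$metric == met, ]
    wide[[paste0("mean_monthly_", met)]] <-
      sub_a$value[match(wide$plot_id, sub_a$plot_id)]
  }
  wide
}

## plot x entity incidence matrices for turnover analyses
incidence_matrices <- function(annotated, cover) {
  al <- annotated[annotated$is_allergenic, , drop = FALSE]
  pres <- cover[, al$species, drop = FALSE] > 0
  mols <- unique(unlist(al$molecules, use.names = FALSE))
  fams <- unique(unlist(al$families, use.names = FALSE))
  mol_m <- matrix(0, nrow(cover), length(mols),
                  dimnames = list(rownames(cover), mols))
  fam_m <- matrix(0, nrow(cover), length(fams),
                  dimnames = list(rownames(cover), fams))
  for (i in seq_len(nrow(al))) {
    p <- pres[, i]
    if (length(al$molecules[[i]])) mol_m[p, al$molecules[[i]]] <- 1
    if (length(al$families[[i]])) fam_m[p, al$families[[i]]] <- 1
  }
  list(species = pres * 1, molecule = mol_m, family = fam_m)
}

#' Run the full gradient analysis
#'
#' Annotates the species table, computes the community and monthly
#' profiles, and fits the full report: for every status subset and
#' community metric, a GLM against urbanisation (% impervious surfaces) and
#' against the proportion of neophytes (family per the fixed mapping:
#' counts Poisson, molecule richness negative binomial, proportions
#' quasi-binomial with plot richness as trials, cover and PAV means
#' Gaussian), AICc model selection over both predictors with interaction,
#' Moran's I on the residuals of each urbanisation model, distance-based
#' redundancy analyses of Jaccard (and optionally Bray-Curtis) turnover in
#' allergenic species, allergen molecules and protein families, and
#' phenology statistics (allergy-season bounds and peaks with Spearman
#' trends, flowering distributions by status with bootstrap comparisons).
#' Plots where a subset has no members yield missing metric values and are
#' dropped from that subset's models (residual df varies accordingly);
#' failures of individual cells are recorded and the run continues.
#'
#' @param study list with `species`, `catalog`, `cover`, `env` (see
#'   [read_study()] / [simulate_study()]).
#' @param n_perm dbRDA permutations (default 999).
#' @param n_boot bootstrap resamples for phenology comparisons.
#' @param ci_level confidence level for bootstrap intervals.
#' @param seed integer seed controlling every stochastic step.
#' @param run_dbrda set `FALSE` to skip the ordination stage.
#' @param bray also run Bray-Curtis dbRDA on species covers.
#' @param aicc_rule model-selection rule (see [select_model()]).
#' @return List of tidy data frames: `glm_table` (subset, metric,
#'   predictor, family, df, coef, se, r2, p, note), `selection`,
#'   `moran`, `dbrda`, `season`, `season_trends`, `phenology_groups`,
#'   `profile`, `monthly`, and `meta`.
#' @export
run_full_analysis <- function(study, n_perm = 999, n_boot = 1000,
                              ci_level = 0.90, seed = NULL,
                              run_dbrda = TRUE, bray = FALSE,
                              aicc_rule = "beat_null") {
  annotated <- annotate_species(study$species, study$catalog)
  cover <- as_cover_matrix(study$cover)
  env <- study$env[match(rownames(cover), study$env$plot_id), , drop = FALSE]
  env$neophyte_prop <- neophyte_proportion(annotated, cover)

  profile <- community_profile(annotated, cover)
  monthly <- monthly_profiles(annotated, cover)

  predictors <- list(impervious_pct = env$impervious_pct,
                     neophyte_prop = env$neophyte_prop)

  glm_rows <- list(); sel_rows <- list(); moran_rows <- list()
  for (subset in SUBSET_LEVELS) {
    wide <- subset_metric_table(profile, monthly, subset)
    wide <- wide[match(rownames(cover), wide$plot_id), , drop = FALSE]
    trials <- wide$richness
    for (metric in names(METRIC_FAMILY)) {
      y <- wide[[metric]]
      if (is.null(y)) next
      fam <- METRIC_FAMILY[[metric]]
      w <- if (fam == "quasibinomial") trials else NULL
      for (pn in names(predictors)) {
        res <- tryCatch(
          fit_glm(y, data.frame(x = predictors[[pn]]), fam, weights = w),
          error = function(e) e)
        if (inherits(res, "error")) {
          glm_rows[[length(glm_rows) + 1L]] <- data.frame(
            subset = subset, metric = metric, predictor = pn,
            model_family = fam, df = NA, coef = NA, se = NA, r2 = NA, p = NA,
            note = conditionMessage(res), stringsAsFactors = FALSE)
          next
        }
        glm_rows[[length(glm_rows) + 1L]] <- data.frame(
          subset = subset, metric = metric, predictor = pn,
          model_family = fam, df = res$df_resid,
          coef = res$coefficients[2, "estimate"],
          se = res$coefficients[2, "se"],
          r2 = res$nagelkerke_r2, p = res$lrt_p, note = "",
          stringsAsFactors = FALSE)
        if (pn == "impervious_pct") {
          mres <- tryCatch({
            keep <- !is.na(y) & !is.na(predictors[[pn]])
            r <- residuals(res$fit, type = "pearson")
            morans_i(r, as.matrix(env[keep, c("x", "y")]))
          }, error = function(e) e)
          moran_rows[[length(moran_rows) + 1L]] <- if (inherits(mres, "error")) {
            data.frame(subset = subset, metric = metric, observed_i = NA,
                       expected_i = NA, sd = NA, p = NA,
                       note = conditionMessage(mres), stringsAsFactors = FALSE)
          } else {
            data.frame(subset = subset, metric = metric,
                       observed_i = mres$observed_i,
                       expected_i = mres$expected_i, sd = mres$sd, p = mres$p,
                       note = "", stringsAsFactors = FALSE)
          }
        }
      }
      sel <- tryCatch(
        suppressWarnings(select_model(y, env$impervious_pct, env$neophyte_prop,
                                      fam, weights = w,
                                      aicc_rule = aicc_rule)),
        error = function(e) e)
      if (!inherits(sel, "error")) {
        tb <- sel$table
        tb$subset <- subset; tb$metric <- metric
        sel_rows[[length(sel_rows) + 1L]] <- tb
      }
    }
  }
  glm_table <- do.call(rbind, glm_rows)
  selection <- if (length(sel_rows)) do.call(rbind, sel_rows) else NULL
  moran <- do.call(rbind, moran_rows)

  dbrda_tab <- NULL
  if (run_dbrda) {
    inc <- incidence_matrices(annotated, cover)
    db_rows <- list()
    lvl <- c("species", "molecule", "family")
    for (i in seq_along(lvl)) {
      m <- inc[[lvl[i]]]
      keep <- rowSums(m) > 0
      methods <- if (bray && lvl[i] == "species") c("jaccard", "bray_curtis") else "jaccard"
      for (meth in methods) {
        mat <- if (meth == "bray_curtis") cover[keep, colnames(m), drop = FALSE] else m[keep, , drop = FALSE]
        res <- tryCatch({
          D <- dissimilarity(mat, meth)
          dbrda_analysis(D, env[keep, c("impervious_pct", "neophyte_prop")],
                         n_perm = n_perm,
                         seed = if (is.null(seed)) NULL else seed + 100 + i)
        }, error = function(e) e)
        db_rows[[length(db_rows) + 1L]] <- if (inherits(res, "error")) {
          data.frame(level = lvl[i], method = meth, n_plots = sum(keep),
                     r2 = NA, pseudo_f = NA, p = NA, n_perm = n_perm,
                     note = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          data.frame(level = lvl[i], method = meth, n_plots = sum(keep),
                     r2 = res$r2, pseudo_f = res$pseudo_f, p = res$p_perm,
                     n_perm = n_perm, note = "", stringsAsFactors = FALSE)
        }
      }
    }
    dbrda_tab <- do.call(rbind, db_rows)
  }

  ## phenology: per-plot season bounds/peaks + trends with both gradients
  season <- do.call(rbind, lapply(rownames(cover), function(p) {
    sb <- season_bounds(annotated, cover, p)
    data.frame(plot_id = p, season_start = sb[["first"]],
               season_end = sb[["last"]],
               peak = peak_month(annotated, cover, p),
               stringsAsFactors = FALSE)
  }))
  season_trends <- do.call(rbind, lapply(
    c("season_start", "season_end", "peak"), function(v) {
      do.call(rbind, lapply(names(predictors), function(pn) {
        st <- tryCatch(spearman_test(season[[v]], predictors[[pn]]),
                       error = function(e) NULL)
        if (is.null(st)) return(NULL)
        data.frame(variable = v, predictor = pn, rho = st$rho, p = st$p,
                   n = st$n, stringsAsFactors = FALSE)
      }))
    }))

  flw <- flowering_stats_by_status(study$species)
  phen_groups <- do.call(rbind, lapply(c("first", "last", "duration"),
    function(v) {
      bc <- bootstrap_group_compare(flw[[v]], flw$status, n_boot = n_boot,
                                    seed = if (is.null(seed)) NULL else seed + 200,
                                    ci_level = ci_level)
      bc$variable <- v
      bc
    }))

  list(glm_table = glm_table, selection = selection, moran = moran,
       dbrda = dbrda_tab, season = season, season_trends = season_trends,
       phenology_groups = phen_groups, profile = profile, monthly = monthly,
       annotated = annotated, env = env,
       meta = list(seed = seed, n_perm = n_perm, n_boot = n_boot,
                   ci_level = ci_level, aicc_rule = aicc_rule,
                   package_version = as.character(utils::packageVersion("allergiscape"))))
}

#' Write the analysis report as tidy CSVs
#'
#' @param results list from [run_full_analysis()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("glm_table", "selection", "moran", "dbrda", "season",
            "season_trends", "phenology_groups", "profile", "monthly")
  for (t in tabs) {
    if (!is.null(results[[t]])) {
      utils::write.csv(results[[t]], file.path(dir, paste0(t, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(results$meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
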