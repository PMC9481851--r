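## Seeded synthetic vegetation-survey generator: species pool with allergen
## catalog, urbanisation landscape, and plot-by-species cover matrices with
## known ground-truth effect sizes.

#' Configuration of the synthetic study
#'
#' Defaults emulate a 56-plot dry-grassland survey of 216 herbaceous
#' species: introduction-status shares 69/17/14% (native / archaeophyte /
#' neophyte), 34.3% allergenic species (equal across statuses, all grasses
#' allergenic), 1-13 allergen molecules per catalogued species (median 6)
#' with molecule records covering 53/74 of allergenic species, protein-family
#' pools of 19/17/26 per status, about 23% wind-pollinated species
#' concentrated among allergenics, status-specific flowering (mean durations
#' 2.4/3.6/2.7 months, neophytes starting about a month later), an
#' imperviousness gradient with target Spearman correlation 0.46 to the
#' invasion propensity, and a plot-level allergenic-cover gradient of 0.256
#' cover-% per impervious-%.
#'
#' @param n_plots,n_species study dimensions.
#' @param status_props named shares of native/archaeophyte/neophyte species.
#' @param allergenic_frac fraction of allergenic species.
#' @param grass_frac fraction of grass (Poaceae) species, all allergenic.
#' @param molecule_coverage fraction of allergenic species whose taxon key
#'   has catalog molecule records.
#' @param mol_meanlog,mol_sdlog log-normal molecule-count parameters,
#'   discretised and clipped to 1..13.
#' @param family_pool_sizes protein-family pool size per status.
#' @param rho_target target Spearman correlation between imperviousness and
#'   invasion propensity (Gaussian copula).
#' @param cover_baseline,cover_slope,cover_noise_sd plot-level allergenic
#'   cumulative cover model: baseline + slope x impervious_pct + noise.
#' @param nonallergenic_cover_target expected cumulative cover of
#'   non-allergenic species per plot.
#' @param first_month_mean,duration_mean status-specific flowering targets
#'   (months).
#' @param wind_frac overall fraction of wind-pollinated species.
#' @param occupancy_shape Beta parameters of per-species occupancy.
#' @param neophyte_tilt logit-scale slope of neophyte occupancy on the
#'   plot invasion propensity.
#' @param cover_meanlog,cover_sdlog within-plot log-normal cover draw.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plots = 56,
                             n_species = 216,
                             status_props = c(native = 0.69,
                                              archaeophyte = 0.17,
                                              neophyte = 0.14),
                             allergenic_frac = 0.343,
                             grass_frac = 36 / 216,
                             molecule_coverage = 53 / 74,
                             mol_meanlog = log(6),
                             mol_sdlog = 0.55,
                             family_pool_sizes = c(native = 19,
                                                   archaeophyte = 17,
                                                   neophyte = 26),
                             rho_target = 0.46,
                             cover_baseline = 46,
                             cover_slope = 0.256,
                             cover_noise_sd = 15,
                             nonallergenic_cover_target = 45,
                             first_month_mean = c(native = 5,
                                                  archaeophyte = 5,
                                                  neophyte = 6),
                             duration_mean = c(native = 2.4,
                                               archaeophyte = 3.6,
                                               neophyte = 2.7),
                             wind_frac = 0.23,
                             occupancy_shape = c(0.8, 4.5),
                             neophyte_tilt = 2,
                             cover_meanlog = 1.2,
                             cover_sdlog = 1) {
  cfg <- list(n_plots = n_plots, n_species = n_species,
              status_props = status_props, allergenic_frac = allergenic_frac,
              grass_frac = grass_frac, molecule_coverage = molecule_coverage,
              mol_meanlog = mol_meanlog, mol_sdlog = mol_sdlog,
              family_pool_sizes = family_pool_sizes, rho_target = rho_target,
              cover_baseline = cover_baseline, cover_slope = cover_slope,
              cover_noise_sd = cover_noise_sd,
              nonallergenic_cover_target = nonallergenic_cover_target,
              first_month_mean = first_month_mean,
              duration_mean = duration_mean, wind_frac = wind_frac,
              occupancy_shape = occupancy_shape,
              neophyte_tilt = neophyte_tilt,
              cover_meanlog = cover_meanlog, cover_sdlog = cover_sdlog)
  if (abs(sum(cfg$status_props) - 1) > 1e-8) {
    stop_field("status_props must sum to 1")
  }
  if (cfg$n_plots < 2 || cfg$n_species < 10) stop_field("study too small")
  if (cfg$allergenic_frac < 0 || cfg$allergenic_frac > 1) {
    stop_field("allergenic_frac must lie in [0, 1]")
  }
  if (any(cfg$family_pool_sizes < 13)) {
    stop_field("family pools must hold at least 13 families (max molecules per key)")
  }
  if (!all(is.finite(c(cfg$cover_slope, cfg$neophyte_tilt)))) {
    stop_field("effect sizes must be finite")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

## global protein-family universe with overlapping per-status pools
family_pools <- function(sizes) {
  ## native pool starts at family 1, archaeophyte and neophyte pools are
  ## shifted so pools overlap partially (families shared between statuses)
  all_ids <- function(from, size) sprintf("famF%02d", seq(from, from + size - 1))
  list(native = all_ids(1, sizes[["native"]]),
       archaeophyte = all_ids(8, sizes[["archaeophyte"]]),
       neophyte = all_ids(15, sizes[["neophyte"]]))
}

#' Generate a synthetic species pool and allergen catalog
#'
#' Draws taxonomy (genera of 1-3 congeners within status, grasses in
#' tribes), introduction status, allergenicity (all grasses, plus whole
#' genera anchored on a direct-hit species), an allergen catalog with
#' genus/tribe keys carrying 1-13 molecules and status-pool protein
#' families, pollination syndromes and status-specific flowering phenology.
#' The output passes the annotation-module rules unchanged: classifying the
#' table against the returned catalog reproduces the generated allergenic
#' flags.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return List with `species` (trait table), `catalog`
#'   ([allergen_catalog()]) and `truth` (generating parameters and realised
#'   counts).
#' @export
generate_species_pool <- function(config = synthetic_config(), seed = NULL) {
  with_seed(seed, {
    n <- config$n_species
    n_status <- largest_remainder(n, config$status_props)
    statuses <- rep(names(n_status), n_status)
    n_allergenic <- round(config$allergenic_frac * n)
    ## grasses are allergenic by rule, so they cannot exceed the target
    n_grass <- min(round(config$grass_frac * n), n_allergenic)
    g_status <- largest_remainder(n_grass, config$status_props)
    a_status <- pmax(round(config$allergenic_frac * n_status), g_status)

    species <- sprintf("Species %03d", seq_len(n))
    df <- data.frame(species = species, genus = NA_character_,
                     family = NA_character_, tribe = NA_character_,
                     status = statuses, stringsAsFactors = FALSE)

    tribes <- sprintf("Tribe%s", LETTERS[1:6])
    is_grass <- logical(n)
    allergenic <- logical(n)
    direct_hits <- character(0)
    key_tab <- list()  # key -> list(rank, members)

    for (s in names(n_status)) {
      rows <- which(df$status == s)
      ## grasses first
      g_rows <- rows[seq_len(g_status[[s]])]
      if (length(g_rows)) {
        df$family[g_rows] <- "Poaceae"
        df$tribe[g_rows] <- sample(tribes, length(g_rows), replace = TRUE)
        df$genus[g_rows] <- sprintf("Poagen_%s_%02d", substr(s, 1, 3),
                                    seq_along(g_rows))
        is_grass[g_rows] <- TRUE
        allergenic[g_rows] <- TRUE
      }
      ## non-grass species partitioned into genera of 1-3 congeners
      ng_rows <- setdiff(rows, g_rows)
      sizes <- integer(0)
      while (sum(sizes) < length(ng_rows)) {
        sizes <- c(sizes, sample(c(1L, 1L, 1L, 2L, 2L, 3L), 1))
      }
      if (sum(sizes) > length(ng_rows)) {
        sizes[length(sizes)] <- sizes[length(sizes)] -
          (sum(sizes) - length(ng_rows))
      }
      sizes <- sizes[sizes > 0]
      genus_of <- rep(seq_along(sizes), sizes)
      df$genus[ng_rows] <- sprintf("Genus_%s_%03d", substr(s, 1, 3),
                                   genus_of)
      df$family[ng_rows] <- sprintf("Family_%02d",
                                    1 + (genus_of + sample.int(29, 1)) %% 30)
      ## allergenic genera: whole genera until the status target is met
      need <- a_status[[s]] - g_status[[s]]
      if (need > 0) {
        gsplit <- split(ng_rows, genus_of)
        for (gi in sample(seq_along(gsplit))) {
          if (need <= 0) break
          members <- gsplit[[gi]]
          if (length(members) > need + 1) next
          allergenic[members] <- TRUE
          direct_hits <- c(direct_hits, df$species[members[1]])
          key <- df$genus[members[1]]
          key_tab[[key]] <- list(rank = "genus", members = df$species[members])
          need <- need - length(members)
        }
      }
    }
    ## tribe keys collect all grasses of a tribe
    for (tr in unique(df$tribe[is_grass])) {
      key_tab[[tr]] <- list(rank = "tribe",
                            members = df$species[is_grass & df$tribe == tr])
    }

    ## choose which keys get molecule records so that coverage of
    ## allergenic species approximates the target
    n_covered_target <- round(config$molecule_coverage * sum(allergenic))
    keys <- names(key_tab)
    covered <- 0
    entries <- list()
    pools <- family_pools(config$family_pool_sizes)
    status_of <- setNames(df$status, df$species)
    for (key in sample(keys)) {
      if (covered >= n_covered_target) break
      info <- key_tab[[key]]
      n_mol <- min(max(round(rlnorm(1, config$mol_meanlog, config$mol_sdlog)), 1), 13)
      owner <- names(which.max(table(status_of[info$members])))
      fams <- sample(pools[[owner]], n_mol)
      entries[[key]] <- data.frame(
        taxon_key = key, key_rank = info$rank,
        molecule = sprintf("mol_%s_%02d", key, seq_len(n_mol)),
        protein_family = fams, stringsAsFactors = FALSE)
      covered <- covered + length(info$members)
    }
    catalog <- allergen_catalog(do.call(rbind, entries), direct_hits)

    ## pollination: grasses wind; remaining wind budget mostly to
    ## allergenic forbs
    pol <- rep("biotic", n)
    pol[is_grass] <- "wind"
    extra_wind <- max(round(config$wind_frac * n) - sum(is_grass), 0)
    cand <- which(!is_grass & allergenic)
    cand2 <- which(!is_grass & !allergenic)
    take1 <- min(round(extra_wind * 0.75), length(cand))
    wind_rows <- c(sample(cand, take1),
                   sample(cand2, min(extra_wind - take1, length(cand2))))
    pol[wind_rows] <- "wind"
    rest <- setdiff(which(!is_grass), wind_rows)
    pol[rest] <- sample(c("biotic", "mixed", "none"), length(rest),
                        replace = TRUE, prob = c(0.70, 0.15, 0.15))
    df$pollination <- pol

    ## phenology: status-specific duration and onset
    dur <- integer(n); first <- integer(n)
    for (s in names(n_status)) {
      rows <- which(df$status == s)
      dm <- config$duration_mean[[s]]
      dur[rows] <- pmin(1 + rpois(length(rows), max(dm - 1, 0)), 8)
      f <- round(rnorm(length(rows), config$first_month_mean[[s]], 1.3))
      first[rows] <- pmin(pmax(f, 1), 12 - dur[rows] + 1)
    }
    df$flower_first <- first
    df$flower_last <- first + dur - 1

    ## allergenicity scores: tied to molecule counts where known
    df$allergenicity_score <- 0L
    cl <- classify_allergenic(df, catalog)
    mols <- assign_molecules(cl, catalog)
    n_mol_sp <- vapply(mols, length, integer(1))
    score <- integer(n)
    has_mol <- allergenic & n_mol_sp > 0
    score[has_mol] <- as.integer(cut(n_mol_sp[has_mol], c(0, 2, 5, 8, 13)))
    score[allergenic & !has_mol] <- sample(1:2, sum(allergenic & !has_mol),
                                           replace = TRUE)
    df$allergenicity_score <- score

    df <- df[c("species", "genus", "family", "tribe", "status", "pollination",
               "allergenicity_score", "flower_first", "flower_last")]
    validate_species_table(df, require_tribe = TRUE)

    truth <- list(
      n_species = n, n_status = as.list(n_status),
      n_allergenic = sum(allergenic), n_grass = sum(is_grass),
      n_with_molecules = sum(has_mol),
      allergenic_frac = sum(allergenic) / n,
      wind_frac = mean(df$pollination == "wind"),
      duration_mean = as.list(config$duration_mean),
      first_month_mean = as.list(config$first_month_mean))
    list(species = df, catalog = catalog, truth = truth)
  })
}

#' Generate the plot landscape: urbanisation, invasion propensity, space
#'
#' Imperviousness is log-uniform on \[1, 100\] (balancing the near-rural /
#' low-urban / high-urban clusters); a latent invasion propensity in (0, 1)
#' is tied to it by a Gaussian copula with the target Spearman correlation;
#' plot coordinates are continuous uniform (no duplicates almost surely).
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return Data frame `plot_id, impervious_pct, invasion, x, y`.
#' @export
generate_landscape <- function(config = synthetic_config(), seed = NULL) {
  with_seed(seed, {
    n <- config$n_plots
    r <- 2 * sin(pi * config$rho_target / 6)  # copula: Pearson from Spearman
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    u1 <- pnorm(z1); u2 <- pnorm(z2)
    data.frame(
      plot_id = sprintf("plot_%03d", seq_len(n)),
      impervious_pct = 100^u1,
      invasion = u2,
      x = runif(n, 0, 30), y = runif(n, 0, 30),
      stringsAsFactors = FALSE)
  })
}

#' Generate plot-by-species cover matrices
#'
#' Species occurrence follows per-species Beta occupancies, tilted on the
#' logit scale toward neophytes in plots with high invasion propensity.
#' Within-plot covers are log-normal and then rescaled at the plot level so
#' that cumulative allergenic cover follows baseline + slope x
#' impervious_pct + Gaussian noise (the gradient is injected at the plot
#' level, matching the plot-level cover regressions), and non-allergenic
#' cover fluctuates around its target.
#'
#' @param config a [synthetic_config()].
#' @param pool output of [generate_species_pool()].
#' @param env output of [generate_landscape()].
#' @param seed integer seed.
#' @return Numeric plot-by-species cover matrix (per-cent units).
#' @export
generate_communities <- function(config = synthetic_config(), pool, env,
                                 seed = NULL) {
  with_seed(seed, {
    sp <- classify_allergenic(pool$species, pool$catalog)
    n_sp <- nrow(sp); n_pl <- nrow(env)
    occ_p <- rbeta(n_sp, config$occupancy_shape[1], config$occupancy_shape[2])
    occ_p <- pmin(pmax(occ_p, 0.02), 0.9)
    base_logit <- qlogis(occ_p)
    inv_c <- env$invasion - mean(env$invasion)
    neo <- sp$status == "neophyte"
    cover <- matrix(0, n_pl, n_sp,
                    dimnames = list(env$plot_id, sp$species))
    for (j in seq_len(n_pl)) {
      lp <- base_logit
      lp[neo] <- lp[neo] + config$neophyte_tilt * inv_c[j]
      pres <- rbinom(n_sp, 1, plogis(lp)) == 1
      ## keep plots interpretable: at least 5 species, one of them allergenic
      if (sum(pres) < 5) {
        pres[order(plogis(lp), decreasing = TRUE)[1:5]] <- TRUE
      }
      if (!any(pres & sp$is_allergenic)) {
        pres[which(sp$is_allergenic)[which.max(occ_p[sp$is_allergenic])]] <- TRUE
      }
      raw <- rlnorm(sum(pres), config$cover_meanlog, config$cover_sdlog)
      cv <- numeric(n_sp); cv[pres] <- raw
      al <- sp$is_allergenic & pres
      target_al <- config$cover_baseline +
        config$cover_slope * env$impervious_pct[j] +
        rnorm(1, 0, config$cover_noise_sd)
      target_al <- max(target_al, 2)
      if (any(al)) cv[al] <- cv[al] * target_al / sum(cv[al])
      nal <- pres & !sp$is_allergenic
      target_nal <- max(config$nonallergenic_cover_target + rnorm(1, 0, 8), 2)
      if (any(nal)) cv[nal] <- cv[nal] * target_nal / sum(cv[nal])
      cover[j, ] <- cv
    }
    cover
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the three generators with a deterministic seed chain (`seed`,
#' `seed + 1`, `seed + 2`) and optionally writes the study as plain-text
#' inputs: `species.csv`, `catalog.csv`, `direct_hits.csv`, `cover.csv`
#' (wide), `environment.csv`, plus a `truth.json` sidecar with every
#' generating parameter, so recovery tests are self-describing.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (keep below 2^31 - 3).
#' @param dir output directory, or `NULL` to skip writing.
#' @return List `species`, `catalog`, `cover`, `env`, `truth`.
#' @export
simulate_study <- function(config = synthetic_config(), seed = NULL,
                           dir = NULL) {
  pool <- generate_species_pool(config, seed)
  env <- generate_landscape(config, if (is.null(seed)) NULL else seed + 1)
  cover <- generate_communities(config, pool, env,
                                if (is.null(seed)) NULL else seed + 2)
  truth <- c(pool$truth, list(
    seed = seed,
    config = unclass(config),
    realized_rho_impervious_invasion =
      spearman_test(env$impervious_pct, env$invasion)$rho))
  study <- list(species = pool$species, catalog = pool$catalog,
                cover = cover, env = env, truth = truth)
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a study to CSV inputs plus a truth sidecar
#'
#' @param study list as returned by [simulate_study()] or [read_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(study$catalog$entries, file.path(dir, "catalog.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(species = study$catalog$direct_hits),
                   file.path(dir, "direct_hits.csv"), row.names = FALSE)
  wide <- data.frame(plot_id = rownames(study$cover), study$cover,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(wide, file.path(dir, "cover.csv"), row.names = FALSE)
  utils::write.csv(study$env, file.path(dir, "environment.csv"),
                   row.names = FALSE)
  if (!is.null(study$truth)) {
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(dir)
}
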