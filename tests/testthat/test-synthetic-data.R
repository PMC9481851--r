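test_that("species pool hits the configured composition", {
  pool <- generate_species_pool(seed = 101)
  tab <- pool$species
  expect_equal(nrow(tab), 216)
  ## largest-remainder apportionment of the status shares
  expect_equal(sum(tab$status == "native"), 149)
  expect_equal(sum(tab$status == "archaeophyte"), 37)
  expect_equal(sum(tab$status == "neophyte"), 30)
  ## generated tables pass the annotation validators unchanged
  ann <- annotate_species(tab, pool$catalog)
  expect_equal(sum(ann$is_allergenic), pool$truth$n_allergenic)
  expect_lte(abs(sum(ann$is_allergenic) - round(0.343 * 216)), 2)
  ## molecule counts within 1..13, median near 6
  nm <- ann$n_molecules[ann$n_molecules > 0]
  expect_true(all(nm >= 1 & nm <= 13))
  expect_lte(abs(median(nm) - 6), 1)
  ## roughly a quarter wind-pollinated, concentrated among allergenics
  expect_lt(abs(mean(tab$pollination == "wind") - 0.23), 0.05)
  expect_gt(mean(tab$pollination[ann$is_allergenic] == "wind"),
            mean(tab$pollination[!ann$is_allergenic] == "wind"))
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_species_pool(seed = 7)
  b <- generate_species_pool(seed = 7)
  expect_identical(a, b)
  cfg <- synthetic_config(n_plots = 12)
  expect_identical(generate_landscape(cfg, seed = 3),
                   generate_landscape(cfg, seed = 3))
  env <- generate_landscape(cfg, seed = 3)
  expect_identical(generate_communities(cfg, a, env, seed = 4),
                   generate_communities(cfg, a, env, seed = 4))
  ## and sensitive to the seed
  expect_false(identical(generate_species_pool(seed = 8)$species,
                         a$species))
})

test_that("allergenic_frac = 0 silences every downstream metric", {
  cfg <- synthetic_config(n_plots = 6, allergenic_frac = 0)
  st <- simulate_study(cfg, seed = 5)
  ann <- annotate_species(st$species, st$catalog)
  expect_equal(sum(ann$is_allergenic), 0)
  pr <- community_profile(ann, st$cover)
  expect_true(all(pr$value[pr$metric %in%
    c("allergenic_richness", "allergenic_cover", "molecule_richness",
      "family_richness")] == 0, na.rm = TRUE))
})

test_that("landscape copula realises the target rank correlation", {
  cfg0 <- synthetic_config(rho_target = 0)
  hits <- 0
  for (s in 1:40) {
    env <- generate_landscape(cfg0, seed = s)
    if (abs(spearman_test(env$impervious_pct, env$invasion)$rho) < 0.3) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 40, 0.95)
  cfg1 <- synthetic_config(n_plots = 200, rho_target = 1)
  env1 <- generate_landscape(cfg1, seed = 1)
  expect_gt(spearman_test(env1$impervious_pct, env1$invasion)$rho, 0.9)
  ## default target is approached at n = 56
  envd <- generate_landscape(synthetic_config(), seed = 2)
  expect_lt(abs(spearman_test(envd$impervious_pct, envd$invasion)$rho - 0.46),
            0.15)
  ## continuous sampler: coordinates never coincide
  expect_false(anyDuplicated(envd[c("x", "y")]) > 0)
})

test_that("noise-free covers reproduce the plot-level linear predictor", {
  cfg <- synthetic_config(n_plots = 10, cover_noise_sd = 0)
  pool <- generate_species_pool(cfg, seed = 31)
  env <- generate_landscape(cfg, seed = 32)
  cov <- generate_communities(cfg, pool, env, seed = 33)
  ann <- annotate_species(pool$species, pool$catalog)
  al <- ann$species[ann$is_allergenic]
  got <- rowSums(cov[, intersect(colnames(cov), al), drop = FALSE])
  want <- pmax(cfg$cover_baseline + cfg$cover_slope * env$impervious_pct, 2)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("study round-trips through CSV unchanged", {
  dir <- withr::local_tempdir()
  st <- simulate_study(synthetic_config(n_plots = 8), seed = 9, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("species.csv", "catalog.csv", "direct_hits.csv", "cover.csv",
      "environment.csv", "truth.json")))))
  rt <- read_study(dir)
  expect_equal(rt$species, st$species)
  expect_equal(rt$cover, st$cover)
  expect_equal(rt$env, st$env)
  expect_equal(rt$catalog$entries[order(rt$catalog$entries$molecule), ],
               st$catalog$entries[order(st$catalog$entries$molecule), ],
               ignore_attr = TRUE)
  expect_setequal(rt$catalog$direct_hits, st$catalog$direct_hits)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(status_props = c(native = 0.5,
                                                 archaeophyte = 0.2,
                                                 neophyte = 0.2)),
               "sum to 1")
  expect_error(synthetic_config(family_pool_sizes =
                                  c(native = 5, archaeophyte = 17,
                                    neophyte = 26)), "13")
  expect_error(synthetic_config(cover_slope = Inf), "finite")
})
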