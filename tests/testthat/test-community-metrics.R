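test_that("presence uses a strict cover > 0 threshold", {
  cov <- fixture_cover()
  expect_setequal(presence(cov, "A"),
                  c("Agrostis alba", "Artemisia vulgaris", "Trifolium pratense"))
  cov["C", ] <- 0
  expect_length(presence(cov, "C"), 0)
  expect_error(presence(cov, "Z"), "unknown plot")
  cov["A", 1] <- -1
  expect_error(as_cover_matrix(cov), ">= 0")
})

test_that("plot metrics match hand enumeration on the crafted community", {
  pr <- community_profile(fixture_annotated(), fixture_cover())
  ## plot A: 3 present, 2 allergenic (Agrostis 60 + Artemisia 49)
  expect_equal(profile_value(pr, "A", "all", "richness"), 3)
  expect_equal(profile_value(pr, "A", "all", "allergenic_richness"), 2)
  expect_equal(profile_value(pr, "A", "all", "allergenic_prop"), 2 / 3)
  expect_equal(profile_value(pr, "A", "all", "allergenic_cover"), 109)
  ## mean PAV over ALL present species: (36 + 36 + 0)/3
  expect_equal(profile_value(pr, "A", "all", "mean_pav"), 24)
  ## CWM PAV: (60*36 + 49*36 + 10*0)/119
  expect_equal(profile_value(pr, "A", "all", "cwm_pav"), (60 + 49) * 36 / 119)
  ## molecule union: {Poa 1, Poa 2, Art 1, Art 2}; families {C, D, A, B}
  expect_equal(profile_value(pr, "A", "all", "molecule_richness"), 4)
  expect_equal(profile_value(pr, "A", "all", "family_richness"), 4)
  ## plot C has no allergenic species
  expect_equal(profile_value(pr, "C", "all", "allergenic_richness"), 0)
  expect_equal(profile_value(pr, "C", "all", "allergenic_cover"), 0)
  ## neophyte subset empty on plot A: undefined metrics reported missing
  expect_equal(profile_value(pr, "A", "neophyte", "richness"), 0)
  expect_true(is.na(profile_value(pr, "A", "neophyte", "allergenic_prop")))
  expect_true(is.na(profile_value(pr, "A", "neophyte", "mean_pav")))
})

test_that("status subsets partition the community", {
  pr <- community_profile(fixture_annotated(), fixture_cover())
  for (p in c("A", "B", "C")) {
    for (met in c("richness", "allergenic_richness", "allergenic_cover",
                  "molecule_richness")) {
      parts <- vapply(c("native", "archaeophyte", "neophyte"),
                      function(s) profile_value(pr, p, s, met), numeric(1))
      if (met == "molecule_richness") next  # unions need not be additive
      expect_equal(sum(parts), profile_value(pr, p, "all", met))
    }
    ## non-native = archaeophytes + neophytes
    expect_equal(profile_value(pr, p, "non-native", "richness"),
                 profile_value(pr, p, "archaeophyte", "richness") +
                   profile_value(pr, p, "neophyte", "richness"))
  }
  ## family richness never exceeds molecule richness
  wide <- split(pr, paste(pr$plot_id, pr$subset))
  for (w in wide) {
    expect_lte(w$value[w$metric == "family_richness"],
               max(w$value[w$metric == "molecule_richness"], 0))
  }
})

test_that("CWM PAV is invariant to rescaling covers", {
  ann <- fixture_annotated()
  cov <- fixture_cover()
  pr1 <- community_profile(ann, cov)
  pr2 <- community_profile(ann, cov * 3.7)
  expect_equal(profile_value(pr1, "A", "all", "cwm_pav"),
               profile_value(pr2, "A", "all", "cwm_pav"))
  ## two-species checks enumerable by hand
  tab <- data.frame(
    species = c("s1", "s2"), genus = c("G1", "G2"), family = "F",
    tribe = NA, status = "native", pollination = c("none", "wind"),
    allergenicity_score = c(0L, 4L), flower_first = c(5L, 4L),
    flower_last = c(5L, 8L), stringsAsFactors = FALSE)
  ann2 <- annotate_species(tab, allergen_catalog())
  m <- matrix(c(50, 50, 10, 30), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("s2", "s1")))
  pr <- community_profile(ann2, m)
  expect_equal(profile_value(pr, "p1", "all", "cwm_pav"), 18)  # 50/50, 36/0
  expect_equal(profile_value(pr, "p2", "all", "cwm_pav"), 10 * 36 / 40)
})

test_that("neophyte proportion counts present species", {
  np <- neophyte_proportion(fixture_annotated(), fixture_cover())
  expect_equal(unname(np["A"]), 0)
  expect_equal(unname(np["B"]), 1 / 3)  # Solidago of 3 present
})

test_that("rarefaction matches the combinatorial expectation", {
  pool <- list(a = c("f1", "f2"), b = c("f1"), c = c("f3"),
               d = c("f2", "f4"), e = character(0), f = c("f5", "f1"))
  ## k = 1 closed form: mean per-species family count
  ex1 <- rarefy_allergen_families(pool, 1, mode = "exact")
  expect_equal(ex1$mean, mean(lengths(pool)))
  ## k = pool size: every family seen, zero spread
  full <- rarefy_allergen_families(pool, 6, n_draws = 50, seed = 1)
  expect_equal(full$mean, 5)
  expect_equal(full$sd, 0)
  ## Monte-Carlo mean within 3 standard errors of the exact expectation
  mc <- rarefy_allergen_families(pool, 3, n_draws = 2000, seed = 42)
  ex <- rarefy_allergen_families(pool, 3, mode = "exact")
  expect_lt(abs(mc$mean - ex$mean), 3 * mc$sd / sqrt(2000))
  ## curve is non-decreasing and exact curve matches brute-force enumeration
  expect_true(all(diff(ex$curve$exact) > 0))
  combs <- utils::combn(6, 3)
  brute <- mean(apply(combs, 2, function(id)
    length(unique(unlist(pool[id])))))
  expect_equal(ex$mean, brute)
  ## union idempotence: duplicating an existing set leaves the ceiling alone
  pool2 <- c(pool, list(g = c("f1", "f2")))
  expect_equal(rarefy_allergen_families(pool2, 7, mode = "exact")$mean, 5)
  expect_error(rarefy_allergen_families(pool, 9), "pool size")
})
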