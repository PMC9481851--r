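## Small hand-enumerable fixtures shared across tests.

fixture_species <- function() {
  data.frame(
    species = c("Agrostis alba", "Bromus tectorum", "Artemisia vulgaris",
                "Artemisia campestris", "Trifolium pratense",
                "Solidago canadensis", "Medicago varia"),
    genus = c("Agrostis", "Bromus", "Artemisia", "Artemisia", "Trifolium",
              "Solidago", "Medicago"),
    family = c("Poaceae", "Poaceae", "Asteraceae", "Asteraceae", "Fabaceae",
               "Asteraceae", "Fabaceae"),
    tribe = c("Poeae", "Bromeae", NA, NA, NA, NA, NA),
    status = c("native", "archaeophyte", "native", "native", "native",
               "neophyte", "neophyte"),
    pollination = c("wind", "wind", "wind", "wind", "biotic", "mixed",
                    "biotic"),
    allergenicity_score = c(4L, 3L, 4L, 3L, 0L, 2L, 0L),
    flower_first = c(6L, 5L, 7L, 7L, 5L, 8L, 5L),
    flower_last = c(8L, 7L, 9L, 8L, 9L, 10L, 6L),
    stringsAsFactors = FALSE)
}

fixture_catalog <- function() {
  allergen_catalog(
    entries = data.frame(
      taxon_key = c("Artemisia", "Artemisia", "Solidago", "Poeae", "Poeae"),
      key_rank = c("genus", "genus", "genus", "tribe", "tribe"),
      molecule = c("Art 1", "Art 2", "Sol 1", "Poa 1", "Poa 2"),
      protein_family = c("famA", "famB", "famA", "famC", "famD"),
      stringsAsFactors = FALSE),
    direct_hits = c("Artemisia vulgaris", "Solidago canadensis"))
}

## 3 plots: A has allergenic cover 109 (sums above 100 are legal),
## C holds only a non-allergenic species
fixture_cover <- function() {
  sp <- fixture_species()$species
  m <- matrix(0, 3, length(sp), dimnames = list(c("A", "B", "C"), sp))
  m["A", c("Agrostis alba", "Artemisia vulgaris", "Trifolium pratense")] <-
    c(60, 49, 10)
  m["B", c("Solidago canadensis", "Trifolium pratense",
           "Artemisia campestris")] <- c(10, 30, 5)
  m["C", "Trifolium pratense"] <- 20
  m
}

fixture_annotated <- function() {
  annotate_species(fixture_species(), fixture_catalog())
}

profile_value <- function(profile, plot, subset, metric) {
  profile$value[profile$plot_id == plot & profile$subset == subset &
                  profile$metric == metric]
}
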