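## Species annotation: allergenic classification, molecule assignment and
## potential allergenic value (PAV) scoring.

POLLINATION_LEVELS <- c("none", "biotic", "mixed", "wind")
STATUS_LEVELS <- c("native", "archaeophyte", "neophyte")

#' Validate a raw species trait table
#'
#' Checks the schema and value ranges of a species trait table: taxonomy
#' (species, genus, family, tribe for grasses), introduction status,
#' pollination syndrome, allergenicity score 0-4 and flowering months.
#' Errors name the offending species.
#'
#' @param table data frame with columns `species`, `genus`, `family`,
#'   `tribe` (may be `NA` except for Poaceae), `status`, `pollination`,
#'   `allergenicity_score`, `flower_first`, `flower_last`.
#' @param require_tribe check that every Poaceae row has a tribe (needed for
#'   molecule assignment, not for classification).
#' @return The table, invisibly, with character columns normalised.
#' @export
validate_species_table <- function(table, require_tribe = FALSE) {
  need <- c("species", "genus", "family", "status", "pollination",
            "allergenicity_score", "flower_first", "flower_last")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_field("species table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (!"tribe" %in% names(table)) table$tribe <- NA_character_
  if (anyDuplicated(table$species)) {
    stop_field("duplicated species name(s): %s",
               paste(unique(table$species[duplicated(table$species)]), collapse = ", "))
  }
  bad <- !nzchar(table$genus) | is.na(table$genus) |
    !nzchar(table$family) | is.na(table$family)
  if (any(bad)) {
    stop_field("missing genus/family for species: %s",
               paste(table$species[bad], collapse = ", "))
  }
  bad_status <- !(table$status %in% STATUS_LEVELS)
  if (any(bad_status)) {
    stop_field("invalid status for species: %s",
               paste(table$species[bad_status], collapse = ", "))
  }
  bad_pol <- !(table$pollination %in% POLLINATION_LEVELS)
  if (any(bad_pol)) {
    stop_field("invalid pollination syndrome for species: %s",
               paste(table$species[bad_pol], collapse = ", "))
  }
  s <- table$allergenicity_score
  if (anyNA(s) || any(s != as.integer(s)) || any(s < 0 | s > 4)) {
    stop_field("allergenicity_score must be an integer in 0..4 (species: %s)",
               paste(table$species[is.na(s) | s != round(s) | s < 0 | s > 4],
                     collapse = ", "))
  }
  f1 <- table$flower_first; f2 <- table$flower_last
  bad_m <- is.na(f1) | is.na(f2) | f1 < 1 | f1 > 12 | f2 < 1 | f2 > 12
  if (any(bad_m)) {
    stop_field("flowering months must lie in 1..12 (species: %s)",
               paste(table$species[bad_m], collapse = ", "))
  }
  if (any(f1 > f2)) {
    stop_field("flower_first > flower_last (no wraparound supported) for: %s",
               paste(table$species[f1 > f2], collapse = ", "))
  }
  if (require_tribe) {
    grass <- table$family == "Poaceae"
    no_tribe <- grass & (is.na(table$tribe) | !nzchar(table$tribe))
    if (any(no_tribe)) {
      stop_field("Poaceae species lacking tribe: %s",
                 paste(table$species[no_tribe], collapse = ", "))
    }
  }
  invisible(table)
}

#' Classify species as allergenic
#'
#' A species is classified allergenic when it has direct allergen-database
#' evidence, shares its genus with a direct-hit species, or is a grass
#' (family Poaceae). Extrapolation is a single round from direct hits; it is
#' not chained through extrapolated species.
#'
#' @param table species trait table (see [validate_species_table()]).
#' @param catalog an [allergen_catalog()] (may be empty).
#' @return The table with a logical `is_allergenic` column, input order
#'   preserved.
#' @export
classify_allergenic <- function(table, catalog = allergen_catalog()) {
  table <- validate_species_table(table)
  hit <- table$species %in% catalog$direct_hits
  hit_genera <- unique(table$genus[hit])
  table$is_allergenic <- hit | table$genus %in% hit_genera |
    table$family == "Poaceae"
  table
}

#' Assign allergen molecules to classified species
#'
#' Allergenic species inherit the molecule set recorded in the catalog under
#' their genus key (tribe key for Poaceae). Allergenic species whose key has
#' no catalog entry keep an empty set: allergenic without known molecules.
#' Non-allergenic species get an empty set.
#'
#' @param table species table with `is_allergenic` filled
#'   (see [classify_allergenic()]).
#' @param catalog an [allergen_catalog()].
#' @return Named list mapping species name to a character vector of molecule
#'   ids.
#' @export
assign_molecules <- function(table, catalog) {
  if (!"is_allergenic" %in% names(table)) {
    stop_field("run classify_allergenic() before assign_molecules()")
  }
  grass <- table$family == "Poaceae"
  no_tribe <- table$is_allergenic & grass &
    (is.na(table$tribe) | !nzchar(table$tribe))
  if (any(no_tribe)) {
    stop_field("Poaceae species lacking tribe: %s",
               paste(table$species[no_tribe], collapse = ", "))
  }
  out <- vector("list", nrow(table))
  names(out) <- table$species
  for (i in seq_len(nrow(table))) {
    if (!table$is_allergenic[i]) {
      out[[i]] <- character()
    } else if (grass[i]) {
      out[[i]] <- catalog_molecules(catalog, table$tribe[i], "tribe")
    } else {
      out[[i]] <- catalog_molecules(catalog, table$genus[i], "genus")
    }
  }
  out
}

#' Pollination emission score
#'
#' Ordinal pollen-emission score of the pollination syndrome: 0 no pollen
#' emissions, 1 biotic pollination or low emissions, 2 mixed pollination
#' with moderate emissions, 3 wind pollination with high emissions.
#'
#' @param pollination character vector with values in
#'   `c("none", "biotic", "mixed", "wind")`.
#' @return Integer vector in 0..3.
#' @export
pollination_score <- function(pollination) {
  bad <- !(pollination %in% POLLINATION_LEVELS)
  if (any(bad)) {
    stop_field("unknown pollination syndrome: %s",
               paste(unique(pollination[bad]), collapse = ", "))
  }
  match(pollination, POLLINATION_LEVELS) - 1L
}

#' Flowering-duration score
#'
#' Ordinal score of flowering-season length in months: duration 1 scores 1,
#' duration 2 scores 2, durations of three months or more score 3. Duration
#' is `flower_last - flower_first + 1`; December-to-January wraparound is
#' rejected.
#'
#' @param flower_first,flower_last integer months in 1..12,
#'   `flower_first <= flower_last`.
#' @return Integer vector in 1..3.
#' @export
phenology_score <- function(flower_first, flower_last) {
  if (any(is.na(flower_first) | is.na(flower_last)) ||
      any(flower_first < 1 | flower_last > 12)) {
    stop_field("flowering months must lie in 1..12")
  }
  if (any(flower_first > flower_last)) {
    stop_field("flower_first > flower_last (no wraparound supported)")
  }
  pmin(flower_last - flower_first + 1L, 3L)
}

#' Potential allergenic value (PAV) of species
#'
#' Multiplies the three ordinal factors -- allergenicity score (0-4),
#' pollination emission score (0-3) and flowering-duration score (1-3) --
#' into a species-level potential allergenic value ranging from 0 to 36.
#'
#' @param allergenicity_score integer vector in 0..4.
#' @param pollination character vector of pollination syndromes.
#' @param flower_first,flower_last integer flowering months.
#' @return Integer PAV vector in 0..36.
#' @export
score_pav <- function(allergenicity_score, pollination, flower_first,
                      flower_last) {
  if (any(is.na(allergenicity_score)) ||
      any(allergenicity_score != round(allergenicity_score)) ||
      any(allergenicity_score < 0 | allergenicity_score > 4)) {
    stop_field("allergenicity_score must be an integer in 0..4")
  }
  as.integer(allergenicity_score) * pollination_score(pollination) *
    phenology_score(flower_first, flower_last)
}

#' Annotate a species table end-to-end
#'
#' Runs allergenic classification, molecule assignment and PAV scoring,
#' returning the table with derived columns `is_allergenic`, `pav`,
#' `n_molecules`, `n_families` and list columns `molecules` and `families`.
#'
#' @param table species trait table.
#' @param catalog an [allergen_catalog()].
#' @return Annotated data frame, one row per input species, input order
#'   preserved.
#' @examples
#' tab <- data.frame(
#'   species = "Phleum pratense", genus = "Phleum", family = "Poaceae",
#'   tribe = "Poeae", status = "native", pollination = "wind",
#'   allergenicity_score = 4L, flower_first = 6L, flower_last = 8L
#' )
#' annotate_species(tab, allergen_catalog())
#' @export
annotate_species <- function(table, catalog = allergen_catalog()) {
  table <- classify_allergenic(table, catalog)
  mols <- assign_molecules(table, catalog)
  fams <- lapply(mols, function(m) catalog_families(catalog, m))
  table$molecules <- unname(mols)
  table$families <- unname(fams)
  table$n_molecules <- vapply(mols, length, integer(1), USE.NAMES = FALSE)
  table$n_families <- vapply(fams, length, integer(1), USE.NAMES = FALSE)
  table$pav <- score_pav(table$allergenicity_score, table$pollination,
                         table$flower_first, table$flower_last)
  zero_allergenic <- table$is_allergenic & table$allergenicity_score == 0
  if (any(zero_allergenic)) {
    warning(sprintf(
      "allergenic species with allergenicity score 0 (PAV forced to 0): %s",
      paste(table$species[zero_allergenic], collapse = ", ")), call. = FALSE)
  }
  table
}
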