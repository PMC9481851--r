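#' Allergen catalog
#'
#' An allergen catalog maps taxon keys to sets of allergen molecules and
#' their protein families. Keys are genus names, or tribe names for grasses
#' (Poaceae), following the convention of extrapolating allergen records
#' from species with direct database evidence to congeneric (or con-tribal)
#' species. The catalog also carries the set of species names with direct
#' database evidence (`direct_hits`), which drives the allergenic
#' classification rule.
#'
#' @param entries data frame with columns `taxon_key`, `key_rank`
#'   (`"genus"` or `"tribe"`), `molecule`, `protein_family`. One row per
#'   (key, molecule) pair. May have zero rows.
#' @param direct_hits character vector of species names with at least one
#'   allergenic pollen molecule recorded directly in an allergen database.
#' @return An object of class `allergen_catalog`.
#' @examples
#' cat <- allergen_catalog(
#'   entries = data.frame(
#'     taxon_key = c("Artemisia", "Artemisia", "Poeae"),
#'     key_rank = c("genus", "genus", "tribe"),
#'     molecule = c("Art v 1", "Art v 3", "Phl p 1"),
#'     protein_family = c("defensin", "nsLTP", "grass group 1")
#'   ),
#'   direct_hits = "Artemisia vulgaris"
#' )
#' @export
allergen_catalog <- function(entries = NULL, direct_hits = character()) {
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- data.frame(taxon_key = character(), key_rank = character(),
                          molecule = character(), protein_family = character(),
                          stringsAsFactors = FALSE)
  }
  need <- c("taxon_key", "key_rank", "molecule", "protein_family")
  miss <- setdiff(need, names(entries))
  if (length(miss)) {
    stop_field("catalog entries lack column(s): %s", paste(miss, collapse = ", "))
  }
  entries <- entries[need]
  entries[] <- lapply(entries, as.character)
  if (any(!nzchar(entries$taxon_key)) || anyNA(entries$taxon_key)) {
    stop_field("catalog taxon keys must be non-empty")
  }
  bad_rank <- setdiff(unique(entries$key_rank), c("genus", "tribe"))
  if (length(bad_rank)) {
    stop_field("unknown key_rank value(s): %s", paste(bad_rank, collapse = ", "))
  }
  ## each molecule id must map to a single protein family catalog-wide
  fam_per_mol <- tapply(entries$protein_family, entries$molecule,
                        function(x) length(unique(x)))
  if (any(fam_per_mol > 1)) {
    stop_field("molecule(s) mapped to more than one protein family: %s",
               paste(names(fam_per_mol)[fam_per_mol > 1], collapse = ", "))
  }
  entries <- unique(entries)
  structure(
    list(entries = entries, direct_hits = unique(as.character(direct_hits))),
    class = "allergen_catalog"
  )
}

#' @export
print.allergen_catalog <- function(x, ...) {
  cat("Allergen catalog:", length(unique(x$entries$taxon_key)), "taxon keys,",
      length(unique(x$entries$molecule)), "molecules,",
      length(unique(x$entries$protein_family)), "protein families,",
      length(x$direct_hits), "direct-hit species\n")
  invisible(x)
}

## molecules for one taxon key at a given rank
catalog_molecules <- function(catalog, key, rank) {
  e <- catalog$entries
  unique(e$molecule[e$taxon_key == key & e$key_rank == rank])
}

## protein families for a set of molecule ids
catalog_families <- function(catalog, molecules) {
  e <- catalog$entries
  unique(e$protein_family[e$molecule %in% molecules])
}

#' Read an allergen catalog from CSV files
#'
#' @param entries_csv path to a CSV with columns
#'   `taxon_key,key_rank,molecule,protein_family`.
#' @param direct_hits_csv path to a CSV with a `species` column, or `NULL`.
#' @return An [allergen_catalog()].
#' @export
read_allergen_catalog <- function(entries_csv, direct_hits_csv = NULL) {
  entries <- utils::read.csv(entries_csv, stringsAsFactors = FALSE)
  hits <- character()
  if (!is.null(direct_hits_csv)) {
    dh <- utils::read.csv(direct_hits_csv, stringsAsFactors = FALSE)
    if (!"species" %in% names(dh)) {
      stop_field("direct-hits file %s lacks a 'species' column", direct_hits_csv)
    }
    hits <- dh$species
  }
  allergen_catalog(entries, hits)
}
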