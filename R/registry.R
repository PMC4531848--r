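# Nomenclature registry: the offline stand-in for the live nomenclature
# resources (validly published names, type-strain collection IDs, the
# "reference sequence" accession list, manually curated erroneous
# accessions). Stored as plain tab-separated tables so that a database build
# is fully reproducible offline.

#' Construct a nomenclature registry
#'
#' @param valid_names Character vector of validly published binomial (or
#'   trinomial) names.
#' @param taxid_overrides Named character vector mapping NCBI TaxId (as
#'   character) to the corrected species name; applied before the validity
#'   check so that a misspelt organism field can still be tagged `v`.
#' @param erroneous_accessions Accessions with a known-erroneous species
#'   assignment; such records are always tagged `X`.
#' @param ts_strain_ids Named character vector mapping a strain collection ID
#'   to the species whose type strain it identifies.
#' @param lpsn_reference_accessions Accessions designated "reference
#'   sequence" for their species; such records are tagged `TT`.
#' @param genus_type_species Named character vector mapping a genus to its
#'   type species (used by the genus-level database flavor).
#' @return An object of class `nomenclature_registry`.
#' @export
nomenclature_registry <- function(valid_names = character(),
                                  taxid_overrides = character(),
                                  erroneous_accessions = character(),
                                  ts_strain_ids = character(),
                                  lpsn_reference_accessions = character(),
                                  genus_type_species = character()) {
  if (length(taxid_overrides) && is.null(names(taxid_overrides)))
    stop_proxitax("taxid_overrides must be named by TaxId", "registry_error")
  if (length(ts_strain_ids) && is.null(names(ts_strain_ids)))
    stop_proxitax("ts_strain_ids must be named by strain collection ID",
                  "registry_error")
  if (length(genus_type_species) && is.null(names(genus_type_species)))
    stop_proxitax("genus_type_species must be named by genus", "registry_error")
  structure(
    list(
      valid_names = unique(as.character(valid_names)),
      taxid_overrides = taxid_overrides,
      erroneous_accessions = unique(as.character(erroneous_accessions)),
      ts_strain_ids = ts_strain_ids[!duplicated(names(ts_strain_ids))],
      lpsn_reference_accessions = unique(as.character(lpsn_reference_accessions)),
      genus_type_species = genus_type_species[!duplicated(names(genus_type_species))]
    ),
    class = "nomenclature_registry"
  )
}

#' @export
print.nomenclature_registry <- function(x, ...) {
  cat("<nomenclature_registry>\n")
  cat("  valid names:          ", length(x$valid_names), "\n")
  cat("  taxid overrides:      ", length(x$taxid_overrides), "\n")
  cat("  erroneous accessions: ", length(x$erroneous_accessions), "\n")
  cat("  TS strain IDs:        ", length(x$ts_strain_ids), "\n")
  cat("  LPSN reference seqs:  ", length(x$lpsn_reference_accessions), "\n")
  cat("  genus type species:   ", length(x$genus_type_species), "\n")
  invisible(x)
}

#' Write a registry to a directory of tab-separated tables
#'
#' @param reg A [nomenclature_registry()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(reg, dir) {
  stopifnot(inherits(reg, "nomenclature_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  w(data.frame(name = reg$valid_names), "valid_names.tsv")
  w(data.frame(taxid = names(reg$taxid_overrides),
               name = unname(reg$taxid_overrides)), "taxid_overrides.tsv")
  w(data.frame(accession = reg$erroneous_accessions), "erroneous_accessions.tsv")
  w(data.frame(strain_id = names(reg$ts_strain_ids),
               species = unname(reg$ts_strain_ids)), "ts_strains.tsv")
  w(data.frame(accession = reg$lpsn_reference_accessions), "lpsn_reference.tsv")
  w(data.frame(genus = names(reg$genus_type_species),
               species = unname(reg$genus_type_species)), "genus_type_species.tsv")
  invisible(dir)
}

#' Read a registry written by [write_registry()]
#'
#' @param dir Directory containing the registry tables.
#' @return A [nomenclature_registry()].
#' @export
read_registry <- function(dir) {
  r <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      comment.char = "")
  }
  tab_or <- function(df, col, default = character()) {
    if (is.null(df) || nrow(df) == 0L) default else df[[col]]
  }
  named_col <- function(df, key, val) {
    if (is.null(df) || nrow(df) == 0L) return(character())
    stats::setNames(df[[val]], df[[key]])
  }
  nomenclature_registry(
    valid_names = tab_or(r("valid_names.tsv"), "name"),
    taxid_overrides = named_col(r("taxid_overrides.tsv"), "taxid", "name"),
    erroneous_accessions = tab_or(r("erroneous_accessions.tsv"), "accession"),
    ts_strain_ids = named_col(r("ts_strains.tsv"), "strain_id", "species"),
    lpsn_reference_accessions = tab_or(r("lpsn_reference.tsv"), "accession"),
    genus_type_species = named_col(r("genus_type_species.tsv"), "genus", "species")
  )
}
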