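# Reference-database construction.
#
# The "lax" database keeps every sufficiently long, taxonomically informative
# sequence and annotates each record with a nomenclature tag and a
# type-strain tag. The stricter flavors are subsets of the lax database
# selected purely on those tags:
#
#   lax            all surviving records
#   stringent      validly named records, plus type-strain records whose
#                  names are not (yet) validated
#   ts_stringent   type-strain records (tags TT or T)
#   superstringent LPSN "reference sequence" records (tag TT)
#   genus_level    one species per genus: the TT records of the genus's
#                  type species

FLAVORS <- c("lax", "stringent", "ts_stringent", "superstringent", "genus_level")

#' Database flavors available for a marker
#'
#' SSU rRNA databases come in all five stringency flavors; other markers
#' (housekeeping genes, LSU rRNA, tmRNA) are curated only down to the
#' type-strain level.
#'
#' @param marker_type `"ssu"` or `"other"`.
#' @return Character vector of flavor names.
#' @export
marker_flavors <- function(marker_type = c("ssu", "other")) {
  marker_type <- match.arg(marker_type)
  if (marker_type == "ssu") FLAVORS else FLAVORS[1:3]
}

#' Filter GenBank records down to database candidates
#'
#' A record is a candidate when its sequence is strictly longer than
#' `min_len` (default 300 bp) and its lineage carries taxonomic information
#' more specific than the domain alone. Records without any lineage are
#' excluded and counted, never fatal. Order-preserving and idempotent.
#'
#' @param records List of `genbank_record` objects.
#' @param min_len Minimum length in bp (exclusive).
#' @return The surviving records, with attributes `n_short`, `n_domain_only`
#'   and `n_no_lineage` giving the exclusion counts.
#' @export
extract_candidates <- function(records, min_len = 300) {
  stopifnot(min_len >= 1)
  len <- vapply(records, function(r) nchar(r$sequence), integer(1))
  depth <- vapply(records, function(r) length(r$lineage), integer(1))
  no_lineage <- depth == 0L
  domain_only <- depth == 1L
  short <- len <= min_len
  keep <- !short & !no_lineage & !domain_only
  out <- records[keep]
  attr(out, "n_short") <- sum(short)
  attr(out, "n_domain_only") <- sum(domain_only & !short)
  attr(out, "n_no_lineage") <- sum(no_lineage & !short)
  out
}

#' Assign the nomenclature tag of a record
#'
#' Tagging precedence: `X` when the accession is on the known-erroneous list
#' (regardless of the name); otherwise the organism name — corrected through
#' the TaxId override table when one exists — is checked against the
#' validly published names and tagged `v` on a hit, `?` otherwise.
#'
#' @param record A `genbank_record`.
#' @param reg A [nomenclature_registry()].
#' @return A list with `name` (the possibly TaxId-corrected name string) and
#'   `tag` (one of `"v"`, `"?"`, `"X"`).
#' @export
assign_nom_tag <- function(record, reg) {
  name <- squish(record$organism_name)
  if (!is.null(record$taxid) && as.character(record$taxid) %in% names(reg$taxid_overrides))
    name <- unname(reg$taxid_overrides[[as.character(record$taxid)]])
  if (record$accession %in% reg$erroneous_accessions)
    return(list(name = name, tag = "X"))
  if (name %in% reg$valid_names)
    return(list(name = name, tag = "v"))
  list(name = name, tag = "?")
}

#' Assign the type-strain tag of a record
#'
#' `TT` when the accession is designated "reference sequence" by the
#' nomenclature registry; otherwise, when a strain ID carries the terminal
#' `T` flag (e.g. `CIP8828T`) or is a registered type-strain collection ID,
#' the record is tagged `T` if its name is grammatical and `t` otherwise (so
#' that candidate type strains of not-yet-named species are never lost);
#' `N` in all remaining cases.
#'
#' @param record A `genbank_record`.
#' @param name_ok Logical: is the resolved organism name grammatical (see
#'   [is_grammatical_name()])?
#' @param reg A [nomenclature_registry()].
#' @return One of `"TT"`, `"T"`, `"t"`, `"N"`.
#' @export
assign_ts_tag <- function(record, name_ok, reg) {
  if (record$accession %in% reg$lpsn_reference_accessions) return("TT")
  ids <- record$strain_ids
  has_flag <- length(ids) > 0L &&
    (any(grepl("T$", ids)) || any(ids %in% names(reg$ts_strain_ids)))
  if (has_flag) {
    if (isTRUE(name_ok)) "T" else "t"
  } else {
    "N"
  }
}

#' Build the lax reference database
#'
#' Runs candidate filtering and both tagging rules over a set of GenBank
#' records and assembles the annotated database. Output order is
#' deterministic: records are sorted by (name, accession) under C collation.
#'
#' @param records List of `genbank_record` objects.
#' @param reg A [nomenclature_registry()].
#' @param min_len Minimum sequence length in bp (exclusive), default 300.
#' @return A data frame of class `refdb` with one row per surviving record:
#'   columns `accession`, `name`, `genus`, `species`, `grammatical`, `nom`,
#'   `ts`, `lineage` (`;`-joined), `header` (descriptor line) and `sequence`.
#' @export
build_lax <- function(records, reg, min_len = 300) {
  cands <- extract_candidates(records, min_len = min_len)
  n <- length(cands)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- cands[[i]]
    nom <- assign_nom_tag(r, reg)
    tn <- as_taxon_name(nom$name)
    name_ok <- is_grammatical_name(nom$name)
    ts <- assign_ts_tag(r, name_ok, reg)
    hname <- if (!is.null(tn)) tn else sanitize_label(nom$name)
    h <- seq_header(hname, nom$tag, ts, r$accession, r$lineage)
    rows[[i]] <- data.frame(
      accession = r$accession,
      name = name_string(hname),
      genus = if (!is.null(tn)) tn$genus else NA_character_,
      species = if (!is.null(tn)) paste(tn$genus, tn$species) else NA_character_,
      grammatical = !is.null(tn),
      nom = nom$tag,
      ts = ts,
      lineage = paste(r$lineage, collapse = ";"),
      header = format_header(h),
      sequence = r$sequence,
      stringsAsFactors = FALSE
    )
  }
  db <- if (n) do.call(rbind, rows) else empty_refdb()
  db <- db[order_c(db$name, db$accession), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("refdb", "data.frame")
  attr(db, "excluded") <- c(
    short = attr(cands, "n_short"),
    domain_only = attr(cands, "n_domain_only"),
    no_lineage = attr(cands, "n_no_lineage")
  )
  db
}

empty_refdb <- function() {
  data.frame(accession = character(), name = character(), genus = character(),
             species = character(), grammatical = logical(), nom = character(),
             ts = character(), lineage = character(), header = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

# Raw organism labels may contain characters reserved by the descriptor
# grammar; replace them so every emitted header reparses.
sanitize_label <- function(x) {
  squish(gsub("[~=;>]", "_", x))
}

#' Extract a stringency flavor from a lax database
#'
#' @param db A `refdb` data frame from [build_lax()].
#' @param flavor One of `"lax"`, `"stringent"`, `"ts_stringent"`,
#'   `"superstringent"`, `"genus_level"`.
#' @param reg A [nomenclature_registry()]; required for the genus-level
#'   flavor (type-species lookup).
#' @return The subset of `db` rows belonging to the flavor.
#' @export
extract_flavor <- function(db, flavor = FLAVORS, reg = NULL) {
  flavor <- match.arg(flavor)
  keep <- switch(
    flavor,
    lax = rep(TRUE, nrow(db)),
    stringent = db$nom == "v" | db$ts %in% c("TT", "T", "t"),
    ts_stringent = db$ts %in% c("TT", "T"),
    superstringent = db$ts == "TT",
    genus_level = {
      if (is.null(reg))
        stop_proxitax("genus_level flavor requires a registry", "refdb_error")
      type_sp <- unname(reg$genus_type_species)
      db$ts == "TT" & !is.na(db$species) & db$species %in% type_sp
    }
  )
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("refdb", "data.frame")
  attr(out, "flavor") <- flavor
  out
}

#' Report type-strain species missing from a database
#'
#' Compares the species covered by the registry's type-strain collection IDs
#' with the species having a `TT`- or `T`-tagged entry in the database. An
#' empty result means exhaustive type-strain coverage.
#'
#' @param db A `refdb` data frame.
#' @param reg A [nomenclature_registry()].
#' @return Sorted character vector of species names without a type-strain
#'   entry.
#' @export
qc_missing_ts <- function(db, reg) {
  expected <- unique(unname(reg$ts_strain_ids))
  covered <- unique(db$species[db$ts %in% c("TT", "T") & !is.na(db$species)])
  sort_c(setdiff(expected, covered))
}

#' Write a database to FASTA
#'
#' Headers are the descriptor lines; sequences are wrapped at 80 columns.
#'
#' @param db A `refdb` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_refdb_fasta <- function(db, path) {
  seqs <- Biostrings::DNAStringSet(db$sequence)
  names(seqs) <- sub("^>", "", db$header)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a flavor FASTA back into a database table
#'
#' @param path FASTA file written by [write_refdb_fasta()].
#' @return A `refdb` data frame (lineage columns reconstructed from the
#'   headers).
#' @export
read_refdb_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- lapply(names(seqs), parse_header)
  rows <- lapply(seq_along(headers), function(i) {
    h <- headers[[i]]
    tn <- if (inherits(h$name, "taxon_name")) h$name else NULL
    data.frame(
      accession = h$accession,
      name = name_string(h$name),
      genus = if (!is.null(tn)) tn$genus else NA_character_,
      species = if (!is.null(tn)) paste(tn$genus, tn$species) else NA_character_,
      grammatical = !is.null(tn),
      nom = h$nom,
      ts = h$ts,
      lineage = paste(h$lineage, collapse = ";"),
      header = format_header(h),
      sequence = as.character(seqs[[i]]),
      stringsAsFactors = FALSE
    )
  })
  db <- if (length(rows)) do.call(rbind, rows) else empty_refdb()
  rownames(db) <- NULL
  class(db) <- c("refdb", "data.frame")
  db
}
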