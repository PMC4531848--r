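# Reference-sequence descriptor grammar.
#
# Every sequence of a curated reference database carries a structured FASTA
# header:
#
#   >Genus_species[_subsp_subspecies]~[v/?/X]~[TT/T/t/N]~Accession=rank1;rank2;...
#
# The first tag records nomenclature status (v = validly published name,
# ? = not compliant, X = accession on the known-erroneous list), the second
# the type-strain status (TT = nomenclatural reference sequence, T = type
# strain, t = type-strain flag without a grammatical name, N = neither), the
# third field is the sequence accession and the trailing field the taxonomic
# lineage from the domain downward.

NOM_TAGS <- c("v", "?", "X")
TS_TAGS <- c("TT", "T", "t", "N")

#' Construct a binomial or trinomial taxon name
#'
#' A grammatical prokaryotic name is either a binomial ("Genus species") or a
#' trinomial with a subspecies epithet ("Genus species subsp. subspecies").
#'
#' @param genus Capitalized genus name (single word).
#' @param species Lowercase species epithet (single word).
#' @param subspecies Optional lowercase subspecies epithet.
#' @return An object of class `taxon_name`.
#' @examples
#' taxon_name("Bacillus", "subtilis")
#' taxon_name("Bacillus", "subtilis", "spizizenii")
#' @export
taxon_name <- function(genus, species, subspecies = NULL) {
  if (!grepl("^[A-Z][A-Za-z-]*$", genus))
    stop_proxitax(sprintf("invalid genus name: '%s'", genus), "taxon_name_error")
  ok_epithet <- function(x) grepl("^[a-z][a-z0-9-]*$", x)
  if (!ok_epithet(species))
    stop_proxitax(sprintf("invalid species epithet: '%s'", species), "taxon_name_error")
  if (!is.null(subspecies) && !ok_epithet(subspecies))
    stop_proxitax(sprintf("invalid subspecies epithet: '%s'", subspecies), "taxon_name_error")
  structure(
    list(genus = genus, species = species, subspecies = subspecies),
    class = "taxon_name"
  )
}

#' @export
format.taxon_name <- function(x, ...) {
  if (is.null(x$subspecies)) {
    paste(x$genus, x$species)
  } else {
    paste(x$genus, x$species, "subsp.", x$subspecies)
  }
}

#' @export
print.taxon_name <- function(x, ...) {
  cat("<taxon_name>", format(x), "\n")
  invisible(x)
}

#' Test whether a species-name string is grammatically correct
#'
#' A name is grammatical when, after whitespace normalization, it consists of
#' exactly two words with the first capitalized, or of exactly four words one
#' of which is the token `subsp.` (with the trailing period). Anything else —
#' clone identifiers, "sp." placeholders, free-text environmental labels — is
#' not a usable binomial and is treated as a raw label downstream.
#'
#' @param raw Character vector of candidate name strings.
#' @return Logical vector.
#' @examples
#' is_grammatical_name("Bacillus subtilis")                     # TRUE
#' is_grammatical_name("bacillus subtilis")                     # FALSE
#' is_grammatical_name("Bacillus subtilis subsp. spizizenii")   # TRUE
#' is_grammatical_name("Bacillus sp. strain 7")                 # FALSE
#' @export
is_grammatical_name <- function(raw) {
  vapply(raw, function(x) {
    x <- squish(x)
    if (!nzchar(x)) return(FALSE)
    w <- strsplit(x, " ", fixed = TRUE)[[1]]
    if (length(w) == 2) return(grepl("^[A-Z]", w[1]))
    if (length(w) == 4) return(any(w == "subsp."))
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

# Try to promote a whitespace-normalized name string to a taxon_name;
# return NULL when the string does not fit the binomial/trinomial grammar.
as_taxon_name <- function(raw) {
  x <- squish(raw)
  w <- strsplit(x, " ", fixed = TRUE)[[1]]
  res <- tryCatch({
    if (length(w) == 2) {
      taxon_name(w[1], w[2])
    } else if (length(w) == 4 && w[3] == "subsp.") {
      taxon_name(w[1], w[2], w[4])
    } else {
      NULL
    }
  }, proxitax_error = function(e) NULL)
  res
}

name_string <- function(name) {
  if (inherits(name, "taxon_name")) format(name) else as.character(name)
}

# Serialize a name (taxon_name or raw label) into the underscored header
# field; "subsp." loses its period in the underscored form.
name_field <- function(name) {
  if (inherits(name, "taxon_name")) {
    if (is.null(name$subspecies)) {
      paste(name$genus, name$species, sep = "_")
    } else {
      paste(name$genus, name$species, "subsp", name$subspecies, sep = "_")
    }
  } else {
    gsub(" ", "_", squish(as.character(name)))
  }
}

# Inverse of name_field: underscores back to spaces, then grammar promotion.
parse_name_field <- function(field) {
  w <- strsplit(field, "_", fixed = TRUE)[[1]]
  if (length(w) == 2) {
    tn <- tryCatch(taxon_name(w[1], w[2]), proxitax_error = function(e) NULL)
    if (!is.null(tn)) return(tn)
  }
  if (length(w) == 4 && w[3] == "subsp") {
    tn <- tryCatch(taxon_name(w[1], w[2], w[4]), proxitax_error = function(e) NULL)
    if (!is.null(tn)) return(tn)
  }
  gsub("_", " ", field)
}

#' Construct a reference-sequence header
#'
#' @param name A [taxon_name()] or, for sequences whose organism annotation is
#'   not a grammatical binomial, a raw character label.
#' @param nom Nomenclature tag, one of `"v"`, `"?"`, `"X"`.
#' @param ts Type-strain tag, one of `"TT"`, `"T"`, `"t"`, `"N"`.
#' @param accession Sequence accession (non-empty, must not contain the `~`
#'   tag separator or the `=` lineage separator).
#' @param lineage Character vector of taxonomic ranks from the domain
#'   downward; the first element must be `"Bacteria"` or `"Archaea"`.
#' @return An object of class `seq_header`.
#' @seealso [parse_header()], [format_header()]
#' @export
seq_header <- function(name, nom, ts, accession, lineage) {
  if (!nom %in% NOM_TAGS)
    stop_proxitax(sprintf("invalid nomenclature tag '%s' (expected one of %s)",
                          nom, paste(NOM_TAGS, collapse = "/")),
                  "header_parse_error")
  if (!ts %in% TS_TAGS)
    stop_proxitax(sprintf("invalid type-strain tag '%s' (expected one of %s)",
                          ts, paste(TS_TAGS, collapse = "/")),
                  "header_parse_error")
  accession <- as.character(accession)
  if (length(accession) != 1L || !nzchar(accession) || grepl("[~=;]", accession))
    stop_proxitax("accession must be non-empty and free of '~', '=' and ';'",
                  "header_parse_error")
  lineage <- as.character(lineage)
  if (length(lineage) < 1L)
    stop_proxitax("lineage must have at least one rank", "header_parse_error")
  if (!lineage[1] %in% c("Bacteria", "Archaea"))
    stop_proxitax("lineage must start at the domain (Bacteria or Archaea)",
                  "header_parse_error")
  if (any(grepl("[;~=]", lineage)))
    stop_proxitax("lineage ranks must not contain ';', '~' or '='",
                  "header_parse_error")
  if (!inherits(name, "taxon_name")) {
    name <- squish(as.character(name))
    if (grepl("[~=;]", name))
      stop_proxitax("raw labels must not contain '~', '=' or ';'",
                    "header_parse_error")
  }
  structure(
    list(name = name, nom = nom, ts = ts, accession = accession,
         lineage = lineage),
    class = "seq_header"
  )
}

#' Parse a reference-database descriptor line
#'
#' @param line A descriptor string, with or without the leading `>`.
#' @return A [seq_header()].
#' @examples
#' h <- parse_header(">Bacillus_subtilis~v~TT~X00007=Bacteria;Firmicutes;Bacilli")
#' h$accession
#' format(h$name)
#' @export
parse_header <- function(line) {
  stopifnot(length(line) == 1L, is.character(line))
  x <- sub("^>", "", trimws(line))
  tilde_at <- gregexpr("~", x, fixed = TRUE)[[1]]
  n_tilde <- if (tilde_at[1] == -1L) 0L else length(tilde_at)
  if (n_tilde != 3L)
    stop_proxitax(sprintf(
      "descriptor must contain exactly 3 '~' separators, found %d in '%s'",
      n_tilde, line), "header_parse_error")
  parts <- strsplit(x, "~", fixed = TRUE)[[1]]
  if (length(parts) != 4L || !all(nzchar(parts[1:4])))
    stop_proxitax(sprintf("empty field in descriptor '%s'", line),
                  "header_parse_error")
  eq_at <- regexpr("=", parts[4], fixed = TRUE)
  if (eq_at == -1L)
    stop_proxitax(sprintf(
      "missing '=' lineage separator (expected after position %d) in '%s'",
      tilde_at[3], line), "header_parse_error")
  accession <- substr(parts[4], 1L, eq_at - 1L)
  lineage_str <- substr(parts[4], eq_at + 1L, nchar(parts[4]))
  lineage <- trimws(strsplit(lineage_str, ";", fixed = TRUE)[[1]])
  if (length(lineage) == 0L || !all(nzchar(lineage)))
    stop_proxitax(sprintf("empty lineage in descriptor '%s'", line),
                  "header_parse_error")
  seq_header(
    name = parse_name_field(parts[1]),
    nom = parts[2],
    ts = parts[3],
    accession = accession,
    lineage = lineage
  )
}

#' Serialize a header back to its descriptor line
#'
#' `parse_header(format_header(h))` is the identity on valid headers; spaces
#' in names become underscores.
#'
#' @param h A [seq_header()].
#' @return A single descriptor string starting with `>`.
#' @export
format_header <- function(h) {
  stopifnot(inherits(h, "seq_header"))
  paste0(">", name_field(h$name), "~", h$nom, "~", h$ts, "~", h$accession,
         "=", paste(h$lineage, collapse = ";"))
}

#' @export
format.seq_header <- function(x, ...) format_header(x)

#' @export
print.seq_header <- function(x, ...) {
  cat("<seq_header>", format_header(x), "\n")
  invisible(x)
}

#' Parse a tree tip label carrying the descriptor tags
#'
#' Tip labels of recruited-neighbor trees carry the name/tag/accession part of
#' the descriptor but usually omit the lineage (`;` cannot appear inside a
#' Newick label). Returns `NULL` for labels that do not follow the tag
#' grammar (e.g. the query leaf).
#'
#' @param label A tip label.
#' @return A list with elements `name`, `nom`, `ts`, `accession`, or `NULL`.
#' @export
parse_leaf_label <- function(label) {
  x <- sub("^>", "", trimws(label))
  x <- sub("=.*$", "", x)  # tolerate a full header with lineage attached
  parts <- strsplit(x, "~", fixed = TRUE)[[1]]
  if (length(parts) != 4L || !all(nzchar(parts))) return(NULL)
  if (!parts[2] %in% NOM_TAGS || !parts[3] %in% TS_TAGS) return(NULL)
  list(name = parse_name_field(parts[1]), nom = parts[2], ts = parts[3],
       accession = parts[4])
}
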