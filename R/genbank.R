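# Minimal GenBank flat-file reader.
#
# Database construction consumes GenBank-format flat files and needs only a
# handful of fields per record: accession, organism name, lineage, NCBI
# TaxId, strain collection IDs and the nucleotide sequence. None of the
# installed sequence packages parses GenBank flat files offline, so this is a
# focused line-oriented reader for exactly those fields.

#' Read GenBank flat-file records
#'
#' Extracts, for every record, the fields needed to build a reference
#' database: `accession`, `organism_name`, `lineage` (from the indented
#' ORGANISM continuation lines), `taxid` (from `/db_xref="taxon:..."`),
#' `strain_ids` (from `/strain` and `/culture_collection` qualifiers, the
#' latter with the `:` separator removed), and `sequence` (from ORIGIN).
#'
#' @param file Path to a GenBank flat file, or `NULL` when `text` is given.
#' @param text Character scalar or vector of lines, as an alternative to
#'   `file`.
#' @return A list of `genbank_record` objects.
#' @export
read_genbank <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  }
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L && length(lines) > 0L)
    stop_proxitax("no record terminator '//' found", "genbank_parse_error")
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:(ends[i] - 1L)]
    records[[i]] <- parse_genbank_record(chunk)
  }
  records[!vapply(records, is.null, logical(1))]
}

genbank_record <- function(accession, sequence, organism_name, taxid = NULL,
                           strain_ids = character(), lineage = character(),
                           taxonomic_rank = NULL) {
  structure(
    list(accession = accession, sequence = sequence,
         organism_name = organism_name, taxid = taxid,
         strain_ids = strain_ids, lineage = lineage,
         taxonomic_rank = taxonomic_rank),
    class = "genbank_record"
  )
}

#' @export
print.genbank_record <- function(x, ...) {
  cat(sprintf("<genbank_record> %s  %s  (%d bp, %d ranks)\n",
              x$accession, x$organism_name, nchar(x$sequence),
              length(x$lineage)))
  invisible(x)
}

parse_genbank_record <- function(chunk) {
  if (!length(chunk)) return(NULL)
  acc_line <- grep("^ACCESSION", chunk, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(squish(acc_line[1]), " ")[[1]][2]
  } else {
    locus <- grep("^LOCUS", chunk, value = TRUE)
    if (!length(locus))
      stop_proxitax("record without ACCESSION or LOCUS line", "genbank_parse_error")
    strsplit(squish(locus[1]), " ")[[1]][2]
  }
  if (is.na(accession) || !nzchar(accession))
    stop_proxitax("record with empty accession", "genbank_parse_error")

  org_at <- grep("^\\s+ORGANISM", chunk)
  organism_name <- ""
  lineage <- character()
  if (length(org_at)) {
    organism_name <- squish(sub("^\\s+ORGANISM\\s*", "", chunk[org_at[1]]))
    j <- org_at[1] + 1L
    lin_lines <- character()
    while (j <= length(chunk) && grepl("^\\s{6,}\\S", chunk[j]) &&
           !grepl("^\\s+\\S+\\s{2,}", chunk[j])) {
      # continuation lines are deeply indented free text
      lin_lines <- c(lin_lines, squish(chunk[j]))
      j <- j + 1L
      if (grepl("\\.$", lin_lines[length(lin_lines)])) break
    }
    lin <- paste(lin_lines, collapse = " ")
    lin <- sub("\\.$", "", lin)
    if (nzchar(lin))
      lineage <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    lineage <- lineage[nzchar(lineage)]
  }

  qualifier <- function(name) {
    pat <- sprintf('/%s="([^"]*)"', name)
    m <- regmatches(chunk, regexec(pat, chunk))
    vals <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                   character(1))
    vals[!is.na(vals)]
  }
  strains <- qualifier("strain")
  cultures <- gsub(":", "", qualifier("culture_collection"), fixed = TRUE)
  strain_ids <- unique(c(strains, cultures))
  taxrefs <- qualifier("db_xref")
  taxid <- sub("^taxon:", "", grep("^taxon:", taxrefs, value = TRUE))
  taxid <- if (length(taxid)) taxid[1] else NULL

  origin_at <- grep("^ORIGIN", chunk)
  sequence <- ""
  if (length(origin_at)) {
    seq_lines <- chunk[seq.int(origin_at[1] + 1L, length.out = max(0L, length(chunk) - origin_at[1]))]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  genbank_record(accession = accession, sequence = sequence,
                 organism_name = organism_name, taxid = taxid,
                 strain_ids = strain_ids, lineage = lineage)
}
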