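one_record <- function(accession = "GB000001", len = 1200,
                       organism = "Bacillus subtilis",
                       lineage = c("Bacteria", "Firmicutes"),
                       strain_ids = character(), taxid = NULL) {
  structure(
    list(accession = accession,
         sequence = paste(rep("ACGT", ceiling(len / 4)), collapse = "") |>
           substr(1, len),
         organism_name = organism, taxid = taxid, strain_ids = strain_ids,
         lineage = lineage, taxonomic_rank = NULL),
    class = "genbank_record"
  )
}

test_that("candidate extraction applies the strict length and lineage rules", {
  recs <- list(
    one_record("A1", len = 300),                          # exactly 300: out
    one_record("A2", len = 301),                          # in
    one_record("A3", len = 1200, lineage = "Bacteria"),   # domain only: out
    one_record("A4", len = 1200, lineage = character())   # no lineage: out
  )
  kept <- extract_candidates(recs)
  expect_identical(vapply(kept, `[[`, "", "accession"), "A2")
  expect_identical(attr(kept, "n_short"), 1L)
  expect_identical(attr(kept, "n_domain_only"), 1L)
  expect_identical(attr(kept, "n_no_lineage"), 1L)
  # order-preserving and idempotent
  many <- c(recs, list(one_record("A5", 500), one_record("A6", 400)))
  kept2 <- extract_candidates(many)
  expect_identical(vapply(kept2, `[[`, "", "accession"), c("A2", "A5", "A6"))
  again <- extract_candidates(kept2)
  expect_identical(lapply(again, identity), lapply(kept2, identity))
})

test_that("generator-built batches survive at the planted rate", {
  gb <- make_genbank_records(n_records = 50, frac_short = 0.24,
                             frac_domain_only = 0.10, seed = 5)
  recs <- read_genbank(text = gb$text)
  kept <- extract_candidates(recs)
  # per-record oracle recomputed from the raw records
  oracle <- vapply(recs, function(r) {
    nchar(r$sequence) > 300 && length(r$lineage) > 1
  }, logical(1))
  expect_length(kept, sum(oracle))
  expect_identical(sum(gb$truth$survives), sum(oracle))
  expect_length(kept, 50 - 12 - 5)
})

test_that("nomenclature tagging follows the X > v > ? precedence exactly", {
  reg <- nomenclature_registry(
    valid_names = "Bacillus subtilis",
    taxid_overrides = c("42" = "Bacillus subtilis"),
    erroneous_accessions = "BAD001"
  )
  # exhaustive truth table over (erroneous, valid-name, taxid-override)
  for (err in c(TRUE, FALSE)) for (valid in c(TRUE, FALSE))
    for (override in c(TRUE, FALSE)) {
      rec <- one_record(
        accession = if (err) "BAD001" else "OK0001",
        organism = if (valid) "Bacillus subtilis" else "Weird thing x9",
        taxid = if (override) "42" else NULL
      )
      got <- assign_nom_tag(rec, reg)
      expected_name <- if (override) "Bacillus subtilis" else rec$organism_name
      expected_tag <- if (err) "X"
        else if (expected_name == "Bacillus subtilis") "v" else "?"
      expect_identical(got$tag, expected_tag,
                       info = sprintf("err=%s valid=%s override=%s",
                                      err, valid, override))
      expect_identical(got$name, expected_name)
    }
})

test_that("type-strain tagging honours the TT > T/t > N precedence", {
  reg <- nomenclature_registry(
    ts_strain_ids = c("DSM10" = "Bacillus subtilis"),
    lpsn_reference_accessions = "REF001"
  )
  for (lpsn in c(TRUE, FALSE)) for (flag in c(TRUE, FALSE))
    for (name_ok in c(TRUE, FALSE)) {
      rec <- one_record(
        accession = if (lpsn) "REF001" else "OK0001",
        strain_ids = if (flag) "CIP8828T" else "CIP8828"
      )
      got <- assign_ts_tag(rec, name_ok, reg)
      expected <- if (lpsn) "TT"
        else if (flag && name_ok) "T"
        else if (flag) "t" else "N"
      expect_identical(got, expected,
                       info = sprintf("lpsn=%s flag=%s name_ok=%s",
                                      lpsn, flag, name_ok))
    }
  # a registered collection ID counts as a type-strain flag without the T
  rec <- one_record(strain_ids = "DSM10")
  expect_identical(assign_ts_tag(rec, TRUE, reg), "T")
  expect_identical(assign_ts_tag(rec, FALSE, reg), "t")
})

test_that("the lax build reproduces the generator's intended tags", {
  gb <- make_genbank_records(n_records = 80, seed = 9)
  recs <- read_genbank(text = gb$text)
  db <- build_lax(recs, gb$registry)
  truth <- gb$truth[gb$truth$survives, ]
  expect_identical(nrow(db), nrow(truth))
  m <- merge(db[, c("accession", "name", "nom", "ts")],
             truth[, c("accession", "name", "nom", "ts")], by = "accession")
  expect_identical(m$nom.x, m$nom.y)
  expect_identical(m$ts.x, m$ts.y)
  expect_identical(m$name.x, m$name.y)
  # every emitted header reparses
  for (hd in db$header) expect_s3_class(parse_header(hd), "seq_header")
  # deterministic output order
  db2 <- build_lax(recs, gb$registry)
  expect_identical(db$header, db2$header)
  expect_false(is.unsorted(db$name))
  # empty input
  expect_identical(nrow(build_lax(list(), gb$registry)), 0L)
})

test_that("flavors nest and select by tag as defined", {
  gb <- make_genbank_records(n_records = 80, seed = 13)
  db <- build_lax(read_genbank(text = gb$text), gb$registry)
  fl <- lapply(stats::setNames(nm = c("lax", "stringent", "ts_stringent",
                                      "superstringent", "genus_level")),
               function(f) extract_flavor(db, f, gb$registry))
  accs <- lapply(fl, `[[`, "accession")
  expect_true(all(accs$genus_level %in% accs$superstringent))
  expect_true(all(accs$superstringent %in% accs$ts_stringent))
  expect_true(all(accs$ts_stringent %in% accs$stringent))
  expect_true(all(accs$stringent %in% accs$lax))
  expect_identical(sort(accs$superstringent), sort(db$accession[db$ts == "TT"]))
  expect_identical(sort(accs$ts_stringent),
                   sort(db$accession[db$ts %in% c("TT", "T")]))
  # a ~?~N~ entry is in lax only
  raw_accs <- db$accession[db$nom == "?" & db$ts == "N"]
  expect_gt(length(raw_accs), 0)
  expect_false(any(raw_accs %in% accs$stringent))
  # genus-level: one type species per genus, TT entries only
  gl <- fl$genus_level
  expect_true(all(gl$ts == "TT"))
  expect_true(all(gl$species %in% unname(gb$registry$genus_type_species)))
})

test_that("non-SSU markers expose only the three loose flavors", {
  expect_identical(marker_flavors("ssu"),
                   c("lax", "stringent", "ts_stringent", "superstringent",
                     "genus_level"))
  expect_identical(marker_flavors("other"),
                   c("lax", "stringent", "ts_stringent"))
})

test_that("missing type strains are found by species set difference", {
  reg <- nomenclature_registry(
    valid_names = c("Aa bb", "Cc dd", "Ee ff"),
    ts_strain_ids = c(S1 = "Aa bb", S2 = "Cc dd", S3 = "Ee ff")
  )
  db <- data.frame(
    accession = c("A1", "A2", "A3"),
    name = c("Aa bb", "Cc dd", "Ee ff"),
    genus = c("Aa", "Cc", "Ee"),
    species = c("Aa bb", "Cc dd", "Ee ff"),
    grammatical = TRUE,
    nom = "v", ts = c("TT", "T", "N"),
    lineage = "Bacteria", header = "", sequence = "ACGT",
    stringsAsFactors = FALSE
  )
  expect_identical(qc_missing_ts(db, reg), "Ee ff")  # N-only: missing
  db$ts[3] <- "T"
  expect_identical(qc_missing_ts(db, reg), character(0))
  expect_identical(qc_missing_ts(db[1, ], reg), c("Cc dd", "Ee ff"))
})

test_that("GenBank flat files yield accession, organism, lineage, strains and taxid", {
  txt <- paste(
    "LOCUS       TEST0001              24 bp    DNA     linear   BCT 01-JAN-2020",
    "DEFINITION  Bacillus subtilis 16S ribosomal RNA gene.",
    "ACCESSION   TEST0001",
    "SOURCE      Bacillus subtilis",
    "  ORGANISM  Bacillus subtilis",
    "            Bacteria; Firmicutes; Bacilli;",
    "            Bacillales.",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "                     /organism=\"Bacillus subtilis\"",
    "                     /strain=\"CIP8828T\"",
    "                     /culture_collection=\"DSM:10\"",
    "                     /db_xref=\"taxon:1423\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgt",
    "//", sep = "\n")
  recs <- read_genbank(text = txt)
  expect_length(recs, 1)
  r <- recs[[1]]
  expect_identical(r$accession, "TEST0001")
  expect_identical(r$organism_name, "Bacillus subtilis")
  expect_identical(r$lineage,
                   c("Bacteria", "Firmicutes", "Bacilli", "Bacillales"))
  expect_identical(sort(r$strain_ids), c("CIP8828T", "DSM10"))
  expect_identical(r$taxid, "1423")
  expect_identical(r$sequence, "ACGTACGTACGTACGTACGTACGT")
})

test_that("registry tables round-trip through a directory of TSVs", {
  reg <- nomenclature_registry(
    valid_names = c("Aa bb", "Cc dd"),
    taxid_overrides = c("7" = "Aa bb"),
    erroneous_accessions = "X1",
    ts_strain_ids = c(CIP1T = "Aa bb"),
    lpsn_reference_accessions = "R1",
    genus_type_species = c(Aa = "Aa bb")
  )
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  expect_identical(read_registry(dir), reg)
})

test_that("flavor FASTA files round-trip through Biostrings", {
  gb <- make_genbank_records(n_records = 30, seed = 21)
  db <- build_lax(read_genbank(text = gb$text), gb$registry)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_refdb_fasta(db, path)
  back <- read_refdb_fasta(path)
  expect_identical(back$header, db$header)
  expect_identical(back$sequence, db$sequence)
})
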