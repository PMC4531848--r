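# Hand-built trees use descriptor-style tip labels so that the engine can
# read genus/species/type-strain information off the leaves; the shared
# two_genus_tree() fixture lives in helper-fixtures.R.

test_that("closest_leaf is the patristic argmin with lexicographic ties", {
  m <- matrix(c(0, 0.01, 0.5,
                0.01, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("q", "A", "B"), c("q", "A", "B")))
  expect_identical(closest_leaf(m, "q"), list(label = "A", distance = 0.01))
  m["q", "B"] <- m["B", "q"] <- 0.01
  expect_identical(closest_leaf(m, "q")$label, "A")
  expect_error(closest_leaf(m[1, 1, drop = FALSE], "q"), class = "assign_error")

  set.seed(53)
  for (i in 1:50) {
    tr <- random_tree(sample(4:15, 1))
    m <- patristic_matrix(tr)
    got <- closest_leaf(m, "t01")
    others <- setdiff(rownames(m), "t01")
    expect_equal(got$distance, min(m["t01", others]))
    expect_identical(got$label,
                     min(others[m["t01", others] == min(m["t01", others])]))
  }
})

test_that("distance pools collect intra-species and congeneric inter-species pairs", {
  # three leaves of one species pairwise 0.01 apart (star with 0.005 arms)
  labs <- vapply(1:3, function(i) ref_label("Genaa", "alpha", acc = paste0("A", i)),
                 "")
  tr <- read_phylo(text = sprintf("(%s:0.005,%s:0.005,%s:0.005);",
                                  labs[1], labs[2], labs[3]))
  d <- distance_distributions(patristic_matrix(tr), genus = "Genaa")
  expect_equal(d$intra_species, rep(0.01, 3))
  expect_equal(d$q75_species, 0.01)
  expect_identical(d$intra_genus_interspecies, numeric(0))
  expect_true(is.na(d$q75_genus))

  # four species cherries with intra distances 1, 2, 3, 4
  cherry <- function(g, e, d, i) {
    sprintf("(%s:%f,%s:%f)", ref_label(g, e, acc = paste0(i, "a")), d / 2,
            ref_label(g, e, acc = paste0(i, "b")), d / 2)
  }
  txt <- sprintf("(%s:10,%s:10,%s:10,%s:10);",
                 cherry("Genaa", "wa", 1, 1), cherry("Genaa", "wb", 2, 2),
                 cherry("Genaa", "wc", 3, 3), cherry("Genaa", "wd", 4, 4))
  tr4 <- read_phylo(text = txt)
  d4 <- distance_distributions(patristic_matrix(tr4), genus = "Genaa")
  expect_equal(sort(d4$intra_species), c(1, 2, 3, 4))
  expect_equal(d4$q75_species, 3.25)  # type-7 linear interpolation
  # genus pool: different-species pairs only
  expect_length(d4$intra_genus_interspecies, 6 * 4)

  # raw-labelled leaves are excluded from every pool
  tr_raw <- read_phylo(text = sprintf("(%s:0.005,%s:0.005,unknown_clone:0.005);",
                                      labs[1], labs[2]))
  d_raw <- distance_distributions(patristic_matrix(tr_raw), genus = "Genaa")
  expect_length(d_raw$intra_species, 1)
})

test_that("assignment suggests species and genus under the 75th percentiles", {
  tr <- two_genus_tree()
  res <- assign_taxon(tr, "QUERY")
  expect_identical(res$closest_leaf, ref_label("Genaa", "alpha", acc = "A1"))
  expect_identical(res$species_suggestion, "Genaa alpha")
  expect_identical(res$genus_suggestion, "Genaa")
  expect_true(res$closest_in_proximal)
  # the closest type strain is reported independently of the closest leaf
  expect_identical(res$closest_ts, ref_label("Genaa", "alpha", ts = "T", acc = "A2"))
  expect_identical(res$warnings, character(0))
})

test_that("a species verdict always implies its genus", {
  set.seed(59)
  for (i in 1:20) {
    fix <- make_reference_tree(synth_spec(n_genera = 2, species_per_genus = 3,
                                          seqs_per_species = 3, seed = 1000 + i))
    g <- graft_query(fix$tree, fix$truth, fix$truth$species[1],
                     distance = 0.0005)
    res <- assign_taxon(g$tree, "QUERY")
    if (!is.null(res$species_suggestion))
      expect_identical(res$genus_suggestion,
                       strsplit(res$species_suggestion, " ")[[1]][1])
  }
})

test_that("a distance exactly at the 75th percentile yields no suggestion", {
  # two same-species references 0.1 apart; the query exactly 0.1 from both
  a <- ref_label("Genaa", "alpha", acc = "A1")
  b <- ref_label("Genaa", "alpha", acc = "A2")
  tr <- read_phylo(text = sprintf("(%s:0.05,%s:0.05,QUERY:0.05);", a, b))
  res <- assign_taxon(tr, "QUERY", midpoint = FALSE)
  expect_equal(res$closest_distance, res$distributions$q75_species)
  expect_null(res$species_suggestion)
})

test_that("warning rules fire on their defining geometries", {
  # closest leaf outside the 2-node neighborhood
  tr <- two_genus_tree()
  res <- assign_taxon(tr, "QUERY")
  expect_null(warn_proximal(res))
  res$proximal$members <- setdiff(res$proximal$members, res$closest_leaf)
  expect_identical(warn_proximal(res), "CLOSEST_NOT_IN_PROXIMAL")
  res$proximal$members <- character(0)  # empty cluster: warning is vacuous
  expect_identical(warn_proximal(res), "CLOSEST_NOT_IN_PROXIMAL")

  # BLAST rank check
  hits <- paste0("h", 1:8)
  expect_null(warn_blast_rank("h1", hits))
  expect_null(warn_blast_rank("h5", hits))
  expect_identical(warn_blast_rank("h7", hits), "CLOSEST_NOT_IN_TOP5_BLAST")
  expect_null(warn_blast_rank("h3", hits[1:3]))  # fewer than five hits

  # outgroup census over grammatical genera only
  one_genus <- read_phylo(text = sprintf(
    "(%s:1,%s:1,unparsed_clone:1,QUERY:1);",
    ref_label("Genaa", "alpha", acc = "A1"),
    ref_label("Genaa", "beta", acc = "B1")))
  expect_identical(warn_outgroup(one_genus, query = "QUERY"), "NO_OUTGROUP")
  expect_null(warn_outgroup(two_genus_tree(), query = "QUERY"))
})

test_that("query QC flags undetermined bases and short first-hit coverage", {
  clean <- make_query_seq(1000, seed = 61)
  qc <- query_qc(clean, first_hit_aln_len = 990)
  expect_identical(qc$warnings, character(0))
  expect_identical(sum(qc$composition), 1000L)
  expect_identical(unname(qc$composition["other"]), 0L)

  # exactly 95 % coverage is compliant
  qc95 <- query_qc(clean, first_hit_aln_len = 950)
  expect_false("SHORT_MATCH_LENGTH" %in% qc95$warnings)
  qc94 <- query_qc(clean, first_hit_aln_len = 949)
  expect_identical(qc94$warnings, "SHORT_MATCH_LENGTH")

  # 5 % N against a 2 % threshold
  noisy <- make_query_seq(1000, seed = 61, n_frac = 0.05)
  qcn <- query_qc(noisy, first_hit_aln_len = 1000, n_threshold = 0.02)
  expect_identical(qcn$warnings, "HIGH_UNDETERMINED_BASES")
  expect_equal(qcn$frac_undetermined, 0.05)
  # 1 % N at the default 1 % threshold: not an excess (strictly greater)
  edge <- query_qc(make_query_seq(1000, seed = 61, n_frac = 0.01),
                   first_hit_aln_len = 1000)
  expect_identical(edge$warnings, character(0))

  expect_error(query_qc(""), class = "assign_error")
})

test_that("assignment is deterministic for a fixed tree", {
  tr <- two_genus_tree()
  r1 <- assign_taxon(tr, "QUERY", blast_hits = paste0("h", 1:10))
  r2 <- assign_taxon(tr, "QUERY", blast_hits = paste0("h", 1:10))
  expect_identical(r1, r2)
})
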