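# Synthetic fixtures with planted ground truth.
#
# The generator emulates the distance hierarchy the assignment engine relies
# on — strains of one species are patristically close, species of one genus
# less so, genera still less — by drawing branch lengths from exponential
# distributions with three increasing scale parameters. Trees carry
# descriptor-labelled leaves; GenBank-format record sets come with the
# registry and a truth table of intended tags so that database construction
# can be checked record-by-record. Everything is deterministic under the
# seed.

#' Specification of a synthetic reference tree
#'
#' Default scales emulate 16S-like divergence: expected intra-species
#' patristic distances well below 1 substitution per 100 sites, congeneric
#' inter-species distances around a few percent, inter-genus distances an
#' order of magnitude larger.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus.
#' @param seqs_per_species Sequences (strains) per species.
#' @param intra_species_scale Mean branch length within a species clade
#'   (substitutions/site, default 0.002).
#' @param inter_species_scale Mean branch length joining species within a
#'   genus (default 0.02).
#' @param inter_genus_scale Mean branch length joining genera (default 0.1).
#' @param query_graft_distance Default patristic distance at which
#'   [graft_query()] plants a query (default 0.001).
#' @param seed Integer seed; the same spec always generates the same
#'   fixture.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_genera = 4L, species_per_genus = 3L,
                       seqs_per_species = 3L,
                       intra_species_scale = 0.002,
                       inter_species_scale = 0.02,
                       inter_genus_scale = 0.1,
                       query_graft_distance = 0.001,
                       seed = 1L) {
  if (n_genera < 1L || species_per_genus < 1L || seqs_per_species < 1L)
    stop_proxitax("all clade counts must be at least 1", "synth_error")
  if (!(intra_species_scale < inter_species_scale &&
        inter_species_scale < inter_genus_scale))
    stop_proxitax("branch-length scales must be strictly increasing (intra < inter-species < inter-genus)",
                  "synth_error")
  structure(
    list(n_genera = as.integer(n_genera),
         species_per_genus = as.integer(species_per_genus),
         seqs_per_species = as.integer(seqs_per_species),
         intra_species_scale = intra_species_scale,
         inter_species_scale = inter_species_scale,
         inter_genus_scale = inter_genus_scale,
         query_graft_distance = query_graft_distance,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Deterministic letter-pair suffixes: 1 -> "aa", 2 -> "ab", ...
letter_suffix <- function(i) {
  paste0(letters[(i - 1L) %/% 26L + 1L], letters[(i - 1L) %% 26L + 1L])
}

synth_genus <- function(g) paste0("Genus", letter_suffix(g))
synth_epithet <- function(i) paste0("species", letter_suffix(i))

synth_lineage <- function(genus) {
  suf <- sub("^Genus", "", genus)
  c("Bacteria", paste0("Phylum", suf), paste0("Familia", suf))
}

# Random binary join of newick fragments; every new branch ~ Exp(mean scale).
join_clades <- function(parts, scale) {
  while (length(parts) > 1L) {
    idx <- sample.int(length(parts), 2L)
    len <- stats::rexp(2L, rate = 1 / scale)
    merged <- sprintf("(%s:%.10f,%s:%.10f)",
                      parts[idx[1]], len[1], parts[idx[2]], len[2])
    parts <- c(parts[-idx], merged)
  }
  parts
}

#' Generate a genus/species-structured reference tree with planted truth
#'
#' Leaves are labelled with descriptor headers (name, tags, accession); the
#' first sequence of every species is tagged `TT`, the rest `N`. Branch
#' lengths are drawn from exponential distributions at the three scales of
#' the spec, giving the intra-species < inter-species < inter-genus distance
#' hierarchy in expectation.
#'
#' @param spec A [synth_spec()].
#' @return List with `tree` (a `phylo`), `truth` (data frame: `label`,
#'   `genus`, `species`, `ts`, `lineage`) and `spec`.
#' @export
make_reference_tree <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  truth <- list()
  acc <- 0L
  genus_parts <- character(spec$n_genera)
  for (g in seq_len(spec$n_genera)) {
    genus <- synth_genus(g)
    sp_parts <- character(spec$species_per_genus)
    for (s in seq_len(spec$species_per_genus)) {
      epithet <- synth_epithet((g - 1L) * spec$species_per_genus + s)
      leaf_parts <- character(spec$seqs_per_species)
      for (q in seq_len(spec$seqs_per_species)) {
        acc <- acc + 1L
        ts <- if (q == 1L) "TT" else "N"
        label <- sprintf("%s_%s~v~%s~SYN%05d", genus, epithet, ts, acc)
        truth[[length(truth) + 1L]] <- data.frame(
          label = label, genus = genus,
          species = paste(genus, epithet), ts = ts,
          lineage = paste(c(synth_lineage(genus), genus,
                            paste(genus, epithet)), collapse = ";"),
          stringsAsFactors = FALSE
        )
        leaf_parts[q] <- label
      }
      sp_parts[s] <- join_clades(leaf_parts, spec$intra_species_scale)
    }
    genus_parts[g] <- join_clades(sp_parts, spec$inter_species_scale)
  }
  top <- join_clades(genus_parts, spec$inter_genus_scale)
  tree <- read_phylo(text = paste0(top, ";"))
  list(tree = tree, truth = do.call(rbind, truth), spec = spec)
}

#' Graft a query leaf at a controlled patristic distance
#'
#' Attaches a new leaf onto the terminal branch of a reference leaf of the
#' target species so that the patristic distance between the query and that
#' leaf equals `distance` exactly (attachment height plus pendant length).
#' The attachment height is capped below half the target's terminal branch,
#' which keeps the target the closest reference for distances smaller than
#' the local divergence.
#'
#' @param tree A reference `phylo` tree.
#' @param truth Truth table from [make_reference_tree()].
#' @param target_species Planted species (a `truth$species` value).
#' @param distance Non-negative patristic distance to the target leaf.
#' @param label Query tip label (default `"QUERY"`).
#' @return List with `tree` (query included), `target_leaf` and `distance`.
#' @export
graft_query <- function(tree, truth, target_species, distance,
                        label = "QUERY") {
  if (distance < 0)
    stop_proxitax("graft distance must be non-negative", "synth_error")
  leaves <- truth$label[truth$species == target_species]
  if (!length(leaves))
    stop_proxitax(sprintf("no leaves of species '%s'", target_species),
                  "synth_error")
  # prefer the leaf with the longest terminal branch: widest attachment room
  tip_idx <- match(leaves, tree$tip.label)
  pend <- vapply(tip_idx, function(i) {
    tree$edge.length[tree$edge[, 2] == i]
  }, numeric(1))
  target <- leaves[which.max(pend)]
  ti <- match(target, tree$tip.label)
  p <- min(distance / 2, 0.45 * max(pend))
  out <- phytools::bind.tip(tree, label, edge.length = distance - p,
                            where = ti, position = p)
  list(tree = out, target_leaf = target, distance = distance)
}

#' Fabricate a ranked BLAST hit table from a tree
#'
#' Subjects are the reference leaves ordered by increasing patristic
#' distance to the query leaf; scores decrease with rank. Standard
#' 12-column tabular layout.
#'
#' @param tree A `phylo` tree containing the query leaf.
#' @param query_label Query tip label.
#' @param query_len Nominal query length in bp (fills the alignment-length
#'   column).
#' @return A 12-column hit data frame.
#' @export
make_blast_hits <- function(tree, query_label = "QUERY", query_len = 1400L) {
  m <- patristic_matrix(tree)
  refs <- setdiff(rownames(m), query_label)
  d <- m[query_label, refs]
  ord <- order_c(d, refs)
  refs <- refs[ord]
  n <- length(refs)
  data.frame(
    qseqid = query_label, sseqid = refs,
    pident = round(100 * (1 - d[ord] / max(max(d[ord]), 1e-12)), 2),
    length = query_len, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = query_len, sstart = 1L, send = query_len,
    evalue = 0, bitscore = seq(2 * n, 2, by = -2),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n, n_frac = 0) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n_frac > 0) {
    k <- round(n_frac * n)
    if (k > 0) x[sample.int(n, k)] <- "N"
  }
  paste(x, collapse = "")
}

#' Generate GenBank-format records with intended-tag truth
#'
#' Builds a batch of annotated records with controlled fractions of short
#' sequences, domain-only lineages, ungrammatical organism names,
#' TaxId-corrected names, known-erroneous accessions and type-strain
#' flagged strain IDs, together with the matching nomenclature registry and
#' a truth table of the tags and survival status each record is built to
#' receive. Counts are exact (`round(frac * n)` records per category, drawn
#' from disjoint index sets for the exclusion categories).
#'
#' @param n_records Number of records.
#' @param n_species Number of distinct valid species names to draw from.
#' @param species_per_genus Species per genus in the name pool.
#' @param frac_short Fraction with sequence length at most 300 bp.
#' @param frac_domain_only Fraction whose lineage stops at the domain.
#' @param frac_invalid_name Fraction with an ungrammatical organism name.
#' @param frac_taxid_corrected Fraction with a misspelt organism name that a
#'   TaxId override corrects to a valid name.
#' @param frac_erroneous Fraction whose accession is on the known-erroneous
#'   list.
#' @param frac_tflag Fraction carrying a `T`-flagged strain collection ID.
#' @param seed Integer seed.
#' @return List with `text` (GenBank flat-file content), `registry`
#'   (a [nomenclature_registry()]) and `truth` (data frame: `accession`,
#'   `organism`, `name`, `nom`, `ts`, `survives`).
#' @export
make_genbank_records <- function(n_records = 60L, n_species = 12L,
                                 species_per_genus = 3L,
                                 frac_short = 0.1, frac_domain_only = 0.05,
                                 frac_invalid_name = 0.2,
                                 frac_taxid_corrected = 0.05,
                                 frac_erroneous = 0.05, frac_tflag = 0.3,
                                 seed = 1L) {
  set.seed(seed)
  n <- as.integer(n_records)
  n_genera <- ceiling(n_species / species_per_genus)
  genera <- synth_genus(seq_len(n_genera))
  species_pool <- vapply(seq_len(n_species), function(i) {
    g <- genera[(i - 1L) %/% species_per_genus + 1L]
    paste(g, synth_epithet(i))
  }, character(1))

  idx <- sample.int(n)  # random disjoint category assignment
  take <- function(k) {
    out <- utils::head(idx, k)
    idx <<- utils::tail(idx, -k)
    out
  }
  short_idx <- take(round(frac_short * n))
  domain_idx <- take(round(frac_domain_only * n))
  invalid_idx <- sort(c(take(round(frac_invalid_name * n))))
  taxid_idx <- take(round(frac_taxid_corrected * n))
  err_idx <- take(round(frac_erroneous * n))
  tflag_idx <- sort(sample.int(n, round(frac_tflag * n)))

  accession <- sprintf("GB%06d", seq_len(n))
  taxid <- 100000L + seq_len(n)
  true_species <- sample(species_pool, n, replace = TRUE)
  organism <- true_species
  final_name <- true_species
  organism[invalid_idx] <- sprintf("uncultured bacterium clone C%03d", invalid_idx)
  final_name[invalid_idx] <- organism[invalid_idx]
  # TaxId-corrected records: misspelt (ungrammatical) organism field, but the
  # override table restores the valid name before tagging.
  organism[taxid_idx] <- paste0(sub(" ", "_", true_species[taxid_idx]), " str?")
  final_name[taxid_idx] <- true_species[taxid_idx]

  len <- sample(1000:1500, n, replace = TRUE)
  len[short_idx] <- sample(150:300, length(short_idx), replace = TRUE)

  strain <- sprintf("CIP%04d", 1000L + seq_len(n))
  strain[tflag_idx] <- paste0(strain[tflag_idx], "T")

  grammatical <- is_grammatical_name(final_name)
  nom <- ifelse(accession %in% accession[err_idx], "X",
                ifelse(final_name %in% species_pool, "v", "?"))
  has_flag <- seq_len(n) %in% tflag_idx
  ts <- ifelse(has_flag, ifelse(grammatical, "T", "t"), "N")
  survives <- !(seq_len(n) %in% short_idx) & !(seq_len(n) %in% domain_idx)

  # LPSN "reference sequence" designation: the first surviving, clean,
  # valid-name record of each genus's type species (the pool's first species
  # in the genus), promoted to TT.
  genus_type_species <- stats::setNames(
    species_pool[seq(1L, n_species, by = species_per_genus)],
    genera[seq_len(length(seq(1L, n_species, by = species_per_genus)))]
  )
  lpsn <- character()
  for (tsp in unname(genus_type_species)) {
    cand <- which(final_name == tsp & survives & nom == "v")
    if (length(cand)) {
      lpsn <- c(lpsn, accession[cand[1]])
      ts[cand[1]] <- "TT"
    }
  }

  registry <- nomenclature_registry(
    valid_names = species_pool,
    taxid_overrides = stats::setNames(true_species[taxid_idx],
                                      as.character(taxid[taxid_idx])),
    erroneous_accessions = accession[err_idx],
    ts_strain_ids = stats::setNames(final_name[has_flag & grammatical],
                                    strain[has_flag & grammatical]),
    lpsn_reference_accessions = lpsn,
    genus_type_species = genus_type_species
  )

  lineage <- vapply(seq_len(n), function(i) {
    if (i %in% domain_idx) return("Bacteria")
    g <- strsplit(true_species[i], " ")[[1]][1]
    paste(c(synth_lineage(g), g), collapse = "; ")
  }, character(1))

  recs <- vapply(seq_len(n), function(i) {
    seqtxt <- random_dna(len[i])
    seq_lines <- character()
    pos <- seq(1L, len[i], by = 60L)
    for (p in pos) {
      block <- substr(seqtxt, p, min(p + 59L, len[i]))
      chunks <- substring(block, seq(1, nchar(block), 10),
                          pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
      seq_lines <- c(seq_lines,
                     sprintf("%9d %s", p, paste(tolower(chunks), collapse = " ")))
    }
    paste(c(
      sprintf("LOCUS       %s%17d bp    DNA     linear   BCT 01-JAN-2020",
              accession[i], len[i]),
      sprintf("DEFINITION  %s 16S ribosomal RNA gene, partial sequence.",
              organism[i]),
      sprintf("ACCESSION   %s", accession[i]),
      sprintf("SOURCE      %s", organism[i]),
      sprintf("  ORGANISM  %s", organism[i]),
      sprintf("            %s.", lineage[i]),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", len[i]),
      sprintf("                     /organism=\"%s\"", organism[i]),
      sprintf("                     /strain=\"%s\"", strain[i]),
      sprintf("                     /db_xref=\"taxon:%d\"", taxid[i]),
      "ORIGIN",
      seq_lines,
      "//"
    ), collapse = "\n")
  }, character(1))

  truth <- data.frame(
    accession = accession, organism = organism, name = final_name,
    nom = nom, ts = ts, survives = survives, stringsAsFactors = FALSE
  )
  list(text = paste(recs, collapse = "\n"), registry = registry, truth = truth)
}
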