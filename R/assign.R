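# Tree-analysis engine.
#
# Given a tree over a query leaf and its recruited reference neighbors, the
# engine reports the patristically closest reference, the proximal cluster,
# and percentile-based species/genus suggestions: the query putatively
# belongs to the species of its closest reference when its distance to that
# reference falls under the 75th percentile of the intra-species patristic
# distance distribution observed in the tree, and to the genus of the
# closest species when the same distance falls under the 75th percentile of
# that genus's inter-species distances. A closed set of warning codes flags
# the situations that make the verdicts fragile.

#' Warning codes of the assignment engine
#'
#' @format Character vector of the seven diagnostic codes.
#' @export
WARNING_CODES <- c(
  "CLOSEST_NOT_IN_PROXIMAL",
  "CLOSEST_NOT_IN_TOP5_BLAST",
  "NO_OUTGROUP",
  "TOO_FEW_BLAST_HITS",
  "HIGH_UNDETERMINED_BASES",
  "SHORT_MATCH_LENGTH",
  "NO_INTRASPECIES_DISTRIBUTION"
)

#' Closest reference leaf by patristic distance
#'
#' @param m A patristic matrix (see [patristic_matrix()]).
#' @param query The query label (a row/column of `m`).
#' @param candidates Optional subset of labels to search; defaults to all
#'   labels except the query.
#' @return List with `label` and `distance`; ties are broken by the
#'   lexicographically smallest label (C collation).
#' @export
closest_leaf <- function(m, query, candidates = NULL) {
  if (!query %in% rownames(m))
    stop_proxitax(sprintf("query '%s' not in matrix", query), "assign_error")
  cand <- candidates %||% setdiff(rownames(m), query)
  cand <- setdiff(cand, query)
  if (length(cand) == 0L)
    stop_proxitax("no reference leaves to compare against", "assign_error")
  d <- m[query, cand]
  cand <- sort_c(cand[d == min(d)])
  list(label = cand[1], distance = unname(min(d)))
}

# Species/genus bookkeeping for the reference leaves of a tree: parse every
# tip label through the descriptor grammar; leaves with raw (ungrammatical)
# names carry no usable taxonomy and are excluded from the pools.
leaf_taxonomy <- function(labels, query = NULL) {
  refs <- setdiff(labels, query)
  info <- lapply(refs, parse_leaf_label)
  keep <- vapply(info, function(x) !is.null(x) && inherits(x$name, "taxon_name"),
                 logical(1))
  data.frame(
    label = refs[keep],
    genus = vapply(info[keep], function(x) x$name$genus, character(1)),
    species = vapply(info[keep],
                     function(x) paste(x$name$genus, x$name$species),
                     character(1)),
    ts = vapply(info[keep], function(x) x$ts, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Intra-species and intra-genus distance distributions
#'
#' Pools the patristic distances between reference leaves sharing a binomial
#' (all species in the tree, query excluded) and, within the genus of the
#' closest reference, the distances between leaves of different species.
#' The 75th percentiles use linear interpolation between order statistics
#' (quantile type 7); an empty pool yields an undefined (`NA`) percentile.
#'
#' @param m A patristic matrix over the tree leaves.
#' @param query The query label, excluded from all pools (may be `NULL`).
#' @param genus Genus whose inter-species pool is computed (typically the
#'   genus of the closest reference); `NA` yields an empty genus pool.
#' @return List with `intra_species`, `intra_genus_interspecies`,
#'   `q75_species`, `q75_genus`.
#' @export
distance_distributions <- function(m, query = NULL, genus = NA_character_) {
  tax <- leaf_taxonomy(rownames(m), query)
  intra <- numeric()
  if (nrow(tax) >= 2L) {
    for (sp in unique(tax$species)) {
      lab <- tax$label[tax$species == sp]
      if (length(lab) >= 2L) {
        sub <- m[lab, lab, drop = FALSE]
        intra <- c(intra, sub[upper.tri(sub)])
      }
    }
  }
  inter <- numeric()
  if (!is.na(genus)) {
    gt <- tax[tax$genus == genus, , drop = FALSE]
    if (nrow(gt) >= 2L) {
      for (i in seq_len(nrow(gt) - 1L)) {
        for (j in seq.int(i + 1L, nrow(gt))) {
          if (gt$species[i] != gt$species[j])
            inter <- c(inter, m[gt$label[i], gt$label[j]])
        }
      }
    }
  }
  q75 <- function(x) if (length(x)) stats::quantile(x, 0.75, type = 7, names = FALSE) else NA_real_
  list(
    intra_species = intra,
    intra_genus_interspecies = inter,
    q75_species = q75(intra),
    q75_genus = q75(inter)
  )
}

#' Assign a query leaf to a species and genus from its tree
#'
#' Runs the complete tree analysis: midpoint rooting (optional, on by
#' default so that node distances are read on the displayed tree), closest
#' reference leaf, proximal cluster, distance distributions, percentile
#' verdicts (strict inequality at the boundary), closest type strain, and
#' the warning set.
#'
#' @param tree A `phylo` tree containing the query leaf.
#' @param query The query tip label.
#' @param blast_hits Optional character vector of hit subject labels ordered
#'   by decreasing score; enables the top-5-hit cross-check.
#' @param k Node-distance radius of the proximal cluster (default 2).
#' @param midpoint Midpoint-root the tree before the analysis (default
#'   `TRUE`).
#' @return An object of class `taxon_assignment`: `query`, `closest_leaf`,
#'   `closest_distance`, `proximal` ([proximal_cluster()]),
#'   `closest_in_proximal`, `distributions`, `species_suggestion`,
#'   `genus_suggestion`, `closest_ts`, `closest_ts_distance`,
#'   `closest_ts_in_proximal`, `warnings`.
#' @export
assign_taxon <- function(tree, query, blast_hits = NULL, k = 2L,
                         midpoint = TRUE) {
  if (!query %in% tree$tip.label)
    stop_proxitax(sprintf("query '%s' is not a leaf of the tree", query),
                  "assign_error")
  if (midpoint) tree <- midpoint_root(tree)
  m <- patristic_matrix(tree)
  cl <- closest_leaf(m, query)
  prox <- proximal_cluster(tree, query, k = k)

  tax <- leaf_taxonomy(tree$tip.label, query)
  closest_tax <- tax[tax$label == cl$label, , drop = FALSE]
  genus_of_closest <- if (nrow(closest_tax)) closest_tax$genus else NA_character_
  dist_d <- distance_distributions(m, query = query, genus = genus_of_closest)

  warnings <- character()

  species_suggestion <- NULL
  genus_suggestion <- NULL
  if (length(dist_d$intra_species) == 0L)
    warnings <- c(warnings, "NO_INTRASPECIES_DISTRIBUTION")
  if (nrow(closest_tax)) {
    if (!is.na(dist_d$q75_species) && cl$distance < dist_d$q75_species)
      species_suggestion <- closest_tax$species
    if (!is.na(dist_d$q75_genus) && cl$distance < dist_d$q75_genus)
      genus_suggestion <- genus_of_closest
    # a species verdict always implies its genus
    if (!is.null(species_suggestion) && is.null(genus_suggestion))
      genus_suggestion <- genus_of_closest
  }

  ts_leaves <- tax$label[tax$ts %in% c("TT", "T")]
  closest_ts <- NULL; closest_ts_distance <- NA_real_; ts_in_prox <- NA
  if (length(ts_leaves)) {
    ct <- closest_leaf(m, query, candidates = ts_leaves)
    closest_ts <- ct$label
    closest_ts_distance <- ct$distance
    ts_in_prox <- closest_ts %in% prox$members
  }

  res <- structure(
    list(query = query,
         closest_leaf = cl$label,
         closest_distance = cl$distance,
         proximal = prox,
         closest_in_proximal = cl$label %in% prox$members,
         distributions = dist_d,
         species_suggestion = species_suggestion,
         genus_suggestion = genus_suggestion,
         closest_ts = closest_ts,
         closest_ts_distance = closest_ts_distance,
         closest_ts_in_proximal = ts_in_prox,
         warnings = warnings),
    class = "taxon_assignment"
  )

  w <- warn_proximal(res)
  if (!is.null(w)) res$warnings <- c(res$warnings, w)
  if (!is.null(blast_hits)) {
    w <- warn_blast_rank(cl$label, blast_hits)
    if (!is.null(w)) res$warnings <- c(res$warnings, w)
  }
  w <- warn_outgroup(tree, query = query)
  if (!is.null(w)) res$warnings <- c(res$warnings, w)
  res$warnings <- intersect(WARNING_CODES, res$warnings)  # fixed canonical order
  res
}

#' Warn when the closest leaf lies outside the proximal cluster
#'
#' Disagreement between the patristic ranking and the topological
#' neighborhood indicates a possible reconstruction problem (e.g. long-branch
#' effects) and calls for a careful reading of the tree and its supports.
#'
#' @param result A `taxon_assignment`.
#' @return `"CLOSEST_NOT_IN_PROXIMAL"` or `NULL`.
#' @export
warn_proximal <- function(result) {
  if (!result$closest_leaf %in% result$proximal$members)
    "CLOSEST_NOT_IN_PROXIMAL" else NULL
}

#' Warn when the closest leaf is not among the five best BLAST hits
#'
#' The best BLAST hit frequently is not the evolutionarily closest neighbor;
#' the converse situation — the tree's closest leaf ranking low in the hit
#' list — is worth flagging too.
#'
#' @param closest Closest leaf label.
#' @param hits Hit subject labels ordered by decreasing score; with fewer
#'   than five hits the comparison uses all of them.
#' @param top Number of top hits checked (default 5).
#' @return `"CLOSEST_NOT_IN_TOP5_BLAST"` or `NULL`.
#' @export
warn_blast_rank <- function(closest, hits, top = 5L) {
  if (!closest %in% utils::head(hits, top)) "CLOSEST_NOT_IN_TOP5_BLAST" else NULL
}

#' Warn when the tree contains a single genus
#'
#' The genera of all reference leaves with grammatical names are collated;
#' if they are all identical no outgroup is available and it is advisable to
#' repeat the analysis with more recruited sequences.
#'
#' @param tree A `phylo` tree.
#' @param query Query tip label to exclude from the census.
#' @return `"NO_OUTGROUP"` or `NULL`.
#' @export
warn_outgroup <- function(tree, query = NULL) {
  tax <- leaf_taxonomy(tree$tip.label, query)
  genera <- unique(tax$genus)
  if (length(genera) == 1L) "NO_OUTGROUP" else NULL
}

#' Query-sequence quality control
#'
#' Reports the base composition of the query and flags (i) an excess of
#' undetermined (non-ACGT) bases, which degrade the phylogeny, and (ii) a
#' first-hit alignment covering less than 95 % of the query length, which
#' may indicate local low sequence quality.
#'
#' @param seq Query nucleotide string (IUPAC alphabet).
#' @param first_hit_aln_len Alignment length of the best BLAST hit in bp, or
#'   `NA` to skip the coverage check.
#' @param n_threshold Maximum tolerated fraction of undetermined bases
#'   (default 0.01).
#' @param min_match_frac Minimum compliant alignment-length fraction
#'   (default 0.95; exactly 95 % is compliant).
#' @return List with `length`, `composition` (named counts of A/C/G/T and
#'   `other`), `frac_undetermined`, `match_frac` and `warnings`.
#' @export
query_qc <- function(seq, first_hit_aln_len = NA, n_threshold = 0.01,
                     min_match_frac = 0.95) {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  n <- nchar(seq)
  if (n == 0L) stop_proxitax("empty query sequence", "assign_error")
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = sum(chars == "A"), C = sum(chars == "C"),
            G = sum(chars == "G"), T = sum(chars == "T"))
  comp <- c(comp, other = n - sum(comp))
  frac_undet <- unname(comp["other"]) / n
  warnings <- character()
  if (frac_undet > n_threshold)
    warnings <- c(warnings, "HIGH_UNDETERMINED_BASES")
  match_frac <- NA_real_
  if (!is.na(first_hit_aln_len)) {
    match_frac <- first_hit_aln_len / n
    if (match_frac < min_match_frac)
      warnings <- c(warnings, "SHORT_MATCH_LENGTH")
  }
  list(length = n, composition = comp, frac_undetermined = frac_undet,
       match_frac = match_frac, warnings = warnings)
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat("<taxon_assignment>", x$query, "\n")
  cat(sprintf("  closest: %s (d = %.6g)%s\n", x$closest_leaf,
              x$closest_distance,
              if (x$closest_in_proximal) " [in proximal cluster]" else ""))
  cat(sprintf("  proximal cluster (k = %d): %d members\n",
              x$proximal$k, length(x$proximal$members)))
  cat("  species suggestion:", x$species_suggestion %||% "none", "\n")
  cat("  genus suggestion:  ", x$genus_suggestion %||% "none", "\n")
  cat("  warnings:", if (length(x$warnings)) paste(x$warnings, collapse = ", ") else "none", "\n")
  invisible(x)
}
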