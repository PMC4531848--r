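# Taxonomy-relabelled trees ("taxo-trees").
#
# Relabelling every reference leaf with its full taxonomic classification
# string, minus the prefix shared by all leaves of the tree, turns the tree
# into a quick visual check for BLAST recruitment errors: an outlier whose
# taxonomy does not match its surroundings stands out immediately.

#' Longest rank-wise common prefix of a set of lineages
#'
#' Operates on whole ranks, never on characters within a rank name.
#'
#' @param lineages A list of character vectors (lineages from the domain
#'   downward).
#' @return Character vector: the shared prefix (possibly empty).
#' @export
shared_prefix <- function(lineages) {
  if (length(lineages) == 0L)
    stop_proxitax("need at least one lineage", "taxotree_error")
  prefix <- lineages[[1]]
  for (lin in lineages[-1]) {
    n <- min(length(prefix), length(lin))
    if (n == 0L) return(character())
    same <- prefix[seq_len(n)] == lin[seq_len(n)]
    upto <- if (all(same)) n else which(!same)[1] - 1L
    if (upto == 0L) return(character())
    prefix <- prefix[seq_len(upto)]
  }
  prefix
}

#' Relabel tree leaves with their unshared taxonomy suffix
#'
#' Topology and branch lengths are untouched; each reference leaf label is
#' replaced by the part of its lineage remaining after removal of the
#' rank-wise prefix shared by all reference leaves, joined by `";"`. When
#' all lineages are identical the suffix would be empty, so the display
#' falls back to the terminal rank. The query leaf (if named) keeps its
#' label.
#'
#' @param tree A `phylo` tree.
#' @param lineage_of Named list (or named character vector of `;`-joined
#'   strings) mapping each reference tip label to its lineage.
#' @param query Optional query tip label, exempt from relabelling.
#' @return The relabelled `phylo` tree.
#' @export
relabel_taxo <- function(tree, lineage_of, query = NULL) {
  if (is.character(lineage_of))
    lineage_of <- lapply(lineage_of, function(x) strsplit(x, ";", fixed = TRUE)[[1]])
  refs <- setdiff(tree$tip.label, query)
  missing <- refs[!refs %in% names(lineage_of)]
  if (length(missing))
    stop_proxitax(paste0("leaves without lineage: ",
                         paste(missing, collapse = ", ")),
                  "taxotree_error")
  lins <- lineage_of[refs]
  prefix <- shared_prefix(lins)
  np <- length(prefix)
  out <- tree
  newlab <- tree$tip.label
  for (i in seq_along(newlab)) {
    leaf <- tree$tip.label[i]
    if (!leaf %in% refs) next
    lin <- lins[[leaf]]
    suffix <- if (length(lin) > np) lin[seq.int(np + 1L, length(lin))] else lin[length(lin)]
    newlab[i] <- paste(suffix, collapse = ";")
  }
  out$tip.label <- newlab
  out
}
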