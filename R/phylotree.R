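# Tree geometry kernel: Newick I/O with support labels, midpoint rooting,
# patristic distances, topological node distances and the proximal cluster.
#
# Trees are `ape::phylo` objects. Internal node labels, when numeric, are
# read as per-split support values in [0, 1] (the convention of
# approximate-ML programs that attach SH-test supports to splits).

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with the validation the assignment engine relies
#' on: unique tip labels, finite non-negative branch lengths, and numeric
#' internal-node labels interpreted as supports in `[0, 1]`.
#'
#' @param file Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_phylo <- function(file = NULL, text = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_proxitax("malformed Newick input", "newick_parse_error")
  validate_phylo(tree)
  tree
}

validate_phylo <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop_proxitax(sprintf(
      "duplicate tip labels: %s",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")),
      "newick_parse_error")
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)))
      stop_proxitax("non-finite branch length", "newick_parse_error")
    if (any(tree$edge.length < 0))
      stop_proxitax("negative branch length", "newick_parse_error")
  }
  sup <- node_supports(tree)
  bad <- !is.na(sup) & (sup < 0 | sup > 1)
  if (any(bad))
    stop_proxitax("support values must lie in [0, 1]", "newick_parse_error")
  invisible(tree)
}

#' Numeric support values of internal nodes
#'
#' @param tree A `phylo` tree.
#' @return Numeric vector (length = number of internal nodes); `NA` where a
#'   node has no numeric label.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` tree.
#' @param file Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_phylo <- function(tree, file = NULL) {
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(ape::write.tree(tree))
  }
}

#' Midpoint-root a tree
#'
#' Places the root at the middle of the largest tip-to-tip patristic
#' distance, so that both endpoint leaves lie at distance D/2 from the root.
#' Total branch length and the patristic matrix are conserved; support
#' labels are remapped to the corresponding splits.
#'
#' @param tree A `phylo` tree with at least 2 tips and at least one strictly
#'   positive branch length.
#' @return The midpoint-rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) < 2L)
    stop_proxitax("midpoint rooting needs at least 2 tips", "phylo_error")
  if (is.null(tree$edge.length) || all(tree$edge.length <= 0))
    stop_proxitax("degenerate tree: all branch lengths are zero", "phylo_error")
  phangorn::midpoint(tree, node.labels = "support")
}

#' Patristic distance matrix
#'
#' The patristic distance between two leaves is the sum of the branch
#' lengths on the path connecting them; it is invariant to (re)rooting.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length))
    stop_proxitax("tree has no branch lengths", "phylo_error")
  ape::cophenetic.phylo(tree)
}

# Adjacency list over all nodes (tips + internals) of a phylo tree.
phylo_adjacency <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS over the node graph: number of edges from `from` to every node.
bfs_edge_dist <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Topological node distance between two leaves
#'
#' The number of internal nodes on the simple path between two leaves (the
#' leaves themselves excluded). Siblings are at distance 1; `a == b` is
#' defined as 0. When the tree is rooted the root counts as an internal node
#' if it lies on the path, so the distance should be read on the
#' midpoint-rooted tree the user sees.
#'
#' @param tree A `phylo` tree.
#' @param a,b Tip labels.
#' @return Integer node count.
#' @export
node_distance <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib))
    stop_proxitax(sprintf("unknown leaf: %s",
                          paste(c(a, b)[is.na(c(ia, ib))], collapse = ", ")),
                  "phylo_error")
  if (ia == ib) return(0L)
  d <- bfs_edge_dist(phylo_adjacency(tree), ia)
  # path has (edges + 1) nodes, two of which are the endpoint leaves
  d[ib] - 1L
}

#' Node distances from one leaf to all others
#'
#' @param tree A `phylo` tree.
#' @param query A tip label.
#' @return Named integer vector over the other tips.
#' @export
node_distances <- function(tree, query) {
  iq <- match(query, tree$tip.label)
  if (is.na(iq))
    stop_proxitax(sprintf("unknown leaf: %s", query), "phylo_error")
  d <- bfs_edge_dist(phylo_adjacency(tree), iq)
  tips <- setdiff(seq_len(ape::Ntip(tree)), iq)
  stats::setNames(d[tips] - 1L, tree$tip.label[tips])
}

#' Proximal cluster of a query leaf
#'
#' All leaves at a topological distance of `k` internal nodes or less from
#' the query (default `k = 2`): the query's local neighborhood in the tree,
#' against which the patristically closest sequence is cross-checked.
#'
#' @param tree A `phylo` tree.
#' @param query The query tip label.
#' @param k Maximum node distance (default 2).
#' @return An object of class `proximal_cluster` with elements `query`,
#'   `members` (sorted tip labels) and `k`.
#' @export
proximal_cluster <- function(tree, query, k = 2L) {
  stopifnot(k >= 0)
  nd <- node_distances(tree, query)
  structure(
    list(query = query, members = sort_c(names(nd)[nd <= k]), k = as.integer(k)),
    class = "proximal_cluster"
  )
}

#' @export
print.proximal_cluster <- function(x, ...) {
  cat(sprintf("<proximal_cluster> query=%s k=%d members=%d\n",
              x$query, x$k, length(x$members)))
  if (length(x$members)) cat(" ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a split support value
#'
#' Branch-display convention: supports at or above 0.95 are strong (drawn
#' widest), supports at or below 0.80 are weak (drawn thin), the rest
#' intermediate.
#'
#' @param sh Numeric vector of support values in `[0, 1]`.
#' @return Character vector over `{"strong", "intermediate", "weak"}`.
#' @export
support_class <- function(sh) {
  if (any(!is.na(sh) & (sh < 0 | sh > 1)))
    stop_proxitax("support values must lie in [0, 1]", "phylo_error")
  ifelse(is.na(sh), NA_character_,
         ifelse(sh >= 0.95, "strong",
                ifelse(sh <= 0.80, "weak", "intermediate")))
}
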