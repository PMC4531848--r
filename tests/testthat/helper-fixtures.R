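# Fixture builders shared across the suite. All randomness uses the ambient
# RNG; tests seed explicitly so every run is reproducible.

rand_word <- function(n = 6, upper = FALSE) {
  w <- paste(sample(letters, n, replace = TRUE), collapse = "")
  if (upper) w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, n))
  w
}

rand_words <- function(k, upper = TRUE) {
  vapply(seq_len(k), function(i) rand_word(upper = upper), character(1))
}

# A random valid header: grammatical binomial/trinomial or a raw label,
# random tags, accession and lineage.
random_header <- function() {
  kind <- sample(c("binomial", "trinomial", "raw"), 1)
  name <- switch(kind,
    binomial = taxon_name(rand_word(upper = TRUE), rand_word()),
    trinomial = taxon_name(rand_word(upper = TRUE), rand_word(), rand_word()),
    raw = paste("uncultured", rand_word(), "clone", rand_word(4))
  )
  seq_header(
    name = name,
    nom = sample(c("v", "?", "X"), 1),
    ts = sample(c("TT", "T", "t", "N"), 1),
    accession = paste0(toupper(rand_word(2)), sample(10000:99999, 1)),
    lineage = c(sample(c("Bacteria", "Archaea"), 1),
                rand_words(sample(0:3, 1)))
  )
}

# Random tree with exponential branch lengths and simple unique tip labels.
random_tree <- function(n, scale = 0.1) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / scale)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

tree_graph <- function(tree) {
  igraph::graph_from_edgelist(tree$edge, directed = FALSE)
}

# All-pairs shortest-path oracle for patristic distances (Dijkstra over the
# weighted node graph).
oracle_patristic <- function(tree) {
  g <- tree_graph(tree)
  n <- ape::Ntip(tree)
  d <- igraph::distances(g, weights = tree$edge.length)
  out <- d[seq_len(n), seq_len(n)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# BFS oracle for the internal-node-count distance between two tips.
oracle_node_dist <- function(tree) {
  g <- tree_graph(tree)
  n <- ape::Ntip(tree)
  d <- igraph::distances(g, weights = NA)[seq_len(n), seq_len(n)]
  out <- d - 1
  diag(out) <- 0
  storage.mode(out) <- "integer"
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Reference leaf label in descriptor form (no lineage, as on tree tips).
ref_label <- function(genus, epithet, ts = "N", nom = "v", acc = "A0001") {
  sprintf("%s_%s~%s~%s~%s", genus, epithet, nom, ts, acc)
}

# A small hand-built assignment fixture: query next to a two-strain species,
# a congeneric species pair, and a distant outgroup genus pair.
two_genus_tree <- function() {
  labs <- c(
    a1 = ref_label("Genaa", "alpha", acc = "A1"),
    a2 = ref_label("Genaa", "alpha", ts = "T", acc = "A2"),
    b1 = ref_label("Genaa", "beta", acc = "B1"),
    b2 = ref_label("Genaa", "beta", ts = "TT", acc = "B2"),
    c1 = ref_label("Genbb", "gamma", acc = "C1"),
    c2 = ref_label("Genbb", "gamma", acc = "C2")
  )
  txt <- sprintf(
    "(((QUERY:0.001,%s:0.004):0.001,%s:0.005):0.02,((%s:0.004,%s:0.006):0.02,(%s:0.005,%s:0.005):0.2):0.02);",
    labs["a1"], labs["a2"], labs["b1"], labs["b2"], labs["c1"], labs["c2"])
  read_phylo(text = txt)
}

# Deterministic pseudo-random query sequence.
make_query_seq <- function(n = 1200, seed = 11, n_frac = 0) {
  set.seed(seed)
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n_frac > 0) x[seq_len(round(n_frac * n))] <- "N"
  paste(x, collapse = "")
}

# Sorted bipartition fingerprint of a tree, in terms of tip indices, for
# topology-preservation checks that must not depend on labels.
bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  n <- ape::Ntip(tree)
  canon <- lapply(pp, function(p) {
    p <- sort(p)
    comp <- sort(setdiff(seq_len(n), p))
    key <- if (1L %in% p) p else comp
    paste(key, collapse = ",")
  })
  sort(unlist(canon))
}
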