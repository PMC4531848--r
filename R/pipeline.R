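# Pipeline orchestration.
#
# The end-to-end analysis of a query is: recruit the most similar reference
# sequences by BLAST, align them (MAFFT), trim the alignment (BMGE), infer
# an approximate-ML tree (FastTree, GTR+Gamma, SH supports), midpoint-root,
# analyze, report. The external programs sit behind a backend interface of
# four stage contracts (search, align, trim, infer); a fully deterministic
# mock backend, driven by a tree with planted truth, ships with the package
# so that everything around the external tools is testable offline.

#' Pipeline configuration
#'
#' Only two parameters are meant for routine user control: the number of
#' closely related sequences recruited into the tree and the alignment mode
#' (speed or accuracy). The remaining knobs encode the pipeline's fixed
#' conventions.
#'
#' @param flavor Reference-database flavor name.
#' @param n_neighbors Number of recruited reference sequences (default 50).
#' @param align_mode `"speed"` or `"accuracy"`.
#' @param min_hits Minimum number of BLAST hits below which the analysis
#'   aborts (default 10): fewer hits signal that something went wrong.
#' @param evalue_max BLAST expectation-value cutoff (default 0.1; the search
#'   runs without low-complexity filtering).
#' @param k_proximal Node-distance radius of the proximal cluster.
#' @param n_threshold Maximum tolerated undetermined-base fraction.
#' @param batch_max Maximum number of queries per batch (default 1000).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(flavor = "stringent", n_neighbors = 50L,
                            align_mode = c("accuracy", "speed"),
                            min_hits = 10L, evalue_max = 0.1,
                            k_proximal = 2L, n_threshold = 0.01,
                            batch_max = 1000L) {
  align_mode <- match.arg(align_mode)
  stopifnot(n_neighbors >= 1L, evalue_max > 0, min_hits >= 0L, batch_max >= 1L)
  structure(
    list(flavor = flavor, n_neighbors = as.integer(n_neighbors),
         align_mode = align_mode, min_hits = as.integer(min_hits),
         evalue_max = evalue_max, k_proximal = as.integer(k_proximal),
         n_threshold = n_threshold, batch_max = as.integer(batch_max)),
    class = "pipeline_config"
  )
}

#' Read a 12-column tabular BLAST hit list
#'
#' The standard tabular dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param file Path to the hit table, or `NULL` when `text` is given.
#' @param text Character scalar with the table content.
#' @return A data frame with the twelve standard columns.
#' @export
read_blast_tab <- function(file = NULL, text = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- if (is.null(text)) {
    utils::read.table(file, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
  } else {
    utils::read.table(text = text, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
  }
  if (ncol(df) != 12L)
    stop_proxitax(sprintf("expected 12 tab-separated columns, found %d", ncol(df)),
                  "blast_parse_error")
  names(df) <- cols
  df
}

#' Recruit reference sequences from a ranked BLAST hit list
#'
#' Takes the first `n` distinct subject labels from the score-ordered hit
#' list (duplicated subjects are deduplicated, promoting the next-ranked
#' hit). Aborts with a `too_few_blast_hits_error` when fewer than `min_hits`
#' hits are available.
#'
#' @param hits A hit data frame (see [read_blast_tab()]) or a character
#'   vector of subject labels, ordered by decreasing score.
#' @param n Number of sequences to recruit.
#' @param min_hits Abort threshold (default 10).
#' @return Character vector of recruited subject labels.
#' @export
recruit <- function(hits, n, min_hits = 10L) {
  labels <- if (is.data.frame(hits)) hits$sseqid else as.character(hits)
  if (length(labels) < min_hits)
    stop_proxitax(sprintf(
      "only %d BLAST hits (< %d): something went wrong with the query [TOO_FEW_BLAST_HITS]",
      length(labels), min_hits), "too_few_blast_hits_error")
  utils::head(unique(labels), n)
}

#' Mock pipeline backend driven by a fixed tree
#'
#' Implements the four stage contracts without external programs: `search`
#' ranks the reference leaves of `tree` by patristic distance to the query
#' leaf and fabricates a 12-column hit table; `align` and `trim` pass
#' sequences through; `infer` prunes `tree` to the recruited leaves plus the
#' query (path lengths are conserved under pruning, so the planted
#' geometry survives). Fully deterministic.
#'
#' @param tree A `phylo` tree containing the query leaf and reference
#'   leaves labelled with descriptor headers.
#' @param query_label Tip label of the query inside `tree`.
#' @return A backend list with elements `search`, `align`, `trim`, `infer`.
#' @export
mock_backend <- function(tree, query_label = "QUERY") {
  force(tree); force(query_label)
  m <- patristic_matrix(tree)
  list(
    search = function(query_id, query_seq, config) {
      refs <- setdiff(rownames(m), query_label)
      d <- m[query_label, refs]
      ord <- order_c(d, refs)
      refs <- refs[ord]
      n <- length(refs)
      data.frame(
        qseqid = query_id, sseqid = refs,
        pident = round(100 * (1 - d[ord] / max(d[ord], 1e-12)), 2),
        length = nchar(query_seq), mismatch = 0L, gapopen = 0L,
        qstart = 1L, qend = nchar(query_seq),
        sstart = 1L, send = nchar(query_seq),
        evalue = 0, bitscore = seq(2 * n, 2, by = -2),
        stringsAsFactors = FALSE
      )
    },
    align = function(seqs, config) seqs,
    trim = function(aln, config) aln,
    infer = function(aln, config) {
      keep <- intersect(tree$tip.label, c(query_label, names(aln)))
      ape::keep.tip(tree, keep)
    }
  )
}

#' Run the analysis pipeline over a batch of queries
#'
#' Each query is processed in isolation (one failure does not abort the
#' batch): search, recruit, align, trim, infer, midpoint-root, tree
#' analysis, taxo-tree, report.
#'
#' @param queries Named character vector of query nucleotide sequences.
#' @param config A [pipeline_config()].
#' @param backend A backend list (see [mock_backend()]).
#' @param lineage_of Optional named lineage map for the taxo-tree; when
#'   `NULL` the taxo-tree is skipped.
#' @param db_meta Optional list describing the database (`flavor`, `n`);
#'   used by the report header.
#' @return A list of per-query results: each either a `query_report` (with
#'   elements `query`, `assignment`, `qc`, `tree`, `taxo_tree`, `recruited`,
#'   `report` — the rendered text) or a `query_error` (`query`, `stage`,
#'   `message`).
#' @export
run_pipeline <- function(queries, config = pipeline_config(), backend,
                         lineage_of = NULL, db_meta = NULL) {
  stopifnot(!is.null(names(queries)), all(nzchar(names(queries))))
  if (length(queries) > config$batch_max)
    stop_proxitax(sprintf("batch of %d queries exceeds the configured maximum (%d)",
                          length(queries), config$batch_max), "pipeline_error")
  lapply(names(queries), function(qid) {
    run_one_query(qid, queries[[qid]], config, backend, lineage_of, db_meta)
  })
}

run_one_query <- function(qid, qseq, config, backend, lineage_of, db_meta) {
  stage <- "search"
  tryCatch({
    hits <- backend$search(qid, qseq, config)
    hits <- hits[hits$evalue <= config$evalue_max, , drop = FALSE]
    stage <- "recruit"
    recruited <- recruit(hits, config$n_neighbors, config$min_hits)
    stage <- "align"
    seqs <- stats::setNames(c(qseq, rep("", length(recruited))),
                            c(qid, recruited))
    aln <- backend$align(seqs, config)
    stage <- "trim"
    aln <- backend$trim(aln, config)
    stage <- "infer"
    tree <- backend$infer(aln, config)
    stage <- "analyze"
    rooted <- midpoint_root(tree)
    qc <- query_qc(qseq, first_hit_aln_len = hits$length[1],
                   n_threshold = config$n_threshold)
    assignment <- assign_taxon(rooted, query = query_tip(rooted, qid),
                               blast_hits = hits$sseqid,
                               k = config$k_proximal, midpoint = FALSE)
    assignment$warnings <- intersect(WARNING_CODES,
                                     c(assignment$warnings, qc$warnings))
    assignment$query <- qid
    taxo <- NULL
    if (!is.null(lineage_of)) {
      stage <- "taxotree"
      taxo <- relabel_taxo(rooted, lineage_of, query = query_tip(rooted, qid))
    }
    stage <- "report"
    report <- render_report(assignment, config, db_meta = db_meta, qc = qc)
    structure(
      list(query = qid, assignment = assignment, qc = qc, tree = rooted,
           taxo_tree = taxo, recruited = recruited, report = report),
      class = "query_report"
    )
  }, error = function(e) {
    structure(
      list(query = qid, stage = stage, message = conditionMessage(e)),
      class = "query_error"
    )
  })
}

# The query leaf inside the inferred tree: its own id, or the mock query
# label when the backend carries one.
query_tip <- function(tree, qid) {
  if (qid %in% tree$tip.label) return(qid)
  if ("QUERY" %in% tree$tip.label) return("QUERY")
  stop_proxitax(sprintf("query leaf '%s' missing from the inferred tree", qid),
                "pipeline_error")
}

#' Render an assignment report
#'
#' A fixed-order plain-text summary of one query analysis, suitable for
#' diffing: database statement, query composition, match-length statement,
#' closest leaf and distance, proximal-cluster and type-strain information,
#' percentile verdicts and all warnings.
#'
#' @param result A `taxon_assignment`.
#' @param config A [pipeline_config()].
#' @param db_meta Optional list with `flavor` and `n` (database size).
#' @param qc Optional result of [query_qc()].
#' @return Character vector of report lines.
#' @export
render_report <- function(result, config = pipeline_config(), db_meta = NULL,
                          qc = NULL) {
  fmt <- function(x) {
    if (is.na(x)) "undefined" else sprintf("%.6f", x)
  }
  lines <- c(
    "== Taxonomic assignment report ==",
    sprintf("query: %s", result$query),
    sprintf("database flavor: %s%s", db_meta$flavor %||% config$flavor,
            if (!is.null(db_meta$n)) sprintf(" (%d sequences)", db_meta$n) else "")
  )
  if (!is.null(qc)) {
    comp <- qc$composition
    lines <- c(lines,
      sprintf("query length: %d bp", qc$length),
      sprintf("composition: A=%d C=%d G=%d T=%d other=%d",
              comp[["A"]], comp[["C"]], comp[["G"]], comp[["T"]], comp[["other"]]),
      sprintf("undetermined bases: %.2f%%", 100 * qc$frac_undetermined),
      sprintf("first-hit match length: %s of query (>=95%% expected)",
              if (is.na(qc$match_frac)) "unknown fraction"
              else sprintf("%.1f%%", 100 * qc$match_frac))
    )
  }
  lines <- c(lines,
    sprintf("closest leaf: %s", result$closest_leaf),
    sprintf("closest patristic distance: %s", fmt(result$closest_distance)),
    sprintf("closest leaf in proximal cluster: %s",
            if (result$closest_in_proximal) "yes" else "no"),
    sprintf("proximal cluster (k=%d): %d members", result$proximal$k,
            length(result$proximal$members)),
    sprintf("closest type strain: %s", result$closest_ts %||% "none"),
    sprintf("closest type strain in proximal cluster: %s",
            if (is.na(result$closest_ts_in_proximal)) "n/a"
            else if (result$closest_ts_in_proximal) "yes" else "no"),
    sprintf("intra-species distance q75: %s", fmt(result$distributions$q75_species)),
    sprintf("genus inter-species distance q75: %s", fmt(result$distributions$q75_genus)),
    sprintf("species suggestion: %s", result$species_suggestion %||% "none"),
    sprintf("genus suggestion: %s", result$genus_suggestion %||% "none"),
    sprintf("warnings: %s",
            if (length(result$warnings)) paste(result$warnings, collapse = ", ")
            else "none")
  )
  if ("NO_OUTGROUP" %in% result$warnings)
    lines <- c(lines,
      "advice: no outgroup available; it is advisable to repeat the analysis after increasing the number of recruited sequences")
  lines
}

#' System backend using locally installed command-line tools
#'
#' Maps the stage contracts onto `blastn` (E-value cutoff, no
#' low-complexity filtering), `mafft` (`--retree 1` in speed mode,
#' `--maxiterate 1000 --localpair` in accuracy mode), an optional trimming
#' command, and `FastTree -nt -gtr -gamma`. Intended for real analyses on a
#' machine where the tools are installed; all package tests run on the mock
#' backend instead.
#'
#' @param db_fasta Path to the BLAST-formatted reference FASTA.
#' @param trim_cmd Optional trimming command reading/writing FASTA on
#'   stdin/stdout (e.g. a BMGE invocation); `NULL` passes the alignment
#'   through untrimmed.
#' @return A backend list with elements `search`, `align`, `trim`, `infer`.
#' @export
system_backend <- function(db_fasta, trim_cmd = NULL) {
  list(
    search = function(query_id, query_seq, config) {
      qf <- tempfile(fileext = ".fasta"); on.exit(unlink(qf))
      writeLines(c(paste0(">", query_id), query_seq), qf)
      out <- system2("blastn",
                     c("-query", qf, "-subject", shQuote(db_fasta),
                       "-evalue", format(config$evalue_max), "-dust", "no",
                       "-outfmt", "6"),
                     stdout = TRUE)
      read_blast_tab(text = paste(out, collapse = "\n"))
    },
    align = function(seqs, config) {
      inf <- tempfile(fileext = ".fasta"); on.exit(unlink(inf))
      writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), inf)
      mode_flags <- if (config$align_mode == "speed") c("--retree", "1")
                    else c("--maxiterate", "1000", "--localpair")
      out <- system2("mafft", c(mode_flags, "--quiet", inf), stdout = TRUE)
      fasta_to_named(out)
    },
    trim = function(aln, config) {
      if (is.null(trim_cmd)) return(aln)
      inf <- tempfile(fileext = ".fasta"); on.exit(unlink(inf))
      writeLines(as.vector(rbind(paste0(">", names(aln)), unname(aln))), inf)
      out <- system2(trim_cmd[1], c(trim_cmd[-1], inf), stdout = TRUE)
      fasta_to_named(out)
    },
    infer = function(aln, config) {
      inf <- tempfile(fileext = ".fasta"); on.exit(unlink(inf))
      writeLines(as.vector(rbind(paste0(">", names(aln)), unname(aln))), inf)
      out <- system2("FastTree", c("-nt", "-gtr", "-gamma", "-quiet", inf),
                     stdout = TRUE)
      read_phylo(text = paste(out, collapse = ""))
    }
  )
}

fasta_to_named <- function(lines) {
  at <- grep("^>", lines)
  ids <- sub("^>", "", lines[at])
  ends <- c(at[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(at), function(i) {
    paste(lines[seq.int(at[i] + 1L, ends[i])], collapse = "")
  }, character(1))
  stats::setNames(seqs, ids)
}
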