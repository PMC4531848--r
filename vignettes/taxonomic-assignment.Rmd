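---
title: "Phylogeny-based taxonomic assignment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-based taxonomic assignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitax)
```

# Overview

`proxitax` assigns prokaryotic marker sequences (typically 16S/SSU rRNA) to
species and genera by reading a phylogenetic tree, not a percent-identity
table. The package has three layers:

1. a **reference-database curation layer** that turns GenBank-format records
   into tag-annotated FASTA databases of five stringency flavors;
2. a **tree-analysis engine** that, given a tree over a query and its
   recruited neighbors, produces distance-percentile species/genus verdicts
   and a set of diagnostic warnings;
3. a **pipeline orchestrator** that composes the external stages (similarity
   search, alignment, trimming, approximate-ML inference) through a backend
   interface, with a deterministic mock backend for validation.

This vignette explains the model and its assumptions, the parameters that
matter, the synthetic-data generator used for validation, and the design
decisions taken where the problem statement left room.

# The curation model

## Descriptor grammar and tags

Every reference sequence carries a structured header:

```
>Genus_species[_subsp_subspecies]~[v/?/X]~[TT/T/t/N]~Accession=rank1;rank2;...
```

The name field is *grammatical* when it is a two-word binomial with a
capitalized genus, or a four-word trinomial containing the token `subsp.`
(the period is required; in the underscored header form the token is
serialized without it). Anything else — "uncultured bacterium clone A7",
"Bacillus sp." — is carried verbatim as a raw label. Raw labels are never
dropped at parse time: filtering is the database layer's job, and the lax
flavor keeps everything.

The nomenclature tag is decided with a strict precedence: an accession on
the curated known-erroneous list is `X` no matter how plausible its name;
otherwise the organism name — corrected through the TaxId override table if
an override exists — is `v` when validly published and `?` otherwise. The
erroneous list exists precisely to override plausible names, hence the
precedence. Whether a TaxId correction should be able to rescue an
`X`-listed accession is genuinely ambiguous; we keep `X` absolute, because
the list is hand-curated evidence about the *record*, not about the name.

The type-strain tag is `TT` for accessions designated "reference sequence"
by the nomenclature authority, `T` for records whose strain collection ID
carries the terminal type-strain flag (e.g. `CIP8828T`) or matches the
registered type-strain IDs *and* whose name is grammatical, `t` when the
flag is present but the name is not grammatical (often the first trace of a
species awaiting description — the information is kept, not lost), and `N`
otherwise.

## Flavors

Flavors are pure tag predicates over the lax database:

| flavor         | predicate                                   |
|----------------|---------------------------------------------|
| lax            | all surviving records                        |
| stringent      | `nom == v` **or** `ts ∈ {TT, T, t}`          |
| ts_stringent   | `ts ∈ {TT, T}`                               |
| superstringent | `ts == TT`                                   |
| genus_level    | `TT` records of each genus's type species    |

The stringent definition deserves a note: it is "validly named sequences
plus type strains of newly described organisms". We read the addition as
*any* type-strain-tagged record (`TT`, `T`, `t`), which both preserves the
nesting chain `ts_stringent ⊆ stringent` and keeps candidate type strains of
not-yet-validated species available at the stringency level where they are
most useful. The superstringent flavor is defined as *all* `TT` records
rather than "exactly one per species", because the reference-sequence
designation itself may list more than one sequence; the flavor follows the
tag, not a uniqueness postulate. SSU databases expose all five flavors;
other markers only the first three (`marker_flavors()`).

Candidate filtering is strict on both rules: a sequence must be *longer
than* 300 bp (a 300 bp sequence is excluded) and its lineage must be deeper
than the domain alone. Output order is deterministic — sorted by (name,
accession) under C collation — so two builds of the same inputs are
byte-identical.

The live nomenclature authorities (DSMZ, LPSN, StrainInfo) are modelled as
an offline registry of plain tab-separated tables: valid names, TaxId
overrides, erroneous accessions, type-strain collection IDs, reference
sequence accessions, and genus type species. Manual curation steps become
explicit, versionable inputs.

# The assignment model

## Distances

The engine works on the **patristic distance** — the sum of branch lengths
along the leaf-to-leaf path — which is invariant to rooting. Trees are
midpoint-rooted before analysis (the root is placed at the middle of the
largest tip-to-tip distance), because that is the tree the user sees and
topological quantities should be read on it.

The **node distance** between two leaves is the number of internal nodes on
the path between them: siblings are at distance 1, and on a rooted tree the
root counts when it lies on the path. The phrase "topological distance of
two nodes" counts nodes rather than edges under this reading, which makes
the k = 2 **proximal cluster** the query's sibling-to-grandparent
neighborhood — a small local cluster, which is the intent. This is a
documented interpretation, not a certainty; the edge-count alternative would
shift every threshold by one.

## Percentile rules

Within the analysed tree, all patristic distances between reference leaves
sharing a binomial are pooled (intra-species distribution), and all
distances between different species of the closest leaf's genus form the
genus inter-species distribution. The query is suggested to belong to the
closest leaf's species when its distance to that leaf is *strictly under*
the 75th percentile of the intra-species pool, and to the genus under the
same rule on the genus pool. Choices worth stating:

- **Percentile method**: linear interpolation between order statistics
  (`quantile(type = 7)`), the most widespread default.
- **Boundary**: "under the percentile" is a strict `<`; a query exactly at
  the percentile is not suggested.
- **75th rather than the maximum**: the pools routinely contain outliers —
  mostly ill-identified sequences — and the upper quartile bound is robust
  to them.
- **Per-tree, not per-database**: the distributions are computed from the
  leaves of the current tree. The report describes *this* analysis, and the
  operation stays self-contained; the cost is that sparse trees can have
  empty pools, which is flagged (`NO_INTRASPECIES_DISTRIBUTION`) instead of
  silently widening the rule.
- **Species implies genus**: the genus test is evaluated independently, but
  a species verdict always carries its genus, so the implication
  species ⇒ genus can never be violated even when the genus pool is empty.
- **Raw labels**: leaves whose labels are not grammatical binomials carry no
  usable taxonomy; they stay in the tree but are excluded from the distance
  pools and the genus census.
- **Closest type strain**: searched globally over the tree (not only the
  proximal cluster), with its cluster membership reported as a flag, so the
  user sees both the nearest anchor to validated nomenclature and whether
  it sits in the query's neighborhood.

## Warnings

Seven closed warning codes cover the failure modes: the patristically
closest leaf lying outside the proximal cluster (possible reconstruction
artifact, e.g. long-branch attraction), the closest leaf missing from the
five best similarity hits (similarity and relatedness disagree), a
single-genus tree (no outgroup; the report advises recruiting more
sequences), fewer than 10 similarity hits (the analysis aborts — that few
hits means something upstream went wrong), more than 1 % undetermined bases
(configurable), a first-hit alignment covering less than 95 % of the query
(exactly 95 % is compliant), and an empty intra-species pool. Each code is
triggered independently by a dedicated fixture in the test suite.

# The pipeline

Only two parameters are intended for routine control: the number of
recruited neighbors (default 50; at least 50 reduces the risk of missing
the phylogenetically closest strains far down the hit list) and the
alignment mode (speed/accuracy). The external stages are contracts:
`search` (BLASTN at E ≤ 0.1 without low-complexity filtering), `align`
(MAFFT), `trim` (block selection), `infer` (FastTree, GTR + Gamma, SH
supports on splits). The package never re-implements these tools. A
`system_backend()` maps the contracts onto locally installed binaries; the
`mock_backend()` used throughout the tests ranks reference leaves by
patristic distance on a fixed tree and prunes that tree to the recruited
set, so the whole orchestration — recruitment, deduplication, abort rule,
per-query isolation, reporting — is exercised deterministically and
byte-reproducibly. Support values at or above 0.95 are classed strong and
at or below 0.80 weak, mirroring the branch-width display convention.

# The synthetic-data generator

`make_reference_tree()` emulates exactly the property the assignment rule
relies on: a three-level divergence hierarchy. Clades are joined randomly
with branch lengths drawn from exponential distributions at three scales —
within species 0.002, between congeneric species 0.02, between genera 0.1
substitutions/site by default. These defaults mirror 16S practice: strains
of one species typically differ by well under 1 %, congeneric species by a
few percent, genera by substantially more. Exponential draws are simple,
strictly positive, and give the hierarchy in expectation, which the suite
verifies empirically.

`graft_query()` plants a query at an exact patristic distance from its
target leaf by splitting the target's terminal branch (attachment height
capped below half that branch, so for small distances the target provably
remains the closest reference). `make_genbank_records()` emits GenBank
flat-file text with controlled, exactly counted fractions of short
sequences, domain-only lineages, ungrammatical names, TaxId-corrected
names, erroneous accessions and type-strain flags — together with the
matching registry and a record-level truth table. Every downstream
recovery test compares against the emitted truth, never against re-derived
values. All generators are deterministic under their seed.

What the generator does **not** emulate: sequence evolution (sequences are
random nucleotides; alignment and inference are mocked, so tests validate
the analysis engine, not the external tools), rRNA secondary structure,
compositional biases, chimeras, and the real error structure of public
annotations. Passing tests therefore demonstrate that the engine implements
its rules exactly and recovers planted truth under the stated distance
hierarchy — not that the rules are optimal on real data.

# Numerical and degenerate-case choices

- Ties in the closest-leaf and closest-type-strain searches break to the
  lexicographically smallest label under C collation; all sorting in
  databases and reports uses C collation so outputs are locale-independent
  and byte-stable across platforms.
- Midpoint rooting rejects trees with all-zero branch lengths
  ("degenerate tree"); zero-length branches elsewhere are legal, contribute
  0 to patristic distance, but their nodes still count topologically
  (approximate-ML programs do emit zero-length branches). When several leaf
  pairs realize the tree diameter the rooting follows the underlying
  midpoint routine's internal order; all realized roots satisfy the
  arms-equal-D/2 property that the suite checks to 1e-9.
- Support labels are read from internal-node labels (the approximate-ML
  output dialect), must lie in [0, 1], and are remapped to the
  corresponding splits on re-rooting; the split absorbed into a new root
  loses its (now undefined) support.
- Taxonomy relabelling removes the shared lineage prefix rank-wise, never
  within a rank name; when all lineages are identical the display falls
  back to the terminal rank rather than emitting empty labels.
- The k = 0 proximal cluster is empty by construction (two distinct leaves
  are always separated by at least one internal node).
- Headers whose raw labels contain grammar-reserved characters (`~`, `=`,
  `;`, `>`) are sanitized at database build so that every emitted header
  reparses; an un-parseable header is treated as a build bug, not a datum.

# Validation sizes

The acceptance suite runs at fixed sizes chosen to exercise every rule
while keeping the default test run quick: 1000 generated headers for the
grammar round trip; exhaustive 8-way truth tables for both tagging rules;
50 seeded databases of 60 records for flavor nesting and census recovery;
100 random trees (4–30 leaves) for the patristic, midpoint and
proximal-cluster kernels against independent shortest-path/BFS oracles;
200 seeded trees for planted-query recovery (near and far regimes, plus the
exact-percentile boundary); dedicated fixtures for all seven warnings; 50
lineage sets for the taxo-tree; and a golden-file comparison for
byte-reproducibility of the mock pipeline. `scripts/acceptance.R` recomputes
the same classes of quantities from scratch at a 200-record / 100-tree
scale under a user-supplied seed.

# Known limitations

- The curation layer consumes GenBank-format flat files; live retrieval
  from sequence archives and nomenclature services is out of scope, as are
  inter-release growth audits.
- The registry is only as good as its tables; the package ships no
  authority data.
- Assignment quality on real data is bounded by the recruited neighborhood
  and the inferred tree; the engine reads the tree it is given.
- The identity-percentage species rule (e.g. the 97 % convention) is
  deliberately not an assignment criterion; it appears nowhere in the
  engine.
- SVG tree rendering and hyperlinked reports are display concerns left to
  other tools; the package outputs Newick, plain text and tab-separated
  tables.
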