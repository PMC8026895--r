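---
title: "Graph-based genospecies delimitation from identity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based genospecies delimitation from identity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoclust)
```

## The problem

Prokaryotic species are today delimited genomically: two strains are
conventionally conspecific when their average nucleotide identity (ANI) is
about 95–96% and their digital DNA–DNA hybridization (dDDH) is at least
70%. An all-vs-all ANI run over a few hundred genomes produces a pairwise
matrix with hundreds of thousands of entries, and hierarchical clustering
of such a matrix is a poor fit for the question taxonomists actually ask:
trees force non-overlapping clusters, hide cases where some — but not
all — members of a group exceed the cut-off, and cannot combine several
matrices (e.g. ANI *and* alignment coverage) into one decision.

`genoclust` treats the problem as graph construction instead. Genomes are
nodes; a pair is connected when it meets every user-chosen criterion; the
clusters of interest are then read off the graph at two granularities:

* **maximal cliques** — sets of genomes in which *every* pair exceeds the
  cut-off: the strict candidate genospecies. Cliques may overlap; a
  genome can sit in two cliques of the same component, which is exactly
  the borderline signal a taxonomist wants surfaced rather than averaged
  away.
* **connected components** — sets in which each genome exceeds the
  cut-off with *at least one* other member: the loose cluster, and the
  natural unit for "did these two names end up in the same group at all?"

## The procedure

Given one or more square labeled matrices (identity, coverage, or
distance semantics):

1. **Pair averaging** (`symmetrize_average`). Directional values
   $m_{ij} \ne m_{ji}$ are replaced by $(m_{ij}+m_{ji})/2$. If only one
   direction was measured, that value is used; a pair missing in both
   directions stays missing.
2. **Binarization** (`binarize`). Each pair is tested against a
   criterion — $\ge t$ for identity/coverage, $\le t$ for distances —
   with the boundary inclusive (a pair at exactly 95 passes an ANI ≥ 95
   criterion). Missing values never pass: absence of evidence never
   creates an edge.
3. **Consensus** (`consensus`). With several matrices, the Boolean
   relations are combined by element-wise AND. The canonical use is
   ANI ≥ 95% **and** alignment coverage ≥ 50%, so that a high identity
   computed over a negligible aligned fraction (e.g. after horizontal
   transfer) cannot connect two genomes.
4. **Graph, cliques, components** (`build_graph`, `maximal_cliques`,
   `graph_components`). Cliques are enumerated with the Bron–Kerbosch
   algorithm using pivoting over a degeneracy ordering; components come
   from igraph. Both outputs are sorted (size descending, then
   lexicographically) so identical inputs give byte-identical outputs.
5. **Name-aware filters** (`apply_filters`). Four composable filters,
   applied in the order given:
   * *remove-isolated* — drop genomes that clustered with nothing;
   * *remove-larger-component* / *only-larger-component* — drop or keep
     the component with the most genomes (ties resolved to the
     lexicographically smallest member list, with a warning);
   * *different-names-connected* — keep components whose members carry
     two or more distinct binomial names: candidate heterotypic synonyms
     and misclassified assemblies;
   * *same-names-not-connected* — keep genomes of species names that are
     split across two or more components: candidate unauthentic genomes
     and false type strains.

"Unconnected" in the last filter is resolved at component granularity,
not clique granularity: the synonym-hunting question is whether two
same-named genomes fail to reach the same cluster at all, not whether
they co-occupy a fully connected subset.

A note on the components output: we define it as standard connected
components (isolated nodes becoming singleton components), which is the
definition consistent with the "at least one other genome above the
cut-off" reading; components are *not* required to be complete graphs —
that case is what cliques report.

## A worked micro-example

```{r chain}
m <- chain_matrix()   # a~b = 96, b~c = 96, a~c = 93
g <- build_graph(binarize(m, criterion(95)))
graph_components(g)
maximal_cliques(g)
```

One component of three genomes, two cliques of two: `b` is within reach
of both neighbours, but `a` and `c` are below the cut-off with each
other, so no three-genome genospecies is supported.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| identity cut-off | 95 | % ANI | the conventional species boundary (95–96%); inclusive |
| coverage cut-off | 50 | % aligned | guards against high-ANI/low-overlap artifacts; inclusive |
| completeness flag | ≤ 0.9 | fraction | marker-gene weighted completeness below which an assembly is suspect |
| redundancy flag | ≥ 1.1 | ratio | weighted marker redundancy above which contamination is suspected |
| 16S length filter | ≤ 400 | nt (ungapped) | fragments this short do not support reliable identity comparisons |
| same-OTU threshold | ≥ 99 | % identity | 16S identity confirming two sequences belong to one OTU |

All thresholds are inclusive at the boundary, matching the screening
conventions they implement. Scale handling is strict: thresholds are
compared on the matrix's declared scale (percent 0–100 or fraction 0–1,
auto-detected at read time), and a percent-style threshold against a
fraction-scaled matrix is an error unless conversion is requested
explicitly — a silent guess here would silently empty or saturate the
graph.

## Genome-quality and 16S screening

`qc_flag` consumes the tabular output of a marker-based completeness
estimator (any table with `completeness` and `redundancy` columns) and
flags records at the thresholds above; it does not recompute completeness
from markers. `pairwise_identity` computes percent identity from a
pre-aligned 16S FASTA. Gap columns are handled by *pairwise deletion* by
default — for each pair, only columns where both sequences have a residue
are compared. The phrase "distances from aligned sequences with no gaps"
admits both this and *complete deletion* (drop any column with a gap in
any sequence); we default to pairwise deletion because it uses all the
signal available to each pair, and expose
`deletion = "complete"` for the stricter reading. `U` equals `T`; `N`
and other ambiguity codes are compared but never match, which biases
identity downward rather than upward — the conservative direction for a
confirmation rule. A pair with no comparable columns is reported missing,
with a warning, rather than as an arbitrary number.

## The synthetic generator

`make_block_matrix` emulates the one property of real OGRI matrices the
clustering method actually consumes: the order relation between
within-species and between-species values around the cut-off. Values are
drawn uniformly from a within-range (default 96–100%) and a between-range
(default 75–85%), and the two directions of each pair are jittered
independently by ±0.2 percentage points so the matrix is genuinely
asymmetric. Uniform draws are a deliberate simplification — only the
position of values relative to the cut-off matters to the method — so
passing recovery tests shows the graph machinery is correct, *not* that
real ANI estimates are well calibrated. The generator does not emulate:
correlated errors between related genomes, the coverage/identity
correlation, missing pairs below a reporting floor (exercised separately
via `long_to_matrix` policies), or chained near-boundary clusters (probed
directly by `chain_matrix`). Separated ranges guarantee by construction
that blocks are recovered exactly; overlapping ranges must be requested
with `overlapping = TRUE`.

Generation restores the caller's RNG state, and the same seed yields
byte-identical matrix files.

## Numerical and degenerate-input choices

* Cluster output order: size descending, then lexicographic member
  order — runs are reproducible byte-for-byte.
* Diagonals: forced to the scale maximum (identity/coverage) or 0
  (distance) after averaging; self-pairs never form edges.
* Matrix round trips: files are written with 12 decimal places, so
  read∘write is the identity to well below 1e-12 per cell.
* Unreported pairs in long-format input default to a floor value of 0
  (`missing_policy = "fill-floor"`), which cannot pass any ≥ criterion;
  `"absent"` stores `NA` with the same no-edge consequence.
* Empty graphs, edgeless graphs, and single-genome inputs flow through
  every filter and output without error.

## Problem sizes used in validation

The test suite validates clique enumeration against exhaustive
subset enumeration on 200 random graphs of up to 12 nodes (the largest
size at which 2^n subsets are cheaply enumerable), block recovery on 100
seeded synthetic matrices of 3 species × 2–5 genomes, and component
extraction against a transitive-closure oracle on graphs of up to 50
nodes — sizes chosen so the full suite runs in seconds while still
exercising every code path; the algorithms themselves have no such size
limits (degeneracy-ordered Bron–Kerbosch scales to the sparse graphs
typical of ANI data at realistic collection sizes).

## Known limitations

* Name parsing is positional (first token genus, second epithet): it is
  robust to quotes, *Candidatus*, `sp.` placeholders and type-strain
  markers, but a label that leads with anything else (e.g. an accession)
  yields an undefined species and is invisible to the name filters.
* Subspecies are merged into one species key by design; subspecies-level
  splits must be judged downstream.
* The package parses upstream OGRI outputs; it does not compute ANI or
  dDDH from sequence, nor completeness from markers, nor alignments.
* Weighted community detection (e.g. Louvain) is out of scope; clusters
  here are threshold-defined cliques and components only.
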