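# genoclust

Graph-based genome clustering for prokaryotic species delimitation from
overall genome-related index (OGRI) matrices — ANI, alignment coverage,
dDDH, or any other identity/similarity/distance matrix.

## What it does, and for whom

Taxonomists delimiting bacterial species from genome collections work
from all-vs-all pairwise matrices: two strains are conventionally
conspecific at ANI ≥ 95–96% and dDDH ≥ 70%. Hierarchical clustering of
such matrices returns trees whose clusters cannot overlap and cannot
combine several matrices into one decision. `genoclust` instead builds a
graph: genomes are nodes, and a pair is connected when it meets **every**
chosen criterion (e.g. ANI ≥ 95% *and* alignment coverage ≥ 50%). The
procedure is

1. symmetrize each matrix by pair averaging,
   m′ᵢⱼ = (mᵢⱼ + mⱼᵢ)/2;
2. binarize against an inclusive cut-off (≥ t for identity/coverage,
   ≤ t for distance; missing values never pass);
3. AND the Boolean relations across matrices (consensus);
4. read clusters off the graph as **maximal cliques** (every member pair
   above the cut-off; enumerated by Bron–Kerbosch with pivoting and
   degeneracy ordering; cliques may overlap) and **connected
   components** (each member above the cut-off with at least one other);
5. optionally filter by taxonomy: keep connected groups carrying more
   than one binomial name (candidate synonyms), or same-named genomes
   split across components (candidate misidentified genomes and false
   type strains), or drop isolated nodes / the largest component.

It also implements the accompanying screening rules used before such an
analysis: flagging assemblies with weighted completeness ≤ 0.9 or
redundancy ≥ 1.1, removing 16S rRNA fragments of ≤ 400 nt, gap-aware
pairwise 16S identity from a pre-aligned FASTA, and the ≥ 99% identity
same-OTU confirmation rule. A seeded synthetic block-matrix generator
provides ground-truth fixtures.

## Worked example

```r
library(genoclust)

# three genospecies with known truth: 3 + 3 + 2 genomes
truth <- genospecies_truth(c(3, 3, 2), seed = 11)
sim   <- make_block_matrix(truth)     # asymmetric ANI-like matrix

res <- run_pipeline(
  list(list(matrix = sim$matrix, threshold = 95)),
  filters = "remove-isolated",
  out_dir = "readme_run")
str(res$summary[c("n_nodes", "n_edges", "n_cliques", "n_components")])
#> List of 4
#>  $ n_nodes     : num 8
#>  $ n_edges     : num 7
#>  $ n_cliques   : int 3
#>  $ n_components: int 3
```

`readme_run/clusters.tsv` then contains (the three generating blocks,
recovered identically as cliques and as components):

```
cluster_id  cluster_type  size  members
cliq1       clique        3     Simulobacter alpha STR12-1;Simulobacter alpha STR12-2;Simulobacter alpha STR12-3
cliq2       clique        3     Simulobacter beta STR13-1;Simulobacter beta STR13-2;Simulobacter beta STR13-3
cliq3       clique        2     Simulobacter gamma STR14-1;Simulobacter gamma STR14-2
comp1       component     3     Simulobacter alpha STR12-1;...
comp2       component     3     Simulobacter beta STR13-1;...
comp3       component     2     Simulobacter gamma STR14-1;...
```

alongside `graph.graphml`, `edges.tsv`, an SVG rendering colored by
species name, and a JSON run summary. The clique/component distinction
matters on borderline data:

```r
m <- chain_matrix()   # a~b = 96, b~c = 96, a~c = 93
g <- build_graph(binarize(m, criterion(95)))
graph_components(g)   # one component: {a, b, c}
maximal_cliques(g)    # two cliques: {a, b} and {b, c}
```

One loose cluster of three genomes, but no three-genome set in which all
pairs exceed the cut-off — `b` is the genome the taxonomist should look
at.

### Command line

```sh
Rscript inst/cli/genoclust.R cluster \
    --ani ani.tsv --ani-cutoff 95 \
    --coverage cov.tsv --coverage-cutoff 50 \
    --different-names-connected --same-names-not-connected \
    --granularity both --out run/
Rscript inst/cli/genoclust.R qc --table qc.tsv
Rscript inst/cli/genoclust.R rrna-identity --aligned aln.fasta
Rscript inst/cli/genoclust.R simulate --species 3 --size 4 --out sim/
```

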