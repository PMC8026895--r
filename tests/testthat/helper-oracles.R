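# Independent oracles used across the suite. They share no code with the
# implementation paths they check.

# Exhaustive maximal-clique enumeration over all 2^n vertex subsets,
# using bitmask arithmetic; only feasible for n <= ~14.
brute_force_cliques <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 14)
  labs <- igraph::V(g)$name
  if (n == 0) return(list())
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nbmask <- vapply(seq_len(n),
                   function(v) sum(2L^(which(A[v, ] > 0) - 1L)),
                   numeric(1))
  masks <- seq_len(2L^n - 1L)          # non-empty subsets
  is_clique <- rep(TRUE, length(masks))
  extendable <- rep(FALSE, length(masks))
  for (v in seq_len(n)) {
    bit <- 2L^(v - 1L)
    has_v <- bitwAnd(masks, bit) > 0
    others <- masks - ifelse(has_v, bit, 0L)
    is_clique <- is_clique &
      !(has_v & bitwAnd(others, nbmask[v]) != others)
    extendable <- extendable |
      (!has_v & bitwAnd(masks, nbmask[v]) == masks)
  }
  maximal <- masks[is_clique & !extendable]
  cl <- lapply(maximal, function(m) sort(labs[bitwAnd(m, 2L^(seq_len(n) - 1L)) > 0]))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(-lengths(cl), keys)]
}

# Connected components as the transitive closure of the adjacency
# relation, by repeated Boolean matrix squaring.
closure_components <- function(g) {
  n <- igraph::vcount(g)
  labs <- igraph::V(g)$name
  if (n == 0) return(list())
  R <- (as.matrix(igraph::as_adjacency_matrix(g)) > 0) | diag(n) > 0
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  groups <- unique(apply(R, 1, paste, collapse = ""))
  cl <- lapply(groups, function(gr) {
    sort(labs[apply(R, 1, paste, collapse = "") == gr])
  })
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(-lengths(cl), keys)]
}

# Random simple labeled graph on n vertices with edge probability p.
random_named_graph <- function(n, p, labels = NULL) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- if (is.null(labels))
    sprintf("v%02d", seq_len(n)) else labels
  g
}

# Random genome-style labels: k species names spread over n nodes.
random_taxon_labels <- function(n, k) {
  sp <- make_labels(rep(1L, k), style = "binomial-strain")
  sp <- sub(" STR.*$", "", sp)
  paste(sample(sp, n, replace = TRUE), sprintf("S%03d", seq_len(n)))
}

sorted_clusters_equal <- function(a, b) {
  identical(lapply(a, sort), lapply(b, sort))
}
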