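#' Symmetrize a pairwise matrix by pair averaging
#'
#' All-vs-all comparisons are directional (query vs reference differs from
#' reference vs query); clustering needs one value per unordered pair. Each
#' off-diagonal pair is replaced by the arithmetic mean of its two
#' directions. If exactly one direction is missing the present value is
#' used; if both are missing the pair stays missing. The diagonal is forced
#' to the scale maximum for identity/coverage matrices and to 0 for
#' distance matrices.
#'
#' @param m a [labeled_matrix].
#' @return a symmetric [labeled_matrix] on the same labels and scale.
#' @export
symmetrize_average <- function(m) {
  stopifnot(inherits(m, "labeled_matrix"))
  v <- m$values
  tv <- t(v)
  avg <- (v + tv) / 2
  only_fwd <- is.na(tv) & !is.na(v)
  only_rev <- is.na(v) & !is.na(tv)
  avg[only_fwd] <- v[only_fwd]
  avg[only_rev] <- tv[only_rev]
  diag(avg) <- if (m$kind == "distance") 0 else scale_max(m$scale)
  m$values <- avg
  m
}

#' Binarization criterion
#'
#' A cut-off on a pairwise matrix: a genome pair is related when its value
#' is `>= threshold` (`direction = "ge"`, the natural direction for
#' identity and coverage, e.g. ANI >= 95) or `<= threshold`
#' (`direction = "le"`, for distances). Both comparisons are inclusive.
#'
#' @param threshold numeric cut-off on the scale of the matrix it will be
#'   applied to.
#' @param direction `"ge"` or `"le"`.
#' @return an object of class `criterion`.
#' @export
#' @examples
#' criterion(95)            # ANI >= 95%
#' criterion(50)            # coverage >= 50%
#' criterion(0.06, "le")    # distance <= 0.06
criterion <- function(threshold, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  structure(list(threshold = threshold, direction = direction),
            class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cat(sprintf("criterion: value %s %g\n",
              if (x$direction == "ge") ">=" else "<=", x$threshold))
  invisible(x)
}

#' Binarize a pairwise matrix against a criterion
#'
#' Symmetrizes the matrix (see [symmetrize_average()]) and replaces each
#' off-diagonal value by whether it meets the criterion. Missing values
#' never meet a criterion, and the diagonal is always `FALSE` (a genome is
#' not its own cluster partner). The threshold must live on the matrix's
#' declared scale: a threshold above 1 applied to a fraction-scaled matrix
#' is an error unless `auto_convert = TRUE`, which divides it by 100.
#'
#' @param m a [labeled_matrix].
#' @param crit a [criterion()], or a bare number taken as a `>=` threshold
#'   for identity/coverage matrices and `<=` for distance matrices.
#' @param auto_convert allow a percent-style threshold on a
#'   fraction-scaled matrix (and vice versa) by rescaling the threshold.
#' @return an object of class `boolean_relation`: list with `labels` and a
#'   symmetric logical matrix `adj` with a `FALSE` diagonal.
#' @export
binarize <- function(m, crit, auto_convert = FALSE) {
  stopifnot(inherits(m, "labeled_matrix"))
  if (!inherits(crit, "criterion")) {
    crit <- criterion(crit, if (m$kind == "distance") "le" else "ge")
  }
  thr <- crit$threshold
  if (m$scale == "fraction" && thr > 1) {
    if (!auto_convert) {
      stop(sprintf("threshold %g looks percent-scaled but the matrix is on the fraction scale; rescale or set auto_convert = TRUE",
                   thr), call. = FALSE)
    }
    thr <- thr / 100
  }
  sm <- symmetrize_average(m)
  adj <- if (crit$direction == "ge") sm$values >= thr else sm$values <= thr
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  boolean_relation(adj, matrix_labels(m))
}

boolean_relation <- function(adj, labels) {
  stopifnot(is.logical(adj), nrow(adj) == ncol(adj),
            length(labels) == nrow(adj))
  if (!identical(adj, t(adj))) stop("relation is not symmetric",
                                    call. = FALSE)
  if (any(diag(adj))) stop("relation has self-loops", call. = FALSE)
  dimnames(adj) <- list(labels, labels)
  structure(list(labels = labels, adj = adj), class = "boolean_relation")
}

#' @export
print.boolean_relation <- function(x, ...) {
  cat(sprintf("boolean_relation: %d labels, %d related pairs\n",
              length(x$labels), sum(x$adj) / 2))
  invisible(x)
}

#' Consensus of several Boolean relations
#'
#' Element-wise logical AND across relations that share one label set:
#' a genome pair is related in the consensus only when it is related under
#' every input criterion. This is how an identity matrix (e.g. ANI >= 95%)
#' is combined with an alignment-coverage matrix (e.g. coverage >= 50%) so
#' that high identity over a negligible fraction of the genome does not
#' create an edge.
#'
#' @param relations list of `boolean_relation` objects over identical label
#'   sets (any order of labels).
#' @return a single `boolean_relation` on the label order of the first
#'   input.
#' @export
consensus <- function(relations) {
  if (inherits(relations, "boolean_relation")) relations <- list(relations)
  if (!length(relations)) stop("empty relation list", call. = FALSE)
  stopifnot(all(vapply(relations, inherits, logical(1), "boolean_relation")))
  labs <- relations[[1L]]$labels
  for (r in relations[-1L]) {
    if (!setequal(labs, r$labels)) {
      diff <- c(setdiff(labs, r$labels), setdiff(r$labels, labs))
      stop(sprintf("relations have different label sets; symmetric difference: %s",
                   paste(diff, collapse = ", ")), call. = FALSE)
    }
  }
  adj <- relations[[1L]]$adj
  for (r in relations[-1L]) {
    adj <- adj & r$adj[labs, labs]
  }
  boolean_relation(adj, labs)
}

#' Build the relation graph
#'
#' Turns a Boolean relation into a simple undirected [igraph][igraph::graph]
#' graph whose vertices are the genome labels and whose edges are the
#' related pairs. Isolated genomes are kept as degree-0 vertices.
#'
#' @param r a `boolean_relation`.
#' @return an igraph object with a `name` vertex attribute.
#' @export
build_graph <- function(r) {
  stopifnot(inherits(r, "boolean_relation"))
  igraph::graph_from_adjacency_matrix(r$adj, mode = "undirected",
                                      diag = FALSE)
}

# sort cluster lists: size descending, then lexicographic on the
# (sorted) member vectors -- makes every run byte-reproducible
sort_clusters <- function(cl) {
  cl <- lapply(unname(cl), function(x) sort(as.character(x)))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(-lengths(cl), keys)]
}

#' Enumerate maximal cliques
#'
#' A maximal clique is a set of genomes that are all pairwise related and
#' that cannot be extended by any further genome — the strictest cluster
#' notion, in which every member pair exceeds the cut-off. Uses the
#' Bron--Kerbosch algorithm with pivoting on a degeneracy ordering of the
#' vertices; singletons are reported for isolated genomes, so the returned
#' cliques cover every vertex.
#'
#' @param g an igraph graph (from [build_graph()]).
#' @return list of character vectors of member labels, sorted by
#'   decreasing size then lexicographically.
#' @export
#' @examples
#' r <- binarize(chain_matrix(), criterion(95))
#' maximal_cliques(build_graph(r))  # {a,b} and {b,c}
maximal_cliques <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  labs <- igraph::V(g)$name
  if (n == 0L) return(list())
  adj <- lapply(igraph::as_adj_list(g, mode = "all"),
                function(v) sort(unique(as.integer(v))))
  # degeneracy ordering: repeatedly remove a minimum-degree vertex
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  order_out <- integer(n)
  for (k in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    order_out[k] <- v
    alive[v] <- FALSE
    nb <- adj[[v]]
    deg[nb[alive[nb]]] <- deg[nb[alive[nb]]] - 1L
  }
  rank <- integer(n)
  rank[order_out] <- seq_len(n)

  out <- vector("list", 64L)
  n_out <- 0L
  emit <- function(members) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- members
  }
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      emit(R)
      return(invisible())
    }
    # pivot: vertex of P U X with most neighbours in P
    pux <- c(P, X)
    gain <- vapply(pux, function(u) length(intersect(adj[[u]], P)),
                   integer(1))
    pivot <- pux[which.max(gain)]
    for (v in setdiff(P, adj[[pivot]])) {
      nb <- adj[[v]]
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible()
  }
  # outer loop over the degeneracy order keeps recursion shallow
  for (v in order_out) {
    nb <- adj[[v]]
    bk(v, nb[rank[nb] > rank[v]], nb[rank[nb] < rank[v]])
  }
  sort_clusters(lapply(out[seq_len(n_out)], function(ix) labs[ix]))
}

#' Extract connected components
#'
#' A component is a maximal set of genomes linked by paths of
#' above-cut-off pairs: each member exceeds the cut-off with at least one
#' other member, but not necessarily with all of them. Components
#' partition the vertex set; isolated genomes are singleton components.
#'
#' @param g an igraph graph.
#' @return list of character vectors of member labels, sorted by
#'   decreasing size then lexicographically.
#' @export
graph_components <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  sort_clusters(split(igraph::V(g)$name, comp$membership))
}

#' Write a cluster table
#'
#' @param cliques,components cluster lists from [maximal_cliques()] /
#'   [graph_components()]; either may be `NULL`.
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_cluster_table <- function(path, cliques = NULL, components = NULL) {
  one <- function(cl, type) {
    if (!length(cl)) return(NULL)
    data.frame(cluster_id = paste0(substr(type, 1, 4), seq_along(cl)),
               cluster_type = type, size = lengths(cl),
               members = vapply(cl, paste, character(1), collapse = ";"),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(one(cliques, "clique"), one(components, "component"))
  if (is.null(tab)) {
    tab <- data.frame(cluster_id = character(), cluster_type = character(),
                      size = integer(), members = character())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Export a relation graph
#'
#' @param g an igraph graph.
#' @param path output path.
#' @param format `"graphml"`, `"dot"`, or `"edgelist"` (TSV with two label
#'   columns).
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g, names = TRUE)
    utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}
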