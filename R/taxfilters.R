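#' Parse binomial species names out of genome labels
#'
#' Genome labels in taxonomy work typically read like
#' `"Rhizobium gallicum SEMIA 4085^T^"`: a genus, a species epithet, then a
#' strain designation, possibly wrapped in quotes (names not validly
#' published) and carrying a trailing type-strain marker (`^T^` or a bare
#' `T` superscript remnant). This parser decomposes such labels; it is
#' total — any string yields a row, with `genus`/`epithet`/`species_key`
#' `NA` when the first two tokens do not form a binomial. The epithet
#' placeholder `sp.` (an unnamed species) leaves the species undefined.
#'
#' @param labels character vector of node labels.
#' @return a `data.frame` with one row per label: `raw`, `genus`,
#'   `epithet`, `qualifier` (`"none"`, `"candidatus-or-quoted"`,
#'   `"sp-placeholder"`), `strain` (residual text) and `species_key`
#'   (lowercase `"genus epithet"`, or `NA` when undefined).
#' @export
#' @examples
#' parse_binomial(c("Rhizobium gallicum SEMIA 4085^T^",
#'                  "\"Aminobacter aminovorans\" KCTC 2477^T^",
#'                  "Aminobacter sp. SR38"))
parse_binomial <- function(labels) {
  labels <- as.character(labels)
  one <- function(raw) {
    s <- trimws(raw)
    quoted <- grepl("^[\"“‘']", s)
    # strip surrounding quote characters and type-strain markers
    s <- gsub("[\"“”‘’']", "", s)
    s <- gsub("\\^T\\^", "", s)
    s <- sub("(\\s|\\))T$", "\\1", s)
    s <- trimws(gsub("\\s+", " ", s))
    candidatus <- grepl("^Candidatus\\s", s, ignore.case = TRUE)
    if (candidatus) s <- sub("^Candidatus\\s+", "", s, ignore.case = TRUE)
    tok <- strsplit(s, " ", fixed = TRUE)[[1L]]
    genus <- epithet <- key <- NA_character_
    qualifier <- if (quoted || candidatus) "candidatus-or-quoted" else "none"
    strain <- ""
    if (length(tok) >= 1L && nzchar(tok[1L])) genus <- tok[1L]
    if (length(tok) >= 2L) {
      if (tok[2L] %in% c("sp.", "sp")) {
        qualifier <- "sp-placeholder"
        strain <- paste(tok[-(1:2)], collapse = " ")
      } else {
        epithet <- tok[2L]
        key <- tolower(paste(genus, epithet))
        strain <- paste(tok[-(1:2)], collapse = " ")
      }
    }
    data.frame(raw = raw, genus = genus, epithet = epithet,
               qualifier = qualifier, strain = strain, species_key = key,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(labels, one))
}

species_keys_of <- function(g) {
  parse_binomial(igraph::V(g)$name)$species_key
}

#' Remove isolated nodes
#'
#' Drops every degree-0 genome from the graph, leaving only genomes that
#' cluster with at least one other genome.
#'
#' @param g an igraph graph with named vertices.
#' @return the filtered graph.
#' @export
filter_remove_isolated <- function(g) {
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Remove or keep only the largest component
#'
#' Identifies the connected component with the most genomes and either
#' deletes it (`mode = "remove"`) or keeps only it (`mode = "only"`). When
#' several components tie for the largest size, the one whose sorted member
#' list is lexicographically smallest is taken as "the" largest, and a
#' warning is emitted.
#'
#' @param g an igraph graph with named vertices.
#' @param mode `"remove"` or `"only"`.
#' @return the filtered graph (possibly empty).
#' @export
filter_larger_component <- function(g, mode = c("remove", "only")) {
  mode <- match.arg(mode)
  if (igraph::vcount(g) == 0L) return(g)
  comps <- graph_components(g)  # size desc, then lexicographic
  top <- comps[[1L]]
  if (length(comps) > 1L && length(comps[[2L]]) == length(top)) {
    warning("several components tie for largest; keeping the lexicographically first",
            call. = FALSE)
  }
  keep <- if (mode == "only") top else
    setdiff(igraph::V(g)$name, top)
  igraph::induced_subgraph(g, keep)
}

#' Retain connected groups carrying more than one species name
#'
#' Keeps exactly the components whose members carry at least two distinct
#' defined binomial names — the signature of candidate heterotypic
#' synonyms or misclassified genomes (several names, one genospecies).
#' Genomes without a defined binomial (`sp.` placeholders, single-token
#' labels) ride along with their component but never count as a distinct
#' name.
#'
#' @param g an igraph graph with named vertices.
#' @return the subgraph induced by the retained components.
#' @export
filter_different_names_connected <- function(g) {
  if (igraph::vcount(g) == 0L) return(g)
  keys <- species_keys_of(g)
  memb <- igraph::components(g)$membership
  n_names <- vapply(split(keys, memb),
                    function(k) length(unique(k[!is.na(k)])), integer(1))
  keep_comp <- as.integer(names(n_names)[n_names >= 2L])
  igraph::induced_subgraph(g, which(memb %in% keep_comp))
}

#' Retain same-named genomes that fail to connect
#'
#' A defined species name is "split" when its genomes occur in two or more
#' different components — the signature of an unauthentic genome or a
#' false type strain (one name, several genospecies). Returns the subgraph
#' induced by all genomes of all split names.
#'
#' @param g an igraph graph with named vertices.
#' @return the subgraph induced by the retained nodes.
#' @export
filter_same_names_not_connected <- function(g) {
  if (igraph::vcount(g) == 0L) return(g)
  keys <- species_keys_of(g)
  memb <- igraph::components(g)$membership
  defined <- !is.na(keys)
  n_comp <- vapply(split(memb[defined], keys[defined]),
                   function(m) length(unique(m)), integer(1))
  split_keys <- names(n_comp)[n_comp >= 2L]
  igraph::induced_subgraph(g, which(keys %in% split_keys))
}

#' Apply a sequence of named filters
#'
#' @param g an igraph graph.
#' @param filters character vector drawn from `"remove-isolated"`,
#'   `"remove-larger-component"`, `"only-larger-component"`,
#'   `"different-names-connected"`, `"same-names-not-connected"`, applied
#'   in the order given.
#' @return the filtered graph.
#' @export
apply_filters <- function(g, filters) {
  for (f in filters) {
    g <- switch(f,
      "remove-isolated" = filter_remove_isolated(g),
      "remove-larger-component" = filter_larger_component(g, "remove"),
      "only-larger-component" = filter_larger_component(g, "only"),
      "different-names-connected" = filter_different_names_connected(g),
      "same-names-not-connected" = filter_same_names_not_connected(g),
      stop(sprintf("unknown filter '%s'", f), call. = FALSE))
  }
  g
}
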