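#' Run the full clustering pipeline
#'
#' Composes the whole workflow: each input matrix is read (or taken as a
#' [labeled_matrix]), symmetrized by pair averaging, binarized against its
#' criterion; the relations are combined by logical consensus; the graph
#' is built, the requested filters applied in order, and maximal cliques
#' and/or connected components extracted. Writes the four outputs —
#' cluster tables, a GraphML graph export (plus an edge list), and an SVG
#' rendering — together with a JSON run summary. The run is deterministic:
#' identical inputs give byte-identical tables.
#'
#' @param inputs list of input descriptors; each is a list with either
#'   `matrix` (a [labeled_matrix]) or `path` + `kind` (read via
#'   [read_square_matrix()]), plus `threshold` and optional `direction`
#'   (see [criterion()]).
#' @param filters character vector of filter names, applied in order; see
#'   [apply_filters()].
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output and only returns the summary.
#' @param granularity `"both"` (default), `"cliques"` or `"components"`.
#' @return invisibly, a list with the final `graph`, `cliques`,
#'   `components`, and `summary` (node/edge/cluster counts and
#'   parameters).
#' @export
#' @examples
#' res <- run_pipeline(
#'   list(list(matrix = chain_matrix(), threshold = 95)),
#'   out_dir = NULL)
#' res$summary$n_components  # 1
run_pipeline <- function(inputs, filters = character(), out_dir = NULL,
                         granularity = c("both", "cliques", "components")) {
  granularity <- match.arg(granularity)
  if (!length(inputs)) stop("at least one input matrix is required",
                            call. = FALSE)
  relations <- vector("list", length(inputs))
  input_meta <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    m <- if (!is.null(inp$matrix)) inp$matrix
         else read_square_matrix(inp$path,
                                 kind = if (is.null(inp$kind)) "identity"
                                        else inp$kind)
    if (is.null(inp$threshold)) {
      stop(sprintf("input %d: no threshold given", i), call. = FALSE)
    }
    crit <- criterion(inp$threshold,
                      if (!is.null(inp$direction)) inp$direction
                      else if (m$kind == "distance") "le" else "ge")
    relations[[i]] <- binarize(m, crit,
                               auto_convert = isTRUE(inp$auto_convert))
    input_meta[[i]] <- list(path = if (is.null(inp$path)) NA else inp$path,
                            kind = m$kind, scale = m$scale,
                            threshold = crit$threshold,
                            direction = crit$direction)
  }
  g <- build_graph(consensus(relations))
  g_filtered <- apply_filters(g, filters)

  cliques <- if (granularity != "components") maximal_cliques(g_filtered)
             else NULL
  comps <- if (granularity != "cliques") graph_components(g_filtered)
           else NULL

  summary <- list(
    n_inputs = length(inputs),
    inputs = input_meta,
    filters = as.list(filters),
    granularity = granularity,
    n_nodes = igraph::vcount(g_filtered),
    n_edges = igraph::ecount(g_filtered),
    n_nodes_unfiltered = igraph::vcount(g),
    n_edges_unfiltered = igraph::ecount(g),
    n_cliques = if (is.null(cliques)) NA else length(cliques),
    n_components = if (is.null(comps)) NA else length(comps),
    package_version = as.character(utils::packageVersion("genoclust"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cluster_table(file.path(out_dir, "clusters.tsv"),
                        cliques = cliques, components = comps)
    export_graph(g_filtered, file.path(out_dir, "graph.graphml"), "graphml")
    export_graph(g_filtered, file.path(out_dir, "edges.tsv"), "edgelist")
    render_plot(g_filtered, file.path(out_dir, "graph.svg"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(graph = g_filtered, cliques = cliques,
                 components = comps, summary = summary))
}

#' Render a relation graph as SVG
#'
#' Writes a self-contained static SVG with a force-directed
#' (Fruchterman--Reingold) layout. Nodes are colored by parsed binomial
#' species name — one color per distinct name, grey for genomes without a
#' defined binomial — so that clusters mixing several names stand out.
#' The layout seed is fixed internally, so the rendering is deterministic
#' and the caller's random number stream is left untouched.
#'
#' @param g an igraph graph with named vertices.
#' @param path output `.svg` path.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_plot <- function(g, path, width = 800, height = 600) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  labs <- igraph::V(g)$name
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(42L)
  xy <- if (n > 0) igraph::layout_with_fr(g) else matrix(0, 0, 2)
  pad <- 30
  norm <- function(z, lim) {
    r <- range(z)
    if (diff(r) < 1e-9) rep(lim / 2, length(z))
    else pad + (z - r[1]) / diff(r) * (lim - 2 * pad)
  }
  px <- if (n > 0) norm(xy[, 1], width) else numeric(0)
  py <- if (n > 0) norm(xy[, 2], height) else numeric(0)

  keys <- if (n > 0) parse_binomial(labs)$species_key else character(0)
  uk <- sort(unique(keys[!is.na(keys)]))
  pal <- if (length(uk)) grDevices::hcl.colors(max(length(uk), 2L), "Dark 3")
         else character(0)
  fill <- rep("#9e9e9e", n)  # undefined binomials in grey
  fill[!is.na(keys)] <- pal[match(keys[!is.na(keys)], uk)]

  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edge_svg <- if (nrow(el)) sprintf(
    '  <line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#777" stroke-width="1"/>',
    px[el[, 1]], py[el[, 1]], px[el[, 2]], py[el[, 2]]) else character(0)
  node_svg <- if (n > 0) sprintf(
    '  <circle class="node" cx="%.1f" cy="%.1f" r="7" fill="%s" stroke="#333"><title>%s</title></circle>',
    px, py, fill, esc(labs)) else character(0)
  label_svg <- if (n > 0) sprintf(
    '  <text x="%.1f" y="%.1f" font-size="9" font-family="sans-serif">%s</text>',
    px + 9, py + 3, esc(labs)) else character(0)

  writeLines(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '  <rect width="100%" height="100%" fill="white"/>',
    edge_svg, node_svg, label_svg,
    '</svg>'), path)
  invisible(path)
}
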