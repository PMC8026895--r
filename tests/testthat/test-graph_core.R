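test_that("pair averaging symmetrizes, keeps lone directions, and is idempotent", {
  v <- matrix(c(100, 96, 94, 100), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  m <- labeled_matrix(v, kind = "identity", scale = "percent")
  s <- symmetrize_average(m)
  expect_equal(s$values["A", "B"], 95)
  expect_equal(s$values["B", "A"], 95)
  expect_equal(symmetrize_average(s)$values, s$values)

  # one missing direction: the present value is used; both missing: NA
  v <- matrix(c(100, 96, NA, NA, 100, NA, NA, NA, 100), 3, 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  s <- symmetrize_average(labeled_matrix(v, kind = "identity",
                                         scale = "percent"))
  expect_equal(s$values["b", "a"], 96)
  expect_true(is.na(s$values["a", "c"]))
  expect_equal(unname(diag(s$values)), c(100, 100, 100))
})

test_that("pair averaging equals the transpose-average on random matrices", {
  set.seed(21)
  v <- matrix(runif(64, 70, 100), 8, 8,
              dimnames = list(paste0("g", 1:8), paste0("g", 1:8)))
  m <- labeled_matrix(v, kind = "identity", scale = "percent")
  s <- symmetrize_average(m)
  expected <- (v + t(v)) / 2
  off <- row(v) != col(v)
  expect_equal(s$values[off], expected[off])
  # invariance under input transposition, through binarization
  mt <- labeled_matrix(t(v), kind = "identity", scale = "percent")
  expect_identical(binarize(m, 90)$adj, binarize(mt, 90)$adj)
})

test_that("binarization is inclusive at the threshold and conservative on NA", {
  pairval <- function(x) {
    v <- matrix(c(100, x, x, 100), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
    m <- labeled_matrix(v, kind = "identity", scale = "percent")
    binarize(m, criterion(95))$adj["A", "B"]
  }
  expect_true(pairval(95.9))
  expect_false(pairval(91.3))
  expect_true(pairval(95))      # inclusive boundary
  expect_false(pairval(94.999))
  expect_false(pairval(NA))     # missing never makes an edge

  # distance semantics flip the direction
  v <- matrix(c(0, 0.04, 0.04, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  d <- labeled_matrix(v, kind = "distance", scale = "fraction")
  expect_true(binarize(d, criterion(0.06, "le"))$adj["A", "B"])
  expect_false(binarize(d, criterion(0.01, "le"))$adj["A", "B"])
})

test_that("scale mismatches error unless conversion is requested", {
  v <- matrix(c(1, 0.96, 0.96, 1), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  m <- labeled_matrix(v, kind = "identity", scale = "fraction")
  expect_error(binarize(m, 95), "fraction scale")
  expect_true(binarize(m, 95, auto_convert = TRUE)$adj["A", "B"])
  expect_true(binarize(m, 0.95)$adj["A", "B"])
})

test_that("consensus is the element-wise AND, with algebraic properties", {
  set.seed(5)
  labs <- paste0("n", 1:10)
  rels <- lapply(1:3, function(i) {
    a <- matrix(runif(100) < 0.4, 10, 10)
    a <- a & t(a); diag(a) <- FALSE
    binarize(labeled_matrix((a * 100) + 0, labs, "identity", "percent"), 50)
  })
  cons <- consensus(rels)
  expect_identical(cons$adj, rels[[1]]$adj & rels[[2]]$adj & rels[[3]]$adj)
  # commutative, and identity on a single input
  expect_identical(consensus(rev(rels))$adj, cons$adj)
  expect_identical(consensus(rels[1])$adj, rels[[1]]$adj)
  # monotone: adding a relation never adds an edge
  expect_true(all(cons$adj <= (rels[[1]]$adj & rels[[2]]$adj)))
  # label order may differ but label sets must match
  perm <- sample(labs)
  r_perm <- rels[[2]]
  r_perm$adj <- rels[[2]]$adj[perm, perm]
  r_perm$labels <- perm
  expect_identical(consensus(list(rels[[1]], r_perm))$adj,
                   (rels[[1]]$adj & rels[[2]]$adj))
  bad <- rels[[1]]; bad$labels[1] <- "zz"
  dimnames(bad$adj) <- list(bad$labels, bad$labels)
  expect_error(consensus(list(rels[[2]], bad)), "symmetric difference")
  expect_error(consensus(list()), "empty")
})

test_that("graph construction keeps isolated labels and all true pairs", {
  labs <- c("a", "b", "c", "d")
  adj <- matrix(FALSE, 4, 4, dimnames = list(labs, labs))
  g <- build_graph(structure(list(labels = labs, adj = adj),
                             class = "boolean_relation"))
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 0)

  set.seed(9)
  a <- matrix(runif(64) < 0.5, 8, 8); a <- a & t(a); diag(a) <- FALSE
  labs <- paste0("x", 1:8)
  dimnames(a) <- list(labs, labs)
  g <- build_graph(structure(list(labels = labs, adj = a),
                             class = "boolean_relation"))
  expect_equal(igraph::ecount(g), sum(a) / 2)
})

test_that("maximal cliques match exhaustive enumeration and igraph on random graphs", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(1:12, 1)
    g <- random_named_graph(n, runif(1, 0.1, 0.9))
    got <- maximal_cliques(g)
    expect_identical(got, brute_force_cliques(g))
    # independent library cross-check
    ig <- lapply(igraph::max_cliques(g), function(v) sort(v$name))
    keys <- vapply(ig, paste, character(1), collapse = "\r")
    expect_identical(got, ig[order(-lengths(ig), keys)])
  }
})

test_that("cliques cover all vertices and nest inside single components", {
  set.seed(13)
  for (rep in 1:20) {
    g <- random_named_graph(sample(2:25, 1), runif(1, 0.05, 0.5))
    cl <- maximal_cliques(g)
    comps <- graph_components(g)
    expect_setequal(unique(unlist(cl)), igraph::V(g)$name)
    comp_of <- rep(seq_along(comps), lengths(comps))
    names(comp_of) <- unlist(comps)
    for (k in cl) expect_length(unique(comp_of[k]), 1)
  }
})

test_that("components equal the transitive closure of the edge relation", {
  set.seed(17)
  expect_identical(graph_components(igraph::make_empty_graph(0)), list())
  for (rep in 1:25) {
    g <- random_named_graph(sample(1:50, 1), runif(1, 0.02, 0.3))
    expect_identical(graph_components(g), closure_components(g))
  }
})

test_that("cluster outputs are deterministically ordered and exportable", {
  g <- build_graph(binarize(chain_matrix(), 95))
  cl <- maximal_cliques(g)
  expect_identical(cl, list(c("a", "b"), c("b", "c")))
  tab <- write_cluster_table(withr::local_tempfile(fileext = ".tsv"),
                             cliques = cl,
                             components = graph_components(g))
  expect_equal(tab$size, c(2, 2, 3))
  expect_equal(tab$members[3], "a;b;c")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  expect_true(any(grepl("graphml", readLines(gml))))
  el <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, el, "edgelist")
  expect_equal(nrow(utils::read.delim(el)), 2)
})
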