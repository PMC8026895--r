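#' Ground-truth genospecies layout for synthetic matrices
#'
#' Describes a block-structured identity matrix: `n_species` genospecies of
#' `sizes` genomes each, with within-species identities drawn from
#' `within_range` and between-species identities from `between_range`
#' (percent scale). With `within_range[1] > between_range[2]` and a cut-off
#' in between, the generating blocks are exactly recoverable as both
#' cliques and components; overlapping ranges must be requested explicitly.
#'
#' @param sizes integer vector, genomes per species block.
#' @param within_range,between_range length-2 numeric ranges in 0--100.
#' @param seed integer seed making the draw reproducible.
#' @param labels optional character vector of genome labels (length
#'   `sum(sizes)`); default labels are generated by [make_labels()] in the
#'   `"binomial-strain"` style.
#' @param overlapping set `TRUE` to allow `within_range` and
#'   `between_range` to overlap.
#' @return an object of class `genospecies_truth` with fields
#'   `species_blocks` (named list of member labels), `within_range`,
#'   `between_range`, `seed`.
#' @export
genospecies_truth <- function(sizes, within_range = c(96, 100),
                              between_range = c(75, 85), seed = 1L,
                              labels = NULL, overlapping = FALSE) {
  stopifnot(length(within_range) == 2L, length(between_range) == 2L,
            all(sizes >= 1L))
  if (any(c(within_range, between_range) < 0) ||
      any(c(within_range, between_range) > 100)) {
    stop("ranges must lie within [0, 100]", call. = FALSE)
  }
  if (!overlapping && within_range[1] <= between_range[2]) {
    stop("within_range must lie strictly above between_range (or set overlapping = TRUE)",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- make_labels(sizes, seed = seed)
  }
  stopifnot(length(labels) == sum(sizes), !anyDuplicated(labels))
  blocks <- split(labels, rep(seq_along(sizes), sizes))
  names(blocks) <- vapply(blocks, function(b) {
    k <- parse_binomial(b[1])$species_key
    if (is.na(k)) b[1] else k
  }, character(1))
  structure(list(species_blocks = blocks, within_range = within_range,
                 between_range = between_range, seed = as.integer(seed)),
            class = "genospecies_truth")
}

# invented but plausible-looking genus/epithet pools for synthetic labels
.synth_genera <- c("Simulobacter", "Fictirhizobium", "Pseudovirga",
                   "Blockimonas", "Syntheticum", "Testibacillus",
                   "Mockobacterium", "Exemplaria")
.synth_epithets <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                     "eta", "theta", "iota", "kappa", "lambda", "mu")

#' Generate genome labels in field naming styles
#'
#' Emits labels exercising the naming conventions the name-based filters
#' must cope with: plain `"Genus epithet STRAIN"` binomials, quoted (not
#' validly published) names, or a mix including `sp.` placeholders.
#'
#' @param sizes integer vector of genomes per species.
#' @param style `"binomial-strain"` (default), `"quoted"`, or `"mixed"`
#'   (every third species quoted, every fourth a `sp.` placeholder).
#' @param seed integer seed (used only to vary strain numbers
#'   deterministically).
#' @return character vector of `sum(sizes)` unique labels.
#' @export
make_labels <- function(sizes, style = c("binomial-strain", "quoted",
                                         "mixed"), seed = 1L) {
  style <- match.arg(style)
  k <- length(sizes)
  if (k > length(.synth_genera) * length(.synth_epithets)) {
    stop("too many species blocks for the synthetic name pools",
         call. = FALSE)
  }
  genus <- .synth_genera[((seq_len(k) - 1L) %/% length(.synth_epithets)) + 1L]
  epithet <- .synth_epithets[((seq_len(k) - 1L) %% length(.synth_epithets)) + 1L]
  unlist(lapply(seq_len(k), function(i) {
    strains <- sprintf("STR%d-%d", (seed %% 97L) + i, seq_len(sizes[i]))
    name <- switch(style,
      "binomial-strain" = paste(genus[i], epithet[i]),
      "quoted" = sprintf("\"%s %s\"", genus[i], epithet[i]),
      "mixed" = if (i %% 4L == 0L) paste(genus[i], "sp.")
                else if (i %% 3L == 0L)
                  sprintf("\"%s %s\"", genus[i], epithet[i])
                else paste(genus[i], epithet[i]))
    paste(name, strains)
  }), use.names = FALSE)
}

#' Synthesize a block-structured asymmetric identity matrix
#'
#' Draws a directional (hence asymmetric) all-vs-all identity matrix from
#' a [genospecies_truth()] layout: the unordered-pair base value comes
#' uniformly from the within- or between-species range, and each direction
#' is offset by an independent uniform jitter in `[-asymmetry_jitter,
#' +asymmetry_jitter]` percentage points, mimicking the query/reference
#' asymmetry of real ANI runs and exercising [symmetrize_average()]. The
#' diagonal is 100. Reproducible from `truth$seed`.
#'
#' @param truth a [genospecies_truth()].
#' @param asymmetry_jitter nonnegative jitter half-width in percentage
#'   points; default 0.2.
#' @return list with elements `matrix` (a [labeled_matrix], percent scale)
#'   and `truth`.
#' @export
make_block_matrix <- function(truth, asymmetry_jitter = 0.2) {
  stopifnot(inherits(truth, "genospecies_truth"), asymmetry_jitter >= 0)
  labels <- unlist(truth$species_blocks, use.names = FALSE)
  n <- length(labels)
  block_of <- rep(seq_along(truth$species_blocks),
                  lengths(truth$species_blocks))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(truth$seed)
  v <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      rng <- if (block_of[i] == block_of[j]) truth$within_range
             else truth$between_range
      base <- stats::runif(1, rng[1], rng[2])
      jit <- stats::runif(2, -asymmetry_jitter, asymmetry_jitter)
      v[i, j] <- min(100, max(0, base + jit[1]))
      v[j, i] <- min(100, max(0, base + jit[2]))
    }
  }
  diag(v) <- 100
  list(matrix = labeled_matrix(v, labels = labels, kind = "identity",
                               scale = "percent"),
       truth = truth)
}

#' The three-genome chain matrix
#'
#' A minimal worked example of the clique/component distinction: genomes
#' `a` and `b` share 96% identity, `b` and `c` share 96%, but `a` and `c`
#' only 93%. At a 95% cut-off the graph is the path `a - b - c`: one
#' component of three genomes but two maximal cliques (`{a,b}`, `{b,c}`),
#' with `b` a member of both.
#'
#' @return a 3x3 [labeled_matrix] (percent identity).
#' @export
chain_matrix <- function() {
  v <- matrix(c(100, 96, 93,
                96, 100, 96,
                93, 96, 100), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  labeled_matrix(v, kind = "identity", scale = "percent")
}
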