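#' Labeled pairwise matrix
#'
#' The central container of the package: a square numeric matrix of pairwise
#' genome measures keyed by genome labels. `kind` records the semantics of
#' the values (identity-like, coverage-like, or distance-like) and `scale`
#' whether values live on 0--100 (`"percent"`) or 0--1 (`"fraction"`).
#' Missing pairwise values are `NA` and are treated conservatively
#' downstream: a missing value never satisfies a clustering criterion.
#'
#' @param values square numeric matrix; row and column names, when present,
#'   must agree and become the labels.
#' @param labels character vector of unique, non-empty genome labels. May be
#'   omitted when `values` carries dimnames.
#' @param kind one of `"identity"`, `"coverage"`, `"distance"`.
#' @param scale one of `"percent"` (values in 0--100) or `"fraction"`
#'   (values in 0--1).
#'
#' @return An object of class `labeled_matrix`: a list with elements
#'   `values` (matrix with dimnames), `kind` and `scale`.
#' @export
#'
#' @examples
#' m <- matrix(c(100, 96, 96, 100), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' labeled_matrix(m, kind = "identity", scale = "percent")
labeled_matrix <- function(values, labels = NULL,
                           kind = c("identity", "coverage", "distance"),
                           scale = c("percent", "fraction")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) != ncol(values)) {
    stop(sprintf("matrix is not square: %d rows vs %d columns",
                 nrow(values), ncol(values)), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) {
      stop("'labels' must be given when 'values' has no dimnames",
           call. = FALSE)
    }
  }
  labels <- trimws(as.character(labels))
  if (length(labels) != nrow(values)) {
    stop("length of 'labels' does not match matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate label(s): %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(labels))) stop("empty label", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  top <- if (scale == "percent") 100 else 1
  if (kind != "distance") {
    rng <- range(values, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > top + 1e-9)) {
      stop(sprintf("%s values outside declared %s scale [0, %g]",
                   kind, scale, top), call. = FALSE)
    }
  }
  structure(list(values = values, kind = kind, scale = scale),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d x %d, kind=%s, scale=%s\n",
              nrow(x$values), ncol(x$values), x$kind, x$scale))
  n <- nrow(x$values)
  k <- min(n, 6L)
  print(x$values[seq_len(k), seq_len(k), drop = FALSE], ...)
  if (n > k) cat(sprintf("... %d further labels not shown\n", n - k))
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Genome labels of a labeled matrix
#' @param m a [labeled_matrix].
#' @return character vector of labels in storage order.
#' @export
matrix_labels <- function(m) rownames(m$values)

scale_max <- function(scale) if (scale == "percent") 100 else 1

#' Convert a labeled matrix to the percent scale
#'
#' Internal computations compare thresholds on the percent scale; this is
#' the canonicalization used throughout.
#'
#' @param m a [labeled_matrix].
#' @return the same matrix with `scale = "percent"`.
#' @export
as_percent <- function(m) {
  stopifnot(inherits(m, "labeled_matrix"))
  if (m$scale == "percent") return(m)
  m$values <- m$values * 100
  m$scale <- "percent"
  m
}
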