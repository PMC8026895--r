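#' Read a square labeled pairwise matrix
#'
#' Reads the square matrix dialect written by all-vs-all genome comparison
#' tools (e.g. pyANI's `percentage_identity` / `alignment_coverage`
#' tables): the first row and first column carry genome labels, the body is
#' numeric. The value scale is auto-detected unless given: if every finite
#' off-diagonal value is at most 1 the matrix is taken to be on the
#' fraction (0--1) scale, otherwise percent (0--100). Plain and
#' gzip-compressed files are both accepted.
#'
#' @param path path to a TSV (or CSV, see `dialect`) file.
#' @param kind value semantics: `"identity"`, `"coverage"` or `"distance"`.
#' @param dialect `"tab"` (default) or `"comma"` separated.
#' @param scale `NULL` for auto-detection, or `"percent"` / `"fraction"`.
#' @param missing_token strings parsed as missing, in addition to empty
#'   cells; default `c("NA", "NaN", "")`.
#' @return a [labeled_matrix].
#' @export
read_square_matrix <- function(path,
                               kind = c("identity", "coverage", "distance"),
                               dialect = c("tab", "comma"),
                               scale = NULL,
                               missing_token = c("NA", "NaN", "")) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(sprintf("%s: no matrix body", path),
                               call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(cells[[1L]])
  col_labels <- header[-1L]  # first cell blank or "label"
  n <- length(col_labels)
  if (anyDuplicated(col_labels)) {
    stop(sprintf("%s: duplicate column label(s): %s", path,
                 paste(unique(col_labels[duplicated(col_labels)]),
                       collapse = ", ")), call. = FALSE)
  }
  body <- cells[-1L]
  if (length(body) != n) {
    stop(sprintf("%s: non-square matrix: %d columns but %d data rows",
                 path, n, length(body)), call. = FALSE)
  }
  row_labels <- character(n)
  values <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    row <- trimws(cells[[i + 1L]])
    if (length(row) != n + 1L) {
      stop(sprintf("%s: row %d ('%s') has %d cells, expected %d",
                   path, i, row[1L], length(row), n + 1L), call. = FALSE)
    }
    row_labels[i] <- row[1L]
    raw <- row[-1L]
    is_missing <- raw %in% missing_token
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is_missing)
    if (length(bad)) {
      stop(sprintf("%s: unparseable cell '%s' at row %d ('%s'), column %d ('%s')",
                   path, raw[bad[1L]], i, row_labels[i], bad[1L],
                   col_labels[bad[1L]]), call. = FALSE)
    }
    num[is_missing] <- NA_real_
    values[i, ] <- num
  }
  if (anyDuplicated(row_labels)) {
    stop(sprintf("%s: duplicate row label(s): %s", path,
                 paste(unique(row_labels[duplicated(row_labels)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (!setequal(row_labels, col_labels)) {
    stop(sprintf("%s: row and column labels differ", path), call. = FALSE)
  }
  # align columns to row order, preserving the file's row order
  values <- values[, match(row_labels, col_labels), drop = FALSE]
  if (is.null(scale)) scale <- detect_scale(values)
  labeled_matrix(values, labels = row_labels, kind = kind, scale = scale)
}

detect_scale <- function(values) {
  off <- values[row(values) != col(values)]
  off <- off[is.finite(off)]
  if (length(off) && all(off <= 1)) "fraction" else "percent"
}

#' Write a labeled matrix in the square TSV dialect
#'
#' Inverse of [read_square_matrix()] for the tab-separated dialect. Values
#' are written in fixed decimal notation with 12 decimal places so that a
#' read/write round trip reproduces each cell to well below 1e-12.
#'
#' @param m a [labeled_matrix].
#' @param path output path; `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  stopifnot(inherits(m, "labeled_matrix"))
  labs <- matrix_labels(m)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.12f", v))
  rows <- vapply(seq_along(labs), function(i) {
    paste(c(labs[i], fmt(m$values[i, ])), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste(c("label", labs), collapse = "\t"), rows), con)
  invisible(path)
}

#' Read long-format all-vs-all records
#'
#' Parses the five-column, headerless layout used by fast ANI estimators:
#' query label, reference label, value, count of mapped fragments,
#' total fragment count.
#'
#' @param path path to a tab/whitespace separated file (optionally `.gz`).
#' @param strip_paths drop directory components and the final file
#'   extension from the query/reference labels (useful when the upstream
#'   tool recorded genome file paths).
#' @return a `data.frame` with columns `query`, `reference`, `value`,
#'   `numerator`, `denominator` and attribute `scale`.
#' @export
read_long_records <- function(path, strip_paths = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("%s: no records", path), call. = FALSE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf != 5L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d columns, expected 5 (query, reference, value, numerator, denominator)",
                 path, bad[1L], nf[bad[1L]]), call. = FALSE)
  }
  tab <- do.call(rbind, parts)
  rec <- data.frame(query = tab[, 1L], reference = tab[, 2L],
                    value = as.numeric(tab[, 3L]),
                    numerator = as.numeric(tab[, 4L]),
                    denominator = as.numeric(tab[, 5L]),
                    stringsAsFactors = FALSE)
  if (anyNA(rec$value) || anyNA(rec$numerator) || anyNA(rec$denominator)) {
    bad <- which(is.na(rec$value) | is.na(rec$numerator) |
                   is.na(rec$denominator))[1L]
    stop(sprintf("%s: non-numeric field on line %d", path, bad),
         call. = FALSE)
  }
  if (any(rec$numerator < 0) || any(rec$numerator > rec$denominator)) {
    stop(sprintf("%s: fragment counts must satisfy 0 <= numerator <= denominator",
                 path), call. = FALSE)
  }
  if (strip_paths) {
    strip <- function(x) sub("\\.[A-Za-z0-9]+(\\.gz)?$", "", basename(x))
    rec$query <- strip(rec$query)
    rec$reference <- strip(rec$reference)
  }
  key <- paste(rec$query, rec$reference, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("%s: duplicate (query, reference) pair: %s",
                 path, gsub("\r", " -> ", d)), call. = FALSE)
  }
  attr(rec, "scale") <- detect_scale(matrix(rec$value, nrow = 1))
  rec
}

#' Tabulate long-format records into a square labeled matrix
#'
#' @param rs record set from [read_long_records()] (any `data.frame` with
#'   `query`, `reference`, `value` columns works).
#' @param kind value semantics of the records, default `"identity"`.
#' @param missing_policy what to store for ordered pairs never reported:
#'   `"fill-floor"` (default) writes 0, which can never satisfy a
#'   greater-or-equal criterion, matching the usual interpretation that an
#'   unreported pair fell below the tool's reporting floor; `"absent"`
#'   stores `NA` (which downstream also never creates an edge).
#' @param scale `NULL` to auto-detect from the values.
#' @return a [labeled_matrix] over the union of query and reference labels,
#'   with the diagonal set to the scale maximum.
#' @export
long_to_matrix <- function(rs, kind = c("identity", "coverage", "distance"),
                           missing_policy = c("fill-floor", "absent"),
                           scale = NULL) {
  kind <- match.arg(kind)
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.data.frame(rs), nrow(rs) > 0)
  labs <- sort(unique(c(rs$query, rs$reference)))
  if (is.null(scale)) {
    scale <- if (all(rs$value <= 1)) "fraction" else "percent"
  }
  fill <- if (missing_policy == "fill-floor") 0 else NA_real_
  n <- length(labs)
  values <- matrix(fill, n, n, dimnames = list(labs, labs))
  values[cbind(match(rs$query, labs), match(rs$reference, labs))] <- rs$value
  diag(values) <- scale_max(scale)
  labeled_matrix(values, labels = labs, kind = kind, scale = scale)
}

#' All-vs-all comparison plan
#'
#' Enumerates every ordered (query, reference) pair over a set of genome
#' identifiers, self-comparisons included — the comparison plan an
#' all-vs-all ANI run executes, with `n^2` entries for `n` genomes.
#'
#' @param labels character vector of unique genome identifiers.
#' @return data.frame with columns `query` and `reference`; `length(labels)^2` rows.
#' @export
#' @examples
#' nrow(comparison_plan(c("A", "B", "C")))  # 9
comparison_plan <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  g <- expand.grid(reference = labels, query = labels,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  data.frame(query = g$query, reference = g$reference,
             stringsAsFactors = FALSE)
}
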