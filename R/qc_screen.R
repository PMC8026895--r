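#' Read a per-genome quality table
#'
#' Expects a TSV with a header containing at least the columns
#' `completeness` and `redundancy` (marker-gene based genome quality
#' scores, as computed upstream by completeness estimators); the
#' conventional full layout is `accession`, `organism`, `length_mb`,
#' `contigs`, `completeness`, `redundancy`.
#'
#' @param path TSV path (optionally gzip-compressed).
#' @return a `data.frame`.
#' @export
read_qc_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("completeness", "redundancy")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Flag genomes of dubious assembly quality
#'
#' A genome is flagged when its weighted completeness is at or below
#' `completeness_max` or its weighted redundancy is at or above
#' `redundancy_min` (both bounds inclusive). The defaults, completeness
#' <= 0.9 or redundancy >= 1.1, are the screening thresholds conventionally
#' used to pick out incomplete or contaminated assemblies before
#' genome-based taxonomy.
#'
#' @param records a `data.frame` with numeric `completeness` (in 0--1) and
#'   `redundancy` (>= 0) columns, e.g. from [read_qc_table()].
#' @param completeness_max flag when completeness <= this; default 0.9.
#' @param redundancy_min flag when redundancy >= this; default 1.1.
#' @return `records` with an added logical column `flagged`, input order
#'   preserved.
#' @export
#' @examples
#' qc_flag(data.frame(completeness = c(0.7077, 0.98),
#'                    redundancy = c(1.6195, 1.02)))$flagged  # TRUE FALSE
qc_flag <- function(records, completeness_max = 0.9, redundancy_min = 1.1) {
  stopifnot(is.data.frame(records),
            all(c("completeness", "redundancy") %in% names(records)))
  comp <- records$completeness
  red <- records$redundancy
  if (any(comp < 0 | comp > 1, na.rm = TRUE)) {
    stop("completeness must lie in [0, 1]", call. = FALSE)
  }
  if (any(red < 0, na.rm = TRUE)) {
    stop("redundancy must be >= 0", call. = FALSE)
  }
  records$flagged <- (comp <= completeness_max) | (red >= redundancy_min)
  records$flagged[is.na(records$flagged)] <- FALSE
  records
}

GAP_CHARS <- c("-", ".")

#' Read pre-aligned sequences from aligned FASTA
#'
#' @param path aligned FASTA path (plain or gzip). All sequences must have
#'   the same aligned length.
#' @return named character vector of aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`,
                        character(1), 1L)
  if (length(unique(nchar(seqs))) > 1L) {
    stop(sprintf("%s: sequences have unequal aligned lengths", path),
         call. = FALSE)
  }
  seqs
}

#' Ungapped sequence lengths
#' @param seqs named character vector of (aligned) sequences.
#' @return integer vector of lengths excluding gap characters (`-`, `.`).
#' @export
ungapped_lengths <- function(seqs) {
  vapply(seqs,
         function(s) sum(!strsplit(s, "")[[1L]] %in% GAP_CHARS),
         integer(1))
}

#' Drop short sequences
#'
#' Removes sequences whose ungapped length is at or below the cut-off.
#' The default, 400 nt, is the conventional minimum for a 16S rRNA
#' fragment to support reliable identity comparisons.
#'
#' @param seqs named character vector of (aligned) sequences.
#' @param min_exclusive sequences with ungapped length `<=` this are
#'   removed; default 400.
#' @return the retained subset of `seqs`.
#' @export
length_filter <- function(seqs, min_exclusive = 400) {
  seqs[ungapped_lengths(seqs) > min_exclusive]
}

#' Pairwise percent identity from aligned sequences
#'
#' For each sequence pair, alignment columns where either sequence has a
#' gap are excluded (`deletion = "pairwise"`, the default), or columns with
#' a gap in *any* sequence are excluded globally
#' (`deletion = "complete"`). Identity is `100 * matches / compared
#' columns`. Case is ignored and `U` is treated as `T`; `N` and other
#' ambiguity codes count as compared columns but never as matches. A pair
#' with zero comparable columns gets `NA` with a warning.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 2), e.g. from [read_aligned_fasta()].
#' @param deletion `"pairwise"` or `"complete"` gap handling.
#' @return a [labeled_matrix] (`kind = "identity"`, `scale = "percent"`)
#'   with 100 on the diagonal.
#' @export
#' @examples
#' pairwise_identity(c(a = "ACGT-ACGT", b = "ACGTTACGA"))$values["a", "b"]
#' # 87.5: 8 comparable columns, 7 matches
pairwise_identity <- function(seqs, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(seqs) >= 2L)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  chars <- lapply(seqs, function(s) {
    x <- toupper(strsplit(s, "")[[1L]])
    x[x == "U"] <- "T"
    x
  })
  if (length(unique(lengths(chars))) > 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  is_gap <- lapply(chars, function(x) x %in% GAP_CHARS)
  if (deletion == "complete") {
    keep <- !Reduce(`|`, is_gap)
    chars <- lapply(chars, function(x) x[keep])
    is_gap <- lapply(is_gap, function(x) x[keep])
  }
  n <- length(seqs)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(v) <- 100
  unambiguous <- c("A", "C", "G", "T")
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is_gap[[i]] & !is_gap[[j]]
      n_comp <- sum(ok)
      if (n_comp == 0L) {
        warning(sprintf("no comparable columns between '%s' and '%s'",
                        ids[i], ids[j]), call. = FALSE)
        next
      }
      a <- chars[[i]][ok]
      b <- chars[[j]][ok]
      matches <- sum(a == b & a %in% unambiguous)
      v[i, j] <- v[j, i] <- 100 * matches / n_comp
    }
  }
  labeled_matrix(v, labels = ids, kind = "identity", scale = "percent")
}

#' Same-OTU confirmation from 16S identity
#'
#' Two 16S rRNA sequences at or above the identity threshold (default
#' 99%) are taken to confirm assignment to the same operational taxonomic
#' unit; below it, the genome's labeled identity is in doubt.
#'
#' @param identity_percent numeric vector of identities in 0--100.
#' @param threshold inclusive cut-off, default 99.
#' @return logical vector.
#' @export
confirm_same_otu <- function(identity_percent, threshold = 99) {
  stopifnot(all(identity_percent >= 0 & identity_percent <= 100,
                na.rm = TRUE))
  identity_percent >= threshold
}
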