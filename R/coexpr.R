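#' Extract highly co-expressed gene pairs from one dataset
#'
#' Computes the Pearson correlation coefficient (PCC) between every pair of
#' gene rows and returns the unordered pairs whose PCC is greater than or
#' equal to `threshold` (inclusive). PCC uses the sample (n-1) variance
#' convention; the choice cancels in the correlation but is documented for
#' completeness. Rows with zero variance have undefined PCC and are skipped
#' with a warning; a gene flat in one study may still vary in another, so
#' the exclusion is per dataset.
#'
#' @param x An [expression_dataset] or a numeric matrix (genes x samples,
#'   gene ids as rownames) with at least two genes.
#' @param threshold PCC cutoff in (-1, 1]; default 0.9.
#' @return Data frame with columns `gene_a`, `gene_b`
#'   (`gene_a < gene_b` lexicographically), one row per surviving pair.
#' @export
coexpr_pairs <- function(x, threshold = 0.9) {
  if (inherits(x, "expression_dataset")) x <- x$values
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (!(threshold > -1 && threshold <= 1)) {
    stop("`threshold` must lie in (-1, 1]", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop("`x` must have gene ids as rownames", call. = FALSE)
  }
  rv <- apply(x, 1L, var)
  flat <- rv == 0 | !is.finite(rv)
  if (any(flat)) {
    warning(sprintf(
      "skipping %d zero-variance gene(s) (PCC undefined): %s",
      sum(flat), paste(head(rownames(x)[flat], 5L), collapse = ", ")))
    x <- x[!flat, , drop = FALSE]
  }
  if (nrow(x) < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  cc <- cor(t(x))
  hit <- which(upper.tri(cc) & cc >= threshold, arr.ind = TRUE)
  .canonical_pairs(rownames(x)[hit[, 1L]], rownames(x)[hit[, 2L]])
}

#' Merge per-dataset pair sets into a co-expression corpus
#'
#' Pairs selected independently in each dataset are pooled; the multiplicity
#' of a pair is the number of datasets in which it was selected. Biological
#' conditions are not distinguished during merging. The corpus is the
#' training input for [train_embedding()], where multiplicity acts as a
#' repeat count.
#'
#' @param pair_sets List of data frames as returned by [coexpr_pairs()], one
#'   per dataset. Names (or `dataset_ids`) identify the sources.
#' @param dataset_ids Optional character vector of dataset ids; defaults to
#'   `names(pair_sets)` or `ds1`, `ds2`, ...
#' @return An object of class `coexpr_corpus`: list with `pairs` (data frame
#'   `gene_a`, `gene_b`, `multiplicity`, `gene_a < gene_b`) and
#'   `source_counts` (named integer vector of per-dataset pair counts).
#' @export
merge_corpora <- function(pair_sets, dataset_ids = NULL) {
  stopifnot(is.list(pair_sets))
  if (is.null(dataset_ids)) {
    dataset_ids <- names(pair_sets)
    if (is.null(dataset_ids)) {
      dataset_ids <- paste0("ds", seq_along(pair_sets), recycle0 = TRUE)
    }
  }
  stopifnot(length(dataset_ids) == length(pair_sets))
  keys <- character(0)
  source_counts <- integer(length(pair_sets))
  names(source_counts) <- dataset_ids
  for (i in seq_along(pair_sets)) {
    ps <- pair_sets[[i]]
    if (nrow(ps) == 0L) next
    ps <- .canonical_pairs(ps$gene_a, ps$gene_b)  # dedupe within dataset
    if (any(ps$gene_a == ps$gene_b)) {
      stop("self-pairs are not allowed in a co-expression corpus",
           call. = FALSE)
    }
    source_counts[i] <- nrow(ps)
    keys <- c(keys, paste(ps$gene_a, ps$gene_b, sep = "\t"))
  }
  if (length(keys) == 0L) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        multiplicity = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    pairs <- data.frame(
      gene_a = vapply(parts, `[`, "", 1L),
      gene_b = vapply(parts, `[`, "", 2L),
      multiplicity = as.integer(tab),
      stringsAsFactors = FALSE
    )
    pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, source_counts = source_counts),
            class = "coexpr_corpus")
}

#' @export
print.coexpr_corpus <- function(x, ...) {
  cat(sprintf(
    "<coexpr_corpus: %d unique pairs, %d total occurrences, %d genes, %d dataset(s)>\n",
    nrow(x$pairs), corpus_size(x),
    length(unique(c(x$pairs$gene_a, x$pairs$gene_b))),
    length(x$source_counts)))
  invisible(x)
}

#' Total number of pair occurrences in a corpus
#'
#' @param corpus A `coexpr_corpus`.
#' @return Integer: sum of multiplicities.
#' @export
corpus_size <- function(corpus) {
  stopifnot(inherits(corpus, "coexpr_corpus"))
  as.integer(sum(corpus$pairs$multiplicity))
}

#' Multiplicity-weighted gene frequencies in a corpus
#'
#' A gene's frequency is the number of pair occurrences that touch it,
#' counting multiplicity. This is the count the minimum-frequency filter in
#' [train_embedding()] operates on.
#'
#' @param corpus A `coexpr_corpus`.
#' @return Named integer vector, sorted by decreasing frequency then gene id.
#' @export
gene_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "coexpr_corpus"))
  p <- corpus$pairs
  f <- rowsum(c(p$multiplicity, p$multiplicity), c(p$gene_a, p$gene_b))
  out <- stats::setNames(as.integer(f), rownames(f))
  out[order(-out, names(out))]
}

#' Run the expression-to-corpus pipeline over several datasets
#'
#' Convenience wrapper: applies [coexpr_pairs()] to each dataset and merges
#' the results with [merge_corpora()].
#'
#' @param datasets List of [expression_dataset] objects.
#' @param threshold PCC cutoff passed to [coexpr_pairs()].
#' @return A `coexpr_corpus`.
#' @export
build_corpus <- function(datasets, threshold = 0.9) {
  sets <- lapply(datasets, coexpr_pairs, threshold = threshold)
  ids <- vapply(datasets, function(d) d$dataset_id, "")
  merge_corpora(sets, dataset_ids = ids)
}

#' Write a co-expression corpus to TSV
#'
#' Three tab-separated columns `gene_a`, `gene_b`, `multiplicity` with
#' `gene_a < gene_b`, preceded by one `#` metadata line recording the source
#' datasets. No header row.
#'
#' @param corpus A `coexpr_corpus`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "coexpr_corpus"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# coexpr corpus: %d pairs; datasets: %s",
    nrow(corpus$pairs),
    paste(sprintf("%s=%d", names(corpus$source_counts),
                  corpus$source_counts), collapse = ",")), con)
  write.table(corpus$pairs, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a co-expression corpus from TSV
#'
#' @param path Path to a file written by [write_corpus()] (leading `#` lines
#'   are ignored).
#' @return A `coexpr_corpus`. Per-dataset source counts are not recoverable
#'   from the pair list and are returned empty.
#' @export
read_corpus <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("gene_a", "gene_b", "multiplicity"),
                   colClasses = c("character", "character", "integer"))
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(pairs = df,
                 source_counts = stats::setNames(integer(0), character(0))),
            class = "coexpr_corpus")
}
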