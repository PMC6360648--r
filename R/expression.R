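#' Construct an expression dataset
#'
#' Bundles one study's preprocessed expression matrix (genes in rows, samples
#' in columns, log2 scale) with its identifier. Datasets with fewer than
#' `min_samples` samples are rejected: correlation estimates from small
#' studies are too noisy to contribute co-expression pairs.
#'
#' @param dataset_id Character scalar naming the study.
#' @param values Numeric matrix of log2 intensities with unique gene ids as
#'   rownames.
#' @param min_samples Minimum number of samples required (default 30).
#' @return An object of class `expression_dataset` with fields `dataset_id`,
#'   `gene_ids`, `values` and `sample_count`.
#' @export
expression_dataset <- function(dataset_id, values, min_samples = 30L) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L,
            is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) {
    stop("`values` must have gene ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in `values`", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` contains non-finite entries", call. = FALSE)
  }
  if (ncol(values) < min_samples) {
    stop(sprintf("dataset '%s' has %d samples; at least %d required",
                 dataset_id, ncol(values), min_samples), call. = FALSE)
  }
  structure(
    list(dataset_id = dataset_id,
         gene_ids = rownames(values),
         values = values,
         sample_count = ncol(values)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d genes x %d samples>\n",
              x$dataset_id, nrow(x$values), x$sample_count))
  invisible(x)
}

#' Log-transform and quantile-normalize an expression matrix
#'
#' Applies log2 to linear-scale intensities and then quantile normalization,
#' so that every sample (column) ends up with an identical distribution of
#' values. Quantile normalization replaces each column's sorted values with
#' the mean of the sorted columns; it is delegated to
#' [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix, probes/genes in rows and samples in columns.
#' @param log_transform If `TRUE` (default) the input is linear-scale and is
#'   log2-transformed first; all entries must be strictly positive. Set to
#'   `FALSE` for data already on log scale.
#' @return Matrix of the same dimensions with identical column value
#'   multisets.
#' @examples
#' m <- matrix(c(1, 16, 4, 2), nrow = 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' preprocess_expression(m)
#' @export
preprocess_expression <- function(x, log_transform = TRUE) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (log_transform) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      rn <- rownames(x)
      cn <- colnames(x)
      r <- if (is.null(rn)) bad[1L, 1L] else rn[bad[1L, 1L]]
      s <- if (is.null(cn)) bad[1L, 2L] else cn[bad[1L, 2L]]
      stop(sprintf(
        "non-positive value %g at row '%s', column '%s'; cannot log2-transform (use log_transform = FALSE for log-scale input)",
        x[bad[1L, 1L], bad[1L, 2L]], r, s), call. = FALSE)
    }
    x <- log2(x)
  }
  if (ncol(x) == 1L) {
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray platforms measure many genes with several probe sets. For each
#' gene the probe with the largest variance across samples is retained, on
#' the rationale that the most variable probe carries the most co-expression
#' signal. Ties in variance are broken by lexicographically smallest probe
#' id so the result does not depend on input row order.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns; at least two samples.
#' @param probe_map Data frame with columns `probe_id` and `gene_id`; each
#'   probe maps to exactly one gene. Probes absent from the map (and genes
#'   with no mapped probe present in `values`) are dropped.
#' @return Numeric matrix with one row per gene (rownames = gene ids,
#'   sorted); attribute `"probe"` records which probe was retained per gene.
#' @export
collapse_probes <- function(values, probe_map) {
  stopifnot(is.matrix(values), ncol(values) >= 2L,
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (is.null(rownames(values))) {
    stop("`values` must have probe ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("each probe must map to exactly one gene", call. = FALSE)
  }
  probe_map <- probe_map[probe_map$probe_id %in% rownames(values), ,
                         drop = FALSE]
  if (nrow(probe_map) == 0L) {
    stop("no probe in `probe_map` matches rownames of `values`",
         call. = FALSE)
  }
  v <- apply(values[probe_map$probe_id, , drop = FALSE], 1L, var)
  ord <- order(probe_map$gene_id, -v, probe_map$probe_id)
  keep <- ord[!duplicated(probe_map$gene_id[ord])]
  keep <- keep[order(probe_map$gene_id[keep])]
  out <- values[probe_map$probe_id[keep], , drop = FALSE]
  rownames(out) <- probe_map$gene_id[keep]
  attr(out, "probe") <- stats::setNames(probe_map$probe_id[keep],
                                        probe_map$gene_id[keep])
  out
}

#' Read an expression matrix from TSV or HDF5
#'
#' TSV layout: genes in rows, first column gene/probe ids, header row of
#' sample ids. HDF5 layout (`.h5`/`.hdf5`): datasets `gene_ids` (character)
#' and `values` (genes x samples numeric); requires the rhdf5 package.
#'
#' @param path File path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      stop("reading HDF5 expression input requires the rhdf5 package",
           call. = FALSE)
    }
    gene_ids <- as.character(rhdf5::h5read(path, "gene_ids"))
    values <- rhdf5::h5read(path, "values")
    if (length(dim(values)) != 2L || nrow(values) != length(gene_ids)) {
      stop("HDF5 `values` must be a genes x samples matrix matching `gene_ids`",
           call. = FALSE)
    }
    values <- matrix(as.numeric(values), nrow = nrow(values))
    rownames(values) <- gene_ids
    return(values)
  }
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV
#'
#' @param values Numeric matrix with gene ids as rownames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
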