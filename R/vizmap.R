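#' Project an embedding to a 2-D gene co-expression map
#'
#' Centers the embedding, reduces it to at most `pca_dim` principal
#' components (a pure rotation when the embedding dimension is already
#' `<= pca_dim`, so pairwise distances are preserved), then runs Barnes-Hut
#' t-SNE (via [Rtsne::Rtsne()], theta = 0.5, single-threaded) down to two
#' dimensions. t-SNE needs more than `3 * perplexity` points; fewer genes
#' raise an error quoting that rule.
#'
#' @param emb A `gene_embedding`.
#' @param pca_dim Maximum number of principal components kept (default 50).
#' @param perplexity t-SNE perplexity (default 30).
#' @param learning_rate t-SNE learning rate eta (default 200).
#' @param iterations t-SNE iterations. The default here is 1000, a
#'   test-scale setting; production maps of genome-scale vocabularies use
#'   far more (the method stabilizes slowly).
#' @param seed Integer seed (initial layout and t-SNE internals draw from
#'   R's RNG).
#' @return Data frame of class `map_coordinates`: columns `gene`, `F1`,
#'   `F2` (the two t-SNE dimensions), one row per embedded gene.
#' @export
reduce_and_map <- function(emb, pca_dim = 50L, perplexity = 30,
                           learning_rate = 200, iterations = 1000L,
                           seed = 1L) {
  stopifnot(inherits(emb, "gene_embedding"))
  V <- emb$vectors
  n <- nrow(V)
  if (n <= 3 * perplexity) {
    stop(sprintf(
      "t-SNE needs more than 3 x perplexity genes (rule: n > 3 * perplexity); got n = %d for perplexity = %g",
      n, perplexity), call. = FALSE)
  }
  rank <- min(pca_dim, ncol(V), n - 1L)
  scores <- prcomp(V, center = TRUE, scale. = FALSE, rank. = rank)$x
  set.seed(seed)
  fit <- Rtsne::Rtsne(scores, dims = 2L, perplexity = perplexity,
                      eta = learning_rate, max_iter = iterations,
                      theta = 0.5, pca = FALSE, check_duplicates = FALSE,
                      num_threads = 1L, verbose = FALSE)
  out <- data.frame(gene = rownames(V), F1 = fit$Y[, 1L], F2 = fit$Y[, 2L],
                    stringsAsFactors = FALSE)
  class(out) <- c("map_coordinates", "data.frame")
  attr(out, "params") <- list(pca_dim = rank, perplexity = perplexity,
                              learning_rate = learning_rate,
                              iterations = iterations, seed = seed)
  out
}

#' Write map coordinates (and optional overlays) as TSV
#'
#' Columns `gene_id`, `F1`, `F2`, plus one z-score column per tissue when
#' `zscores` is supplied (genes absent from the tissue table get `NA`).
#'
#' @param map A `map_coordinates` data frame.
#' @param path Output path.
#' @param zscores Optional matrix from [tissue_zscores()].
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, zscores = NULL) {
  df <- data.frame(gene_id = map$gene, F1 = map$F1, F2 = map$F2,
                   stringsAsFactors = FALSE)
  if (!is.null(zscores)) {
    z <- zscores[match(map$gene, rownames(zscores)), , drop = FALSE]
    colnames(z) <- paste0("z_", colnames(zscores))
    df <- cbind(df, as.data.frame(z))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tissue-specificity z-scores
#'
#' Standardizes each gene's mean expression across tissues:
#' `z[g, t] = (x[g, t] - mean_t x[g, .]) / sd_t x[g, .]` with the sample
#' (n - 1) standard deviation. A large positive z marks a gene whose
#' expression in that tissue stands out from its own cross-tissue average.
#' Genes constant across tissues have undefined z and get an all-zero row;
#' they are listed in the `"constant_genes"` attribute. The z-scores are
#' invariant to per-gene affine transforms (shift and positive scale) of
#' the input.
#'
#' @param mean_expr Numeric matrix, genes x tissues (>= 2 tissues), of mean
#'   expression per tissue.
#' @param log_transform If `TRUE` (default), apply `log2(x + 1)` first
#'   (entries must be >= 0); expression summaries are usually compared on
#'   log scale.
#' @return Matrix of z-scores (class `tissue_specificity`), same dimnames,
#'   with attributes `constant_genes` and `sd_convention`.
#' @export
tissue_zscores <- function(mean_expr, log_transform = TRUE) {
  stopifnot(is.matrix(mean_expr), ncol(mean_expr) >= 2L)
  x <- mean_expr
  if (log_transform) {
    if (any(x < 0)) {
      stop("negative values; use log_transform = FALSE for log-scale input",
           call. = FALSE)
    }
    x <- log2(x + 1)
  }
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  flat <- s == 0 | !is.finite(s)
  s[flat] <- 1  # placeholder; rows zeroed below
  z <- (x - mu) / s
  z[flat, ] <- 0
  structure(z,
            class = c("tissue_specificity", class(z)),
            constant_genes = rownames(x)[flat],
            sd_convention = "sample (n-1)",
            log_transform = log_transform)
}
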