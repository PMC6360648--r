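#' Construct a pathway collection
#'
#' Named gene sets used as the reference for the clusteredness statistic and
#' for positive-pair construction. Duplicate genes within a set are removed;
#' sets outside `[min_size, max_size]` genes are dropped (small pathways
#' carry no pair, very large ones are computationally heavy and diffuse).
#'
#' @param x Named list of character vectors (pathway name -> gene ids).
#' @param min_size,max_size Retained size range (defaults 2 and 50).
#' @return Object of class `pathway_collection` (a named list of gene sets
#'   with attributes `min_size`, `max_size`).
#' @export
pathway_collection <- function(x, min_size = 2L, max_size = 50L) {
  stopifnot(is.list(x), !is.null(names(x)))
  x <- lapply(x, function(g) unique(as.character(g)))
  sizes <- lengths(x)
  x <- x[sizes >= min_size & sizes <= max_size]
  structure(x, class = "pathway_collection",
            min_size = min_size, max_size = max_size)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection: %d sets, sizes %s..%s>\n", length(x),
              if (length(x)) min(lengths(x)) else "-",
              if (length(x)) max(lengths(x)) else "-"))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, fields tab-separated, the first
#' two being the set name and a description, the rest gene ids. Parsing is
#' delegated to [fgsea::gmtPathways()].
#'
#' @param path Path to a `.gmt` file.
#' @param min_size,max_size Size filter passed to [pathway_collection()].
#' @return A `pathway_collection`.
#' @export
read_gmt <- function(path, min_size = 2L, max_size = 50L) {
  pathway_collection(fgsea::gmtPathways(path),
                     min_size = min_size, max_size = max_size)
}

#' Write gene sets to a GMT file
#'
#' @param pathways A `pathway_collection` or named list of gene id vectors.
#' @param path Output path.
#' @param description Second GMT field, recycled across sets.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path, description = "na") {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, description, pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Random gene-pair background for clusteredness
#'
#' Samples `n` genes without replacement (seeded) and enumerates all
#' `n (n - 1) / 2` unordered pairs among them; the mean inner product over
#' these pairs is the clusteredness denominator. With `n = 1000` this gives
#' 499,500 pairs.
#'
#' @param genes Character vector of candidate genes, or a `gene_embedding`
#'   (its vocabulary is used).
#' @param n Number of genes to sample; must not exceed the candidate count.
#' @param seed Integer seed for the sample.
#' @return Object of class `pair_background`: list with `genes` (sampled),
#'   `pair_i`, `pair_j` (integer indices into `genes`) and `seed`.
#' @export
background_pairs <- function(genes, n, seed = 1L) {
  if (inherits(genes, "gene_embedding")) genes <- rownames(genes$vectors)
  stopifnot(is.character(genes))
  n <- as.integer(n)
  if (n > length(genes)) {
    stop(sprintf("n = %d exceeds the number of available genes (%d)",
                 n, length(genes)), call. = FALSE)
  }
  if (n < 2L) stop("need n >= 2 to form a pair", call. = FALSE)
  set.seed(seed)
  sampled <- sample(genes, n)
  idx <- combn(n, 2L)
  structure(list(genes = sampled,
                 pair_i = as.integer(idx[1L, ]),
                 pair_j = as.integer(idx[2L, ]),
                 seed = as.integer(seed)),
            class = "pair_background")
}

#' @export
print.pair_background <- function(x, ...) {
  cat(sprintf("<pair_background: %d genes, %d pairs, seed %d>\n",
              length(x$genes), length(x$pair_i), x$seed))
  invisible(x)
}

#' Pathway clusteredness of an embedding
#'
#' The hyperparameter-tuning objective: the ratio of (a) the mean over
#' pathways of the mean within-pathway inner product \eqn{v_i^\top v_j}
#' (each pathway weighted equally, pairs enumerated over its in-vocabulary
#' genes) to (b) the mean inner product over the random background pairs. A
#' value of 1 means pathway members are no more aligned than random genes.
#' Pathways with fewer than two in-vocabulary genes are skipped. The ratio
#' is invariant under global rotation and under global rescaling of the
#' vectors (numerator and denominator both scale as \eqn{c^2}).
#'
#' @param emb A `gene_embedding`.
#' @param pathways A `pathway_collection`.
#' @param background A `pair_background` whose genes are all in the
#'   embedding vocabulary.
#' @return Numeric scalar.
#' @export
clusteredness <- function(emb, pathways, background) {
  stopifnot(inherits(emb, "gene_embedding"),
            inherits(background, "pair_background"))
  V <- emb$vectors
  vocab <- rownames(V)
  means <- vapply(pathways, function(genes) {
    g <- intersect(genes, vocab)
    if (length(g) < 2L) return(NA_real_)
    Gm <- tcrossprod(V[g, , drop = FALSE])
    mean(Gm[upper.tri(Gm)])
  }, numeric(1L))
  means <- means[!is.na(means)]
  if (length(means) == 0L) {
    stop("no pathway has >= 2 genes in the embedding vocabulary",
         call. = FALSE)
  }
  Vb <- V[.match_genes(background$genes, vocab), , drop = FALSE]
  denom <- mean(rowSums(Vb[background$pair_i, , drop = FALSE] *
                        Vb[background$pair_j, , drop = FALSE]))
  if (abs(denom) < 1e-12) {
    stop("degenerate embedding: background mean inner product is ~0",
         call. = FALSE)
  }
  mean(means) / denom
}

#' Grid search over embedding dimension and iteration count
#'
#' Trains one embedding per dimension with per-epoch checkpoints, so a
#' single `iterations`-epoch run scores every iteration count of the grid
#' (equivalent in expectation to independent runs, at a fraction of the
#' cost). Each checkpoint is scored by [clusteredness()] against the same
#' pathway collection and background. Ties at the maximum are broken toward
#' smaller dimension, then fewer iterations.
#'
#' @param corpus A `coexpr_corpus`.
#' @param dims Integer vector of embedding dimensions to try.
#' @param iterations Maximum epoch count; all of `1:iterations` are scored.
#' @param pathways A `pathway_collection`.
#' @param background Optional `pair_background`; built from the corpus
#'   vocabulary when `NULL`.
#' @param n_background Genes sampled for the default background.
#' @param seed Seed used for every training run and the default background.
#' @param ... Further arguments passed to [train_embedding()]
#'   (e.g. `min_frequency`, `negative_samples`, `method`).
#' @return Object of class `grid_result`: list with `table` (dims x
#'   iterations matrix of clusteredness), `best` (list `k`, `iterations`,
#'   `clusteredness`) and `background_seed`.
#' @export
grid_search <- function(corpus, dims, iterations = 10L, pathways,
                        background = NULL, n_background = 1000L,
                        seed = 1L, ...) {
  stopifnot(length(dims) >= 1L, iterations >= 1L)
  if (is.null(background)) {
    vocab <- build_vocab(corpus, ...elt_or(list(...), "min_frequency", 5L))
    background <- background_pairs(vocab$gene,
                                   min(n_background, nrow(vocab)),
                                   seed = seed)
  }
  tab <- matrix(NA_real_, nrow = length(dims), ncol = iterations,
                dimnames = list(dims, seq_len(iterations)))
  for (di in seq_along(dims)) {
    fit <- tryCatch(
      train_embedding(corpus, k = dims[di], iterations = iterations,
                      seed = seed, checkpoints = TRUE, ...),
      error = function(e) {
        stop(sprintf("training failed at dimension %d: %s",
                     dims[di], conditionMessage(e)), call. = FALSE)
      })
    for (it in seq_len(iterations)) {
      tab[di, it] <- clusteredness(fit$checkpoints[[it]], pathways,
                                   background)
    }
  }
  cand <- which(tab == max(tab), arr.ind = TRUE)
  cand <- cand[order(dims[cand[, 1L]], cand[, 2L]), , drop = FALSE]
  best <- list(k = dims[cand[1L, 1L]],
               iterations = as.integer(cand[1L, 2L]),
               clusteredness = max(tab))
  structure(list(table = tab, best = best,
                 background_seed = background$seed),
            class = "grid_result")
}

# fetch a named element from a dots-list with a default
...elt_or <- function(dots, name, default) {
  if (!is.null(dots[[name]])) dots[[name]] else default
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>\n")
  print(round(x$table, 3L))
  cat(sprintf("best: k = %d, iterations = %d (clusteredness %.3f)\n",
              x$best$k, x$best$iterations, x$best$clusteredness))
  invisible(x)
}

#' Write a grid-search table as TSV
#'
#' Rows are dimensions, columns iteration counts, cells clusteredness.
#'
#' @param grid A `grid_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path) {
  df <- data.frame(dimension = rownames(grid$table), grid$table,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
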