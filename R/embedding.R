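#' Build a gene vocabulary from a corpus
#'
#' Genes whose multiplicity-weighted occurrence count falls below
#' `min_frequency` are excluded from training, mirroring the word2vec
#' minimum-count filter. Frequencies are counted on the full corpus (before
#' any pair is dropped), so every vocabulary gene satisfies the threshold by
#' construction. Order is decreasing frequency, ties broken by gene id.
#'
#' @param corpus A `coexpr_corpus`.
#' @param min_frequency Minimum multiplicity-weighted count (default 5).
#' @return Data frame with columns `gene`, `frequency`.
#' @export
build_vocab <- function(corpus, min_frequency = 5L) {
  f <- gene_frequencies(corpus)
  f <- f[f >= min_frequency]
  if (length(f) == 0L) {
    stop(sprintf(
      "no gene reaches min_frequency = %d; lower the threshold or supply more data",
      min_frequency), call. = FALSE)
  }
  data.frame(gene = names(f), frequency = as.integer(f),
             stringsAsFactors = FALSE)
}

#' Restrict a corpus to a gene vocabulary
#'
#' Drops every pair touching a gene outside `genes`; the filtered corpus
#' contains no reference to a removed gene.
#'
#' @param corpus A `coexpr_corpus`.
#' @param genes Character vector of genes to keep.
#' @return A `coexpr_corpus`.
#' @export
filter_corpus <- function(corpus, genes) {
  stopifnot(inherits(corpus, "coexpr_corpus"))
  p <- corpus$pairs
  keep <- p$gene_a %in% genes & p$gene_b %in% genes
  structure(list(pairs = p[keep, , drop = FALSE],
                 source_counts = corpus$source_counts),
            class = "coexpr_corpus")
}

#' Construct a gene embedding object
#'
#' @param W Numeric matrix, one row per gene (rownames = gene ids), `k`
#'   columns. Row `i` is the vector `v_i` of gene `i`.
#' @param frequency Optional named integer vector of corpus frequencies.
#' @param meta List of training metadata (hyperparameters, seed, method).
#' @return Object of class `gene_embedding` with fields `vectors`, `vocab`,
#'   `k`, `meta`.
#' @export
gene_embedding <- function(W, frequency = NULL, meta = list()) {
  stopifnot(is.matrix(W), is.numeric(W), !is.null(rownames(W)))
  if (!all(is.finite(W))) stop("embedding has non-finite entries", call. = FALSE)
  if (anyDuplicated(rownames(W))) stop("duplicate gene ids", call. = FALSE)
  freq <- if (is.null(frequency)) rep(NA_integer_, nrow(W)) else
    as.integer(frequency[rownames(W)])
  structure(
    list(vectors = W,
         vocab = data.frame(gene = rownames(W), frequency = freq,
                            stringsAsFactors = FALSE),
         k = ncol(W),
         meta = meta),
    class = "gene_embedding"
  )
}

#' @export
print.gene_embedding <- function(x, ...) {
  cat(sprintf("<gene_embedding: %d genes x k = %d (%s)>\n",
              nrow(x$vectors), x$k,
              if (length(x$meta)) paste0("method = ",
                                         x$meta$method %||% "unknown")
              else "no metadata"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.emb_index <- function(emb, g) {
  if (is.character(g)) .match_genes(g, rownames(emb$vectors)) else as.integer(g)
}

#' Full-softmax pair probability
#'
#' Probability assigned by the embedding to gene `j` as the co-expression
#' context of gene `i`:
#' \deqn{\Pr(j \mid i) = \frac{\exp(v_i^\top v_j)}{\sum_{j'} \exp(v_i^\top v_{j'})}}
#' The normalization runs over the second argument's slot, so
#' `sum_j pair_probability(emb, i, j) == 1`. The maximum score is subtracted
#' before exponentiation to guard against overflow.
#'
#' @param emb A `gene_embedding`.
#' @param i,j Gene ids (character) or integer indices into the vocabulary.
#' @return Numeric scalar in (0, 1).
#' @export
pair_probability <- function(emb, i, j) {
  stopifnot(inherits(emb, "gene_embedding"))
  V <- emb$vectors
  if (nrow(V) == 0L) stop("empty vocabulary", call. = FALSE)
  i <- .emb_index(emb, i)
  j <- .emb_index(emb, j)
  s <- as.vector(V %*% V[i, ])
  s <- s - max(s)
  e <- exp(s)
  e[j] / sum(e)
}

# log-sum-exp of each row of a matrix
.row_lse <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# corpus pairs as integer index columns into the embedding vocabulary
.corpus_idx <- function(emb, corpus) {
  genes <- rownames(emb$vectors)
  ia <- .match_genes(corpus$pairs$gene_a, genes, what = "vocabulary")
  ib <- .match_genes(corpus$pairs$gene_b, genes, what = "vocabulary")
  list(ia = ia, ib = ib, mult = corpus$pairs$multiplicity)
}

#' Full-softmax negative log-likelihood of a corpus
#'
#' The training objective in its exact form: the sum over pair occurrences
#' (with multiplicity) of `-log Pr(gene_b | gene_a)` under the full-softmax
#' model of [pair_probability()]. Nonnegative, and additive under corpus
#' concatenation. With a uniform embedding (all vectors equal) the loss is
#' `N * log(d)` for `N` occurrences and vocabulary size `d`.
#'
#' @param emb A `gene_embedding` whose vocabulary covers every corpus gene.
#' @param corpus A `coexpr_corpus`.
#' @return Numeric scalar.
#' @export
corpus_loss <- function(emb, corpus) {
  stopifnot(inherits(emb, "gene_embedding"), inherits(corpus, "coexpr_corpus"))
  if (nrow(corpus$pairs) == 0L) return(0)
  ix <- .corpus_idx(emb, corpus)
  G <- tcrossprod(emb$vectors)
  lse <- .row_lse(G)
  sum(ix$mult * (lse[ix$ia] - G[cbind(ix$ia, ix$ib)]))
}

#' Analytic gradient of the full-softmax corpus loss
#'
#' Gradient of [corpus_loss()] with respect to the (tied) embedding matrix
#' `W`, used by the exact trainer and by finite-difference verification.
#' With `G = W W^T`, `dL/dG[x, y] = c(x) P[x, y] - C[x, y]` where `P` is the
#' row-softmax of `G`, `C` the pair count matrix and `c` the row sums of
#' `C`; the chain rule through the symmetric product gives
#' `dL/dW = (D + D^T) W`.
#'
#' @inheritParams corpus_loss
#' @return Numeric matrix, same shape as `emb$vectors`.
#' @export
corpus_loss_grad <- function(emb, corpus) {
  stopifnot(inherits(emb, "gene_embedding"), inherits(corpus, "coexpr_corpus"))
  V <- emb$vectors
  d <- nrow(V)
  if (nrow(corpus$pairs) == 0L) return(matrix(0, d, ncol(V)))
  ix <- .corpus_idx(emb, corpus)
  G <- tcrossprod(V)
  P <- exp(G - .row_lse(G))          # row-stochastic
  cnt <- numeric(d)
  agg <- rowsum(as.numeric(ix$mult), ix$ia)
  cnt[as.integer(rownames(agg))] <- agg[, 1L]
  D <- cnt * P
  # corpus pairs are unique, so direct subtraction is safe
  D[cbind(ix$ia, ix$ib)] <- D[cbind(ix$ia, ix$ib)] - ix$mult
  (D + t(D)) %*% V
}

#' Train a skip-gram gene embedding
#'
#' Each co-expressed pair is a two-token sentence; skip-gram with negative
#' sampling (`method = "sgns"`, compiled) maximizes the probability of each
#' gene given its partner against `negative_samples` draws from a
#' unigram^0.75 noise distribution, with both directions of every pair
#' trained and the learning rate decaying linearly from `learning_rate` to
#' `learning_rate_min` across all epochs. The pair sequence is reshuffled
#' every epoch (seeded), so visit order changes but the pair multiset does
#' not. `method = "exact"` instead minimizes the full-softmax
#' [corpus_loss()] directly by backtracking gradient descent with a single
#' tied weight matrix; it is intended for small vocabularies where the
#' printed objective is tractable.
#'
#' Genes below `min_frequency` (multiplicity-weighted) are removed, along
#' with every pair touching them. Training is single-threaded and fully
#' deterministic given `seed`.
#'
#' @param corpus A `coexpr_corpus`.
#' @param k Embedding dimension (default 100).
#' @param iterations Number of epochs (default 5).
#' @param min_frequency Vocabulary filter (default 5).
#' @param negative_samples Negatives per positive in sgns mode (default 5,
#'   the word2vec default).
#' @param learning_rate,learning_rate_min Linear decay endpoints for sgns
#'   (defaults 0.025 and 1e-4, the word2vec defaults).
#' @param seed Integer seed controlling initialization, shuffling and
#'   negative draws.
#' @param method `"sgns"` (default) or `"exact"`.
#' @param checkpoints If `TRUE`, also return the embedding after each epoch
#'   (used by [grid_search()] to score all iteration counts from one run).
#' @param exact_steps Gradient-descent steps per epoch in exact mode.
#' @return A `gene_embedding`; with `checkpoints = TRUE`, a list with
#'   elements `embedding` (final) and `checkpoints` (list of per-epoch
#'   `gene_embedding`s).
#' @export
train_embedding <- function(corpus, k = 100L, iterations = 5L,
                            min_frequency = 5L, negative_samples = 5L,
                            learning_rate = 0.025, learning_rate_min = 1e-4,
                            seed = 1L, method = c("sgns", "exact"),
                            checkpoints = FALSE, exact_steps = 25L) {
  method <- match.arg(method)
  stopifnot(k >= 1L, iterations >= 1L, negative_samples >= 1L)
  vocab <- build_vocab(corpus, min_frequency = min_frequency)
  corpus <- filter_corpus(corpus, vocab$gene)
  if (nrow(corpus$pairs) == 0L) {
    stop(sprintf("corpus is empty after min_frequency = %d filtering",
                 min_frequency), call. = FALSE)
  }
  d <- nrow(vocab)
  genes <- vocab$gene
  ia <- match(corpus$pairs$gene_a, genes)
  ib <- match(corpus$pairs$gene_b, genes)
  # expand multiplicities into an occurrence list
  occ_a <- rep.int(ia, corpus$pairs$multiplicity)
  occ_b <- rep.int(ib, corpus$pairs$multiplicity)
  n_occ <- length(occ_a)
  meta <- list(method = method, k = k, iterations = iterations,
               min_frequency = min_frequency,
               negative_samples = negative_samples,
               learning_rate = learning_rate, seed = seed)
  snap <- vector("list", if (isTRUE(checkpoints)) iterations else 0L)
  set.seed(seed)
  if (method == "sgns") {
    syn0 <- matrix((runif(d * k) - 0.5) / k, nrow = d, ncol = k)
    syn1 <- matrix(0, nrow = d, ncol = k)
    freq <- as.numeric(vocab$frequency)
    p <- freq^0.75 / sum(freq^0.75)
    table_size <- max(100000L, 10L * d)
    cum <- cumsum(p)
    neg_table <- findInterval((seq_len(table_size) - 0.5) / table_size,
                              cum) # 0-based gene index
    neg_table <- as.integer(pmin(neg_table, d - 1L))
    for (e in seq_len(iterations)) {
      perm <- sample.int(n_occ)
      a0 <- alpha_at(learning_rate, learning_rate_min, (e - 1) / iterations)
      a1 <- alpha_at(learning_rate, learning_rate_min, e / iterations)
      sgns_epoch(syn0, syn1, occ_a[perm] - 1L, occ_b[perm] - 1L,
                 neg_table, a0, a1, as.integer(negative_samples))
      if (isTRUE(checkpoints)) {
        W <- syn0 + 0  # force a copy of the in-place buffer
        rownames(W) <- genes
        m <- meta; m$iterations <- e
        snap[[e]] <- gene_embedding(W, stats::setNames(vocab$frequency, genes), m)
      }
    }
    W <- syn0
  } else {
    W <- matrix((runif(d * k) - 0.5) / k, nrow = d, ncol = k)
    rownames(W) <- genes
    emb <- gene_embedding(W, stats::setNames(vocab$frequency, genes), meta)
    # gradient descent with Barzilai-Borwein step sizes and a backtracking
    # safeguard; plain fixed-step descent converges too slowly on this
    # ill-conditioned objective
    step <- 1 / n_occ
    cur <- corpus_loss(emb, corpus)
    g_prev <- NULL
    W_prev <- NULL
    for (e in seq_len(iterations)) {
      for (s in seq_len(exact_steps)) {
        gr <- corpus_loss_grad(emb, corpus)
        if (!is.null(g_prev)) {
          dw <- emb$vectors - W_prev
          dg <- gr - g_prev
          bb <- sum(dw * dg) / sum(dg * dg)
          if (is.finite(bb) && bb > 0) step <- bb
        }
        W_prev <- emb$vectors
        g_prev <- gr
        repeat {
          W2 <- emb$vectors - step * gr
          emb2 <- emb; emb2$vectors <- W2
          new <- corpus_loss(emb2, corpus)
          if (new <= cur + 1e-12 || step < 1e-14) break
          step <- step / 2
        }
        if (new <= cur + 1e-12) {
          emb$vectors <- W2
          cur <- new
        }
      }
      if (isTRUE(checkpoints)) {
        m <- meta; m$iterations <- e
        snap[[e]] <- gene_embedding(emb$vectors,
                                    stats::setNames(vocab$frequency, genes), m)
      }
    }
    W <- emb$vectors
  }
  rownames(W) <- genes
  out <- gene_embedding(W, stats::setNames(vocab$frequency, genes), meta)
  if (isTRUE(checkpoints)) list(embedding = out, checkpoints = snap) else out
}

# linear learning-rate decay at fractional progress t in [0, 1]
alpha_at <- function(lr0, lr_min, t) lr0 + (lr_min - lr0) * t

#' Write an embedding in word2vec text format
#'
#' First line `d k`, then one line per gene: the gene id followed by `k`
#' vector components, space-separated, 6 significant digits.
#'
#' @param emb A `gene_embedding`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "gene_embedding"))
  V <- emb$vectors
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(V), ncol(V)), con)
  rows <- apply(V, 1L, function(r) paste(sprintf("%.6g", r), collapse = " "))
  writeLines(paste(rownames(V), rows), con)
  invisible(path)
}

#' Read an embedding in word2vec text format
#'
#' @param path Path to a file as written by [write_embedding()].
#' @return A `gene_embedding`.
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L) stop("malformed header; expected 'd k'", call. = FALSE)
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  genes <- vapply(body, `[`, "", 1L)
  W <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(hdr[2L])))
  if (hdr[2L] == 1L) W <- matrix(W, ncol = 1L)
  rownames(W) <- genes
  if (nrow(W) != hdr[1L]) {
    stop("row count disagrees with header", call. = FALSE)
  }
  gene_embedding(W, meta = list(source = path))
}
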