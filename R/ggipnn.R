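#' Construct a gene annotation table
#'
#' Bundles gene-to-term annotation records (with evidence codes) with a
#' term hierarchy (directed parent -> child edges, as extracted from an
#' ontology). Term levels are computed as the minimum depth from a root
#' (root = level 0) over all parent paths. The hierarchy must be acyclic.
#'
#' @param records Data frame with columns `gene`, `term`, `evidence`.
#' @param hierarchy Data frame with columns `parent`, `child`.
#' @param root Optional character vector of root term ids; by default every
#'   term that never appears as a child.
#' @return Object of class `annotation_table`: list with `records`,
#'   `hierarchy`, `levels` (named integer, `NA` for terms unreachable from a
#'   root) and `children` (adjacency list).
#' @export
annotation_table <- function(records, hierarchy, root = NULL) {
  stopifnot(all(c("gene", "term", "evidence") %in% names(records)),
            all(c("parent", "child") %in% names(hierarchy)))
  records[] <- lapply(records, as.character)
  hierarchy[] <- lapply(hierarchy, as.character)
  terms <- unique(c(records$term, hierarchy$parent, hierarchy$child))
  if (any(hierarchy$parent == hierarchy$child)) {
    stop("hierarchy contains a self-loop", call. = FALSE)
  }
  if (nrow(hierarchy) > 0L) {
    g <- igraph::graph_from_data_frame(hierarchy, directed = TRUE,
                                       vertices = terms)
    if (!igraph::is_dag(g)) {
      stop("term hierarchy contains a cycle", call. = FALSE)
    }
    if (is.null(root)) {
      root <- setdiff(terms, hierarchy$child)
    }
    if (length(root) == 0L) stop("no root term found", call. = FALSE)
    dmat <- igraph::distances(g, v = root, to = terms, mode = "out")
    lev <- apply(dmat, 2L, min)
    lev[!is.finite(lev)] <- NA_real_
    levels <- stats::setNames(as.integer(lev), terms)
    children <- split(hierarchy$child, factor(hierarchy$parent,
                                              levels = terms))
  } else {
    levels <- stats::setNames(rep(NA_integer_, length(terms)), terms)
    if (!is.null(root)) levels[root] <- 0L
    children <- split(character(0), factor(character(0), levels = terms))
  }
  structure(list(records = records, hierarchy = hierarchy,
                 levels = levels, children = children),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf(
    "<annotation_table: %d records, %d genes, %d terms, %d hierarchy edges>\n",
    nrow(x$records), length(unique(x$records$gene)),
    length(x$levels), nrow(x$hierarchy)))
  invisible(x)
}

#' Read an annotation table from TSV files
#'
#' @param records_path 3-column TSV `gene`, `term`, `evidence` (no header).
#' @param hierarchy_path 2-column TSV `parent`, `child` (no header).
#' @param root Optional root term ids (see [annotation_table()]).
#' @return An `annotation_table`.
#' @export
read_annotations <- function(records_path, hierarchy_path, root = NULL) {
  rec <- read.delim(records_path, header = FALSE, comment.char = "#",
                    col.names = c("gene", "term", "evidence"),
                    colClasses = "character")
  hier <- read.delim(hierarchy_path, header = FALSE, comment.char = "#",
                     col.names = c("parent", "child"),
                     colClasses = "character")
  annotation_table(rec, hier, root = root)
}

# descendant closure (term itself + all descendants) for each requested term
.term_closures <- function(ann, terms) {
  memo <- new.env(parent = emptyenv())
  closure <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    memo[[t]] <- t  # break cycles defensively; hierarchy is checked acyclic
    kids <- ann$children[[t]]
    out <- t
    if (length(kids)) {
      out <- unique(c(t, unlist(lapply(unique(kids), closure),
                                use.names = FALSE)))
    }
    memo[[t]] <- out
    out
  }
  stats::setNames(lapply(terms, closure), terms)
}

#' Positive gene pairs from shared annotations
#'
#' A pair is positive when both genes carry a common retained term. A term
#' is retained when its evidence code is in `evidence`, it is not in
#' `excluded_terms`, and its hierarchy level is deeper than `max_excluded_level`
#' (shallow terms are too generic to indicate specific shared function).
#' The default exclusions are the over-represented signal-transduction and
#' phosphorylation terms.
#'
#' @param ann An `annotation_table`.
#' @param evidence Allowed evidence codes (default the experimental codes
#'   IDA, IMP, IPI, IGI, TAS).
#' @param excluded_terms Term ids removed outright.
#' @param max_excluded_level Levels `<=` this value are excluded (default 3,
#'   i.e. only terms at level 4 or deeper count).
#' @return Data frame `gene_a`, `gene_b` (`gene_a < gene_b`).
#' @export
positive_pairs <- function(ann,
                           evidence = c("IDA", "IMP", "IPI", "IGI", "TAS"),
                           excluded_terms = c("GO:0007165", "GO:0006468",
                                              "GO:0046777", "GO:0006470"),
                           max_excluded_level = 3L) {
  stopifnot(inherits(ann, "annotation_table"))
  rec <- ann$records[ann$records$evidence %in% evidence, , drop = FALSE]
  rec <- rec[!(rec$term %in% excluded_terms), , drop = FALSE]
  lev <- ann$levels[rec$term]
  if (anyNA(lev)) {
    orphans <- unique(rec$term[is.na(lev)])
    stop(sprintf("term(s) without a hierarchy level: %s",
                 paste(head(orphans, 5L), collapse = ", ")), call. = FALSE)
  }
  rec <- rec[lev > max_excluded_level, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  by_term <- split(rec$gene, rec$term)
  pieces <- lapply(by_term, function(g) {
    g <- unique(g)
    if (length(g) < 2L) return(NULL)
    idx <- combn(sort(g), 2L)
    data.frame(gene_a = idx[1L, ], gene_b = idx[2L, ],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (is.null(all)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  .canonical_pairs(all$gene_a, all$gene_b)
}

#' Negative gene pairs by disjoint annotation subtrees
#'
#' A pair is negative when the descendant-closed term sets of the two genes
#' are disjoint: the genes share no annotated term and no child (at any
#' depth) of an annotated term. All annotation records contribute,
#' regardless of evidence code — sharing any term disqualifies a pair.
#'
#' @param ann An `annotation_table`.
#' @param universe Optional character vector of all genes under
#'   consideration; used only for the coverage attribute (defaults to the
#'   annotated genes).
#' @return Data frame `gene_a`, `gene_b` with attribute `"coverage"`: the
#'   percentage of `universe` genes that occur in at least one negative
#'   pair (see [gene_coverage()]).
#' @export
negative_pairs <- function(ann, universe = NULL) {
  stopifnot(inherits(ann, "annotation_table"))
  rec <- ann$records
  genes <- sort(unique(rec$gene))
  if (length(genes) < 2L) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
    attr(out, "coverage") <- 0
    return(out)
  }
  closures <- .term_closures(ann, unique(rec$term))
  # gene x closed-term incidence matrix; disjoint closures <=> zero overlap
  gene_terms <- lapply(split(rec$term, rec$gene)[genes], function(ts) {
    unique(unlist(closures[unique(ts)], use.names = FALSE))
  })
  all_terms <- unique(unlist(gene_terms, use.names = FALSE))
  M <- matrix(0L, nrow = length(genes), ncol = length(all_terms),
              dimnames = list(genes, all_terms))
  for (i in seq_along(genes)) {
    M[i, gene_terms[[i]]] <- 1L
  }
  overlap <- tcrossprod(M)
  hit <- which(upper.tri(overlap) & overlap == 0L, arr.ind = TRUE)
  out <- .canonical_pairs(genes[hit[, 1L]], genes[hit[, 2L]])
  if (is.null(universe)) universe <- genes
  covered <- length(unique(c(out$gene_a, out$gene_b)))
  attr(out, "coverage") <- gene_coverage(covered, length(universe))
  out
}

#' Percentage of a gene universe covered by a pair set
#'
#' Small reporting utility: `100 * n_genes / n_universe`, the share of the
#' gene universe that participates in at least one pair.
#'
#' @param n_genes Number of genes occurring in the pair set.
#' @param n_universe Size of the gene universe.
#' @return Numeric percentage.
#' @examples
#' gene_coverage(12521, 19307)  # ~64.85
#' @export
gene_coverage <- function(n_genes, n_universe) {
  stopifnot(n_universe > 0)
  100 * n_genes / n_universe
}

#' Assemble a balanced labeled pair dataset
#'
#' Labels positives 1 and negatives 0, downsampling the negatives (seeded)
#' to the number of positives so that the classes are balanced. The
#' downsampling happens before any split.
#'
#' @param positives,negatives Data frames `gene_a`, `gene_b`.
#' @param seed Integer seed for the downsample.
#' @return Data frame `gene_a`, `gene_b`, `label`.
#' @export
build_pair_dataset <- function(positives, negatives, seed = 1L) {
  npos <- nrow(positives)
  if (nrow(negatives) < npos) {
    stop(sprintf(
      "only %d negative pairs available for %d positives; cannot balance",
      nrow(negatives), npos), call. = FALSE)
  }
  set.seed(seed)
  neg <- negatives[sample.int(nrow(negatives), npos), , drop = FALSE]
  out <- rbind(
    data.frame(gene_a = positives$gene_a, gene_b = positives$gene_b,
               label = 1L, stringsAsFactors = FALSE),
    data.frame(gene_a = neg$gene_a, gene_b = neg$gene_b, label = 0L,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Gene-disjoint train/validation/test split
#'
#' Partitions the unique genes (not the pairs) into train, validation and
#' test groups in the given proportions, then keeps a pair only when both
#' its genes fall in the same group. No gene — and hence no pair — appears
#' in more than one group, which prevents the classifier from memorizing
#' per-gene interaction propensity. Pairs spanning two groups are dropped.
#'
#' @param pairs Data frame `gene_a`, `gene_b` and optionally `label`.
#' @param proportions Numeric length-3 vector (train, validation, test);
#'   default `c(7, 1, 2)`.
#' @param seed Integer seed for the gene shuffle.
#' @return Object of class `pair_dataset`: list with `pairs` (the retained
#'   pairs plus a `split` column), `gene_split` (named character vector),
#'   `counts` (retained pairs per split) and `dropped` (number of
#'   cross-split pairs discarded).
#' @export
gene_disjoint_split <- function(pairs, proportions = c(7, 1, 2), seed = 1L) {
  stopifnot(length(proportions) == 3L, all(proportions > 0))
  splits <- c("train", "val", "test")
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  n <- length(genes)
  frac <- proportions / sum(proportions)
  sizes <- floor(n * frac)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(n * frac - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  if (any(sizes == 0L)) {
    stop(sprintf(
      "split '%s' would receive no genes; supply more data or adjust proportions",
      splits[which(sizes == 0L)[1L]]), call. = FALSE)
  }
  set.seed(seed)
  perm <- sample(genes)
  gene_split <- stats::setNames(
    rep(splits, times = sizes), perm)
  sa <- gene_split[pairs$gene_a]
  sb <- gene_split[pairs$gene_b]
  keep <- !is.na(sa) & sa == sb
  retained <- pairs[keep, , drop = FALSE]
  retained$split <- unname(sa[keep])
  rownames(retained) <- NULL
  counts <- table(factor(retained$split, levels = splits))
  if (any(counts == 0L)) {
    warning(sprintf(
      "split '%s' retained no pairs; downstream training/evaluation on it will fail",
      splits[which(counts == 0L)[1L]]))
  }
  structure(list(pairs = retained, gene_split = gene_split,
                 counts = counts, dropped = sum(!keep)),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf(
    "<pair_dataset: %d pairs (train %d / val %d / test %d), %d genes, %d cross-split pairs dropped>\n",
    nrow(x$pairs), x$counts[["train"]], x$counts[["val"]],
    x$counts[["test"]], length(x$gene_split), x$dropped))
  invisible(x)
}

#' Configuration for the gene-pair interaction classifier
#'
#' The network maps a pair of gene vectors (looked up in a shared embedding
#' matrix and concatenated, input dimension `2k`) through fully connected
#' layers of sizes 100, 100 and 10 with ReLU activations, dropout 0.5 on
#' the first two hidden layers, and a 2-unit softmax output (equivalent to
#' a sigmoid for this binary task); mean cross-entropy is minimized with
#' Adam.
#'
#' @param embedding `"pretrained"` (rows taken from a trained
#'   `gene_embedding`) or `"random"` (seeded Gaussian rows, sd `1/sqrt(k)`).
#' @param trainable Should the embedding rows be updated during training?
#'   With `FALSE` (frozen) the embedding matrix is bitwise identical before
#'   and after training.
#' @param hidden_dims Hidden layer widths; default `c(100, 100, 10)`.
#' @param dropout Dropout rate on the first two hidden layers (default 0.5).
#' @param epochs Maximum training epochs (default 30).
#' @param batch_size Minibatch size (default 256).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience on validation AUC (default 5);
#'   `Inf` disables early stopping.
#' @param k Embedding dimension, required for `embedding = "random"` when no
#'   pretrained embedding is supplied.
#' @param seed Integer seed covering initialization, batching and dropout.
#' @return A list of class `ggipnn_config`.
#' @export
ggipnn_config <- function(embedding = c("pretrained", "random"),
                          trainable = FALSE,
                          hidden_dims = c(100L, 100L, 10L),
                          dropout = 0.5, epochs = 30L, batch_size = 256L,
                          learning_rate = 1e-3, patience = 5L,
                          k = NULL, seed = 1L) {
  embedding <- match.arg(embedding)
  stopifnot(length(hidden_dims) == 3L, dropout >= 0, dropout < 1,
            epochs >= 1L, batch_size >= 1L)
  structure(list(embedding = embedding, trainable = trainable,
                 hidden_dims = as.integer(hidden_dims), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = patience,
                 k = k, seed = as.integer(seed)),
            class = "ggipnn_config")
}

# forward pass; returns activations when keep_cache for backprop
.ggipnn_forward <- function(params, X, dropout = 0, train = FALSE,
                            keep_cache = FALSE) {
  relu <- function(z) pmax(z, 0)
  drop_mask <- function(dim1, dim2, p) {
    matrix(runif(dim1 * dim2) >= p, dim1, dim2) / (1 - p)
  }
  h1 <- relu(sweep(X %*% params$W1, 2L, params$b1, `+`))
  m1 <- NULL
  if (train && dropout > 0) {
    m1 <- drop_mask(nrow(h1), ncol(h1), dropout)
    h1 <- h1 * m1
  }
  h2 <- relu(sweep(h1 %*% params$W2, 2L, params$b2, `+`))
  m2 <- NULL
  if (train && dropout > 0) {
    m2 <- drop_mask(nrow(h2), ncol(h2), dropout)
    h2 <- h2 * m2
  }
  h3 <- relu(sweep(h2 %*% params$W3, 2L, params$b3, `+`))
  logits <- sweep(h3 %*% params$W4, 2L, params$b4, `+`)
  mx <- pmax(logits[, 1L], logits[, 2L])
  ez <- exp(logits - mx)
  prob <- ez / rowSums(ez)
  if (!keep_cache) return(prob)
  list(prob = prob, X = X, h1 = h1, h2 = h2, h3 = h3, m1 = m1, m2 = m2)
}

# Adam update in place on a parameter list; state carries m/v/t
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train the gene-pair interaction classifier
#'
#' Implements the pair classifier described in [ggipnn_config()]: embedding
#' lookup, concatenation, three ReLU layers (100, 100, 10; dropout 0.5 on
#' the first two) and a 2-unit softmax trained by Adam on mean
#' cross-entropy. Training uses only the `train` split; when a validation
#' split is present and `patience` is finite, the epoch with the best
#' validation AUC is kept. Single-threaded and deterministic given
#' `config$seed`.
#'
#' @param ds A `pair_dataset` from [gene_disjoint_split()] with a `label`
#'   column.
#' @param emb A `gene_embedding` covering every gene in `ds` (required for
#'   `embedding = "pretrained"`; for `"random"` it only supplies `k` if
#'   given).
#' @param config A `ggipnn_config`.
#' @return Object of class `ggipnn`: list with `params`, `embedding` (the
#'   gene x k matrix used, post-training), `embedding_init` (its state
#'   before training), `gene_index`, `config` and `history` (per-epoch train
#'   loss and validation AUC).
#' @export
ggipnn_train <- function(ds, emb = NULL, config = ggipnn_config()) {
  stopifnot(inherits(ds, "pair_dataset"), inherits(config, "ggipnn_config"),
            "label" %in% names(ds$pairs))
  genes <- names(ds$gene_split)
  set.seed(config$seed)
  if (config$embedding == "pretrained") {
    if (!inherits(emb, "gene_embedding")) {
      stop("pretrained mode requires a gene_embedding", call. = FALSE)
    }
    E <- emb$vectors[.match_genes(genes, rownames(emb$vectors)), ,
                     drop = FALSE]
    rownames(E) <- genes
  } else {
    k <- config$k %||% (if (inherits(emb, "gene_embedding")) emb$k else NULL)
    if (is.null(k)) {
      stop("random mode needs `config$k` (or an embedding to copy k from)",
           call. = FALSE)
    }
    E <- matrix(rnorm(length(genes) * k, sd = 1 / sqrt(k)),
                nrow = length(genes),
                dimnames = list(genes, NULL))
  }
  k <- ncol(E)
  E_init <- E
  gene_index <- stats::setNames(seq_along(genes), genes)
  hd <- config$hidden_dims
  he_init <- function(fan_in, fan_out) {
    matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
  }
  params <- list(W1 = he_init(2L * k, hd[1L]), b1 = numeric(hd[1L]),
                 W2 = he_init(hd[1L], hd[2L]), b2 = numeric(hd[2L]),
                 W3 = he_init(hd[2L], hd[3L]), b3 = numeric(hd[3L]),
                 W4 = he_init(hd[3L], 2L), b4 = numeric(2L))
  zero_like <- function(p) lapply(p, function(x) x * 0)
  state <- list(m = zero_like(params), v = zero_like(params), t = 0L)
  if (config$trainable) {
    est <- list(m = E * 0, v = E * 0, t = 0L)
  }
  tr <- ds$pairs[ds$pairs$split == "train", , drop = FALSE]
  va <- ds$pairs[ds$pairs$split == "val", , drop = FALSE]
  ia_tr <- gene_index[tr$gene_a]
  ib_tr <- gene_index[tr$gene_b]
  y_tr <- tr$label
  n_tr <- nrow(tr)
  lookup <- function(E, ia, ib) cbind(E[ia, , drop = FALSE],
                                      E[ib, , drop = FALSE])
  val_auc <- function(E, params) {
    if (nrow(va) == 0L || length(unique(va$label)) < 2L) return(NA_real_)
    X <- lookup(E, gene_index[va$gene_a], gene_index[va$gene_b])
    auc_score(.ggipnn_forward(params, X)[, 2L], va$label)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auc = numeric())
  best <- list(auc = -Inf, params = params, E = E, bad = 0L)
  use_es <- is.finite(config$patience) && nrow(va) > 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n_tr)
    epoch_loss <- 0
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n_tr)]
      B <- length(idx)
      ia <- ia_tr[idx]; ib <- ib_tr[idx]; y <- y_tr[idx]
      X <- lookup(E, ia, ib)
      fw <- .ggipnn_forward(params, X, dropout = config$dropout,
                            train = TRUE, keep_cache = TRUE)
      p <- fw$prob
      eps <- 1e-12
      epoch_loss <- epoch_loss -
        sum(log(ifelse(y == 1L, p[, 2L], p[, 1L]) + eps))
      # backprop: softmax + CE
      dlogits <- p
      dlogits[cbind(seq_len(B), y + 1L)] <-
        dlogits[cbind(seq_len(B), y + 1L)] - 1
      dlogits <- dlogits / B
      gW4 <- crossprod(fw$h3, dlogits); gb4 <- colSums(dlogits)
      dh3 <- dlogits %*% t(params$W4) * (fw$h3 > 0)
      gW3 <- crossprod(fw$h2, dh3); gb3 <- colSums(dh3)
      dh2 <- dh3 %*% t(params$W3)
      if (!is.null(fw$m2)) dh2 <- dh2 * fw$m2
      dh2 <- dh2 * (fw$h2 > 0)
      gW2 <- crossprod(fw$h1, dh2); gb2 <- colSums(dh2)
      dh1 <- dh2 %*% t(params$W2)
      if (!is.null(fw$m1)) dh1 <- dh1 * fw$m1
      dh1 <- dh1 * (fw$h1 > 0)
      gW1 <- crossprod(X, dh1); gb1 <- colSums(dh1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
      upd <- .adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      if (config$trainable) {
        dX <- dh1 %*% t(params$W1)
        gE <- E * 0
        gA <- rowsum(dX[, seq_len(k), drop = FALSE], ia)
        gB <- rowsum(dX[, k + seq_len(k), drop = FALSE], ib)
        gE[as.integer(rownames(gA)), ] <- gA
        gE[as.integer(rownames(gB)), ] <-
          gE[as.integer(rownames(gB)), , drop = FALSE] + gB
        eupd <- .adam_step(list(E = E), list(E = gE),
                           list(m = list(E = est$m), v = list(E = est$v),
                                t = est$t),
                           config$learning_rate)
        E <- eupd$params$E
        est <- list(m = eupd$state$m$E, v = eupd$state$v$E,
                    t = eupd$state$t)
      }
    }
    va_auc <- val_auc(E, params)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n_tr, val_auc = va_auc))
    if (use_es && !is.na(va_auc)) {
      if (va_auc > best$auc) {
        best <- list(auc = va_auc, params = params, E = E, bad = 0L)
      } else {
        best$bad <- best$bad + 1L
        if (best$bad >= config$patience) break
      }
    }
  }
  if (use_es && is.finite(best$auc)) {
    params <- best$params
    E <- best$E
  }
  structure(list(params = params, embedding = E, embedding_init = E_init,
                 gene_index = gene_index, config = config,
                 history = history),
            class = "ggipnn")
}

#' @export
print.ggipnn <- function(x, ...) {
  cat(sprintf(
    "<ggipnn: %s %s embedding (k = %d), %d genes, %d epoch(s) trained>\n",
    x$config$embedding, if (x$config$trainable) "trainable" else "frozen",
    ncol(x$embedding), length(x$gene_index), nrow(x$history)))
  invisible(x)
}

#' Predict interaction probabilities for gene pairs
#'
#' @param object A trained `ggipnn`.
#' @param pairs Data frame `gene_a`, `gene_b`; every gene must be known to
#'   the model.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.ggipnn <- function(object, pairs, ...) {
  ia <- object$gene_index[pairs$gene_a]
  ib <- object$gene_index[pairs$gene_b]
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
    stop(sprintf("gene(s) without an embedding row: %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  X <- cbind(object$embedding[ia, , drop = FALSE],
             object$embedding[ib, , drop = FALSE])
  .ggipnn_forward(object$params, X)[, 2L]
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed from the rank statistic: with midranks `r`, positives `P`
#' and negatives `N`, `AUC = (sum(r[pos]) - |P|(|P|+1)/2) / (|P| |N|)`. Ties
#' are handled by midrank, so a tied positive/negative pair counts 1/2.
#'
#' @param scores Numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return Numeric scalar in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a trained classifier on one split
#'
#' @param model A `ggipnn`.
#' @param ds The `pair_dataset` it was trained on (or a compatible one).
#' @param split Which split to score (default `"test"`).
#' @return AUC of the positive-class probability on that split.
#' @export
evaluate_auc <- function(model, ds, split = "test") {
  stopifnot(inherits(model, "ggipnn"), inherits(ds, "pair_dataset"))
  sub <- ds$pairs[ds$pairs$split == split, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("split '%s' is empty", split),
                            call. = FALSE)
  auc_score(predict(model, sub), sub$label)
}
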