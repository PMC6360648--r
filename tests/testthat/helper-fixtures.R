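# Shared fixtures, memoized so expensive objects are built once per test run.
# The standard planted-module compendium: 200 genes, 4 modules of 40, 3
# datasets of 100 samples, expected within-module PCC 0.96.

.fx <- new.env(parent = emptyenv())

fixture_plan <- function() {
  if (is.null(.fx$plan)) .fx$plan <- module_plan()
  .fx$plan
}

fixture_datasets <- function() {
  if (is.null(.fx$datasets)) {
    .fx$datasets <- simulate_compendium(fixture_plan())
  }
  .fx$datasets
}

fixture_corpus <- function() {
  if (is.null(.fx$corpus)) .fx$corpus <- build_corpus(fixture_datasets())
  .fx$corpus
}

fixture_embedding <- function() {
  if (is.null(.fx$emb)) {
    .fx$emb <- train_embedding(fixture_corpus(), k = 50L, iterations = 5L,
                               seed = 1L)
  }
  .fx$emb
}

fixture_background <- function() {
  if (is.null(.fx$bg)) {
    .fx$bg <- background_pairs(fixture_embedding(), n = 100L, seed = 1L)
  }
  .fx$bg
}

fixture_pair_split <- function() {
  if (is.null(.fx$split)) {
    pairs <- module_pair_dataset(fixture_plan(), seed = 1L)
    .fx$split <- gene_disjoint_split(pairs, seed = 1L)
  }
  .fx$split
}

# within/between-module inner-product summary for an embedding
module_ip_stats <- function(emb, plan) {
  V <- emb$vectors
  mod <- plan$module[rownames(V)]
  G <- tcrossprod(V)
  same <- outer(mod, mod, `==`)
  same[is.na(same)] <- FALSE
  diffm <- outer(mod, mod, `!=`)
  diffm[is.na(diffm)] <- FALSE
  ut <- upper.tri(G)
  w <- G[same & ut]
  b <- G[diffm & ut]
  list(within_mean = mean(w), between_mean = mean(b),
       between_se = sd(b) / sqrt(length(b)))
}

# independent quantile-normalization oracle: replace each column's sorted
# values by the mean of sorted columns (assumes no ties)
qnorm_oracle <- function(m) {
  target <- rowMeans(apply(m, 2L, sort))
  apply(m, 2L, function(col) target[rank(col)])
}

# closed-form Pearson correlation of two vectors (two-pass)
pcc_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# O(n^2) pairwise-comparison AUC with 1/2 credit for ties
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# toy ontology: root (level 0), chain to level 4, two leaf terms at level 5
# plus one shallow term at level 2; five genes with mixed annotations
toy_annotation <- function() {
  hierarchy <- data.frame(
    parent = c("root", "l1", "l2", "l3", "l4", "l4", "l1"),
    child  = c("l1",  "l2", "l3", "l4", "leafA", "leafB", "shallow"),
    stringsAsFactors = FALSE)
  records <- data.frame(
    gene = c("g1", "g2", "g3", "g3", "g4", "g5", "g1", "g2"),
    term = c("leafA", "leafA", "leafB", "shallow", "leafB", "l3",
             "shallow", "shallow"),
    evidence = c("IDA", "IDA", "IMP", "IDA", "TAS", "IDA", "IEA", "IDA"),
    stringsAsFactors = FALSE)
  annotation_table(records, hierarchy)
}
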