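test_that("term levels derive from minimum root depth and cycles are caught", {
  ann <- toy_annotation()
  expect_equal(unname(ann$levels[c("root", "l1", "shallow", "leafA")]),
               c(0L, 1L, 2L, 5L))
  bad <- data.frame(parent = c("a", "b", "c"), child = c("b", "c", "a"))
  expect_error(
    annotation_table(data.frame(gene = "g", term = "a", evidence = "IDA"),
                     bad, root = "a"),
    "cycle")
})

test_that("positive pairs require a shared deep experimental term", {
  ann <- toy_annotation()
  pos <- positive_pairs(ann, excluded_terms = character(0))
  # g1,g2 share leafA (IDA, level 5): included.
  # g3,g4 share leafB (IMP/TAS, level 5): included.
  # g1,g2,g3 also share 'shallow' but it sits at level 2: never counts
  # (and g1's record for it is IEA anyway). g5 only has a level-3 term.
  expect_equal(pos, data.frame(gene_a = c("g1", "g3"),
                               gene_b = c("g2", "g4"),
                               stringsAsFactors = FALSE))

  # exhaustive oracle over all C(5,2) pairs: shared retained term
  rec <- ann$records
  retained <- rec[rec$evidence %in% c("IDA", "IMP", "IPI", "IGI", "TAS") &
                    ann$levels[rec$term] > 3L, , drop = FALSE]
  by_gene <- split(retained$term, retained$gene)
  genes <- sort(unique(ann$records$gene))
  expected <- t(combn(genes, 2L))
  keep <- apply(expected, 1L, function(gp) {
    length(intersect(by_gene[[gp[1L]]], by_gene[[gp[2L]]])) > 0
  })
  expected <- expected[keep, , drop = FALSE]
  expect_equal(as.matrix(pos), expected, ignore_attr = TRUE)

  # explicit exclusion removes a term entirely
  none <- positive_pairs(ann, excluded_terms = c("leafA", "leafB"))
  expect_equal(nrow(none), 0L)

  # records on a term with no hierarchy level are an error
  orphan <- annotation_table(
    data.frame(gene = c("x", "y"), term = "floating", evidence = "IDA"),
    data.frame(parent = "root", child = "l1"), root = "root")
  expect_error(positive_pairs(orphan), "floating")
})

test_that("negative pairs need disjoint descendant closures", {
  ann <- toy_annotation()
  neg <- negative_pairs(ann)
  # g5 is annotated to l3 whose descendants include leafA and leafB, so g5
  # shares closure with every other gene; g1/g2 share leafA and shallow;
  # g3 shares shallow with g1/g2 and leafB with g4.
  expect_equal(neg, data.frame(gene_a = c("g1", "g2"),
                               gene_b = c("g4", "g4"),
                               stringsAsFactors = FALSE),
               ignore_attr = TRUE)

  # brute-force oracle with explicit transitive closure
  kids <- split(ann$hierarchy$child, ann$hierarchy$parent)
  closure <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier)) {
      nxt <- unique(unlist(kids[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, out)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  gene_cl <- lapply(split(ann$records$term, ann$records$gene), function(ts) {
    unique(unlist(lapply(unique(ts), closure)))
  })
  genes <- sort(names(gene_cl))
  combos <- t(combn(genes, 2L))
  keep <- apply(combos, 1L, function(gp) {
    length(intersect(gene_cl[[gp[1L]]], gene_cl[[gp[2L]]])) == 0L
  })
  expect_equal(as.matrix(neg), combos[keep, , drop = FALSE],
               ignore_attr = TRUE)

  # coverage attribute: percentage of the universe appearing in a pair
  expect_equal(attr(neg, "coverage"), 100 * 3 / 5)
  expect_equal(attr(negative_pairs(ann, universe = sprintf("g%d", 1:10)),
                    "coverage"), 100 * 3 / 10)
})

test_that("positive and negative sets are disjoint by construction", {
  for (ann in list(toy_annotation(),
                   modules_to_annotations(fixture_plan()))) {
    pos <- positive_pairs(ann, excluded_terms = character(0))
    neg <- negative_pairs(ann)
    key <- function(df) paste(df$gene_a, df$gene_b)
    expect_length(intersect(key(pos), key(neg)), 0L)
  }
})

test_that("gene-disjoint splitting partitions genes 7:1:2 and drops spanning pairs", {
  # all pairs of 10 genes: gene split sizes must be exactly 7/1/2 (the
  # 1-gene validation group then retains no pair, which warns)
  genes <- sprintf("g%02d", 1:10)
  all_pairs <- as.data.frame(t(combn(genes, 2L)), stringsAsFactors = FALSE)
  names(all_pairs) <- c("gene_a", "gene_b")
  all_pairs$label <- rep_len(c(0L, 1L), nrow(all_pairs))
  expect_warning(ds <- gene_disjoint_split(all_pairs, seed = 3L),
                 "retained no pairs")
  expect_equal(unname(table(ds$gene_split)[c("train", "val", "test")]),
               c(7L, 1L, 2L), ignore_attr = TRUE)
  # defining property: both endpoints of every retained pair share a split
  sa <- ds$gene_split[ds$pairs$gene_a]
  sb <- ds$gene_split[ds$pairs$gene_b]
  expect_true(all(sa == sb & sa == ds$pairs$split))
  expect_equal(nrow(ds$pairs) + ds$dropped, nrow(all_pairs))
})

test_that("split retention counts match an endpoint-lookup recount", {
  set.seed(17)
  genes <- sprintf("g%03d", 1:100)
  pairs <- unique(data.frame(
    gene_a = sample(genes, 500L, replace = TRUE),
    gene_b = sample(genes, 500L, replace = TRUE),
    stringsAsFactors = FALSE))
  pairs <- pairs[pairs$gene_a != pairs$gene_b, ]
  pairs$label <- rep_len(c(0L, 1L), nrow(pairs))
  ds <- gene_disjoint_split(pairs, seed = 2L)
  recount <- table(factor(
    ifelse(ds$gene_split[pairs$gene_a] == ds$gene_split[pairs$gene_b],
           ds$gene_split[pairs$gene_a], NA),
    levels = c("train", "val", "test")))
  expect_equal(as.vector(ds$counts), as.vector(recount))
})

test_that("balanced datasets downsample negatives to the positive count", {
  pos <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"))
  neg <- data.frame(gene_a = sprintf("x%d", 1:10),
                    gene_b = sprintf("y%d", 1:10))
  ds <- build_pair_dataset(pos, neg, seed = 1L)
  expect_equal(sum(ds$label == 1L), sum(ds$label == 0L))
  expect_equal(nrow(ds), 4L)
  expect_error(build_pair_dataset(neg, pos, seed = 1L), "balance")
})

test_that("AUC equals the pairwise-comparison statistic", {
  expect_equal(auc_score(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # hand case with a tie: pairs (p,n): one win, one tie over 2x1... use 6
  set.seed(31)
  for (rep in 1:5) {
    scores <- round(runif(50), 2L)  # rounding forces ties
    labels <- rbinom(50, 1L, 0.4)
    if (length(unique(labels)) < 2L) next
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(32)
  scores <- runif(80)
  labels <- rbinom(80, 1L, 0.5)
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("frozen training never touches the embedding matrix", {
  ds <- fixture_pair_split()
  cfg <- ggipnn_config(embedding = "random", trainable = FALSE, k = 16L,
                       epochs = 3L, seed = 1L)
  m <- ggipnn_train(ds, config = cfg)
  expect_identical(m$embedding, m$embedding_init)

  cfg_t <- ggipnn_config(embedding = "random", trainable = TRUE, k = 16L,
                         epochs = 3L, patience = Inf, seed = 1L)
  mt <- ggipnn_train(ds, config = cfg_t)
  expect_false(identical(mt$embedding, mt$embedding_init))
})

test_that("classifier training is deterministic and reduces the loss", {
  ds <- fixture_pair_split()
  emb <- fixture_embedding()
  cfg <- ggipnn_config(embedding = "pretrained", epochs = 6L,
                       patience = Inf, seed = 4L)
  m1 <- ggipnn_train(ds, emb, cfg)
  m2 <- ggipnn_train(ds, emb, cfg)
  expect_identical(m1$params, m2$params)
  # separable synthetic pairs: loss over the first five epochs trends down
  loss <- m1$history$train_loss[1:5]
  expect_lt(loss[5L], loss[1L])
  expect_lte(sum(diff(loss) > 0), 1L)
})

test_that("prediction rejects unknown genes and scores the test split", {
  ds <- fixture_pair_split()
  emb <- fixture_embedding()
  cfg <- ggipnn_config(embedding = "pretrained", epochs = 5L, seed = 2L)
  m <- ggipnn_train(ds, emb, cfg)
  expect_error(predict(m, data.frame(gene_a = "nope", gene_b = "G0001")),
               "nope")
  auc <- evaluate_auc(m, ds, split = "test")
  expect_true(auc >= 0 && auc <= 1)
  expect_error(evaluate_auc(m, ds, split = "nosuch"), "empty")
})
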