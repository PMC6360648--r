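# small deterministic corpus used across several blocks: 5 genes, pairs
# replicated across 6 pseudo-datasets so every gene clears min_frequency = 5
toy_corpus <- function(reps = 6L) {
  one <- data.frame(gene_a = c("a", "a", "b", "c"),
                    gene_b = c("b", "c", "d", "e"),
                    stringsAsFactors = FALSE)
  merge_corpora(rep(list(one), reps))
}

test_that("minimum-frequency filtering removes rare genes and their pairs", {
  corp <- toy_corpus(2L)  # frequencies: a=4, b=4, c=4, d=2, e=2
  expect_error(build_vocab(corp, min_frequency = 5L), "min_frequency")
  v <- build_vocab(corp, min_frequency = 4L)
  expect_setequal(v$gene, c("a", "b", "c"))
  expect_true(all(v$frequency >= 4L))
  filt <- filter_corpus(corp, v$gene)
  expect_false(any(c(filt$pairs$gene_a, filt$pairs$gene_b) %in% c("d", "e")))

  freq <- gene_frequencies(toy_corpus(6L))
  expect_equal(unname(freq[c("a", "d")]), c(12L, 6L))
})

test_that("pair probability is a proper softmax over the context slot", {
  # all vectors identical: uniform 1/d
  W <- matrix(1, nrow = 4, ncol = 3, dimnames = list(letters[1:4], NULL))
  emb <- gene_embedding(W)
  for (j in 1:4) expect_equal(pair_probability(emb, 1L, j), 0.25)

  # d = 2 with v1.v1 = 1, v1.v2 = 0: closed form e/(e+1)
  W2 <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), NULL))
  emb2 <- gene_embedding(W2)
  expect_equal(pair_probability(emb2, "g1", "g1"), exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  expect_equal(pair_probability(emb2, "g1", "g2"), 1 / (exp(1) + 1),
               tolerance = 1e-12)

  # normalization over the second argument for random embeddings
  set.seed(8)
  W3 <- matrix(rnorm(18), nrow = 6, dimnames = list(letters[1:6], NULL))
  emb3 <- gene_embedding(W3)
  for (i in c(1L, 4L)) {
    expect_equal(sum(vapply(1:6, function(j) pair_probability(emb3, i, j),
                            0)), 1, tolerance = 1e-12)
  }
})

test_that("corpus loss matches brute-force softmax enumeration", {
  # uniform embedding: loss = N log d
  corp <- toy_corpus()
  W <- matrix(0.3, nrow = 5, ncol = 4,
              dimnames = list(c("a", "b", "c", "d", "e"), NULL))
  emb <- gene_embedding(W)
  expect_equal(corpus_loss(emb, corp), corpus_size(corp) * log(5),
               tolerance = 1e-10)

  # empty corpus: 0
  empty <- merge_corpora(list())
  expect_equal(corpus_loss(emb, empty), 0)

  # random embedding: direct enumeration via pair_probability
  set.seed(21)
  Wr <- matrix(rnorm(20, sd = 0.7), nrow = 5,
               dimnames = list(c("a", "b", "c", "d", "e"), NULL))
  er <- gene_embedding(Wr)
  brute <- 0
  for (r in seq_len(nrow(corp$pairs))) {
    brute <- brute - corp$pairs$multiplicity[r] *
      log(pair_probability(er, corp$pairs$gene_a[r], corp$pairs$gene_b[r]))
  }
  expect_equal(corpus_loss(er, corp), brute, tolerance = 1e-10)

  # additive under corpus concatenation
  half <- corp
  half$pairs$multiplicity <- half$pairs$multiplicity * 2L
  expect_equal(corpus_loss(er, half), 2 * corpus_loss(er, corp),
               tolerance = 1e-10)

  # out-of-vocabulary gene is reported by name
  oov <- merge_corpora(list(data.frame(gene_a = "a", gene_b = "zz")))
  expect_error(corpus_loss(er, oov), "zz")
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(4)
  W <- matrix(rnorm(18, sd = 0.5), nrow = 6,
              dimnames = list(letters[1:6], NULL))
  emb <- gene_embedding(W)
  corp <- merge_corpora(list(
    data.frame(gene_a = c("a", "b", "c", "a"),
               gene_b = c("b", "c", "d", "f")),
    data.frame(gene_a = "a", gene_b = "b")))
  g <- corpus_loss_grad(emb, corp)
  h <- 1e-6
  fd <- W * 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      ep <- emb; ep$vectors[i, j] <- W[i, j] + h
      em <- emb; em$vectors[i, j] <- W[i, j] - h
      fd[i, j] <- (corpus_loss(ep, corp) - corpus_loss(em, corp)) / (2 * h)
    }
  }
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("training is deterministic under a fixed seed", {
  corp <- fixture_corpus()
  e1 <- train_embedding(corp, k = 8L, iterations = 2L, seed = 7L)
  e2 <- train_embedding(corp, k = 8L, iterations = 2L, seed = 7L)
  expect_identical(e1$vectors, e2$vectors)
  e3 <- train_embedding(corp, k = 8L, iterations = 2L, seed = 8L)
  expect_false(identical(e1$vectors, e3$vectors))
  # the input corpus is never mutated by training
  expect_identical(corp, fixture_corpus())
})

test_that("training pulls planted-module genes together", {
  emb <- fixture_embedding()
  st <- module_ip_stats(emb, fixture_plan())
  expect_gt(st$within_mean, st$between_mean + 3 * st$between_se)
  expect_equal(nrow(emb$vectors), 160L)  # background genes fall below min freq
})

test_that("full-softmax loss decreases over exact-mode epochs", {
  corp <- toy_corpus()
  fit <- train_embedding(corp, k = 3L, iterations = 4L, seed = 2L,
                         method = "exact", exact_steps = 10L,
                         checkpoints = TRUE)
  fc <- filter_corpus(corp, rownames(fit$embedding$vectors))
  losses <- vapply(fit$checkpoints, corpus_loss, 0, corpus = fc)
  expect_lt(losses[4L], losses[1L])
})

test_that("exact-mode training reaches the directly minimized loss", {
  corp <- toy_corpus()
  emb <- train_embedding(corp, k = 3L, iterations = 10L, seed = 2L,
                         method = "exact", exact_steps = 40L)
  fc <- filter_corpus(corp, rownames(emb$vectors))
  ours <- corpus_loss(emb, fc)
  # independent oracle: generic quasi-Newton minimization of the black-box
  # loss from multiple random starts
  f <- function(par) {
    e2 <- emb
    e2$vectors[] <- par
    corpus_loss(e2, fc)
  }
  best <- Inf
  for (s in 1:3) {
    set.seed(s)
    o <- optim(rnorm(length(emb$vectors), sd = 0.5), f, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_lt(abs(ours - best) / best, 0.01)
})

test_that("negative-sampling and exact trainers agree on module structure", {
  # both objectives must recover the planted modules: within-module inner
  # products exceed between-module ones by many standard errors under each
  corp <- fixture_corpus()
  plan <- fixture_plan()
  for (method in c("sgns", "exact")) {
    emb <- train_embedding(corp, k = 20L, iterations = 5L, seed = 1L,
                           method = method)
    st <- module_ip_stats(emb, plan)
    expect_gt(st$within_mean, st$between_mean + 3 * st$between_se)
  }
})

test_that("embedding text format round-trips", {
  set.seed(13)
  W <- matrix(rnorm(12), nrow = 4,
              dimnames = list(c("gA", "gB", "gC", "gD"), NULL))
  emb <- gene_embedding(W)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embedding(emb, path)
  expect_equal(readLines(path, n = 1L), "4 3")
  back <- read_embedding(path)
  expect_equal(rownames(back$vectors), rownames(W))
  expect_equal(back$vectors, W, tolerance = 1e-5)  # 6 significant digits
})
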