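#' Plan a planted-module expression compendium
#'
#' Defines the synthetic study conditions used throughout the test suite: a
#' multi-dataset compendium in which groups of genes ("modules") share a
#' per-sample latent factor, so their pairwise Pearson correlation has the
#' closed form \eqn{\rho = s^2 / (s^2 + \sigma^2)} for latent strength `s`
#' and noise standard deviation `sigma`. The defaults — 200 genes in 4
#' modules of 40 (the remaining 40 genes are pure-noise background), 3
#' datasets of 100 samples, `latent_strength = 1`,
#' `noise_sd = 1/sqrt(24)` — give an expected within-module correlation of
#' 0.96, comfortably above the usual 0.9 pair-selection threshold while
#' leaving between-module correlations near zero.
#'
#' @param n_genes Total genes (default 200).
#' @param n_modules Number of co-expression modules (default 4).
#' @param module_sizes Integer vector of module sizes; defaults to equal
#'   modules covering 80% of the genes.
#' @param n_datasets Number of datasets in the compendium (default 3).
#' @param samples_per_dataset Samples per dataset (default 100).
#' @param latent_strength Loading of member genes on the module factor
#'   (default 1; must be positive).
#' @param noise_sd Independent noise standard deviation (default
#'   `1/sqrt(24)`, i.e. expected within-module PCC 0.96).
#' @param seed Master seed; per-dataset streams are derived from it (see
#'   [simulate_compendium()]).
#' @return Object of class `module_plan`.
#' @export
module_plan <- function(n_genes = 200L, n_modules = 4L, module_sizes = NULL,
                        n_datasets = 3L, samples_per_dataset = 100L,
                        latent_strength = 1, noise_sd = 1 / sqrt(24),
                        seed = 1L) {
  if (is.null(module_sizes)) {
    module_sizes <- rep(floor(0.8 * n_genes / n_modules), n_modules)
  }
  stopifnot(length(module_sizes) == n_modules,
            sum(module_sizes) <= n_genes,
            latent_strength > 0, noise_sd >= 0,
            n_datasets >= 1L, samples_per_dataset >= 2L)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  module <- rep(NA_character_, n_genes)
  module[seq_len(sum(module_sizes))] <-
    rep(sprintf("M%d", seq_len(n_modules)), times = module_sizes)
  structure(list(n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 module_sizes = as.integer(module_sizes),
                 n_datasets = as.integer(n_datasets),
                 samples_per_dataset = as.integer(samples_per_dataset),
                 latent_strength = latent_strength,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 gene_ids = gene_ids,
                 module = stats::setNames(module, gene_ids)),
            class = "module_plan")
}

#' @export
print.module_plan <- function(x, ...) {
  cat(sprintf(
    "<module_plan: %d genes, %d modules (%s), %d background; %d dataset(s) x %d samples; expected within-module PCC %.3f>\n",
    x$n_genes, x$n_modules, paste(x$module_sizes, collapse = "+"),
    x$n_genes - sum(x$module_sizes), x$n_datasets, x$samples_per_dataset,
    expected_module_pcc(x)))
  invisible(x)
}

#' Expected within-module Pearson correlation under a plan
#'
#' Closed form for the single-factor module model:
#' `s^2 / (s^2 + sigma^2)`.
#'
#' @param plan A `module_plan`.
#' @return Numeric scalar.
#' @export
expected_module_pcc <- function(plan) {
  s2 <- plan$latent_strength^2
  s2 / (s2 + plan$noise_sd^2)
}

#' Simulate a planted-module expression compendium
#'
#' For each dataset and each module, a latent factor value is drawn per
#' sample from N(0, 1); a member gene's expression is
#' `latent_strength * factor + N(0, noise_sd^2)`. Background genes are pure
#' noise with marginal variance matched to module genes
#' (`latent_strength^2 + noise_sd^2`) so that no variance filter can
#' separate them. Values are on log2-like scale (no further preprocessing
#' needed). Each dataset uses its own RNG stream with seed
#' `plan$seed * 1000 + dataset_index`, so datasets are reproducible
#' individually and jointly.
#'
#' @param plan A `module_plan`.
#' @return List of [expression_dataset] objects (ids `sim1`, `sim2`, ...).
#' @export
simulate_compendium <- function(plan) {
  stopifnot(inherits(plan, "module_plan"))
  lapply(seq_len(plan$n_datasets), function(d) {
    set.seed((plan$seed * 1000L + d) %% .Machine$integer.max)
    ns <- plan$samples_per_dataset
    vals <- matrix(0, nrow = plan$n_genes, ncol = ns,
                   dimnames = list(plan$gene_ids,
                                   sprintf("s%03d", seq_len(ns))))
    factors <- matrix(rnorm(plan$n_modules * ns), plan$n_modules, ns)
    bg_sd <- sqrt(plan$latent_strength^2 + plan$noise_sd^2)
    for (g in seq_len(plan$n_genes)) {
      m <- plan$module[g]
      if (is.na(m)) {
        vals[g, ] <- rnorm(ns, sd = bg_sd)
      } else {
        mi <- match(m, sprintf("M%d", seq_len(plan$n_modules)))
        vals[g, ] <- plan$latent_strength * factors[mi, ] +
          rnorm(ns, sd = plan$noise_sd)
      }
    }
    expression_dataset(sprintf("sim%d", d), vals,
                       min_samples = min(30L, ns))
  })
}

#' Pathways derived from planted modules
#'
#' Each module becomes one pathway containing exactly its member genes, so
#' that on simulated data the clusteredness statistic has a known ground
#' truth (trained embeddings should score > 1, random ones ~1).
#'
#' @param plan A `module_plan`.
#' @return A `pathway_collection`.
#' @export
modules_to_pathways <- function(plan) {
  stopifnot(inherits(plan, "module_plan"))
  mods <- split(names(plan$module)[!is.na(plan$module)],
                plan$module[!is.na(plan$module)])
  pathway_collection(mods, min_size = 2L,
                     max_size = max(plan$module_sizes))
}

#' Annotation table derived from planted modules
#'
#' Builds a miniature ontology: a root term (level 0), a chain of four
#' intermediate terms (levels 1-4), and one leaf term per module at level 5
#' annotated to that module's genes with evidence code IDA. Because every
#' informative term sits at level 5, the shallow-level exclusion filter of
#' [positive_pairs()] never removes them, so positives are exactly the
#' within-module pairs and negatives include all between-module pairs
#' (module leaves have no shared descendants).
#'
#' @param plan A `module_plan` with at least two modules.
#' @return An `annotation_table`.
#' @export
modules_to_annotations <- function(plan) {
  stopifnot(inherits(plan, "module_plan"))
  if (plan$n_modules < 2L) {
    stop("need at least 2 modules to build annotations", call. = FALSE)
  }
  chain <- c("T:ROOT", sprintf("T:LVL%d", 1:4))
  mod_terms <- sprintf("T:MOD%02d", seq_len(plan$n_modules))
  hierarchy <- data.frame(
    parent = c(chain[-5L], rep(chain[5L], plan$n_modules)),
    child = c(chain[-1L], mod_terms),
    stringsAsFactors = FALSE)
  in_mod <- !is.na(plan$module)
  records <- data.frame(
    gene = names(plan$module)[in_mod],
    term = mod_terms[match(plan$module[in_mod],
                           sprintf("M%d", seq_len(plan$n_modules)))],
    evidence = "IDA",
    stringsAsFactors = FALSE)
  annotation_table(records, hierarchy, root = "T:ROOT")
}

#' Write a complete synthetic fixture directory
#'
#' Materializes a plan on disk in the formats the rest of the package
#' reads: one expression TSV per dataset (`exprN.tsv`), module pathways
#' (`pathways.gmt`) and the annotation files (`annotations.tsv`,
#' `hierarchy.tsv`).
#'
#' @param plan A `module_plan`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture_dir <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  datasets <- simulate_compendium(plan)
  paths <- character(0)
  for (i in seq_along(datasets)) {
    p <- file.path(dir, sprintf("expr%d.tsv", i))
    write_expression(datasets[[i]]$values, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "pathways.gmt")
  write_gmt(modules_to_pathways(plan), p)
  paths <- c(paths, p)
  ann <- modules_to_annotations(plan)
  p1 <- file.path(dir, "annotations.tsv")
  write.table(ann$records, p1, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  p2 <- file.path(dir, "hierarchy.tsv")
  write.table(ann$hierarchy, p2, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(paths, p1, p2))
}

#' Balanced labeled pairs from module co-membership
#'
#' Positives are all within-module pairs; negatives are a seeded sample of
#' between-module pairs of equal number. This is the synthetic analogue of
#' the shared-annotation positive / disjoint-annotation negative
#' construction, with module identity as ground truth.
#'
#' @param plan A `module_plan`.
#' @param seed Seed for the negative downsample (defaults to `plan$seed`).
#' @return Data frame `gene_a`, `gene_b`, `label`.
#' @export
module_pair_dataset <- function(plan, seed = plan$seed) {
  stopifnot(inherits(plan, "module_plan"))
  ann <- modules_to_annotations(plan)
  pos <- positive_pairs(ann)
  neg <- negative_pairs(ann)
  build_pair_dataset(pos, neg, seed = seed)
}
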