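#' Per-gene Spearman correlation between predicted and held-out expression
#'
#' For each gene, the Spearman rank correlation between predicted and
#' held-out expression across subjects (ties by average rank).  Genes with
#' zero variance in either vector get `NA` and are counted in the
#' `"n_undefined"` attribute; summaries should exclude them.
#'
#' @param pred,truth numeric matrices, subjects x genes, matching shapes.
#' @return named numeric vector of per-gene correlations with attribute
#'   `n_undefined`.
#' @export
per_gene_spearman <- function(pred, truth) {
  stopifnot(is.matrix(pred), is.matrix(truth), all(dim(pred) == dim(truth)))
  if (nrow(pred) < 3) stop("need >= 3 subjects for per-gene Spearman")
  out <- vapply(seq_len(ncol(pred)), function(g) {
    x <- pred[, g]; y <- truth[, g]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
  names(out) <- colnames(pred)
  attr(out, "n_undefined") <- sum(is.na(out))
  out
}

#' Differential-stability (DS) score
#'
#' For each gene, the average Pearson correlation over all unordered subject
#' pairs, where each correlation compares the two subjects' expression
#' profiles across tissues.  High DS means the gene's tissue patterning is
#' reproducible across individuals.  Pairs where either profile has zero
#' variance are skipped and counted in the `"skipped_pairs"` attribute.
#'
#' @param expr_by_subject list of numeric matrices (tissues x genes), one per
#'   subject, sharing tissue and gene axes.
#' @return named numeric vector of per-gene DS scores with attribute
#'   `skipped_pairs`.
#' @export
ds_score <- function(expr_by_subject) {
  S <- length(expr_by_subject)
  if (S < 2) stop("DS score needs >= 2 subjects")
  d <- dim(expr_by_subject[[1]])
  for (m in expr_by_subject) stopifnot(is.matrix(m), all(dim(m) == d))
  G <- d[2]
  acc <- numeric(G); cnt <- numeric(G); skipped <- 0L
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
    A <- expr_by_subject[[i]]; B <- expr_by_subject[[j]]
    sa <- apply(A, 2, stats::sd); sb <- apply(B, 2, stats::sd)
    ok <- sa > 0 & sb > 0
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      r <- vapply(which(ok), function(g) stats::cor(A[, g], B[, g]), numeric(1))
      acc[ok] <- acc[ok] + r
      cnt[ok] <- cnt[ok] + 1
    }
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  names(out) <- colnames(expr_by_subject[[1]])
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Adjusted Rand index between two gene-module assignments
#'
#' Standard permutation-model ARI computed from the contingency table of the
#' two label vectors.  Convention for the degenerate denominator (both
#' partitions trivial, e.g. one cluster vs one cluster): the partitions are
#' then identical and the ARI is defined as 1.0.
#'
#' @param a,b named vectors (gene id -> module label) over the same gene
#'   universe, or unnamed vectors of equal length in matching order.
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("module assignments cover different gene sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("module assignments cover different gene sets")
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1.0)
  (sum_ij - expected) / denom
}

#' Permutation p-value for an ARI
#'
#' Shuffles `a`'s labels over genes `n_perm` times and recomputes the ARI
#' against `b`; the p-value uses the add-one estimator
#' `p = (1 + #\{perm ARI >= observed\}) / (1 + n_perm)`, so it is never zero
#' (an observed ARI exceeding all permutations reports `1/(n_perm + 1)`).
#'
#' @inheritParams ari
#' @param n_perm number of label permutations (>= 1).
#' @param seed RNG seed.
#' @return list with `ari` (observed) and `p`.
#' @export
ari_permutation_p <- function(a, b, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  obs <- ari(a, b)
  set.seed(as.integer(seed))
  hits <- 0L
  av <- unname(a)
  for (k in seq_len(n_perm)) {
    if (ari(sample(av), b) >= obs) hits <- hits + 1L
  }
  list(ari = obs, p = (1 + hits) / (1 + n_perm))
}

#' Convenience gene clustering for evaluation inputs
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - |Pearson correlation|` between genes, cut to a fixed number of
#' modules.  This is only a utility for producing test partitions; it is NOT
#' the weighted co-expression (WGCNA) procedure used in atlas analyses, which
#' is out of scope here.
#'
#' @param expr numeric matrix, samples x genes.
#' @param k number of modules.
#' @return named integer vector (gene -> module label).
#' @export
cluster_genes <- function(expr, k) {
  stopifnot(is.matrix(expr), k >= 1)
  d <- stats::as.dist(1 - abs(stats::cor(expr)))
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Read / write gene-module partitions (two-column TSV)
#' @param path TSV with columns `gene_id`, `module_label`.
#' @return named vector (gene id -> label).
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$module_label, df$gene_id)
}

#' @rdname read_partition
#' @param part named vector (gene id -> label).
#' @export
write_partition <- function(part, path) {
  utils::write.table(data.frame(gene_id = names(part),
                                module_label = unname(part)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
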