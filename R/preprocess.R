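#' Average microarray probes mapping to the same gene
#'
#' Each gene's row is the arithmetic mean of the rows of its probes.  Genes
#' are ordered by first occurrence among the probes.
#'
#' @param probe_values numeric matrix, probes x samples, rownames = probe ids.
#' @param probe_to_gene named character vector (or list) mapping every probe id
#'   to exactly one gene id.
#' @return numeric matrix, genes x samples.
#' @export
average_probes <- function(probe_values, probe_to_gene) {
  stopifnot(is.matrix(probe_values))
  probes <- rownames(probe_values)
  if (is.null(probes)) stop("probe_values must have probe ids as rownames")
  map <- unlist(probe_to_gene)
  unmapped <- setdiff(probes, names(map))
  if (length(unmapped)) {
    stop("unmapped probe(s): ", paste(unmapped, collapse = ", "))
  }
  genes <- unique(unname(map[probes]))
  grp <- factor(unname(map[probes]), levels = genes)
  out <- rowsum(probe_values, grp, reorder = FALSE) / as.vector(table(grp))
  rownames(out) <- genes
  out
}

#' Quantile-normalize an expression tensor per gene
#'
#' For each gene, the multiset of its observed values over the flattened
#' (subject, tissue) axis is replaced by rank-assigned values from a common
#' reference distribution: the mean of order statistics pooled across genes.
#' Ties receive the average of the tied reference values.  When genes have
#' unequal observed counts (whole tissues missing for some subjects), each
#' gene's reference values are obtained by linear interpolation of the pooled
#' reference quantile function at its own rank probabilities.  Missing entries
#' are untouched.  Genes with zero variance still normalize (all entries map
#' to the mean reference value via tie-averaging); all-missing genes are
#' skipped with a warning.
#'
#' @param x an [expr_tensor].
#' @return an [expr_tensor] of the same shape.
#' @export
quantile_normalize_per_gene <- function(x) {
  stopifnot(inherits(x, "expr_tensor"))
  G <- length(x$gene_ids)
  mask <- x$observed
  # per-gene observed vectors over the flattened (subject, tissue) axis
  flat <- lapply(seq_len(G), function(g) {
    v <- x$values[, , g]
    v[mask]
  })
  n_obs <- lengths(flat)
  skip <- n_obs == 0L
  if (any(skip)) {
    warning(sum(skip), " gene(s) with no observed values skipped during quantile normalization")
  }
  use <- which(!skip)
  if (!length(use)) return(x)
  if (any(n_obs[use] < 2L)) {
    stop("quantile normalization requires >=2 observed entries per gene")
  }
  nmax <- max(n_obs[use])
  pgrid <- seq(0, 1, length.out = nmax)
  # pooled reference: mean of order statistics, interpolated to a common grid
  ref <- rowMeans(vapply(use, function(g) {
    s <- sort(flat[[g]])
    if (length(s) == nmax) s else stats::approx(seq(0, 1, length.out = length(s)), s,
                                                xout = pgrid)$y
  }, numeric(nmax)))

  out <- x$values
  for (g in use) {
    v <- flat[[g]]
    n <- length(v)
    refg <- if (n == nmax) ref else stats::approx(pgrid, ref, xout = seq(0, 1, length.out = n))$y
    assigned <- numeric(n)
    assigned[order(v)] <- refg
    # ties receive the average of the reference values at the tied ranks
    newv <- stats::ave(assigned, v, FUN = mean)
    slice <- out[, , g]
    slice[mask] <- newv
    out[, , g] <- slice
  }
  expr_tensor(out, x$observed, x$subject_ids, x$tissue_ids, x$gene_ids)
}

#' Intersect two gene id lists
#'
#' Returns the intersection ordered by the first list.
#'
#' @param ids_a,ids_b character vectors.
#' @return character vector.
#' @export
intersect_genes <- function(ids_a, ids_b) {
  ids_a[ids_a %in% ids_b]
}
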