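#' Approximate-Bayes-factor colocalization
#'
#' Compares five hypotheses about a genomic region given two sets of summary
#' statistics: H0 no association with either trait; H1/H2 association with
#' one trait only; H3 two distinct causal variants; H4 one shared causal
#' variant.  Per-variant evidence uses the Wakefield approximate Bayes
#' factor computed from (beta, se) with prior effect standard deviation
#' `W = 0.15` for quantitative traits and `W = 0.2` for binary traits.
#' Posterior probabilities are returned for two prior configurations: the
#' default `p1 = p2 = 1e-4, p12 = 1e-5`, and a per-region configuration
#' `p1 = p2 = 1/n_variants, p12 = p1/10`.  A region is called colocalized
#' when either configuration gives `PP4 > pp4_threshold` (default 0.7).
#'
#' @param region1,region2 data.frames with columns `variant_id`, `beta`,
#'   `se` for the two traits; the variant intersection is analysed and must
#'   be non-empty.
#' @param trait_types character 2-vector, each `"quantitative"` or
#'   `"binary"`.
#' @param priors optional override, list(p1, p2, p12), replacing the default
#'   configuration (the per-region configuration is always also computed).
#' @param pp4_threshold PP4 threshold for the colocalized call.
#' @return object of class `coloc_result`: list with `n_variants`, per
#'   configuration the priors and `PP0`..`PP4`, and `colocalized`.
#' @export
coloc_abf <- function(region1, region2,
                      trait_types = c("quantitative", "quantitative"),
                      priors = NULL, pp4_threshold = 0.7) {
  for (r in list(region1, region2)) {
    if (!all(c("variant_id", "beta", "se") %in% names(r))) {
      stop("regions need columns variant_id, beta, se")
    }
    if (any(r$se <= 0)) stop("all standard errors must be positive")
  }
  shared <- intersect(region1$variant_id, region2$variant_id)
  if (!length(shared)) stop("regions share no variants")
  i1 <- match(shared, region1$variant_id)
  i2 <- match(shared, region2$variant_id)
  W <- vapply(trait_types, function(tt) {
    switch(match.arg(tt, c("quantitative", "binary")),
           quantitative = 0.15, binary = 0.2)
  }, numeric(1))
  labf <- function(beta, se, w) {
    r <- w^2 / (w^2 + se^2)
    0.5 * (log(1 - r) + r * (beta / se)^2)
  }
  l1 <- labf(region1$beta[i1], region1$se[i1], W[1])
  l2 <- labf(region2$beta[i2], region2$se[i2], W[2])
  n <- length(shared)

  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  # log(sum_{j != k} exp(l1_j + l2_k)) = logdiff(sum_j l1 + sum_k l2, sum_j l1+l2)
  s1 <- lse(l1); s2 <- lse(l2); s12 <- lse(l1 + l2)
  ldiff <- s1 + s2 + log1p(-exp(pmin(s12 - s1 - s2, 0)))
  if (n == 1) ldiff <- -Inf

  eval_config <- function(p1, p2, p12) {
    lh <- c(H0 = 0,
            H1 = log(p1) + s1,
            H2 = log(p2) + s2,
            H3 = if (is.finite(ldiff)) log(p1) + log(p2) + ldiff else -Inf,
            H4 = log(p12) + s12)
    pp <- exp(lh - lse(lh[is.finite(lh)]))
    pp[!is.finite(lh)] <- 0
    names(pp) <- paste0("PP", 0:4)
    list(priors = list(p1 = p1, p2 = p2, p12 = p12), pp = pp)
  }
  default <- if (is.null(priors)) list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) else priors
  cfg1 <- eval_config(default$p1, default$p2, default$p12)
  cfg2 <- eval_config(1 / n, 1 / n, 1 / (10 * n))
  pp4 <- max(cfg1$pp["PP4"], cfg2$pp["PP4"])
  structure(list(n_variants = n, default = cfg1, per_region = cfg2,
                 colocalized = pp4 > pp4_threshold,
                 pp4_max = unname(pp4)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc_result over", x$n_variants, "shared variants\n")
  cat("  default priors    PP0..PP4:",
      paste(sprintf("%.3f", x$default$pp), collapse = " "), "\n")
  cat("  per-region priors PP0..PP4:",
      paste(sprintf("%.3f", x$per_region$pp), collapse = " "), "\n")
  cat("  colocalized:", x$colocalized, "(max PP4 =", sprintf("%.3f", x$pp4_max), ")\n")
  invisible(x)
}

#' Region extraction around a primary variant
#'
#' Returns the rows of a summary-statistics table whose variants fall within
#' `region_bp` (total width, centered on the primary variant's position).
#'
#' @param stats data.frame with `variant_id`; positions looked up in `geno`.
#' @param geno a [genotype_matrix].
#' @param primary_variant variant id at the region center.
#' @param region_bp total window width (default 1e5, i.e. 100 kb).
#' @return subset of `stats`.
#' @export
coloc_region <- function(stats, geno, primary_variant, region_bp = 1e5) {
  vi <- match(primary_variant, geno$variants$variant_id)
  if (is.na(vi)) stop("unknown primary variant '", primary_variant, "'")
  pos0 <- geno$variants$pos[vi]
  chr0 <- geno$variants$chr[vi]
  idx <- match(stats$variant_id, geno$variants$variant_id)
  keep <- !is.na(idx) & geno$variants$chr[idx] == chr0 &
    abs(geno$variants$pos[idx] - pos0) <= region_bp / 2
  stats[keep, , drop = FALSE]
}
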