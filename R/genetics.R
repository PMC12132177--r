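#' Genotype dosage matrix
#'
#' @param dosages numeric matrix, subjects x variants, values in `[0, 2]`.
#' @param variants data.frame with columns `variant_id`, `chr`, `pos`
#'   (1-based), `effect_allele`, `other_allele`; one row per variant, in
#'   column order of `dosages`.
#' @param subject_ids subject labels.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, subject_ids = rownames(dosages)) {
  stopifnot(is.matrix(dosages), is.data.frame(variants),
            nrow(variants) == ncol(dosages))
  need <- c("variant_id", "chr", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(variants))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant id(s)")
  if (any(variants$pos < 0)) stop("variant positions must be nonnegative")
  if (!all(is.finite(dosages)) || any(dosages < 0 | dosages > 2)) {
    stop("dosages must be finite values in [0, 2]")
  }
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(subject_ids, variants$variant_id)
  structure(list(dosages = dosages, variants = variants,
                 subject_ids = as.character(subject_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "subjects x", ncol(x$dosages),
      "variants\n")
  invisible(x)
}

#' Read / write genotype dosages (TSV pair)
#'
#' `path` holds the dosage matrix (first column `subject_id`, then one column
#' per variant); `paste0(path, ".variants.tsv")` holds the variant metadata.
#'
#' @param x a [genotype_matrix]; `path` a file path.
#' @export
write_genotypes <- function(x, path) {
  df <- data.frame(subject_id = x$subject_ids, x$dosages, check.names = FALSE)
  write_tsv_full(df, path)
  write_tsv_full(x$variants, paste0(path, ".variants.tsv"))
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  variants <- utils::read.delim(paste0(path, ".variants.tsv"),
                                stringsAsFactors = FALSE)
  genotype_matrix(as.matrix(df[, -1, drop = FALSE]), variants, df$subject_id)
}

#' cis-eQTL scan with permutation gene-level p-values
#'
#' For each gene, every variant within `window_bp` of the gene position (same
#' chromosome, 1-based inclusive window) is tested with an additive ordinary
#' least squares model of expression on dosage, giving the effect `beta`, its
#' standard error and a t-test nominal p-value.  The gene-level p-value comes
#' from a permutation scheme: expression is shuffled `n_perm` times and
#' `p_gene = (1 + #\{permuted min p <= observed min p\}) / (1 + n_perm)`.
#' Monomorphic variants are skipped (counted in attribute `n_monomorphic`).
#'
#' @param geno a [genotype_matrix].
#' @param expr numeric matrix, subjects x genes (rownames matching the
#'   genotype subjects).
#' @param gene_positions data.frame with columns `gene_id`, `chr`, `pos`.
#' @param window_bp cis-window half-width in base pairs.
#' @param n_perm permutations per gene (0 skips the permutation pass).
#' @param seed RNG seed.
#' @param tissue_id optional tissue label stamped on the records.
#' @return data.frame with columns `variant_id`, `gene_id`, `tissue_id`,
#'   `beta`, `se`, `p_nominal`, `p_gene`, `n`.
#' @export
cis_eqtl_scan <- function(geno, expr, gene_positions, window_bp = 1e6,
                          n_perm = 1000, seed = 1, tissue_id = NA_character_) {
  stopifnot(inherits(geno, "genotype_matrix"), is.matrix(expr))
  n <- nrow(expr)
  if (n < 10) stop("cis-eQTL scan needs >= 10 subjects")
  if (nrow(geno$dosages) != n) stop("genotype and expression subject counts differ")
  set.seed(as.integer(seed))
  D <- geno$dosages
  sd_d <- apply(D, 2, stats::sd)
  mono <- sd_d == 0
  Dc <- sweep(D, 2, colMeans(D))
  ss_d <- colSums(Dc^2)

  res <- vector("list", ncol(expr))
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(expr)))
  for (gidx in seq_along(genes)) {
    gp <- gene_positions[gene_positions$gene_id == genes[gidx], , drop = FALSE]
    if (!nrow(gp)) next
    cis <- which(geno$variants$chr == gp$chr[1] &
                 abs(geno$variants$pos - gp$pos[1]) <= window_bp & !mono)
    if (!length(cis)) next
    y <- expr[, gidx]
    yc <- y - mean(y)
    ss_y <- sum(yc^2)
    if (ss_y == 0) next
    sxy <- as.vector(crossprod(Dc[, cis, drop = FALSE], yc))
    beta <- sxy / ss_d[cis]
    rss <- ss_y - beta * sxy
    rss[rss < 0] <- 0
    se <- sqrt(rss / (n - 2) / ss_d[cis])
    tstat <- beta / se
    p_nom <- 2 * stats::pt(-abs(tstat), df = n - 2)
    # min-p permutation: same n everywhere, so min p <=> max |r|
    p_gene <- NA_real_
    if (n_perm > 0) {
      r_obs <- sxy / sqrt(ss_d[cis] * ss_y)
      max_r_obs <- max(abs(r_obs))
      hits <- 0L
      for (k in seq_len(n_perm)) {
        yp <- yc[sample.int(n)]
        rp <- abs(as.vector(crossprod(Dc[, cis, drop = FALSE], yp))) /
          sqrt(ss_d[cis] * ss_y)
        if (max(rp) >= max_r_obs) hits <- hits + 1L
      }
      p_gene <- (1 + hits) / (1 + n_perm)
    }
    res[[gidx]] <- data.frame(
      variant_id = geno$variants$variant_id[cis], gene_id = genes[gidx],
      tissue_id = tissue_id, beta = beta, se = se, p_nominal = p_nom,
      p_gene = p_gene, n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), gene_id = character(),
                      tissue_id = character(), beta = numeric(), se = numeric(),
                      p_nominal = numeric(), p_gene = numeric(), n = integer())
  }
  rownames(out) <- NULL
  attr(out, "n_monomorphic") <- sum(mono)
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest p-value as a lead
#' (ties broken by variant id), then removes every unclaimed variant within
#' `window_bp` of it whose squared Pearson dosage correlation with the lead
#' exceeds `r2_max`.
#'
#' @param records data.frame with columns `variant_id` and `p` (any
#'   association table).
#' @param geno a [genotype_matrix] supplying dosages and positions.
#' @param window_bp clumping window half-width.
#' @param r2_max r-squared cutoff above which a variant is claimed by a lead.
#' @return character vector of lead variant ids, in selection order.
#' @export
ld_clump <- function(records, geno, window_bp = 1e7, r2_max = 0.001) {
  stopifnot(all(c("variant_id", "p") %in% names(records)))
  idx <- match(records$variant_id, geno$variants$variant_id)
  if (anyNA(idx)) stop("record variant(s) missing from genotype matrix")
  ord <- order(records$p, records$variant_id)
  pos <- geno$variants$pos[idx]
  chr <- geno$variants$chr[idx]
  claimed <- rep(FALSE, nrow(records))
  leads <- character(0)
  for (k in ord) {
    if (claimed[k]) next
    leads <- c(leads, records$variant_id[k])
    claimed[k] <- TRUE
    near <- which(!claimed & chr == chr[k] & abs(pos - pos[k]) <= window_bp)
    if (length(near)) {
      r <- suppressWarnings(stats::cor(geno$dosages[, idx[k]],
                                       geno$dosages[, idx[near], drop = FALSE]))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 0
      claimed[near[r2 > r2_max]] <- TRUE
    }
  }
  leads
}

#' Cross-tissue eQTL sharing by sign
#'
#' Counts the tissues whose effect has the same sign as the reference tissue
#' (the tissue with the largest absolute effect).  Zero effects count as not
#' shared; an all-zero vector returns `NA`.
#'
#' @param effects named numeric vector of per-tissue effects for one lead
#'   eQTL.
#' @return integer count (including the reference tissue).
#' @export
sharing_by_sign <- function(effects) {
  effects <- effects[is.finite(effects)]
  if (!length(effects)) stop("need at least one finite effect")
  if (all(effects == 0)) return(NA_integer_)
  ref <- effects[which.max(abs(effects))]
  sum(sign(effects) == sign(ref) & effects != 0)
}

#' Cross-tissue eQTL sharing by magnitude
#'
#' Counts the tissues with the same sign as the reference tissue (largest
#' absolute effect) whose magnitude is within a factor of two of the
#' reference, i.e. `|beta|` in `[|ref|/2, 2|ref|]`.  The reference is
#' included.
#'
#' @inheritParams sharing_by_sign
#' @return integer count.
#' @export
sharing_by_magnitude <- function(effects) {
  effects <- effects[is.finite(effects)]
  if (!length(effects)) stop("need at least one finite effect")
  if (all(effects == 0)) return(NA_integer_)
  ref <- effects[which.max(abs(effects))]
  same_sign <- sign(effects) == sign(ref) & effects != 0
  in_band <- abs(effects) >= abs(ref) / 2 & abs(effects) <= 2 * abs(ref)
  sum(same_sign & in_band)
}

#' Pairwise tissue-by-tissue sharing matrix
#'
#' Entry (i, j) is the fraction of lead eQTLs whose effects in tissues i and
#' j share sign and differ by no more than a factor of two in magnitude.
#' The diagonal is 1; pairs with no jointly finite effects are `NA`.
#'
#' @param effect_table numeric matrix, lead eQTLs x tissues.
#' @return tissue x tissue numeric matrix.
#' @export
pairwise_sharing_matrix <- function(effect_table) {
  stopifnot(is.matrix(effect_table))
  Tn <- ncol(effect_table)
  out <- matrix(NA_real_, Tn, Tn,
                dimnames = list(colnames(effect_table), colnames(effect_table)))
  for (i in seq_len(Tn)) {
    out[i, i] <- 1
    for (j in seq_len(Tn)) {
      if (j <= i) next
      bi <- effect_table[, i]; bj <- effect_table[, j]
      ok <- is.finite(bi) & is.finite(bj) & bi != 0 & bj != 0
      if (!any(ok)) next
      ratio <- abs(bi[ok]) / abs(bj[ok])
      shared <- sign(bi[ok]) == sign(bj[ok]) & ratio >= 0.5 & ratio <= 2
      out[i, j] <- out[j, i] <- mean(shared)
    }
  }
  out
}

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns the outcome record's effect orientation to the exposure's: if the
#' outcome's effect allele equals the exposure's other allele (and vice
#' versa), the outcome beta is negated.  No strand flipping is attempted
#' (forward-strand semantics); palindromic allele pairs (A/T, C/G) are passed
#' through with a warning; incompatible allele sets are dropped with a
#' reason.
#'
#' @param exposure,outcome single-row data.frames (or lists) each carrying
#'   `effect_allele`, `other_allele` and `beta`.
#' @return list with `exposure`, `outcome` (aligned, or `NULL` if dropped),
#'   `dropped` (logical) and `reason`.
#' @export
harmonize <- function(exposure, outcome) {
  ea_x <- toupper(exposure$effect_allele); oa_x <- toupper(exposure$other_allele)
  ea_y <- toupper(outcome$effect_allele); oa_y <- toupper(outcome$other_allele)
  palindromic <- function(a, b) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    identical(unname(comp[a]), b)
  }
  if (ea_x == ea_y && oa_x == oa_y) {
    if (palindromic(ea_x, oa_x)) {
      warning("palindromic allele pair ", ea_x, "/", oa_x, " passed through unflipped")
    }
    return(list(exposure = exposure, outcome = outcome, dropped = FALSE,
                reason = NA_character_))
  }
  if (ea_x == oa_y && oa_x == ea_y) {
    outcome$beta <- -outcome$beta
    tmp <- outcome$effect_allele
    outcome$effect_allele <- outcome$other_allele
    outcome$other_allele <- tmp
    if (palindromic(ea_x, oa_x)) {
      warning("palindromic allele pair ", ea_x, "/", oa_x, " passed through unflipped")
    }
    return(list(exposure = exposure, outcome = outcome, dropped = FALSE,
                reason = NA_character_))
  }
  list(exposure = exposure, outcome = NULL, dropped = TRUE,
       reason = paste0("incompatible alleles ", ea_x, "/", oa_x, " vs ",
                       ea_y, "/", oa_y))
}

#' Wald-ratio Mendelian randomization for a single instrument
#'
#' `wald_beta = outcome beta / exposure beta`; the standard error uses the
#' first-order delta method (`|outcome se / exposure beta|`, exposure
#' uncertainty ignored) and the p-value the normal approximation.
#'
#' @param exposure list/row with `beta` (nonzero), and optionally
#'   `variant_id`, `gene_id`, `tissue_id`.
#' @param outcome list/row with `beta`, `se`, and optionally `trait_id`.
#' @return data.frame row with `wald_beta`, `wald_se`, `p` plus identifiers.
#' @export
wald_ratio_mr <- function(exposure, outcome) {
  if (is.null(exposure$beta) || exposure$beta == 0) {
    stop("exposure beta must be nonzero for the Wald ratio")
  }
  wb <- outcome$beta / exposure$beta
  ws <- abs(outcome$se / exposure$beta)
  z <- wb / ws
  grab <- function(x, f) if (is.null(x[[f]])) NA_character_ else as.character(x[[f]])
  data.frame(variant_id = grab(exposure, "variant_id"),
             gene_id = grab(exposure, "gene_id"),
             tissue_id = grab(exposure, "tissue_id"),
             trait_id = grab(outcome, "trait_id"),
             wald_beta = wb, wald_se = ws,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' applied once across the full supplied test family.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length/order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Upper-tail hypergeometric gene-set overlap test
#'
#' `P(X >= overlap)` for the overlap of two gene sets of sizes `set_a` and
#' `set_b` drawn from a universe of `n_universe` genes; computed by exact
#' log-space summation of the hypergeometric probability mass.
#'
#' @param n_universe universe size N.
#' @param set_a,set_b set sizes.
#' @param overlap observed overlap.
#' @return p-value.
#' @export
hypergeom_overlap_test <- function(n_universe, set_a, set_b, overlap) {
  ok <- overlap >= 0 && set_a >= overlap && set_b >= overlap &&
    n_universe >= max(set_a, set_b) && set_a >= 0 && set_b >= 0
  if (!ok) stop("require 0 <= overlap <= min(set_a, set_b) <= N")
  if (overlap == 0) return(1.0)
  k <- seq(overlap, min(set_a, set_b))
  lp <- stats::dhyper(k, set_b, n_universe - set_b, set_a, log = TRUE)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' One-sided enrichment test on a 2x2 table
#'
#' Fisher's exact test (alternative "greater") with the sample odds ratio
#' `(n11 n22)/(n12 n21)` (infinite when a denominator cell is zero and the
#' numerator is positive).
#'
#' @param counts 2x2 nonnegative integer matrix; row 1/col 1 is the
#'   (trait, region) cell of interest.
#' @return list with `odds_ratio` and `p`.
#' @export
trait_region_enrichment <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(2, 2)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  p <- stats::fisher.test(counts, alternative = "greater")$p.value
  list(odds_ratio = or, p = p)
}
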