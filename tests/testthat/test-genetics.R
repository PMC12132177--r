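toy_geno <- function(dosages, pos = NULL, chr = "1") {
  n_var <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(n_var) * 1000
  genotype_matrix(dosages, data.frame(
    variant_id = sprintf("v%02d", seq_len(n_var)), chr = chr, pos = pos,
    effect_allele = "A", other_allele = "G", stringsAsFactors = FALSE))
}

test_that("the cis-eQTL scan matches a normal-equations oracle", {
  # printed toy dosage/expression pair (duplicated to meet the sample floor)
  d <- rep(c(0, 1, 2, 0, 1, 2), 2)
  y <- rep(c(0.1, 1.1, 2.0, -0.1, 0.9, 2.1), 2)
  geno <- toy_geno(cbind(d))
  expr <- matrix(y, ncol = 1, dimnames = list(NULL, "g1"))
  gp <- data.frame(gene_id = "g1", chr = "1", pos = 1000)
  rec <- cis_eqtl_scan(geno, expr, gp, window_bp = 1e4, n_perm = 0)
  X <- cbind(1, d)
  bhat <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% bhat
  se <- sqrt(sum(resid^2) / (12 - 2) * solve(crossprod(X))[2, 2])
  expect_equal(rec$beta, bhat[2], tolerance = 1e-10)
  expect_equal(rec$se, se, tolerance = 1e-10)

  # expression exactly equal to dosage
  set.seed(8)
  d20 <- rbinom(20, 2, 0.4)
  geno20 <- toy_geno(cbind(d20))
  rec20 <- cis_eqtl_scan(geno20, matrix(d20, ncol = 1,
                                        dimnames = list(NULL, "g1")),
                         gp, window_bp = 1e4, n_perm = 0)
  expect_equal(rec20$beta, 1.0, tolerance = 1e-12)
  expect_lt(rec20$p_nominal, 1e-6)

  # monomorphic variants skipped and counted; sample floor enforced
  geno_mono <- toy_geno(cbind(d20, rep(2, 20)))
  recm <- cis_eqtl_scan(geno_mono, matrix(d20, ncol = 1,
                                          dimnames = list(NULL, "g1")),
                        gp, window_bp = 1e4, n_perm = 0)
  expect_identical(attr(recm, "n_monomorphic"), 1L)
  expect_equal(nrow(recm), 1L)
  expect_error(cis_eqtl_scan(toy_geno(cbind(d20[1:5])),
                             matrix(d20[1:5], ncol = 1), gp), ">= 10")
})

test_that("LD clumping is greedy by p-value within window and r-squared", {
  set.seed(6)
  v1 <- rbinom(50, 2, 0.3)
  geno <- toy_geno(cbind(v1, v1, rbinom(50, 2, 0.3)),
                   pos = c(1000, 2000, 1e8))   # third variant out of window
  recs <- data.frame(variant_id = c("v01", "v02", "v03"),
                     p = c(1e-4, 1e-8, 1e-3))
  leads <- ld_clump(recs, geno, window_bp = 1e7, r2_max = 0.001)
  # v02 wins its perfectly correlated pair (smaller p); distant v03 stays
  expect_setequal(leads, c("v02", "v03"))
  # mutually uncorrelated variants (orthogonal contrasts) are all leads
  H <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1,
                1, -1, 1, -1, 1, -1, 1, -1,
                1, 1, -1, -1, 1, 1, -1, -1,
                1, -1, -1, 1, 1, -1, -1, 1), 8, 4)
  geno_ind <- toy_geno((H[, 2:4] + 1))
  recs_ind <- data.frame(variant_id = sprintf("v%02d", 1:3), p = runif(3))
  expect_length(ld_clump(recs_ind, geno_ind, 1e7, 0.001), 3L)

  # 5-variant toy against a brute-force greedy trace
  set.seed(13)
  base <- rbinom(80, 2, 0.4)
  D <- cbind(base, base, 2 - base, rbinom(80, 2, 0.4), rbinom(80, 2, 0.4))
  geno5 <- toy_geno(D)
  recs5 <- data.frame(variant_id = sprintf("v%02d", 1:5),
                      p = c(0.02, 0.001, 0.03, 0.005, 0.04))
  oracle <- local({
    claimed <- rep(FALSE, 5); leads <- character(0)
    repeat {
      open <- which(!claimed)
      if (!length(open)) break
      k <- open[order(recs5$p[open])][1]
      leads <- c(leads, recs5$variant_id[k]); claimed[k] <- TRUE
      for (j in which(!claimed)) {
        if (stats::cor(D[, k], D[, j])^2 > 0.001) claimed[j] <- TRUE
      }
    }
    leads
  })
  expect_identical(ld_clump(recs5, geno5, 1e7, 0.001), oracle)
})

test_that("sharing counts use the largest-effect reference tissue", {
  expect_identical(sharing_by_sign(c(2.0, 1.2, 0.9, -0.5)), 3L)
  expect_identical(sharing_by_magnitude(c(2.0, 1.2, 0.9, -0.5)), 2L)
  expect_identical(sharing_by_sign(c(0.3, 0.1, 2.2)), 3L)
  expect_identical(sharing_by_magnitude(rep(0.7, 6)), 6L)
  expect_true(is.na(sharing_by_sign(c(0, 0))))
  expect_error(sharing_by_sign(numeric(0)), "finite effect")

  # brute-force oracles on random vectors
  set.seed(10)
  for (rep in 1:10) {
    v <- round(stats::rnorm(10), 2)
    v[v == 0] <- 0.01
    ref <- v[which.max(abs(v))]
    expect_identical(sharing_by_sign(v), sum(sign(v) == sign(ref)))
    expect_identical(sharing_by_magnitude(v),
                     sum(sign(v) == sign(ref) &
                         abs(v) >= abs(ref) / 2 & abs(v) <= 2 * abs(ref)))
  }
})

test_that("pairwise sharing matrix matches the double-loop oracle", {
  set.seed(20)
  E <- matrix(stats::rnorm(40), 10, 4, dimnames = list(NULL, paste0("t", 1:4)))
  M <- pairwise_sharing_matrix(E)
  expect_equal(unname(diag(M)), rep(1, 4))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    shared <- mean(sapply(1:10, function(r) {
      bi <- E[r, i]; bj <- E[r, j]
      sign(bi) == sign(bj) && abs(bi) / abs(bj) >= 0.5 && abs(bi) / abs(bj) <= 2
    }))
    expect_equal(M[i, j], shared)
  }
  expect_equal(unname(pairwise_sharing_matrix(cbind(E[, 1], E[, 1]))[1, 2]), 1)
  expect_equal(unname(pairwise_sharing_matrix(cbind(E[, 1], -E[, 1]))[1, 2]), 0)
})

test_that("the Wald ratio and its delta-method error behave as arithmetic", {
  r <- wald_ratio_mr(list(beta = 0.5), list(beta = 0.2, se = 0.05))
  expect_equal(r$wald_beta, 0.4)
  expect_equal(r$wald_se, 0.1)
  r1 <- wald_ratio_mr(list(beta = 1), list(beta = -0.13, se = 0.02))
  expect_equal(r1$wald_beta, -0.13)
  expect_equal(r1$wald_se, 0.02)
  rpos <- wald_ratio_mr(list(beta = 0.4), list(beta = 0.2, se = 0.05))
  rneg <- wald_ratio_mr(list(beta = -0.4), list(beta = 0.2, se = 0.05))
  expect_equal(rneg$wald_beta, -rpos$wald_beta)
  expect_equal(rneg$wald_se, rpos$wald_se)
  expect_equal(rneg$p, rpos$p)
  expect_error(wald_ratio_mr(list(beta = 0), list(beta = 1, se = 1)),
               "nonzero")
})

test_that("allele harmonization follows forward-strand semantics", {
  ex <- list(effect_allele = "A", other_allele = "G", beta = 0.5)
  same <- harmonize(ex, list(effect_allele = "A", other_allele = "G",
                             beta = 0.2, se = 0.1))
  expect_false(same$dropped)
  expect_equal(same$outcome$beta, 0.2)

  flipped <- harmonize(ex, list(effect_allele = "G", other_allele = "A",
                                beta = 0.2, se = 0.1))
  expect_false(flipped$dropped)
  expect_equal(flipped$outcome$beta, -0.2)
  expect_equal(flipped$outcome$effect_allele, "A")

  dropped <- harmonize(ex, list(effect_allele = "C", other_allele = "T",
                                beta = 0.2, se = 0.1))
  expect_true(dropped$dropped)
  expect_match(dropped$reason, "incompatible")

  pal <- list(effect_allele = "A", other_allele = "T", beta = 0.3)
  expect_warning(harmonize(pal, list(effect_allele = "A", other_allele = "T",
                                     beta = 0.1, se = 0.1)), "palindromic")
})

test_that("FDR adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("the overlap test reproduces published gene-set statistics", {
  expect_equal(signif(hypergeom_overlap_test(11561, 2, 3, 1), 3), 5.19e-4)
  expect_equal(signif(hypergeom_overlap_test(11561, 3, 4, 1), 3), 1.04e-3)
  expect_identical(hypergeom_overlap_test(500, 10, 20, 0), 1.0)
  expect_error(hypergeom_overlap_test(10, 5, 3, 4), "overlap")

  # brute-force probability-mass oracle on a small grid
  for (N in c(15, 40)) for (a in c(3, 7)) for (b in c(2, 9)) {
    for (k in 0:min(a, b)) {
      oracle <- sum(sapply(k:min(a, b), function(x)
        choose(b, x) * choose(N - b, a - x) / choose(N, a)))
      expect_equal(hypergeom_overlap_test(N, a, b, k), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("trait-region enrichment is a one-sided exact test", {
  res <- trait_region_enrichment(matrix(c(10, 0, 0, 10), 2, 2))
  expect_identical(res$odds_ratio, Inf)
  tail10 <- sum(sapply(10, function(x)
    choose(10, x) * choose(10, 10 - x) / choose(20, 10)))
  expect_equal(res$p, tail10, tolerance = 1e-10)

  even <- trait_region_enrichment(matrix(c(4, 4, 6, 6), 2, 2))
  expect_gte(even$p, 0.5)

  # enumeration over tables with fixed margins for [[3,1],[1,3]]
  res2 <- trait_region_enrichment(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(res2$odds_ratio, 9)
  expect_equal(res2$p, (choose(4, 3) * choose(4, 1) + 1) / choose(8, 4),
               tolerance = 1e-12)
  expect_error(trait_region_enrichment(matrix(c(-1, 1, 1, 1), 2, 2)),
               "nonnegative")
})

test_that("genotype TSVs round-trip", {
  g <- simulate_genotypes(10, 6, ld_blocks = 3, seed = 2)
  p <- tempfile(fileext = ".tsv")
  write_genotypes(g, p)
  g2 <- read_genotypes(p)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$variants$variant_id, g$variants$variant_id)
})
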