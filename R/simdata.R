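#' Default synthetic-data configuration
#'
#' Desk-scale defaults: a balanced depth-4 binary ontology (16 leaves, 31
#' nodes) with 6 composite tissues, 6 atlas subjects, 40 cohort subjects,
#' 200 genes and 500 variants.  Gene-specific cross-subject stability
#' `rho_g` is drawn uniformly on `[0, 1]`; the subject-signal fraction is
#' 0.5 and the measurement-noise standard deviation 0.25 (all expression is
#' on the unit scale of the tree process, whose per-edge step is 1).
#'
#' @param ... overrides for any field.
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(depth = 4, branching = 2, n_composites = 6,
              n_atlas_subjects = 6, n_cohort_subjects = 40,
              n_genes = 200, n_variants = 500,
              stability = function(n) stats::runif(n),
              subject_signal_fraction = 0.5,
              noise_sd = 0.25, tree_step_sd = 1,
              maf_range = c(0.05, 0.5), ld_blocks = 50,
              seed = 1)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$subject_signal_fraction >= 0, cfg$subject_signal_fraction <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a balanced tissue ontology
#'
#' A balanced tree of the given depth and branching factor; the leaves are
#' partitioned into `n_composites` contiguous groups forming the composite
#' map.
#'
#' @param depth tree depth (>= 1; leaves sit at this depth).
#' @param branching children per internal node (>= 2).
#' @param n_composites number of composite tissues (<= leaf count).
#' @param seed RNG seed (kept for interface symmetry; the balanced tree is
#'   deterministic).
#' @return a [brain_ontology].
#' @export
simulate_ontology <- function(depth = 4, branching = 2, n_composites = 6,
                              seed = 1) {
  stopifnot(depth >= 1, branching >= 2)
  n_leaves <- branching^depth
  if (n_composites > n_leaves) {
    stop("n_composites (", n_composites, ") exceeds leaf count (", n_leaves, ")")
  }
  nodes <- data.frame(id = "root", name = "whole brain", level = 0L,
                      parent = NA_character_, stringsAsFactors = FALSE)
  prev <- "root"
  for (lev in seq_len(depth)) {
    ids <- sprintf("L%d_%03d", lev, seq_len(length(prev) * branching))
    nodes <- rbind(nodes, data.frame(
      id = ids, name = paste("tissue", ids), level = lev,
      parent = rep(prev, each = branching), stringsAsFactors = FALSE))
    prev <- ids
  }
  leaves <- prev
  grp <- cut(seq_len(n_leaves), breaks = n_composites, labels = FALSE)
  comps <- split(leaves, grp)
  names(comps) <- sprintf("COMP%02d", seq_len(n_composites))
  brain_ontology(nodes, comps)
}

# one Brownian realisation on the tree: root = 0, child = parent + N(0, step^2)
brownian_on_tree <- function(ont, step_sd) {
  vals <- stats::setNames(numeric(length(ont$node_ids)), ont$node_ids)
  for (i in seq_along(ont$node_ids)) {
    id <- ont$node_ids[i]
    par <- ont$nodes$parent[i]
    vals[id] <- if (is.na(par)) 0 else vals[par] + stats::rnorm(1, sd = step_sd)
  }
  vals[ont$leaf_ids]
}

#' Simulate leaf-level expression with planted structure
#'
#' Per gene g, a tissue archetype `a_g` is generated by Brownian motion along
#' the ontology tree (child value = parent value + Gaussian step), giving
#' tree-local tissue correlation.  Each subject s then observes
#' \deqn{x(s,t,g) = \rho_g a_g(t) + (1-\rho_g) b_{s,g}(t) + f\, u_{s,g}
#'   + \varepsilon,}
#' where `b` is an independent per-subject Brownian pattern (so `rho_g`
#' controls cross-subject stability of the tissue pattern, the quantity the
#' DS score measures), `u` a per-(subject, gene) scalar shift scaled by the
#' subject-signal fraction `f`, and `eps` Gaussian measurement noise.
#'
#' @param ont a [brain_ontology].
#' @param config a [sim_config].
#' @param subject_ids subject labels (default atlas + cohort ids from the
#'   config sizes).
#' @return list with `expr` (an [expr_tensor], subjects x leaves x genes) and
#'   `truth` (list with `archetype` leaves x genes, `rho`, `u` subjects x
#'   genes, config and seed).
#' @export
simulate_expression <- function(ont, config = sim_config(),
                                subject_ids = NULL) {
  set.seed(as.integer(config$seed))
  if (is.null(subject_ids)) {
    subject_ids <- c(sprintf("A%02d", seq_len(config$n_atlas_subjects)),
                     sprintf("S%02d", seq_len(config$n_cohort_subjects)))
  }
  leaves <- ont$leaf_ids
  G <- config$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  rho <- config$stability(G)
  stopifnot(all(rho >= 0 & rho <= 1))
  arch <- vapply(seq_len(G), function(g) brownian_on_tree(ont, config$tree_step_sd),
                 numeric(length(leaves)))
  dimnames(arch) <- list(leaves, genes)
  S <- length(subject_ids)
  u <- matrix(stats::rnorm(S * G), S, G, dimnames = list(subject_ids, genes))
  vals <- array(NA_real_, c(S, length(leaves), G))
  f <- config$subject_signal_fraction
  for (s in seq_len(S)) {
    b <- vapply(seq_len(G), function(g) brownian_on_tree(ont, config$tree_step_sd),
                numeric(length(leaves)))
    noise <- matrix(stats::rnorm(length(leaves) * G, sd = config$noise_sd),
                    length(leaves), G)
    vals[s, , ] <- sweep(arch, 2, rho, `*`) + sweep(b, 2, 1 - rho, `*`) +
      matrix(u[s, ], length(leaves), G, byrow = TRUE) * f + noise
  }
  expr <- expr_tensor(vals, NULL, subject_ids, leaves, genes)
  list(expr = expr,
       truth = list(archetype = arch, rho = stats::setNames(rho, genes),
                    u = u, subject_signal_fraction = f,
                    noise_sd = config$noise_sd, seed = config$seed))
}

#' Simulate block-correlated genotype dosages
#'
#' Variants are organised in LD blocks.  Each block has a founder variant
#' with allele frequency drawn from `maf_range`; every variant in the block
#' copies each of the founder's two allele draws with a per-variant flip
#' probability, which controls the within-block r-squared (flip probability
#' 0 gives r-squared 1).  Blocks are independent.  Positions are evenly
#' spaced along one synthetic chromosome.
#'
#' @param n_subjects,n_variants dimensions.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param ld_blocks number of blocks.
#' @param flip_prob per-haplotype copy flip probability (default 0.05).
#' @param spacing_bp distance between adjacent variant positions.
#' @param seed RNG seed.
#' @return a [genotype_matrix].
#' @export
simulate_genotypes <- function(n_subjects, n_variants, maf_range = c(0.05, 0.5),
                               ld_blocks = 10, flip_prob = 0.05,
                               spacing_bp = 1000, seed = 1) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  set.seed(as.integer(seed))
  block <- cut(seq_len(n_variants), breaks = ld_blocks, labels = FALSE)
  D <- matrix(0L, n_subjects, n_variants)
  for (b in seq_len(ld_blocks)) {
    vs <- which(block == b)
    maf <- stats::runif(1, maf_range[1], maf_range[2])
    h1 <- stats::rbinom(n_subjects, 1, maf)
    h2 <- stats::rbinom(n_subjects, 1, maf)
    for (v in vs) {
      f1 <- stats::rbinom(n_subjects, 1, flip_prob)
      f2 <- stats::rbinom(n_subjects, 1, flip_prob)
      D[, v] <- as.integer(xor(h1, f1)) + as.integer(xor(h2, f2))
    }
  }
  # non-palindromic allele pairs only (palindromic SNPs are dropped by the
  # usual harmonization QC, and would only generate pass-through warnings)
  alleles <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea <- sample(alleles, n_variants, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, c(a, comp[[a]])), 1), "")
  variants <- data.frame(
    variant_id = sprintf("v%04d", seq_len(n_variants)), chr = "1",
    pos = spacing_bp * seq_len(n_variants), effect_allele = ea,
    other_allele = unname(oa), block = block, stringsAsFactors = FALSE)
  genotype_matrix(D + 0, variants, sprintf("S%04d", seq_len(n_subjects)))
}

#' Plant cis-eQTL effects into an expression tensor
#'
#' Adds `beta * dosage(s, variant)` to the expression of the planned gene in
#' the planned tissue(s) for every subject.  Subjects are matched by
#' position: the tensor's subject i uses the genotype matrix's subject i.
#'
#' @param expr an [expr_tensor].
#' @param geno a [genotype_matrix] with as many subjects as `expr`.
#' @param plan data.frame with columns `variant_id`, `gene_id`, `tissue_id`
#'   (a tissue in the tensor, or `"all"`), `beta`.
#' @return list with `expr` (modified tensor) and `truth` (the plan).
#' @export
inject_eqtl_effects <- function(expr, geno, plan) {
  stopifnot(inherits(expr, "expr_tensor"), inherits(geno, "genotype_matrix"))
  if (nrow(geno$dosages) != length(expr$subject_ids)) {
    stop("genotype and expression subject counts differ")
  }
  vals <- expr$values
  for (r in seq_len(nrow(plan))) {
    vi <- match(plan$variant_id[r], geno$variants$variant_id)
    gi <- match(plan$gene_id[r], expr$gene_ids)
    if (is.na(vi) || is.na(gi)) {
      stop("plan row ", r, " references unknown variant or gene")
    }
    tiss <- if (plan$tissue_id[r] == "all") seq_along(expr$tissue_ids) else
      match(plan$tissue_id[r], expr$tissue_ids)
    if (anyNA(tiss)) stop("plan row ", r, " references unknown tissue")
    dose <- geno$dosages[, vi]
    for (t in tiss) vals[, t, gi] <- vals[, t, gi] + plan$beta[r] * dose
  }
  list(expr = expr_tensor(vals, expr$observed, expr$subject_ids,
                          expr$tissue_ids, expr$gene_ids),
       truth = plan)
}

#' Simulate GWAS summary statistics
#'
#' Simulates a phenotype `y = sum(theta_v * dosage_v) + N(0, 1)` and returns
#' per-variant marginal ordinary-least-squares associations (beta, se, p).
#'
#' @param geno a [genotype_matrix].
#' @param causal data.frame with columns `variant_id`, `theta` (may be
#'   empty for a null trait).
#' @param trait_id,trait_type trait label and type
#'   (`"quantitative"`/`"binary"`); the phenotype itself is always simulated
#'   on a continuous liability scale.
#' @param seed RNG seed.
#' @return data.frame with columns `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`, `trait_id`,
#'   `trait_type`.
#' @export
simulate_gwas_summary <- function(geno, causal, trait_id = "trait",
                                  trait_type = "quantitative", seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(geno$dosages)
  y <- stats::rnorm(n)
  if (nrow(causal)) {
    vi <- match(causal$variant_id, geno$variants$variant_id)
    if (anyNA(vi)) stop("causal plan references unknown variant(s)")
    y <- y + as.vector(geno$dosages[, vi, drop = FALSE] %*% causal$theta)
  }
  D <- geno$dosages
  Dc <- sweep(D, 2, colMeans(D))
  ss_d <- colSums(Dc^2)
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(Dc, yc))
  beta <- ifelse(ss_d > 0, sxy / ss_d, NA_real_)
  rss <- sum(yc^2) - beta * sxy
  rss[rss < 0] <- 0
  se <- ifelse(ss_d > 0, sqrt(rss / (n - 2) / ss_d), NA_real_)
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  data.frame(variant_id = geno$variants$variant_id, chr = geno$variants$chr,
             pos = geno$variants$pos,
             effect_allele = geno$variants$effect_allele,
             other_allele = geno$variants$other_allele,
             beta = beta, se = se, p = p, n = n, trait_id = trait_id,
             trait_type = trait_type, stringsAsFactors = FALSE)
}

#' Mask whole composite tissues per subject
#'
#' Marks whole tissues unobserved per subject, either `k` random tissues per
#' subject (`pattern = list(type = "random_k", k = )`) or a fixed tissue list
#' for every subject (`pattern = list(type = "fixed", tissues = )`).  A
#' subject is never left with fewer than `min_observed` observed tissues.
#'
#' @param expr an [expr_tensor] (typically composite-level).
#' @param pattern masking pattern (see above).
#' @param seed RNG seed.
#' @param min_observed minimum observed tissues a subject must retain.
#' @return an [expr_tensor] with updated `observed` mask and `NA` values in
#'   masked entries.
#' @export
mask_tissues <- function(expr, pattern, seed = 1, min_observed = 5) {
  stopifnot(inherits(expr, "expr_tensor"), is.list(pattern))
  Tn <- length(expr$tissue_ids)
  obs <- expr$observed
  set.seed(as.integer(seed))
  if (pattern$type == "random_k") {
    k <- pattern$k
    if (k == 0) return(expr)
    if (Tn - k < min_observed) {
      stop("masking ", k, " of ", Tn, " tissues would leave fewer than ",
           min_observed, " observed")
    }
    for (s in seq_along(expr$subject_ids)) {
      avail <- which(obs[s, ])
      n_mask <- min(k, length(avail) - min_observed)
      obs[s, avail[sample.int(length(avail), n_mask)]] <- FALSE
    }
  } else if (pattern$type == "fixed") {
    ti <- match(pattern$tissues, expr$tissue_ids)
    if (anyNA(ti)) stop("pattern references unknown tissue(s)")
    if (Tn - length(ti) < min_observed) {
      stop("fixed mask would leave fewer than ", min_observed, " observed tissues")
    }
    obs[, ti] <- FALSE
  } else {
    stop("pattern$type must be 'random_k' or 'fixed'")
  }
  vals <- expr$values
  expr_tensor(vals, obs, expr$subject_ids, expr$tissue_ids, expr$gene_ids)
}
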