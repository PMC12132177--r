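#' Pipeline run configuration
#'
#' A flat YAML-serialisable configuration covering every stage.  All
#' method constants are named defaults here: clumping window 10,000 kb with
#' r-squared cutoff 0.001, colocalization priors `p1 = p2 = 1e-4,
#' p12 = 1e-5` with PP4 threshold 0.7 and a 100 kb region, 1000
#' permutations, and a minimum of 5 observed tissues for imputation
#' eligibility.  Every stochastic stage derives its seed from the global
#' seed plus a fixed stage offset.
#'
#' @param out_dir output directory (one subdirectory per stage).
#' @param seed global run seed.
#' @param stages stages to run, in dependency order.
#' @param sim overrides for [sim_config()].
#' @param model overrides for [imputer_config()] plus `extended_targets`
#'   (composite ids to train extended imputers for), `quantile_normalize`
#'   (logical), `gene_dim`, `gene_steps`, `mask_k`.
#' @param genetics overrides: `window_bp`, `n_perm`, `clump_window_bp`,
#'   `clump_r2`, `coloc_p1`, `coloc_p2`, `coloc_p12`, `pp4_threshold`,
#'   `region_bp`, `fdr_threshold`, `min_observed`, `n_gwas_subjects`,
#'   `n_planted_eqtl`, `eqtl_beta`, `gwas_theta`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       stages = c("simulate", "preprocess", "embed", "train",
                                  "impute", "evaluate", "eqtl", "sharing",
                                  "mr", "coloc", "overlap"),
                       sim = list(), model = list(), genetics = list()) {
  model_def <- list(dim_t = 32, gcn_hidden = 32, hidden = c(256, 128, 64, 32),
                    lr = 1e-3, ft_lr_factor = 0.1, epochs_pre = 20,
                    epochs_ft = 10, batch = 1024, gene_dim = 64,
                    gene_steps = 400, quantile_normalize = TRUE,
                    extended_targets = NULL, mask_k = 1)
  gen_def <- list(window_bp = 1e6, n_perm = 1000, clump_window_bp = 1e7,
                  clump_r2 = 0.001, coloc_p1 = 1e-4, coloc_p2 = 1e-4,
                  coloc_p12 = 1e-5, pp4_threshold = 0.7, region_bp = 1e5,
                  fdr_threshold = 0.05, min_observed = 5,
                  n_gwas_subjects = 2000, n_planted_eqtl = 5,
                  eqtl_beta = 0.8, gwas_theta = 0.3)
  stopifnot(all(names(model) %in% names(model_def)),
            all(names(genetics) %in% names(gen_def)))
  model_def[names(model)] <- model
  gen_def[names(genetics)] <- genetics
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 sim = sim, model = model_def, genetics = gen_def),
            class = "run_config")
}

#' Read / write a run configuration (YAML)
#' @param config a [run_config]; `path` a YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(out_dir = raw$out_dir, seed = raw$seed, stages = raw$stages,
             sim = raw$sim, model = raw$model, genetics = raw$genetics)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 101, preprocess = 211, embed = 307, train = 401,
               impute = 503, evaluate = 601, eqtl = 701, sharing = 809,
               mr = 907, coloc = 1009, overlap = 1103)
  (config$seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

write_manifest <- function(dir, stage, config, outputs) {
  tf <- tempfile(fileext = ".yaml"); on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  manifest <- list(stage = stage, seed = stage_seed(config, stage),
                   config_hash = unname(tools::md5sum(tf)),
                   package_version = as.character(utils::packageVersion("neurimpute")),
                   outputs = as.list(file_hashes(outputs)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' simulate -> preprocess -> embed -> train -> impute -> evaluate -> eqtl ->
#' sharing -> mr -> coloc -> overlap.  Each stage writes its artifacts and a
#' `manifest.json` (stage seed, configuration hash, output file hashes) into
#' its own subdirectory of `out_dir`; inputs are never mutated, and a rerun
#' with the same configuration reproduces identical manifests.
#'
#' @param config a [run_config].
#' @return invisibly, a named list of per-stage manifests.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())   # cross-stage state
  manifests <- list()
  order_all <- c("simulate", "preprocess", "embed", "train", "impute",
                 "evaluate", "eqtl", "sharing", "mr", "coloc", "overlap")
  stages <- order_all[order_all %in% config$stages]
  for (stage in stages) {
    dir <- file.path(config$out_dir, stage)
    dir.create(dir, showWarnings = FALSE)
    fn <- get(paste0("stage_", stage), envir = asNamespace("neurimpute"))
    outputs <- fn(st, config, dir)
    manifests[[stage]] <- write_manifest(dir, stage, config, outputs)
  }
  invisible(manifests)
}

need_stage <- function(st, field, stage) {
  if (is.null(st[[field]])) {
    stop("stage '", stage, "' must run first (missing its output '", field, "')")
  }
  st[[field]]
}

stage_simulate <- function(st, config, dir) {
  scfg <- do.call(sim_config, c(config$sim, list(seed = stage_seed(config, "simulate"))))
  ont <- simulate_ontology(scfg$depth, scfg$branching, scfg$n_composites,
                           seed = scfg$seed)
  sim <- simulate_expression(ont, scfg)
  atlas_ids <- grep("^A", sim$expr$subject_ids, value = TRUE)
  cohort_ids <- setdiff(sim$expr$subject_ids, atlas_ids)
  st$ont <- ont
  st$atlas <- tensor_subset(sim$expr, subjects = atlas_ids)
  cohort_leaf <- tensor_subset(sim$expr, subjects = cohort_ids)
  st$truth <- sim$truth

  gen <- config$genetics
  geno <- simulate_genotypes(length(cohort_ids), scfg$n_variants,
                             maf_range = scfg$maf_range,
                             ld_blocks = scfg$ld_blocks,
                             seed = scfg$seed + 1)
  geno$subject_ids <- cohort_ids
  rownames(geno$dosages) <- cohort_ids
  # plant one eQTL per distinct LD block, acting in all tissues
  n_eqtl <- gen$n_planted_eqtl
  blocks <- unique(geno$variants$block)[seq_len(n_eqtl)]
  plan <- data.frame(
    variant_id = vapply(blocks, function(b)
      geno$variants$variant_id[geno$variants$block == b][1], ""),
    gene_id = cohort_leaf$gene_ids[seq_len(n_eqtl)],
    tissue_id = "all", beta = gen$eqtl_beta, stringsAsFactors = FALSE)
  inj <- inject_eqtl_effects(cohort_leaf, geno, plan)
  st$cohort_leaf <- inj$expr
  st$cohort <- collapse_to_composites(inj$expr, ont)
  st$geno <- geno
  st$eqtl_plan <- plan
  # gene positions: genes spread along the synthetic chromosome
  st$gene_positions <- data.frame(
    gene_id = cohort_leaf$gene_ids, chr = "1",
    pos = round(seq(1, max(geno$variants$pos),
                    length.out = length(cohort_leaf$gene_ids))))
  # GWAS cohort: larger sample with the same LD architecture
  gwas_geno <- simulate_genotypes(gen$n_gwas_subjects, scfg$n_variants,
                                  maf_range = scfg$maf_range,
                                  ld_blocks = scfg$ld_blocks,
                                  seed = scfg$seed + 2)
  shared_v <- plan$variant_id[1]
  distinct_block <- setdiff(unique(geno$variants$block), blocks)[1]
  distinct_v <- geno$variants$variant_id[geno$variants$block == distinct_block][1]
  st$gwas <- list(
    shared = simulate_gwas_summary(gwas_geno,
      data.frame(variant_id = shared_v, theta = gen$gwas_theta),
      trait_id = "trait_shared", seed = scfg$seed + 3),
    distinct = simulate_gwas_summary(gwas_geno,
      data.frame(variant_id = distinct_v, theta = gen$gwas_theta),
      trait_id = "trait_distinct", seed = scfg$seed + 4))

  paths <- c(file.path(dir, "ontology.json"), file.path(dir, "expr_atlas.tsv"),
             file.path(dir, "expr_cohort_leaf.tsv"),
             file.path(dir, "genotypes.tsv"),
             file.path(dir, "genotypes.tsv.variants.tsv"),
             file.path(dir, "gwas_trait_shared.tsv"),
             file.path(dir, "gwas_trait_distinct.tsv"),
             file.path(dir, "gene_positions.tsv"),
             file.path(dir, "truth.json"))
  write_ontology(ont, paths[1])
  write_expression_long(st$atlas, paths[2])
  write_expression_long(st$cohort_leaf, paths[3])
  write_genotypes(geno, paths[4])
  write_tsv_full(st$gwas$shared, paths[6])
  write_tsv_full(st$gwas$distinct, paths[7])
  write_tsv_full(st$gene_positions, paths[8])
  jsonlite::write_json(list(rho = as.list(st$truth$rho),
                            eqtl_plan = st$eqtl_plan,
                            shared_variant = shared_v,
                            distinct_variant = distinct_v),
                       paths[9], auto_unbox = TRUE, digits = NA)
  paths
}

stage_preprocess <- function(st, config, dir) {
  atlas <- need_stage(st, "atlas", "simulate")
  if (isTRUE(config$model$quantile_normalize)) {
    st$atlas <- quantile_normalize_per_gene(atlas)
    st$cohort <- quantile_normalize_per_gene(st$cohort)
  }
  p1 <- file.path(dir, "expr_atlas_norm.tsv")
  p2 <- file.path(dir, "expr_cohort_norm.tsv")
  write_expression_long(st$atlas, p1)
  write_expression_long(st$cohort, p2)
  c(p1, p2)
}

stage_embed <- function(st, config, dir) {
  atlas <- need_stage(st, "atlas", "simulate")
  st$gene_emb <- train_gene_embeddings(
    atlas, dim_g = config$model$gene_dim, steps = config$model$gene_steps,
    seed = stage_seed(config, "embed"))
  p <- file.path(dir, "gene_embedding.tsv")
  write_embedding(st$gene_emb, p)
  c(p, paste0(p, ".meta.json"))
}

stage_train <- function(st, config, dir) {
  ont <- need_stage(st, "ont", "simulate")
  emb <- need_stage(st, "gene_emb", "embed")
  mc <- config$model
  icfg <- imputer_config(dim_t = mc$dim_t, gcn_hidden = mc$gcn_hidden,
                         hidden = mc$hidden, lr = mc$lr,
                         ft_lr_factor = mc$ft_lr_factor,
                         epochs_pre = mc$epochs_pre, epochs_ft = mc$epochs_ft,
                         batch = mc$batch)
  sd0 <- stage_seed(config, "train")
  st$base_model <- train_imputer(st$atlas, st$cohort, ont, emb, icfg, seed = sd0)
  targets <- mc$extended_targets
  if (is.null(targets)) targets <- names(ont$composite_map)[1]
  st$extended <- stats::setNames(lapply(seq_along(targets), function(i) {
    train_extended_imputer(targets[i], st$atlas, st$cohort, ont, emb, icfg,
                           seed = sd0 + i)
  }), targets)
  paths <- c(file.path(dir, "model_base.json"),
             file.path(dir, sprintf("model_extended_%s.json", targets)))
  write_imputer(st$base_model, paths[1])
  for (i in seq_along(targets)) write_imputer(st$extended[[i]], paths[1 + i])
  paths
}

stage_impute <- function(st, config, dir) {
  ont <- st$ont
  models <- need_stage(st, "extended", "train")
  target <- names(models)[1]
  masked <- mask_tissues(st$cohort, list(type = "fixed", tissues = target),
                         seed = stage_seed(config, "impute"),
                         min_observed = min(config$genetics$min_observed,
                                            length(ont$composite_map) - 1))
  bank <- fit_lm_bank(st$cohort)
  comps <- names(ont$composite_map)
  genes <- masked$gene_ids
  imp_vals <- masked$values
  rows <- list()
  for (s in seq_along(masked$subject_ids)) {
    prof <- matrix(masked$values[s, , ], length(comps), length(genes),
                   dimnames = list(comps, genes))
    res <- impute_profile(prof, models, bank, ont,
                          min_observed = min(config$genetics$min_observed,
                                             length(comps) - 1))
    imp_vals[s, , ] <- res$profile[comps, ]
    rows[[s]] <- data.frame(subject_id = masked$subject_ids[s],
                            tissue_id = rep(comps, each = length(genes)),
                            gene_id = rep(genes, times = length(comps)),
                            value = as.vector(t(res$profile[comps, ])),
                            imputed_flag = rep(comps %in% res$imputed,
                                               each = length(genes)),
                            stringsAsFactors = FALSE)
  }
  st$imputed <- expr_tensor(imp_vals, NULL, masked$subject_ids, comps, genes)
  st$impute_target <- target
  p <- file.path(dir, "imputed_profiles.tsv")
  write_tsv_full(do.call(rbind, rows), p)
  p
}

stage_evaluate <- function(st, config, dir) {
  imputed <- need_stage(st, "imputed", "impute")
  target <- st$impute_target
  pred <- imputed$values[, match(target, imputed$tissue_ids), ]
  truth <- st$cohort$values[, match(target, st$cohort$tissue_ids), ]
  sp <- per_gene_spearman(pred, truth)
  # DS on the measured cohort leaf expression, against the planted stability
  per_subj <- lapply(seq_along(st$cohort_leaf$subject_ids), function(s)
    st$cohort_leaf$values[s, , ])
  ds <- ds_score(per_subj)
  rho <- st$truth$rho[names(ds)]
  summary <- list(
    imputed_tissue = target,
    median_spearman = stats::median(sp, na.rm = TRUE),
    n_undefined = attr(sp, "n_undefined"),
    ds_rho_spearman = stats::cor(ds, rho, method = "spearman",
                                 use = "complete.obs"),
    ds_skipped_pairs = attr(ds, "skipped_pairs"))
  p <- file.path(dir, "evaluation.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  st$evaluation <- summary
  p
}

stage_eqtl <- function(st, config, dir) {
  geno <- need_stage(st, "geno", "simulate")
  gen <- config$genetics
  sd0 <- stage_seed(config, "eqtl")
  comps <- st$cohort$tissue_ids
  recs <- do.call(rbind, lapply(seq_along(comps), function(k) {
    cis_eqtl_scan(geno, st$cohort$values[, k, ], st$gene_positions,
                  window_bp = gen$window_bp, n_perm = gen$n_perm,
                  seed = sd0 + k, tissue_id = comps[k])
  }))
  st$eqtl_records <- recs
  p <- file.path(dir, "eqtl_records.tsv")
  write_tsv_full(recs, p)
  p
}

stage_sharing <- function(st, config, dir) {
  recs <- need_stage(st, "eqtl_records", "eqtl")
  gen <- config$genetics
  # lead variants: best nominal association per (variant), clumped
  best <- recs[order(recs$p_nominal), ]
  best <- best[!duplicated(best$variant_id), c("variant_id", "p_nominal")]
  names(best)[2] <- "p"
  leads <- ld_clump(best, st$geno, window_bp = gen$clump_window_bp,
                    r2_max = gen$clump_r2)
  comps <- unique(recs$tissue_id)
  take_best <- recs[order(recs$p_nominal), ]
  eff <- sapply(comps, function(tt) {
    sub <- take_best[take_best$tissue_id == tt, ]
    sub$beta[match(leads, sub$variant_id)]
  })
  eff <- matrix(eff, nrow = length(leads),
                dimnames = list(leads, comps))
  sign_counts <- apply(eff, 1, function(v)
    if (all(!is.finite(v))) NA_integer_ else sharing_by_sign(v))
  mag_counts <- apply(eff, 1, function(v)
    if (all(!is.finite(v))) NA_integer_ else sharing_by_magnitude(v))
  pw <- pairwise_sharing_matrix(eff)
  st$leads <- leads
  st$lead_effects <- eff
  p1 <- file.path(dir, "sharing_counts.tsv")
  p2 <- file.path(dir, "pairwise_sharing.tsv")
  write_tsv_full(data.frame(variant_id = leads, shared_by_sign = sign_counts,
                            shared_by_magnitude = mag_counts), p1)
  write_tsv_full(data.frame(tissue_id = rownames(pw), pw, check.names = FALSE), p2)
  c(p1, p2)
}

stage_mr <- function(st, config, dir) {
  recs <- need_stage(st, "eqtl_records", "eqtl")
  gen <- config$genetics
  sig <- recs[!is.na(recs$p_gene) & recs$p_gene <= 0.05, ]
  sig <- sig[order(sig$p_nominal), ]
  sig <- sig[!duplicated(paste(sig$variant_id, sig$tissue_id)), ]
  out <- list()
  for (trait in names(st$gwas)) {
    gw <- st$gwas[[trait]]
    for (r in seq_len(nrow(sig))) {
      orow <- gw[gw$variant_id == sig$variant_id[r], ]
      if (!nrow(orow)) next
      vmeta <- st$geno$variants[
        match(sig$variant_id[r], st$geno$variants$variant_id), ]
      expo <- c(as.list(sig[r, ]), vmeta[c("effect_allele", "other_allele")])
      h <- harmonize(expo, as.list(orow[1, ]))
      if (h$dropped) next
      out[[length(out) + 1]] <- wald_ratio_mr(h$exposure, h$outcome)
    }
  }
  mr <- do.call(rbind, out)
  if (!is.null(mr) && nrow(mr)) mr$q <- bh_fdr(mr$p)
  st$mr_results <- mr
  p <- file.path(dir, "mr_results.tsv")
  write_tsv_full(if (is.null(mr)) data.frame() else mr, p)
  p
}

stage_coloc <- function(st, config, dir) {
  mr <- need_stage(st, "mr_results", "mr")
  gen <- config$genetics
  sig <- mr[mr$q <= gen$fdr_threshold, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(sig))) {
    v <- sig$variant_id[r]; trait <- sig$trait_id[r]
    e_sub <- st$eqtl_records[st$eqtl_records$gene_id == sig$gene_id[r] &
                             st$eqtl_records$tissue_id == sig$tissue_id[r], ]
    r1 <- coloc_region(e_sub, st$geno, v, gen$region_bp)
    r2 <- coloc_region(st$gwas[[sub("^trait_", "", trait)]], st$geno, v,
                       gen$region_bp)
    if (!nrow(r1) || !nrow(r2)) next
    cc <- coloc_abf(r1, r2,
                    priors = list(p1 = gen$coloc_p1, p2 = gen$coloc_p2,
                                  p12 = gen$coloc_p12),
                    pp4_threshold = gen$pp4_threshold)
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = v, gene_id = sig$gene_id[r], tissue_id = sig$tissue_id[r],
      trait_id = trait, n_variants = cc$n_variants,
      pp4_default = unname(cc$default$pp["PP4"]),
      pp4_per_region = unname(cc$per_region$pp["PP4"]),
      colocalized = cc$colocalized, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame()
  st$coloc_results <- res
  p <- file.path(dir, "coloc_results.tsv")
  write_tsv_full(res, p)
  p
}

stage_overlap <- function(st, config, dir) {
  coloc <- need_stage(st, "coloc_results", "coloc")
  universe <- length(st$cohort$gene_ids)
  discovered <- if (nrow(coloc)) unique(coloc$gene_id[coloc$colocalized]) else character(0)
  planted <- unique(st$eqtl_plan$gene_id)
  ov <- length(intersect(discovered, planted))
  p_ov <- hypergeom_overlap_test(universe, length(discovered), length(planted), ov)
  res <- list(universe = universe, discovered = length(discovered),
              planted = length(planted), overlap = ov, p = p_ov)
  st$overlap <- res
  p <- file.path(dir, "overlap.json")
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
  p
}
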