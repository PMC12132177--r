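# Shared fixtures, built lazily and cached for the whole test session.
# Heavy objects (trained imputers) are constructed once here and reused by
# several test files.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# compact training configuration used throughout the tests: small enough to
# train in seconds, large enough to learn the planted structure
fx_train_config <- function() {
  imputer_config(dim_t = 16, gcn_hidden = 16, hidden = c(64, 32, 32, 16),
                 epochs_pre = 15, epochs_ft = 6)
}

# default-scale simulation (6 composites) with a trained base imputer and an
# extended imputer for COMP01; 30 training + 10 held-out cohort subjects
fx_default <- function() fx_get("default", function() {
  ont <- simulate_ontology(4, 2, 6, seed = 1)
  sim <- simulate_expression(ont, sim_config(seed = 7))
  atlas <- tensor_subset(sim$expr,
                         subjects = grep("^A", sim$expr$subject_ids, value = TRUE))
  cohort_leaf <- tensor_subset(sim$expr,
                               subjects = grep("^S", sim$expr$subject_ids, value = TRUE))
  cohort <- collapse_to_composites(cohort_leaf, ont)
  cohort_tr <- tensor_subset(cohort, subjects = cohort$subject_ids[1:30])
  emb <- train_gene_embeddings(atlas, dim_g = 16, steps = 300, seed = 3)
  cfg <- fx_train_config()
  base <- train_imputer(atlas, cohort_tr, ont, emb, cfg, seed = 5)
  ext1 <- train_extended_imputer("COMP01", atlas, cohort_tr, ont, emb, cfg,
                                 seed = 6)
  list(ont = ont, truth = sim$truth, atlas = atlas, cohort_leaf = cohort_leaf,
       cohort = cohort, cohort_tr = cohort_tr, test_idx = 31:40, emb = emb,
       cfg = cfg, base = base, ext1 = ext1,
       bank = fit_lm_bank(cohort_tr))
})

# 10-composite simulation with one extended imputer per composite, used by
# the missing-tissue robustness and DS-stability analyses
fx_robust <- function() fx_get("robust", function() {
  ont <- simulate_ontology(4, 2, 10, seed = 1)
  sim <- simulate_expression(ont, sim_config(seed = 7, n_composites = 10))
  atlas <- tensor_subset(sim$expr,
                         subjects = grep("^A", sim$expr$subject_ids, value = TRUE))
  cohort_leaf <- tensor_subset(sim$expr,
                               subjects = grep("^S", sim$expr$subject_ids, value = TRUE))
  cohort <- collapse_to_composites(cohort_leaf, ont)
  cohort_tr <- tensor_subset(cohort, subjects = cohort$subject_ids[1:30])
  emb <- train_gene_embeddings(atlas, dim_g = 16, steps = 300, seed = 3)
  cfg <- imputer_config(dim_t = 16, gcn_hidden = 16, hidden = c(64, 32, 32, 16),
                        epochs_pre = 10, epochs_ft = 6)
  comps <- names(ont$composite_map)
  models <- stats::setNames(lapply(seq_along(comps), function(i)
    train_extended_imputer(comps[i], atlas, cohort_tr, ont, emb, cfg,
                           seed = 5 + i)), comps)
  list(ont = ont, truth = sim$truth, atlas = atlas, cohort_leaf = cohort_leaf,
       cohort = cohort, cohort_tr = cohort_tr, models = models,
       bank = fit_lm_bank(cohort_tr))
})

# impute one composite for a set of subjects under a given mask set, and
# return the per-gene Spearman median against the measured values
fx_impute_median <- function(fx, masked_set, target = "COMP01",
                             subject_idx = seq_along(fx$cohort$subject_ids)) {
  comps <- fx$cohort$tissue_ids
  genes <- fx$cohort$gene_ids
  truth <- fx$cohort$values[subject_idx, match(target, comps), ]
  pred <- matrix(NA_real_, length(subject_idx), length(genes))
  for (j in seq_along(subject_idx)) {
    prof <- matrix(fx$cohort$values[subject_idx[j], , ], length(comps),
                   length(genes), dimnames = list(comps, genes))
    prof[masked_set, ] <- NA
    res <- impute_profile(prof, fx$models, fx$bank, fx$ont, min_observed = 5)
    pred[j, ] <- res$profile[target, ]
  }
  stats::median(per_gene_spearman(pred, truth), na.rm = TRUE)
}

# a small random tree (valid parent-pointer structure) for property tests
fx_random_tree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  parent <- c(NA_character_,
              vapply(seq_len(n - 1), function(i) ids[sample.int(i, 1)], ""))
  brain_ontology(data.frame(id = ids, name = ids, level = 0L, parent = parent,
                            stringsAsFactors = FALSE))
}
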