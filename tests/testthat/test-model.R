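test_that("prediction is a deterministic dense forward pass", {
  fx <- fx_default()
  m <- fx$base
  genes <- fx$cohort$gene_ids
  prof <- fx$cohort$values[31, , 1]

  # all-zero MLP weights -> 0 for any input
  m0 <- m
  m0$mlp <- lapply(m0$mlp, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_identical(predict_expression(m0, prof, genes[1], m$leaf_ids[2]), 0)

  # hand-rolled matrix-arithmetic oracle
  leaf <- m$leaf_ids[5]; gene <- genes[7]
  cg_H <- gcn_forward(m$Ahat, structure(list(layer_weights = m$gcn,
                                             n_nodes = length(m$node_ids),
                                             dim_out = ncol(m$gcn[[2]])),
                                        class = "tissue_net"))
  x <- c(cg_H[match(leaf, m$node_ids), ], m$gene_emb[gene, ], prof)
  for (k in seq_along(m$mlp)) {
    x <- as.vector(x %*% m$mlp[[k]]$W) + m$mlp[[k]]$b
    if (k < length(m$mlp)) x <- pmax(x, 0)
  }
  expect_equal(predict_expression(m, prof, gene, leaf), x, tolerance = 1e-6)

  # permuting two genes' embedding rows swaps their predictions
  msw <- m
  msw$gene_emb[c(genes[1], genes[2]), ] <- m$gene_emb[c(genes[2], genes[1]), ]
  expect_equal(predict_expression(msw, prof, genes[1], leaf),
               predict_expression(m, prof, genes[2], leaf))

  # input validation
  expect_error(predict_expression(m, prof, "nope", leaf), "unknown gene")
  expect_error(predict_expression(m, prof, genes[1], "nope"), "unknown leaf")
  expect_error(predict_expression(m, c(prof[-1], NA), genes[1], leaf), "finite")
})

test_that("composite prediction is exactly the mean over subordinate leaves", {
  fx <- fx_default()
  prof <- fx$cohort$values[33, , 2]
  gene <- fx$cohort$gene_ids[2]
  for (cid in names(fx$ont$composite_map)) {
    leaves <- subordinate_leaves(fx$ont, cid)
    leaf_preds <- vapply(leaves, function(l)
      predict_expression(fx$base, prof, gene, l), numeric(1))
    expect_identical(predict_composite(fx$base, prof, gene, cid, fx$ont),
                     mean(leaf_preds))
  }
  expect_error(predict_composite(fx$base, prof, gene, "NOPE", fx$ont),
               "unknown composite")
})

test_that("two-phase training reduces the loss and is seed-deterministic", {
  fx <- fx_default()
  expect_lt(tail(fx$base$train$loss_pre, 1), 0.5 * fx$base$train$loss_pre[1])
  expect_lt(tail(fx$base$train$loss_ft, 1), fx$base$train$loss_ft[1])

  # determinism: identical seeds give identical loss traces and weights
  ont <- simulate_ontology(2, 2, 2, seed = 1)
  sim <- simulate_expression(ont, sim_config(seed = 3, depth = 2,
                                             n_composites = 2, n_genes = 12,
                                             n_atlas_subjects = 3,
                                             n_cohort_subjects = 8))
  atlas <- tensor_subset(sim$expr, subjects = grep("^A", sim$expr$subject_ids,
                                                   value = TRUE))
  cohort <- collapse_to_composites(
    tensor_subset(sim$expr, subjects = grep("^S", sim$expr$subject_ids,
                                            value = TRUE)), ont)
  emb <- train_gene_embeddings(atlas, dim_g = 4, pairs_per_step = 64,
                               steps = 20, seed = 2)
  cfg <- imputer_config(dim_t = 4, gcn_hidden = 4, hidden = c(8, 8),
                        epochs_pre = 3, epochs_ft = 2)
  m1 <- train_imputer(atlas, cohort, ont, emb, cfg, seed = 10)
  m2 <- train_imputer(atlas, cohort, ont, emb, cfg, seed = 10)
  expect_identical(m1$train$loss_pre, m2$train$loss_pre)
  expect_identical(m1$mlp, m2$mlp)

  expect_error(train_imputer(atlas,
                             tensor_subset(cohort, subjects = character(0)),
                             ont, emb, cfg),
               "empty training set|must be")
})

test_that("training on a constant target converges to that constant", {
  ont <- simulate_ontology(2, 2, 2, seed = 1)
  cval <- 0.8
  atlas <- expr_tensor(array(cval, c(3, 4, 6)), NULL, paste0("A", 1:3),
                       ont$leaf_ids, paste0("G", 1:6))
  cohort <- expr_tensor(array(cval, c(8, 2, 6)), NULL, paste0("S", 1:8),
                        names(ont$composite_map), paste0("G", 1:6))
  emb <- gene_embedding(matrix(rnorm(6 * 4, sd = 0.1), 6, 4,
                               dimnames = list(paste0("G", 1:6), NULL)))
  cfg <- imputer_config(dim_t = 4, gcn_hidden = 4, hidden = c(16, 8),
                        lr = 0.02, epochs_pre = 120, epochs_ft = 5)
  m <- train_imputer(atlas, cohort, ont, emb, cfg, seed = 4)
  preds <- vapply(ont$leaf_ids, function(l)
    predict_expression(m, rep(cval, 2), "G3", l), numeric(1))
  expect_true(all(abs(preds - cval) < 0.05))
})

test_that("extended imputers drop the target slot and recover averaging
          structure", {
  fx <- fx_default()
  ext <- fx$ext1
  expect_identical(ext$input_spec$target_composite, "COMP01")
  expect_identical(ext$input_spec$n_profile_slots, 5L)
  expect_identical(ext$input_spec$profile_composites,
                   setdiff(names(fx$ont$composite_map), "COMP01"))
  expect_error(train_extended_imputer("NOPE", fx$atlas, fx$cohort_tr, fx$ont,
                                      fx$emb, fx$cfg), "unknown composite")

  # planted-structure recovery: target composite equal to the mean of the
  # others (plus small noise) is imputed with high per-gene rank agreement
  ont <- simulate_ontology(2, 2, 4, seed = 1)   # 4 leaves, singleton comps
  set.seed(77)
  G <- 30
  mk <- function(n, prefix) {
    others <- array(rnorm(n * 3 * G), c(n, 3, G))
    v <- array(NA_real_, c(n, 4, G))
    v[, 2:4, ] <- others
    v[, 1, ] <- apply(others, c(1, 3), mean) + rnorm(n * G, sd = 0.02)
    expr_tensor(v, NULL, paste0(prefix, 1:n), ont$leaf_ids,
                paste0("G", 1:G))
  }
  atlas <- mk(4, "A")
  cohort_leaf <- mk(40, "S")
  cohort <- collapse_to_composites(cohort_leaf, ont)
  emb <- train_gene_embeddings(atlas, dim_g = 4, pairs_per_step = 256,
                               steps = 100, seed = 2)
  cfg <- imputer_config(dim_t = 8, gcn_hidden = 8, hidden = c(32, 16),
                        lr = 5e-3, epochs_pre = 60, epochs_ft = 20)
  target <- names(ont$composite_map)[1]
  mx <- train_extended_imputer(target, atlas,
                               tensor_subset(cohort, subjects = cohort$subject_ids[1:30]),
                               ont, emb, cfg, seed = 3)
  test_i <- 31:40
  slots <- mx$input_spec$profile_composites
  truth <- cohort$values[test_i, match(target, cohort$tissue_ids), ]
  pred <- matrix(NA_real_, length(test_i), G)
  for (j in seq_along(test_i)) {
    for (g in seq_len(G)) {
      prof <- cohort$values[test_i[j], match(slots, cohort$tissue_ids), g]
      pred[j, g] <- predict_composite(mx, prof, paste0("G", g), target, ont)
    }
  }
  sp <- per_gene_spearman(pred, truth)
  expect_gt(stats::median(sp, na.rm = TRUE), 0.8)
})

test_that("the linear-model bank fits exact OLS with lazy caching", {
  fx <- fx_default()
  comps <- names(fx$ont$composite_map)

  # target identical to one predictor -> unit coefficient, zero elsewhere
  v <- fx$cohort_tr$values
  v[, 1, ] <- v[, 2, ]
  ident <- expr_tensor(v, NULL, fx$cohort_tr$subject_ids, comps,
                       fx$cohort_tr$gene_ids)
  bank <- fit_lm_bank(ident)
  fit <- lm_bank_get(bank, comps[1], comps[2:4])
  expect_equal(unname(fit$coef[, 1]), rep(0, nrow(fit$coef)), tolerance = 1e-8)
  expect_equal(unname(fit$coef[, 2]), rep(1, nrow(fit$coef)), tolerance = 1e-8)
  expect_equal(unname(fit$coef[, 3]), rep(0, nrow(fit$coef)), tolerance = 1e-8)

  # normal-equations oracle on a 5-subject example
  set.seed(12)
  v5 <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  small <- expr_tensor(v5, NULL, paste0("s", 1:5), c("c1", "c2", "c3"),
                       c("g1", "g2"))
  b5 <- fit_lm_bank(small)
  f5 <- lm_bank_get(b5, "c1", "c2")
  X <- cbind(1, v5[, 2, 1]); y <- v5[, 1, 1]
  expect_equal(unname(f5$coef["g1", ]),
               as.vector(solve(crossprod(X), crossprod(X, y))),
               tolerance = 1e-10)

  # too few subjects
  tiny <- expr_tensor(v5[1:3, , , drop = FALSE], NULL, paste0("s", 1:3),
                      c("c1", "c2", "c3"), c("g1", "g2"))
  expect_error(lm_bank_get(fit_lm_bank(tiny), "c1", c("c2", "c3")),
               "subjects")

  # cache: the same request is fitted once
  k0 <- length(bank$env$cache)
  lm_bank_get(bank, comps[1], comps[2:4])
  expect_length(bank$env$cache, k0)
})

test_that("two-step imputation preserves observed values and follows the
          linear-model fill", {
  fx <- fx_default()
  comps <- fx$cohort$tissue_ids
  genes <- fx$cohort$gene_ids
  models <- list(COMP01 = fx$ext1)
  prof_full <- matrix(fx$cohort$values[35, , ], length(comps), length(genes),
                      dimnames = list(comps, genes))

  # fully observed: unchanged, but leaf predictions still produced
  res0 <- impute_profile(prof_full, models, fx$bank, fx$ont, min_observed = 5)
  expect_identical(res0$profile, prof_full)
  expect_identical(res0$imputed, character(0))
  expect_identical(rownames(res0$leaf_predictions),
                   subordinate_leaves(fx$ont, "COMP01"))

  # one missing composite: step 1 is a no-op; equals the direct extended
  # prediction
  prof1 <- prof_full; prof1["COMP01", ] <- NA
  res1 <- impute_profile(prof1, models, fx$bank, fx$ont, min_observed = 5)
  slots <- fx$ext1$input_spec$profile_composites
  direct <- vapply(seq_along(genes), function(g)
    predict_composite(fx$ext1, prof_full[slots, g], genes[g], "COMP01",
                      fx$ont), numeric(1))
  expect_equal(unname(res1$profile["COMP01", ]), direct, tolerance = 1e-12)
  expect_identical(res1$profile[slots, ], prof_full[slots, ])

  # two missing: the sibling missing tissue is filled by the lm bank from
  # the observed composites, exactly as a manual trace
  prof2 <- prof_full; prof2[c("COMP01", "COMP02"), ] <- NA
  ext2 <- train_extended_imputer("COMP02", fx$atlas, fx$cohort_tr, fx$ont,
                                 fx$emb, imputer_config(
                                   dim_t = 8, gcn_hidden = 8,
                                   hidden = c(16, 8), epochs_pre = 2,
                                   epochs_ft = 1), seed = 9)
  models2 <- list(COMP01 = fx$ext1, COMP02 = ext2)
  res2 <- impute_profile(prof2, models2, fx$bank, fx$ont, min_observed = 4)
  observed <- setdiff(comps, c("COMP01", "COMP02"))
  fill <- lm_bank_get(fx$bank, "COMP02", observed)
  manual_fill <- fill$coef[, 1] +
    rowSums(t(prof2[fill$predictors, , drop = FALSE]) *
            fill$coef[, -1, drop = FALSE])
  work <- prof2
  work["COMP02", ] <- manual_fill
  manual <- vapply(seq_along(genes), function(g)
    predict_composite(fx$ext1, work[fx$ext1$input_spec$profile_composites, g],
                      genes[g], "COMP01", fx$ont), numeric(1))
  expect_equal(unname(res2$profile["COMP01", ]), manual, tolerance = 1e-12)

  # refusal below the eligibility threshold, with override
  prof5 <- prof_full
  prof5[comps[1:3], ] <- NA
  expect_error(impute_profile(prof5, models2, fx$bank, fx$ont,
                              min_observed = 5), "observed composites")
  expect_error(impute_profile(prof1, models["COMP02"], fx$bank, fx$ont,
                              min_observed = 5), "no extended model")

  # mask preservation on random missingness patterns
  set.seed(44)
  for (rep in 1:3) {
    miss <- sample(comps, 2)
    pr <- prof_full; pr[miss, ] <- NA
    mods <- stats::setNames(lapply(miss, function(mm)
      if (mm == "COMP01") fx$ext1 else
        train_extended_imputer(mm, fx$atlas, fx$cohort_tr, fx$ont, fx$emb,
                               imputer_config(dim_t = 4, gcn_hidden = 4,
                                              hidden = c(8, 8),
                                              epochs_pre = 1, epochs_ft = 1),
                               seed = 50 + rep)), miss)
    rr <- impute_profile(pr, mods, fx$bank, fx$ont, min_observed = 4)
    keep <- setdiff(comps, miss)
    expect_identical(rr$profile[keep, ], prof_full[keep, ])
    expect_true(all(is.finite(rr$profile)))
  }
})

test_that("model checkpoints round-trip through the JSON archive", {
  fx <- fx_default()
  p <- tempfile(fileext = ".json")
  write_imputer(fx$ext1, p)
  m2 <- read_imputer(p)
  prof <- fx$cohort$values[31, match(fx$ext1$input_spec$profile_composites,
                                     fx$cohort$tissue_ids), 3]
  gene <- fx$cohort$gene_ids[3]
  leaf <- subordinate_leaves(fx$ont, "COMP01")[1]
  expect_equal(predict_expression(m2, prof, gene, leaf),
               predict_expression(fx$ext1, prof, gene, leaf),
               tolerance = 1e-12)
  expect_identical(m2$ont_hash, fx$ext1$ont_hash)
})

test_that("leaf embeddings are tree-local after training", {
  fx <- fx_default()
  net <- structure(list(layer_weights = fx$base$gcn,
                        n_nodes = length(fx$base$node_ids),
                        dim_out = ncol(fx$base$gcn[[length(fx$base$gcn)]])),
                   class = "tissue_net")
  H <- gcn_forward(fx$base$Ahat, net)
  leaves <- fx$ont$leaf_ids
  D <- tree_distance_matrix(fx$ont, leaves)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  li <- match(leaves, fx$base$node_ids)
  C <- outer(seq_along(leaves), seq_along(leaves),
             Vectorize(function(i, j) cs(H[li[i], ], H[li[j], ])))
  expect_gt(mean(C[D == 2 & upper.tri(D)]), mean(C[D >= 4 & upper.tri(D)]))
})
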