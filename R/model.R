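#' Training configuration for the tissue imputer
#'
#' Defaults follow the package's reference architecture: a 2-layer graph
#' convolution (hidden width 32, embedding width 32) over the ontology, a
#' frozen pretrained gene embedding, and an MLP with two blocks of hidden
#' layers (widths 256, 128 then 64, 32), each a fully connected linear layer
#' followed by ReLU, ending in a linear scalar head.  Fine-tuning updates all
#' trainable weights (graph convolution and MLP) at `ft_lr_factor` times the
#' pretraining learning rate; gene embeddings stay frozen throughout.
#'
#' @param dim_t tissue embedding width.
#' @param gcn_hidden hidden widths of the graph convolution.
#' @param hidden MLP hidden widths (the two blocks concatenated).
#' @param lr Adam learning rate for phase-1 training.
#' @param ft_lr_factor multiplier on `lr` during fine-tuning.
#' @param epochs_pre,epochs_ft epochs for the two phases.
#' @param batch minibatch size over (subject, gene, tissue) triples.
#' @return a named list of class `imputer_config`.
#' @export
imputer_config <- function(dim_t = 32, gcn_hidden = 32,
                           hidden = c(256, 128, 64, 32),
                           lr = 1e-3, ft_lr_factor = 0.1,
                           epochs_pre = 20, epochs_ft = 10, batch = 1024) {
  structure(list(dim_t = dim_t, gcn_hidden = gcn_hidden, hidden = hidden,
                 lr = lr, ft_lr_factor = ft_lr_factor,
                 epochs_pre = epochs_pre, epochs_ft = epochs_ft, batch = batch),
            class = "imputer_config")
}

# md5 fingerprint of the ontology structure, recorded in checkpoints
ontology_hash <- function(ont) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(list(nodes = ont$node_ids, leaves = ont$leaf_ids,
                            composites = ont$composite_map),
                       tf, auto_unbox = TRUE)
  unname(tools::md5sum(tf))
}

# composite-level values array [subject, composite, gene] from a leaf tensor
composite_values <- function(expr, ont) {
  ct <- collapse_to_composites(expr, ont)
  ct$values
}

new_imputer <- function(ont, gene_emb, config, n_profile_slots,
                        target_composite, seed) {
  comps <- names(ont$composite_map)
  profile_composites <- if (is.null(target_composite)) comps else
    setdiff(comps, target_composite)
  n_nodes <- length(ont$node_ids)
  set.seed(as.integer(seed))
  gcn <- gcn_init(n_nodes, c(config$gcn_hidden, config$dim_t))
  d_in <- config$dim_t + ncol(gene_emb$mat) + n_profile_slots
  mlp <- mlp_init(c(d_in, config$hidden, 1))
  structure(list(
    node_ids = ont$node_ids, leaf_ids = ont$leaf_ids,
    composite_ids = comps, composite_map = ont$composite_map,
    Ahat = normalized_adjacency(ont),
    gcn = gcn, mlp = mlp,
    gene_emb = gene_emb$mat, gene_ids = gene_emb$gene_ids,
    input_spec = list(n_profile_slots = n_profile_slots,
                      target_composite = target_composite,
                      profile_composites = profile_composites),
    train = list(config = config, seed = seed,
                 loss_pre = numeric(0), loss_ft = numeric(0)),
    ont_hash = ontology_hash(ont)),
    class = "tissue_imputer")
}

#' @export
print.tissue_imputer <- function(x, ...) {
  tc <- x$input_spec$target_composite
  cat("tissue_imputer:", if (is.null(tc)) "full-profile model" else
      paste0("extended model for composite '", tc, "'"),
      "|", x$input_spec$n_profile_slots, "profile slots,",
      length(x$leaf_ids), "leaves,", nrow(x$gene_emb), "genes\n")
  invisible(x)
}

# ---- forward passes -------------------------------------------------------

# batched prediction: leaf_idx/gene_idx index the model's leaf/gene tables,
# prof is B x n_profile_slots
imputer_forward <- function(model, leaf_idx, gene_idx, prof, cache = FALSE) {
  cg <- gcn_forward_cache(model$Ahat, model$gcn)
  node_idx <- match(model$leaf_ids[leaf_idx], model$node_ids)
  X <- cbind(cg$H[node_idx, , drop = FALSE],
             model$gene_emb[gene_idx, , drop = FALSE],
             prof)
  fw <- mlp_forward(model$mlp, X)
  if (cache) list(pred = fw$out, acts = fw$acts, gcn_cache = cg,
                  node_idx = node_idx) else fw$out
}

#' Predict expression of one gene in one leaf tissue
#'
#' Deterministic forward pass on the concatenation of the leaf's tissue
#' embedding, the gene's embedding, and the subject's measured-tissue profile.
#'
#' @param model a `tissue_imputer`.
#' @param profile numeric vector of length `n_profile_slots`, ordered as
#'   `model$input_spec$profile_composites`.
#' @param gene gene id.
#' @param leaf leaf tissue id.
#' @return predicted expression value (scalar).
#' @export
predict_expression <- function(model, profile, gene, leaf) {
  stopifnot(inherits(model, "tissue_imputer"))
  if (!gene %in% model$gene_ids) stop("unknown gene id: '", gene, "'")
  if (!leaf %in% model$leaf_ids) stop("unknown leaf tissue id: '", leaf, "'")
  if (length(profile) != model$input_spec$n_profile_slots || !all(is.finite(profile))) {
    stop("profile must be ", model$input_spec$n_profile_slots, " finite values")
  }
  imputer_forward(model, match(leaf, model$leaf_ids),
                  match(gene, model$gene_ids),
                  matrix(profile, nrow = 1))[[1]]
}

#' Predict expression of one gene in a composite tissue
#'
#' The composite prediction is the arithmetic mean of [predict_expression()]
#' over the composite's subordinate leaves.
#'
#' @inheritParams predict_expression
#' @param composite composite tissue id.
#' @param ont a [brain_ontology] (defaults to the composite map stored in the
#'   model).
#' @return predicted expression value (scalar).
#' @export
predict_composite <- function(model, profile, gene, composite, ont = NULL) {
  stopifnot(inherits(model, "tissue_imputer"))
  cmap <- if (is.null(ont)) model$composite_map else ont$composite_map
  if (!composite %in% names(cmap)) stop("unknown composite tissue id: '", composite, "'")
  leaves <- cmap[[composite]]
  mean(vapply(leaves, function(l) predict_expression(model, profile, gene, l),
              numeric(1)))
}

# ---- training -------------------------------------------------------------

# build B x n_slots profile rows from a [subject, composite, gene] array
profile_rows <- function(comp_vals, slot_comp_idx, s_idx, g_idx) {
  prof <- matrix(0, length(s_idx), length(slot_comp_idx))
  for (k in seq_along(slot_comp_idx)) {
    prof[, k] <- comp_vals[cbind(s_idx, slot_comp_idx[k], g_idx)]
  }
  prof
}

# one optimisation phase; samples: data.frame(s, leaf|comp, g, y); for the
# fine-tune phase rows are expanded over subordinate leaves and averaged
run_phase <- function(model, samples, comp_vals, slot_comp_idx, lr, epochs,
                      batch, composite_targets) {
  params <- list(gcn = model$gcn, mlp = model$mlp)
  state <- adam_init(params)
  losses <- numeric(epochs)
  n <- nrow(samples)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch)) {
      rows <- samples[ord[start:min(start + batch - 1, n)], , drop = FALSE]
      model$gcn <- params$gcn; model$mlp <- params$mlp
      if (!composite_targets) {
        prof <- profile_rows(comp_vals, slot_comp_idx, rows$s, rows$g)
        fw <- imputer_forward(model, rows$leaf, rows$g, prof, cache = TRUE)
        res <- fw$pred - rows$y
        loss <- mean(res^2)
        dout <- 2 * res / length(res)
      } else {
        # expand each (s, composite, g) row over its subordinate leaves
        leaves_per <- lapply(rows$comp, function(ci)
          match(model$composite_map[[model$composite_ids[ci]]], model$leaf_ids))
        Ls <- lengths(leaves_per)
        grp <- rep.int(seq_len(nrow(rows)), Ls)
        leaf_idx <- unlist(leaves_per)
        s_long <- rows$s[grp]; g_long <- rows$g[grp]
        prof <- profile_rows(comp_vals, slot_comp_idx, s_long, g_long)
        fw <- imputer_forward(model, leaf_idx, g_long, prof, cache = TRUE)
        avg <- as.vector(rowsum(fw$pred, grp)) / Ls
        res <- avg - rows$y
        loss <- mean(res^2)
        dout <- (2 * res / nrow(rows))[grp] / Ls[grp]
      }
      bw <- mlp_backward(params$mlp, fw$acts, dout)
      dT_rows <- bw$dX[, seq_len(ncol(params$gcn[[length(params$gcn)]])), drop = FALSE]
      dT <- rowsum_into(dT_rows, fw$node_idx, length(model$node_ids))
      dgcn <- gcn_backward_cache(model$Ahat, params$gcn, fw$gcn_cache, dT)
      upd <- adam_step(params, list(gcn = dgcn, mlp = bw$grads), state, lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    losses[ep] <- ep_loss / nb
  }
  list(gcn = params$gcn, mlp = params$mlp, losses = losses)
}

#' Train the expression imputer
#'
#' Two-phase training.  Phase 1 fits [predict_expression()] to the atlas leaf
#' expression by minimising squared error; each atlas subject's profile vector
#' is built by averaging its leaf values over every composite's subordinate
#' leaves.  Phase 2 fine-tunes all trainable weights (graph convolution and
#' MLP, at a reduced learning rate) so that [predict_composite()] matches the
#' cohort's measured composite expression.  Gene embeddings are frozen.
#'
#' @param atlas_expr [expr_tensor] of atlas subjects, all leaves observed.
#' @param cohort_expr [expr_tensor] of complete-profile cohort subjects over
#'   the composite tissues.
#' @param ont a [brain_ontology].
#' @param gene_emb a [gene_embedding] covering the tensor's genes.
#' @param config an [imputer_config].
#' @param seed RNG seed (weights, shuffling).
#' @return a `tissue_imputer` with loss traces in `$train`.
#' @export
train_imputer <- function(atlas_expr, cohort_expr, ont, gene_emb,
                          config = imputer_config(), seed = 1) {
  train_imputer_impl(NULL, atlas_expr, cohort_expr, ont, gene_emb, config, seed)
}

#' Train an extended imputer for one target composite
#'
#' The extended model's subject profile excludes the target composite (slot
#' order: the remaining composites in canonical ontology order) and the model
#' is trained to predict the subordinate leaves of the target composite, so
#' that the target tissue can be imputed from the other measured tissues.
#'
#' @param target_composite composite tissue id to impute.
#' @inheritParams train_imputer
#' @return a `tissue_imputer` with `input_spec$target_composite` set.
#' @export
train_extended_imputer <- function(target_composite, atlas_expr, cohort_expr,
                                   ont, gene_emb, config = imputer_config(),
                                   seed = 1) {
  if (!target_composite %in% names(ont$composite_map)) {
    stop("unknown composite tissue id: '", target_composite, "'")
  }
  train_imputer_impl(target_composite, atlas_expr, cohort_expr, ont, gene_emb,
                     config, seed)
}

train_imputer_impl <- function(target_composite, atlas_expr, cohort_expr, ont,
                               gene_emb, config, seed) {
  stopifnot(inherits(atlas_expr, "expr_tensor"),
            inherits(cohort_expr, "expr_tensor"),
            inherits(ont, "brain_ontology"),
            inherits(gene_emb, "gene_embedding"))
  if (!all(atlas_expr$observed)) stop("atlas subjects must be fully observed on leaves")
  if (!all(cohort_expr$observed)) stop("cohort subjects must be fully observed on composites")
  if (!length(atlas_expr$subject_ids) || !length(cohort_expr$subject_ids)) {
    stop("empty training set")
  }
  genes <- atlas_expr$gene_ids
  if (!identical(genes, cohort_expr$gene_ids)) {
    stop("atlas and cohort tensors must share the gene axis")
  }
  gi <- match(genes, gene_emb$gene_ids)
  if (anyNA(gi)) stop("gene embedding lacks gene(s) in the expression data")
  emb <- gene_embedding(gene_emb$mat[gi, , drop = FALSE], genes, gene_emb$meta)

  comps <- names(ont$composite_map)
  n_slots <- length(comps) - !is.null(target_composite)
  model <- new_imputer(ont, emb, config, n_slots, target_composite, seed)
  slot_comp_idx <- match(model$input_spec$profile_composites, comps)

  target_leaves <- if (is.null(target_composite)) model$leaf_ids else
    subordinate_leaves(ont, target_composite)

  # phase 1: atlas leaf values; atlas profiles = composite means of leaf values
  atlas_comp <- composite_values(atlas_expr, ont)
  li <- match(target_leaves, atlas_expr$tissue_ids)
  if (anyNA(li)) stop("atlas tensor lacks required leaf tissue(s)")
  grid1 <- expand.grid(s = seq_along(atlas_expr$subject_ids),
                       leaf = match(target_leaves, model$leaf_ids),
                       g = seq_along(genes))
  grid1$y <- as.vector(atlas_expr$values[, li, , drop = FALSE])
  ph1 <- run_phase(model, grid1, atlas_comp, slot_comp_idx,
                   lr = config$lr, epochs = config$epochs_pre,
                   batch = config$batch, composite_targets = FALSE)
  model$gcn <- ph1$gcn; model$mlp <- ph1$mlp

  # phase 2: fine-tune against measured cohort composite values
  ci <- match(comps, cohort_expr$tissue_ids)
  if (anyNA(ci)) stop("cohort tensor lacks composite tissue(s)")
  cohort_vals <- cohort_expr$values[, ci, , drop = FALSE]
  target_comps <- if (is.null(target_composite)) seq_along(comps) else
    match(target_composite, comps)
  grid2 <- expand.grid(s = seq_along(cohort_expr$subject_ids),
                       comp = target_comps, g = seq_along(genes))
  grid2$y <- as.vector(cohort_vals[, target_comps, , drop = FALSE])
  ph2 <- run_phase(model, grid2, cohort_vals, slot_comp_idx,
                   lr = config$lr * config$ft_lr_factor,
                   epochs = config$epochs_ft, batch = config$batch,
                   composite_targets = TRUE)
  model$gcn <- ph2$gcn; model$mlp <- ph2$mlp
  model$train$loss_pre <- ph1$losses
  model$train$loss_ft <- ph2$losses
  model
}

# ---- linear-model bank ----------------------------------------------------

#' Bank of per-gene linear imputation models
#'
#' For a requested (target composite, predictor subset), fits one ordinary
#' least squares model per gene: the target composite's expression regressed
#' on the same gene's expression in the predictor composites, across the
#' complete-profile training subjects.  Fits are computed lazily on first
#' request and cached, because the number of observed subsets is
#' combinatorial.  A rank-deficient design falls back to ridge regression
#' with penalty 1e-6 (with a warning).
#'
#' @param cohort_expr [expr_tensor] of complete-profile subjects over
#'   composite tissues.
#' @param requests optional list of `list(target =, predictors =)` to prefit.
#' @return an object of class `lm_bank`.
#' @export
fit_lm_bank <- function(cohort_expr, requests = NULL) {
  stopifnot(inherits(cohort_expr, "expr_tensor"))
  if (!all(cohort_expr$observed)) stop("lm bank training subjects must be complete-profile")
  bank <- new.env(parent = emptyenv())
  bank$vals <- cohort_expr$values
  bank$tissues <- cohort_expr$tissue_ids
  bank$genes <- cohort_expr$gene_ids
  bank$cache <- list()
  obj <- structure(list(env = bank), class = "lm_bank")
  for (rq in requests) lm_bank_get(obj, rq$target, rq$predictors)
  obj
}

#' Fetch (fitting if needed) the per-gene coefficients for one request
#'
#' @param bank an `lm_bank`.
#' @param target target composite id.
#' @param predictors character vector of predictor composite ids.
#' @return list with `coef` (genes x (1 + predictors); first column the
#'   intercept) and `predictors`.
#' @export
lm_bank_get <- function(bank, target, predictors) {
  stopifnot(inherits(bank, "lm_bank"))
  e <- bank$env
  predictors <- e$tissues[e$tissues %in% predictors]  # canonical order
  key <- paste(target, paste(predictors, collapse = ","), sep = "<-")
  if (!is.null(e$cache[[key]])) return(e$cache[[key]])
  ti <- match(target, e$tissues)
  pi <- match(predictors, e$tissues)
  if (is.na(ti) || anyNA(pi)) stop("unknown composite in lm bank request: ", key)
  n <- dim(e$vals)[1]; P <- length(pi)
  if (n < P + 2) {
    stop("lm bank needs >= predictors + 2 subjects (have ", n, ", need ", P + 2, ")")
  }
  G <- length(e$genes)
  coefs <- matrix(NA_real_, G, P + 1,
                  dimnames = list(e$genes, c("(Intercept)", predictors)))
  warned <- FALSE
  for (g in seq_len(G)) {
    X <- cbind(1, e$vals[, pi, g])
    y <- e$vals[, ti, g]
    XtX <- crossprod(X)
    fit <- tryCatch(solve(XtX, crossprod(X, y)), error = function(err) NULL)
    if (is.null(fit) || qr(X)$rank < ncol(X)) {
      if (!warned) {
        warning("rank-deficient design for '", key, "': ridge fallback (penalty 1e-6)")
        warned <- TRUE
      }
      fit <- solve(XtX + 1e-6 * diag(ncol(X)), crossprod(X, y))
    }
    coefs[g, ] <- fit
  }
  e$cache[[key]] <- list(coef = coefs, predictors = predictors)
  e$cache[[key]]
}

# predict a target composite for every gene from a composites x genes matrix
lm_bank_predict <- function(bank, target, predictors, profile_mat) {
  fit <- lm_bank_get(bank, target, predictors)
  X <- t(profile_mat[fit$predictors, , drop = FALSE])   # genes x P
  as.vector(fit$coef[, 1] + rowSums(X * fit$coef[, -1, drop = FALSE]))
}

# ---- two-step imputation --------------------------------------------------

#' Impute a subject's missing composite tissues
#'
#' For each missing composite `m`: step 1 fills every *other* missing
#' composite with the linear-model bank (predictor subset = the observed
#' composites); step 2 runs the extended model for `m` on the resulting
#' profile and averages its subordinate-leaf predictions.  When exactly one
#' composite is missing, step 1 is a no-op.  Observed entries are returned
#' unchanged.  Subjects with fewer than `min_observed` observed composites
#' are refused unless `force = TRUE`.
#'
#' @param profile_mat numeric matrix, composites x genes; missing composites
#'   are all-`NA` rows.
#' @param models named list of extended `tissue_imputer`s (one per missing
#'   composite at minimum).
#' @param lm_bank an `lm_bank` from [fit_lm_bank()].
#' @param ont a [brain_ontology].
#' @param min_observed minimum observed composites (analysis eligibility
#'   threshold; default 5).
#' @param force bypass the `min_observed` refusal.
#' @return list with `profile` (completed composites x genes matrix),
#'   `leaf_predictions` (leaves x genes matrix over the imputed composites'
#'   subordinate leaves) and `imputed` (imputed composite ids).
#' @export
impute_profile <- function(profile_mat, models, lm_bank, ont,
                           min_observed = 5, force = FALSE) {
  comps <- names(ont$composite_map)
  stopifnot(is.matrix(profile_mat))
  if (is.null(rownames(profile_mat)) || !setequal(rownames(profile_mat), comps)) {
    stop("profile_mat rows must be the ontology's composite tissues")
  }
  profile_mat <- profile_mat[comps, , drop = FALSE]
  row_missing <- apply(profile_mat, 1, function(v) all(is.na(v)))
  row_complete <- apply(profile_mat, 1, function(v) all(is.finite(v)))
  if (!all(row_missing | row_complete)) {
    stop("missingness must be tissue-granular: each composite row all-observed or all-NA")
  }
  observed <- comps[row_complete]
  missing <- comps[row_missing]
  if (length(observed) < min_observed && !force) {
    stop("subject has ", length(observed), " observed composites; ",
         min_observed, " required (use force = TRUE to override)")
  }
  out <- profile_mat
  leaf_pred <- NULL
  # with nothing missing, still expand to leaf predictions for every modeled
  # composite; otherwise only the missing composites are predicted
  targets <- if (length(missing)) missing else
    intersect(comps, names(models))
  for (m in targets) {
    mod <- models[[m]]
    if (is.null(mod)) stop("no extended model supplied for missing composite '", m, "'")
    if (!identical(mod$input_spec$target_composite, m)) {
      stop("model supplied for '", m, "' targets '",
           mod$input_spec$target_composite, "'")
    }
    work <- profile_mat
    # step 1: fill the OTHER missing composites from the observed ones
    for (o in setdiff(missing, m)) {
      work[o, ] <- lm_bank_predict(lm_bank, o, observed, profile_mat)
    }
    # step 2: extended model on the filled profile
    slots <- mod$input_spec$profile_composites
    prof9 <- work[slots, , drop = FALSE]                    # slots x genes
    leaves <- subordinate_leaves(ont, m)
    G <- ncol(profile_mat)
    leaf_idx <- rep(match(leaves, mod$leaf_ids), times = G)
    gene_idx <- match(colnames(profile_mat), mod$gene_ids)
    if (anyNA(gene_idx)) stop("model lacks gene(s) in the profile")
    g_long <- rep(gene_idx, each = length(leaves))
    prof_long <- t(prof9)[rep(seq_len(G), each = length(leaves)), , drop = FALSE]
    pred <- imputer_forward(mod, leaf_idx, g_long, prof_long)
    pred_mat <- matrix(pred, nrow = length(leaves),
                       dimnames = list(leaves, colnames(profile_mat)))
    if (m %in% missing) out[m, ] <- colMeans(pred_mat)
    leaf_pred <- rbind(leaf_pred, pred_mat)
  }
  list(profile = out, leaf_predictions = leaf_pred, imputed = missing)
}

# ---- checkpointing --------------------------------------------------------

#' Save / load an imputer checkpoint (single JSON archive)
#'
#' The archive holds every weight matrix, the input specification, training
#' configuration, seed and the ontology fingerprint; numbers are written at
#' full precision so a round-trip reproduces predictions to near machine
#' precision.
#'
#' @param model a `tissue_imputer`.
#' @param path output path.
#' @export
write_imputer <- function(model, path) {
  ser <- list(
    node_ids = model$node_ids, leaf_ids = model$leaf_ids,
    composite_ids = model$composite_ids, composite_map = model$composite_map,
    Ahat = model$Ahat, gcn = model$gcn,
    mlp = lapply(model$mlp, function(l) list(W = l$W, b = l$b)),
    gene_emb = model$gene_emb, gene_ids = model$gene_ids,
    input_spec = model$input_spec,
    train = list(config = unclass(model$train$config), seed = model$train$seed,
                 loss_pre = model$train$loss_pre, loss_ft = model$train$loss_ft),
    ont_hash = model$ont_hash)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_imputer
#' @export
read_imputer <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  model <- list(
    node_ids = s$node_ids, leaf_ids = s$leaf_ids,
    composite_ids = s$composite_ids,
    composite_map = lapply(s$composite_map, as.character),
    Ahat = as_mat(s$Ahat),
    gcn = lapply(s$gcn, as_mat),
    mlp = lapply(s$mlp, function(l) list(W = as_mat(l$W), b = as.numeric(l$b))),
    gene_emb = as_mat(s$gene_emb), gene_ids = s$gene_ids,
    input_spec = list(n_profile_slots = s$input_spec$n_profile_slots,
                      target_composite = s$input_spec$target_composite,
                      profile_composites = s$input_spec$profile_composites),
    train = s$train, ont_hash = s$ont_hash)
  dimnames(model$Ahat) <- list(model$node_ids, model$node_ids)
  rownames(model$gene_emb) <- model$gene_ids
  class(model) <- "tissue_imputer"
  model
}
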