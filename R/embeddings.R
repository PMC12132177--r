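#' Tissue-embedding network
#'
#' Holds the graph-convolution weights that turn the ontology graph into
#' per-tissue embedding vectors.  Input features are the one-hot identity
#' block over all graph nodes, so the first weight matrix has one row per
#' node; hidden layers use ReLU and the last layer is linear.
#'
#' @param n_nodes number of ontology graph nodes.
#' @param dim_hidden integer vector of hidden widths (may be empty).
#' @param dim_out embedding width (> 0).
#' @param seed RNG seed for the weight initialisation.
#' @return an object of class `tissue_net` with elements `layer_weights`,
#'   `n_nodes`, `dim_out`.
#' @export
tissue_net <- function(n_nodes, dim_hidden = 32, dim_out = 32, seed = 1) {
  stopifnot(n_nodes >= 1, dim_out >= 1)
  set.seed(as.integer(seed))
  Ws <- gcn_init(n_nodes, c(dim_hidden, dim_out))
  structure(list(layer_weights = Ws, n_nodes = as.integer(n_nodes),
                 dim_out = as.integer(dim_out)),
            class = "tissue_net")
}

#' Graph-convolution forward pass
#'
#' Propagates one-hot node features through the network:
#' \eqn{H_0 = I}, \eqn{H_{k+1} = \mathrm{relu}(\hat A H_k W_k)} for all but
#' the last layer, which is linear.  Deterministic given the weights.
#'
#' @param adj normalized adjacency from [normalized_adjacency()].
#' @param net a [tissue_net].
#' @return numeric matrix, nodes x `dim_out` (rownames = node ids when `adj`
#'   carries dimnames).
#' @export
gcn_forward <- function(adj, net) {
  stopifnot(inherits(net, "tissue_net"))
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (nrow(adj) != nrow(net$layer_weights[[1]])) {
    stop("adjacency size ", nrow(adj), " does not match network input width ",
         nrow(net$layer_weights[[1]]))
  }
  H <- gcn_forward_cache(adj, net$layer_weights)$H
  rownames(H) <- rownames(adj)
  H
}

#' Gene embeddings
#'
#' @param mat numeric matrix genes x `dim_g` (`dim_g >= 2` so that a Pearson
#'   correlation across embedding coordinates is defined).
#' @param gene_ids gene labels.
#' @param meta optional metadata list (seed, steps, loss trace).
#' @return an object of class `gene_embedding`.
#' @export
gene_embedding <- function(mat, gene_ids = rownames(mat), meta = list()) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, all(is.finite(mat)))
  if (is.null(gene_ids) || length(gene_ids) != nrow(mat)) {
    stop("gene_ids must label every embedding row")
  }
  rownames(mat) <- gene_ids
  structure(list(mat = mat, gene_ids = as.character(gene_ids), meta = meta),
            class = "gene_embedding")
}

#' Train gene embeddings by correlation matching
#'
#' Learns one embedding vector per gene such that the Pearson correlation
#' between two genes' embeddings (computed across the embedding coordinates)
#' approximates the Pearson correlation of their expression across the atlas
#' leaf tissues, for every atlas subject.  The loss is the mean squared
#' difference over sampled gene pairs, minimised with Adam; training examples
#' cycle over atlas subjects round-robin.
#'
#' @param expr an [expr_tensor] of atlas subjects with all leaf tissues
#'   observed.
#' @param dim_g embedding width (>= 2).
#' @param pairs_per_step gene pairs sampled per gradient step.
#' @param steps number of gradient steps; `steps = 0` returns the seeded
#'   random initialisation unchanged.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @return a [gene_embedding]; `meta` holds the seed, step count and loss
#'   trace.  Genes with zero across-tissue variance for a subject are skipped
#'   in that subject's pairs (with one warning).
#' @export
train_gene_embeddings <- function(expr, dim_g = 64, pairs_per_step = 4096,
                                  steps = 400, lr = 1e-3, seed = 1) {
  stopifnot(inherits(expr, "expr_tensor"), dim_g >= 2)
  if (!all(expr$observed)) stop("atlas subjects must have all tissues observed")
  genes <- expr$gene_ids
  G <- length(genes)
  if (G < 2) stop("need at least two genes")
  set.seed(as.integer(seed))
  E <- matrix(stats::rnorm(G * dim_g, sd = 0.1), G, dim_g)
  if (steps == 0) {
    return(gene_embedding(E, genes, meta = list(seed = seed, steps = 0,
                                                dim_g = dim_g, loss = numeric(0))))
  }

  # per-subject gene-gene expression correlations across leaf tissues
  n_subj <- length(expr$subject_ids)
  targets <- vector("list", n_subj)
  degenerate <- FALSE
  for (s in seq_len(n_subj)) {
    Xs <- expr$values[s, , ]             # tissues x genes (genes in columns)
    sds <- apply(Xs, 2, stats::sd)
    ok <- sds > 0
    if (any(!ok)) degenerate <- TRUE
    R <- matrix(NA_real_, G, G)
    if (sum(ok) >= 2) R[ok, ok] <- stats::cor(Xs[, ok, drop = FALSE])
    targets[[s]] <- R
  }
  if (degenerate) {
    warning("gene(s) with zero across-tissue variance: their pairs are skipped for those subjects")
  }

  state <- adam_init(list(E = E))
  params <- list(E = E)
  loss_trace <- numeric(steps)
  for (step in seq_len(steps)) {
    s <- ((step - 1L) %% n_subj) + 1L    # round-robin over atlas subjects
    i <- sample.int(G, pairs_per_step, replace = TRUE)
    j <- sample.int(G, pairs_per_step, replace = TRUE)
    keep <- i != j & !is.na(targets[[s]][cbind(i, j)])
    i <- i[keep]; j <- j[keep]
    tgt <- targets[[s]][cbind(i, j)]
    B <- length(i)
    E <- params$E

    U <- E[i, , drop = FALSE]; U <- U - rowMeans(U)
    V <- E[j, , drop = FALSE]; V <- V - rowMeans(V)
    su <- sqrt(rowSums(U * U)); sv <- sqrt(rowSums(V * V))
    suv <- rowSums(U * V)
    rho <- suv / (su * sv)
    err <- rho - tgt
    loss_trace[step] <- mean(err^2)

    dL_drho <- 2 * err / B
    dU <- (V / (su * sv) - (rho / su^2) * U) * dL_drho
    dV <- (U / (su * sv) - (rho / sv^2) * V) * dL_drho
    dU <- dU - rowMeans(dU)              # centering projector
    dV <- dV - rowMeans(dV)
    dE <- matrix(0, G, dim_g)
    dE <- dE + rowsum_into(dU, i, G)
    dE <- dE + rowsum_into(dV, j, G)

    upd <- adam_step(params, list(E = dE), state, lr)
    params <- upd$params
    state <- upd$state
  }
  gene_embedding(params$E, genes,
                 meta = list(seed = seed, steps = steps, dim_g = dim_g,
                             pairs_per_step = pairs_per_step, lr = lr,
                             loss = loss_trace))
}

# scatter-add rows of X into an out matrix of n rows at positions idx
rowsum_into <- function(X, idx, n) {
  out <- matrix(0, n, ncol(X))
  rs <- rowsum(X, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Pearson correlation between two embedding rows
#'
#' Computed across the embedding coordinates, mirroring how expression
#' correlations are computed across tissues.
#'
#' @param emb a [gene_embedding].
#' @param g,h gene ids.
#' @return numeric scalar.
#' @export
embedding_correlation <- function(emb, g, h) {
  stopifnot(inherits(emb, "gene_embedding"))
  stats::cor(emb$mat[g, ], emb$mat[h, ])
}

#' Save / load embeddings as TSV (+ metadata JSON)
#'
#' @param emb a [gene_embedding].
#' @param path TSV path; metadata goes to `paste0(path, ".meta.json")`.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(id = emb$gene_ids, emb$mat, check.names = FALSE)
  names(df) <- c("id", paste0("d", seq_len(ncol(emb$mat))))
  write_tsv_full(df, path)
  jsonlite::write_json(emb$meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  gene_embedding(as.matrix(df[, -1, drop = FALSE]), df$id, meta)
}
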