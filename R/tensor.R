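#' Expression tensor
#'
#' Container for normalized expression values indexed (subject, tissue, gene).
#' Missingness is tissue-granular: a whole tissue is either observed or missing
#' for a subject, so the observed mask is stored as a subject x tissue logical
#' matrix.  Values must be finite wherever observed; masked entries are `NA`.
#'
#' @param values numeric 3-way array `[subject, tissue, gene]`.
#' @param observed logical matrix `[subject, tissue]`; default all observed.
#' @param subject_ids,tissue_ids,gene_ids ordered label vectors matching the
#'   array dimensions.
#' @return an object of class `expr_tensor`.
#' @export
expr_tensor <- function(values, observed = NULL,
                        subject_ids = dimnames(values)[[1]],
                        tissue_ids = dimnames(values)[[2]],
                        gene_ids = dimnames(values)[[3]]) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values)
  if (is.null(subject_ids) || is.null(tissue_ids) || is.null(gene_ids)) {
    stop("subject/tissue/gene ids are required")
  }
  stopifnot(length(subject_ids) == d[1], length(tissue_ids) == d[2],
            length(gene_ids) == d[3])
  if (is.null(observed)) {
    observed <- matrix(TRUE, d[1], d[2])
  }
  stopifnot(is.logical(observed), all(dim(observed) == d[1:2]))
  dimnames(values) <- list(subject_ids, tissue_ids, gene_ids)
  dimnames(observed) <- list(subject_ids, tissue_ids)
  # finite where observed
  for (t in seq_len(d[2])) {
    obs_subj <- which(observed[, t])
    if (length(obs_subj) && !all(is.finite(values[obs_subj, t, , drop = FALSE]))) {
      stop("non-finite values in observed entries of tissue '", tissue_ids[t], "'")
    }
  }
  values[!array(observed, dim = d)] <- NA_real_  # mask recycles over the gene axis
  structure(list(values = values, observed = observed,
                 subject_ids = as.character(subject_ids),
                 tissue_ids = as.character(tissue_ids),
                 gene_ids = as.character(gene_ids)),
            class = "expr_tensor")
}

#' @export
print.expr_tensor <- function(x, ...) {
  cat("expr_tensor:", length(x$subject_ids), "subjects x", length(x$tissue_ids),
      "tissues x", length(x$gene_ids), "genes;",
      sum(x$observed), "/", length(x$observed), "subject-tissue pairs observed\n")
  invisible(x)
}

#' Subset an expression tensor
#' @param x an [expr_tensor].
#' @param subjects,tissues,genes ids (or indices) to keep; `NULL` keeps all.
#' @return an [expr_tensor].
#' @export
tensor_subset <- function(x, subjects = NULL, tissues = NULL, genes = NULL) {
  si <- if (is.null(subjects)) seq_along(x$subject_ids) else match(subjects, x$subject_ids)
  ti <- if (is.null(tissues)) seq_along(x$tissue_ids) else match(tissues, x$tissue_ids)
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else match(genes, x$gene_ids)
  if (anyNA(c(si, ti, gi))) stop("unknown subject/tissue/gene id in subset")
  expr_tensor(x$values[si, ti, gi, drop = FALSE],
              x$observed[si, ti, drop = FALSE],
              x$subject_ids[si], x$tissue_ids[ti], x$gene_ids[gi])
}

#' Collapse leaf-level expression to composite tissues
#'
#' The composite tissue value of a gene for a subject is the arithmetic mean of
#' the subject's expression over the composite's subordinate leaves.
#'
#' @param x an [expr_tensor] whose tissues are ontology leaves.
#' @param ont a [brain_ontology].
#' @return an [expr_tensor] over the composite tissues.
#' @export
collapse_to_composites <- function(x, ont) {
  comps <- names(ont$composite_map)
  vals <- array(NA_real_, c(length(x$subject_ids), length(comps), length(x$gene_ids)))
  obs <- matrix(TRUE, length(x$subject_ids), length(comps))
  for (k in seq_along(comps)) {
    leaves <- subordinate_leaves(ont, comps[k])
    li <- match(leaves, x$tissue_ids)
    if (anyNA(li)) stop("tensor lacks leaf tissue(s) of composite '", comps[k], "'")
    sub <- x$values[, li, , drop = FALSE]
    vals[, k, ] <- apply(sub, c(1, 3), mean)
    obs[, k] <- apply(x$observed[, li, drop = FALSE], 1, all)
  }
  expr_tensor(vals, obs, x$subject_ids, comps, x$gene_ids)
}

#' Read expression from long-format TSV
#'
#' Columns: `subject_id`, `tissue_id`, `gene_id`, `value`.  Subject, tissue and
#' gene orders follow first occurrence.  (subject, tissue) pairs absent from
#' the file are marked unobserved.
#'
#' @param path TSV path.
#' @return an [expr_tensor].
#' @export
read_expression_long <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "tissue_id", "gene_id", "value")
  if (!all(need %in% names(df))) {
    stop("expression TSV must have columns: ", paste(need, collapse = ", "))
  }
  subj <- unique(df$subject_id); tis <- unique(df$tissue_id); gen <- unique(df$gene_id)
  vals <- array(NA_real_, c(length(subj), length(tis), length(gen)))
  idx <- cbind(match(df$subject_id, subj), match(df$tissue_id, tis),
               match(df$gene_id, gen))
  vals[idx] <- df$value
  obs <- matrix(FALSE, length(subj), length(tis))
  obs[unique(idx[, 1:2, drop = FALSE])] <- TRUE
  expr_tensor(vals, obs, subj, tis, gen)
}

#' Write expression to long-format TSV
#'
#' Only observed entries are written; the writer/reader pair round-trips
#' finite values bit-exactly (values are printed with full precision).
#'
#' @param x an [expr_tensor].
#' @param path output path.
#' @export
write_expression_long <- function(x, path) {
  rows <- which(x$observed, arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    s <- rows[r, 1]; t <- rows[r, 2]
    data.frame(subject_id = x$subject_ids[s], tissue_id = x$tissue_ids[t],
               gene_id = x$gene_ids, value = x$values[s, t, ],
               stringsAsFactors = FALSE)
  }))
  # order: subject, then tissue, then gene (stable, readable)
  out <- out[order(match(out$subject_id, x$subject_ids),
                   match(out$tissue_id, x$tissue_ids),
                   match(out$gene_id, x$gene_ids)), ]
  write_tsv_full(out, path)
  invisible(path)
}

#' Read expression from a wide (GCT-like) TSV
#'
#' Genes in rows (first column `gene_id`), one column per sample named
#' `subject|tissue`.
#'
#' @param path TSV path.
#' @return an [expr_tensor].
#' @export
read_expression_wide <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("wide expression TSV must start with a gene_id column")
  gene <- df$gene_id
  samp <- names(df)[-1]
  parts <- strsplit(samp, "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("sample columns must be named subject|tissue")
  subj <- unique(vapply(parts, `[[`, "", 1L))
  tis <- unique(vapply(parts, `[[`, "", 2L))
  vals <- array(NA_real_, c(length(subj), length(tis), length(gene)))
  obs <- matrix(FALSE, length(subj), length(tis))
  for (k in seq_along(samp)) {
    s <- match(parts[[k]][1], subj); t <- match(parts[[k]][2], tis)
    vals[s, t, ] <- df[[samp[k]]]
    obs[s, t] <- TRUE
  }
  expr_tensor(vals, obs, subj, tis, gene)
}

# full-precision TSV writer shared by all output stages
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
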