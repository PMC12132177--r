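#' Brain-tissue ontology
#'
#' A `brain_ontology` represents the anatomical hierarchy of brain tissues as a
#' rooted tree, together with the mapping from coarse "composite" tissues (the
#' measured panel, e.g. the ten sampled brain regions of a donor cohort) to the
#' fine-grained leaf tissues of an expression atlas.  Leaves are the
#' most-fine-grained tissues; every composite is represented by a non-empty set
#' of leaves subordinate to it.
#'
#' @param nodes data.frame with columns `id`, `name`, `level`, `parent`
#'   (`NA` for the root).  Row order is the canonical node order and is
#'   preserved in all derived matrices.
#' @param composites named list mapping composite tissue ids to character
#'   vectors of leaf ids.
#'
#' @return An object of class `brain_ontology` with elements `nodes`,
#'   `node_ids`, `root_id`, `leaf_ids` (document order), `composite_map`
#'   (leaf sets reordered to `leaf_ids` order) and `children` (named list).
#' @export
brain_ontology <- function(nodes, composites = list()) {
  stopifnot(is.data.frame(nodes), all(c("id", "name", "level", "parent") %in% names(nodes)))
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids)) {
    stop("duplicate node id(s): ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  parent <- as.character(nodes$parent)
  is_root <- is.na(parent)
  if (sum(is_root) != 1L) {
    stop("ontology must have exactly one root (found ", sum(is_root), ")")
  }
  bad_parent <- !is_root & !(parent %in% ids)
  if (any(bad_parent)) {
    stop("node(s) with unknown parent: ", paste(ids[bad_parent], collapse = ", "))
  }
  root_id <- ids[is_root]

  children <- split(ids[!is_root], factor(parent[!is_root], levels = ids))
  # tree check: every node reachable from root exactly once
  seen <- character(0)
  queue <- root_id
  while (length(queue)) {
    nd <- queue[[1L]]; queue <- queue[-1L]
    if (nd %in% seen) stop("cycle detected at node '", nd, "'")
    seen <- c(seen, nd)
    queue <- c(queue, children[[nd]])
  }
  if (length(seen) != length(ids)) {
    stray <- setdiff(ids, seen)
    stop("node(s) not reachable from root (cycle or detached subtree): ",
         paste(stray, collapse = ", "))
  }

  leaf_ids <- ids[vapply(ids, function(i) length(children[[i]]) == 0L, logical(1))]
  composites <- as.list(composites)
  if (length(composites)) {
    if (is.null(names(composites)) || any(names(composites) == "")) {
      stop("composite map must be named by composite id")
    }
    for (cid in names(composites)) {
      lv <- as.character(composites[[cid]])
      if (!length(lv)) stop("composite '", cid, "' maps to no leaves")
      unknown <- setdiff(lv, leaf_ids)
      if (length(unknown)) {
        stop("composite '", cid, "' references unknown leaf id(s): ",
             paste(unknown, collapse = ", "))
      }
      composites[[cid]] <- leaf_ids[leaf_ids %in% lv]  # leaf_ids order
    }
    all_leaves <- unlist(composites, use.names = FALSE)
    if (anyDuplicated(all_leaves)) {
      warning("composite leaf sets overlap on: ",
              paste(unique(all_leaves[duplicated(all_leaves)]), collapse = ", "))
    }
  }

  structure(
    list(nodes = data.frame(id = ids, name = as.character(nodes$name),
                            level = as.integer(nodes$level), parent = parent,
                            stringsAsFactors = FALSE),
         node_ids = ids, root_id = root_id, leaf_ids = leaf_ids,
         composite_map = composites, children = children),
    class = "brain_ontology")
}

#' @export
print.brain_ontology <- function(x, ...) {
  cat("brain_ontology:", length(x$node_ids), "nodes,", length(x$leaf_ids),
      "leaves,", length(x$composite_map), "composite tissues\n")
  invisible(x)
}

#' Load a brain-tissue ontology from JSON
#'
#' The document has the form
#' `{"nodes": [{"id","name","level","parent"}...], "composites": {id: [leaf...]}}`
#' with `parent: null` marking the root.  All structural invariants (single
#' root, acyclic tree, composites referencing known leaves) are validated.
#'
#' @param path path to the JSON document.
#' @return a [brain_ontology].
#' @export
load_ontology <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$nodes)) stop("ontology document lacks a 'nodes' array")
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  for (col in c("id", "name", "level", "parent")) {
    if (is.null(nodes[[col]])) stop("ontology nodes lack field '", col, "'")
  }
  comps <- doc$composites
  if (is.null(comps)) comps <- list()
  brain_ontology(nodes, comps)
}

#' Write an ontology to JSON
#' @param ont a [brain_ontology].
#' @param path output path.
#' @export
write_ontology <- function(ont, path) {
  doc <- list(nodes = ont$nodes, composites = ont$composite_map)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(path)
}

#' Leaves subordinate to a composite tissue
#'
#' @param ont a [brain_ontology].
#' @param composite_id composite tissue id.
#' @return character vector of leaf ids, in the ontology's leaf order.
#' @export
subordinate_leaves <- function(ont, composite_id) {
  stopifnot(inherits(ont, "brain_ontology"))
  if (!composite_id %in% names(ont$composite_map)) {
    stop("unknown composite tissue id: '", composite_id, "'")
  }
  ont$composite_map[[composite_id]]
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Returns the graph operator used by the tissue-embedding network,
#' \eqn{\hat A = D^{-1/2}(A + I)D^{-1/2}}, where `A` is the symmetric
#' parent-child adjacency of the ontology tree and `D` the degree matrix of
#' `A + I`.  Rows/columns follow the ontology node order.
#'
#' @param ont a [brain_ontology].
#' @return a symmetric numeric matrix with dimnames set to node ids.
#' @export
normalized_adjacency <- function(ont) {
  stopifnot(inherits(ont, "brain_ontology"))
  ids <- ont$node_ids
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  pr <- ont$nodes$parent
  for (i in seq_len(n)) {
    if (!is.na(pr[i])) {
      j <- match(pr[i], ids)
      A[i, j] <- 1
      A[j, i] <- 1
    }
  }
  AI <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(AI))
  AI * tcrossprod(dinv)
}

#' Tree distance between two tissues
#'
#' Number of edges on the unique path between `a` and `b` in the ontology tree.
#'
#' @param ont a [brain_ontology].
#' @param a,b tissue ids.
#' @return non-negative integer.
#' @export
tree_distance <- function(ont, a, b) {
  stopifnot(inherits(ont, "brain_ontology"))
  for (x in c(a, b)) {
    if (!x %in% ont$node_ids) stop("unknown tissue id: '", x, "'")
  }
  if (a == b) return(0L)
  path_to_root <- function(x) {
    p <- x
    repeat {
      par <- ont$nodes$parent[match(x, ont$node_ids)]
      if (is.na(par)) break
      p <- c(p, par)
      x <- par
    }
    p
  }
  pa <- path_to_root(a)
  pb <- path_to_root(b)
  common <- intersect(pa, pb)[1L]  # lowest common ancestor
  (match(common, pa) - 1L) + (match(common, pb) - 1L)
}

#' All-pairs tree distances
#' @param ont a [brain_ontology].
#' @param ids node ids (default all nodes).
#' @return integer matrix of pairwise path lengths.
#' @export
tree_distance_matrix <- function(ont, ids = ont$node_ids) {
  n <- length(ids)
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) D[i, j] <- D[j, i] <- tree_distance(ont, ids[i], ids[j])
  }
  D
}
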