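# --- phenoclusters: uncentered-PCC hierarchical clustering -----------------

#' Uncentered Pearson correlation
#'
#' sum(x*y) / sqrt(sum(x^2) * sum(y^2)) with no mean-centering; the
#' similarity used to group morphological signatures.
#'
#' @param x,y numeric vectors of equal length >= 2 with non-zero norm.
#' @return Similarity in [-1, 1].
#' @export
uncentered_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm vector")
  sum(x * y) / (nx * ny)
}

uncentered_pearson_matrix <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("zero-norm vector")
  s <- tcrossprod(m / norms)
  pmin(pmax(s, -1), 1)
}

#' Hierarchical clustering of QMS vectors
#'
#' Agglomerative clustering on distance 1 - uncentered Pearson correlation
#' with average linkage (complete selectable). Merge similarities are
#' reported as 1 - merge height for the phenocluster cut rule.
#'
#' @param qms numeric matrix (conditions x metrics) with unique, non-empty
#'   rownames, or a QMS data.frame from \code{\link{assemble_qms}} (z_*
#'   columns are used).
#' @param linkage \code{"average"} or \code{"complete"}.
#' @return Object of class \code{phenodendro}: the \code{hclust} tree,
#'   labels, the similarity matrix and per-merge similarities.
#' @export
hierarchical_cluster <- function(qms, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (is.data.frame(qms)) {
    m <- as.matrix(qms[, grep("^z_", names(qms)), drop = FALSE])
    rownames(m) <- qms$condition
  } else m <- as.matrix(qms)
  if (is.null(rownames(m))) stop("conditions must be labelled")
  if (anyDuplicated(rownames(m))) stop("duplicate condition labels")
  if (nrow(m) < 2L) stop("need at least 2 conditions")
  stopifnot(all(is.finite(m)))
  s <- uncentered_pearson_matrix(m)
  d <- stats::as.dist(1 - s)
  tree <- stats::hclust(d, method = linkage)
  structure(list(tree = tree, labels = rownames(m), similarity = s,
                 merge_similarity = 1 - tree$height, linkage = linkage),
            class = "phenodendro")
}

#' Cut a dendrogram into phenoclusters
#'
#' A phenocluster is a maximal subtree whose root merge similarity is
#' strictly above the threshold (0.73 in the screen this emulates); leaves
#' in no such subtree are singletons.
#'
#' @param dendro a \code{phenodendro}.
#' @param threshold similarity cut in (-1, 1).
#' @return data.frame: condition, cluster (integer id, singletons get
#'   their own id), cluster_size, defining_similarity (root merge
#'   similarity; NA for singletons).
#' @export
cut_phenoclusters <- function(dendro, threshold = 0.73) {
  stopifnot(inherits(dendro, "phenodendro"),
            threshold > -1, threshold < 1)
  tree <- dendro$tree
  n <- length(dendro$labels)
  # union-find over merges with similarity strictly above the threshold;
  # average/complete linkage heights are monotone, so the resulting
  # components are exactly the maximal subtrees cut at the rule
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_members <- vector("list", nrow(tree$merge))
  keep_sim <- rep(NA_real_, n)
  for (k in seq_len(nrow(tree$merge))) {
    a <- tree$merge[k, 1]; b <- tree$merge[k, 2]
    mem_a <- if (a < 0) -a else node_members[[a]]
    mem_b <- if (b < 0) -b else node_members[[b]]
    node_members[[k]] <- c(mem_a, mem_b)
    sim <- dendro$merge_similarity[k]
    if (sim > threshold) {
      ra <- find(mem_a[1]); rb <- find(mem_b[1])
      parent[rb] <- ra
      keep_sim[ra] <- sim     # root merge of the growing subtree
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  sizes <- as.integer(table(ids)[as.character(ids)])
  data.frame(condition = dendro$labels, cluster = ids,
             cluster_size = sizes,
             defining_similarity = ifelse(sizes > 1L, keep_sim[roots],
                                          NA_real_),
             stringsAsFactors = FALSE)
}

#' Leaf-ordered similarity/QMS matrix for heat-mapping
#'
#' @param dendro a \code{phenodendro}.
#' @param qms optional matrix/data.frame to reorder (defaults to the
#'   similarity matrix).
#' @return Matrix with rows in dendrogram leaf order.
#' @export
ordered_matrix <- function(dendro, qms = NULL) {
  stopifnot(inherits(dendro, "phenodendro"))
  ord <- dendro$tree$order
  if (is.null(qms)) return(dendro$similarity[ord, ord])
  if (is.data.frame(qms)) {
    m <- as.matrix(qms[, grep("^z_", names(qms)), drop = FALSE])
    rownames(m) <- qms$condition
  } else m <- as.matrix(qms)
  m[dendro$labels[ord], , drop = FALSE]
}

#' Export a phenodendrogram in Newick format
#'
#' Branch lengths are merge distances (1 - similarity).
#'
#' @param dendro a \code{phenodendro}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_newick <- function(dendro, path) {
  stopifnot(inherits(dendro, "phenodendro"))
  tree <- dendro$tree
  h <- tree$height
  lab <- dendro$labels
  rec <- function(node, parent_h) {
    if (node < 0) return(sprintf("%s:%.6f", lab[-node], parent_h))
    ch <- tree$merge[node, ]
    sprintf("(%s,%s):%.6f", rec(ch[1], h[node]), rec(ch[2], h[node]),
            parent_h - h[node])
  }
  top <- nrow(tree$merge)
  txt <- sprintf("(%s,%s);", rec(tree$merge[top, 1], h[top]),
                 rec(tree$merge[top, 2], h[top]))
  writeLines(txt, path)
  invisible(path)
}
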