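#' Correlation distance between profiles
#'
#' Distance `1 - Pearson correlation`, ranging from 0 (perfectly correlated
#' profiles) to 2 (perfectly anti-correlated). Profiles with zero variance
#' have undefined correlation; such pairs are assigned distance 1 with a
#' warning, which keeps constant rows (e.g. an allele fixed everywhere) in
#' the matrix rather than dropping them.
#'
#' @param x Numeric matrix; profiles are columns.
#' @return A `dist` object over the columns of `x`.
#' @examples
#' m <- cbind(a = 1:4, b = 4:1)
#' correlation_distance(m) # distance 2: anti-correlated
#' @export
correlation_distance <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("Need at least 2 profiles (columns).")
  sds <- apply(x, 2, sd)
  cc <- suppressWarnings(cor(x))
  d <- 1 - cc
  if (any(sds == 0 | is.na(sds))) {
    warn(paste0(
      "Zero-variance profile(s) have undefined correlation; using ",
      "distance 1: ",
      paste(head(colnames(x)[sds == 0 | is.na(sds)], 5), collapse = ", ")
    ))
    d[is.na(d)] <- 1
  }
  diag(d) <- 0
  as.dist(d)
}

#' Agglomerative hierarchical clustering with centroid linkage
#'
#' Clusters the rows or columns of a matrix with centroid linkage over the
#' `1 - correlation` distance (the convention of classic expression-heatmap
#' tools). The Lance-Williams centroid update is applied directly to the
#' correlation-distance values; centroid linkage can produce inversions
#' (non-monotone merge heights), which are kept and rendered as-is. Ties
#' are broken deterministically by merging the pair whose smallest original
#' leaf indices are lexicographically lowest, so the tree does not depend
#' on floating-point vagaries of input order.
#'
#' @param x Numeric matrix, e.g. an [enrichment_matrix()].
#' @param axis Cluster the `"cols"` (e.g. populations) or `"rows"` (SNPs).
#' @param distance A precomputed `dist` to use instead of
#'   `correlation_distance()`.
#' @return A `cluster_tree`: list with an `hclust`-compatible tree
#'   (`$hclust`), `$labels` and `$order` (leaf ordering by tree traversal).
#' @export
cluster_profiles <- function(x, axis = c("cols", "rows"), distance = NULL) {
  axis <- match.arg(axis)
  m <- as.matrix(x)
  if (axis == "rows") m <- t(m)
  if (ncol(m) < 2) abort("Need at least 2 leaves to cluster.")
  if (is.null(distance)) distance <- correlation_distance(m)
  hc <- agglomerate_centroid(distance, labels = colnames(m))
  structure(
    list(hclust = hc, labels = hc$labels, order = hc$order, axis = axis),
    class = "cluster_tree"
  )
}

# Lance-Williams centroid agglomeration over an arbitrary dissimilarity.
# d(k, i+j) = (ni*d(k,i) + nj*d(k,j))/(ni+nj) - ni*nj*d(i,j)/(ni+nj)^2
agglomerate_centroid <- function(distance, labels = NULL) {
  d <- as.matrix(distance)
  n <- nrow(d)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  diag(d) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  # cluster id per slot: negative leaf index or positive merge index
  ids <- -seq_len(n)
  min_leaf <- seq_len(n) # smallest original leaf index in each slot
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    best <- min(sub)
    hits <- which(sub <= best + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: lowest (min_leaf_i, min_leaf_j) pair
    keys_i <- min_leaf[idx[hits[, 1]]]
    keys_j <- min_leaf[idx[hits[, 2]]]
    lo <- pmin(keys_i, keys_j)
    hi <- pmax(keys_i, keys_j)
    pick <- order(lo, hi)[1]
    i <- idx[hits[pick, 1]]
    j <- idx[hits[pick, 2]]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- d[i, j]
    ni <- sizes[i]
    nj <- sizes[j]
    others <- idx[idx != i & idx != j]
    if (length(others) > 0) {
      dnew <- (ni * d[others, i] + nj * d[others, j]) / (ni + nj) -
        ni * nj * d[i, j] / (ni + nj)^2
      d[others, i] <- dnew
      d[i, others] <- dnew
    }
    sizes[i] <- ni + nj
    ids[i] <- step
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    active[j] <- FALSE
  }
  hc <- list(
    merge = merge,
    height = height,
    order = integer(0),
    labels = labels,
    method = "centroid",
    dist.method = "1 - correlation",
    call = match.call()
  )
  class(hc) <- "hclust"
  hc$order <- tree_leaf_order(merge, n)
  hc
}

# leaf ordering by depth-first traversal of the merge matrix
tree_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) {
      return(-node)
    }
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(
    "<cluster_tree> centroid linkage over 1 - correlation; ",
    length(x$labels), " leaves (axis: ", x$axis, ")\n",
    sep = ""
  )
  cat("  leaf order: ", paste(head(x$labels[x$order], 8), collapse = ", "),
    if (length(x$labels) > 8) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Cut a cluster tree into k groups
#'
#' @param tree A `cluster_tree`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  cutree(tree$hclust, k = k)
}

#' Export a cluster tree in Newick format
#'
#' @param tree A `cluster_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  # ape::as.phylo needs monotone-ish heights only for plotting; conversion
  # itself tolerates inversions but negative edge lengths can arise, which
  # we clamp to zero for the exported tree.
  phy <- ape::as.phylo(hc)
  phy$edge.length[phy$edge.length < 0] <- 0
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Reorder a matrix by row/column trees and export heatmap artifacts
#'
#' Writes the matrix reordered to tree leaf order as a TSV (values
#' unchanged — a pure permutation) and, optionally, a heatmap image
#' rendered with [plot_enrichment_heatmap()].
#'
#' @param x Numeric matrix (e.g. an [enrichment_matrix()]).
#' @param row_tree,col_tree Optional `cluster_tree`s for the two axes.
#' @param path_prefix Output path prefix; writes
#'   `<prefix>_matrix.tsv` and, if `image` is TRUE, `<prefix>_heatmap.png`.
#' @param image Also render a PNG heatmap.
#' @return Named character vector of written paths.
#' @export
export_heatmap <- function(x, row_tree = NULL, col_tree = NULL,
                           path_prefix, image = FALSE) {
  m <- as.matrix(x)
  if (!is.null(row_tree)) {
    stopifnot(identical(sort(row_tree$labels), sort(rownames(m))))
    m <- m[row_tree$labels[row_tree$order], , drop = FALSE]
  }
  if (!is.null(col_tree)) {
    stopifnot(identical(sort(col_tree$labels), sort(colnames(m))))
    m <- m[, col_tree$labels[col_tree$order], drop = FALSE]
  }
  paths <- c(matrix = paste0(path_prefix, "_matrix.tsv"))
  out <- tibble::as_tibble(m, rownames = "rsid")
  readr::write_tsv(out, paths["matrix"], progress = FALSE)
  if (image) {
    paths["heatmap"] <- paste0(path_prefix, "_heatmap.png")
    p <- plot_enrichment_heatmap(m, reorder = FALSE)
    ggplot2::ggsave(paths["heatmap"], p,
      width = 7, height = 7, dpi = 150
    )
  }
  paths
}
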