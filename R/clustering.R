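#' Uncentered Pearson similarity
#'
#' The similarity used for interaction-profile clustering: Pearson's
#' formula without mean-centering, i.e. the cosine of the angle between
#' the two weight vectors, `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`.
#' Unlike centered correlation it treats 0 (no interaction) as a true
#' origin, which is what makes it the appropriate similarity for sparse
#' interaction profiles.
#'
#' @param x,y numeric vectors of equal length; neither may be all zero.
#' @return Similarity in `[-1, 1]`.
#' @examples
#' uncentered_pearson(c(3, 0, 0), c(3, 3, 0))  # 9 / (3 * sqrt(18))
#' @export
uncentered_pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("uncentered Pearson undefined for an all-zero vector", call. = FALSE)
  }
  sum(x * y) / (nx * ny)
}

#' @rdname uncentered_pearson
#' @param s similarity in `[-1, 1]`.
#' @return [similarity_to_distance()] returns the companion distance
#'   `1 - s` in `[0, 2]`.
#' @export
similarity_to_distance <- function(s) {
  stopifnot(all(s >= -1 - 1e-12 & s <= 1 + 1e-12))
  1 - s
}

#' All pairwise uncentered Pearson similarities between matrix rows
#'
#' @param a numeric matrix; rows with all-zero profiles are not allowed.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
row_similarity <- function(a) {
  nrm <- sqrt(rowSums(a^2))
  if (any(nrm == 0)) {
    stop("all-zero profile(s): ",
         paste(rownames(a)[nrm == 0], collapse = ", "), call. = FALSE)
  }
  s <- tcrossprod(a / nrm)
  diag(s) <- 1
  s
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Iteratively merges the closest pair of clusters; the distance between
#' two clusters is the unweighted arithmetic mean of all cross-pair leaf
#' distances. Ties in the minimum are broken deterministically by the
#' smallest (row, column) position in the current cluster ordering, in
#' which a merged cluster takes the position of its first member.
#'
#' @param dist square symmetric distance matrix with zero diagonal and
#'   finite entries; row/column names are the leaf labels.
#' @return An object of class `"chi_dendrogram"`: a list with `labels`,
#'   `merge` (hclust-convention merge matrix: negative entries are
#'   leaves, positive entries earlier merges), `height` (merge
#'   distances, first to last), `similarity` (`1 - height`), and `order`
#'   (leaf display order).
#' @export
average_linkage <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 2L) stop("need at least two items", call. = FALSE)
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(!is.finite(dist))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  labels <- rownames(dist)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  d <- dist
  diag(d) <- Inf
  node <- -seq_len(n)       # hclust ids of the active clusters, in order
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    best <- min(sub)
    # smallest (row, column) in current ordering among the ties
    hits <- which(sub <= best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- idx[hits[1, 1]]
    j <- idx[hits[1, 2]]

    merge[step, ] <- c(node[i], node[j])
    height[step] <- d[i, j]

    # unweighted average linkage update; merged cluster sits at position i
    other <- setdiff(idx, c(i, j))
    if (length(other)) {
      d[i, other] <- (size[i] * d[i, other] + size[j] * d[j, other]) /
        (size[i] + size[j])
      d[other, i] <- d[i, other]
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    node[i] <- step
  }

  structure(list(labels = labels, merge = merge, height = height,
                 similarity = 1 - height,
                 order = dendrogram_order(merge, n)),
            class = "chi_dendrogram")
}

dendrogram_order <- function(merge, n) {
  expand <- function(id) {
    if (id < 0L) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  if (n == 1L) return(1L)
  expand(nrow(merge))
}

#' @export
print.chi_dendrogram <- function(x, ...) {
  cat(sprintf("average-linkage dendrogram: %d leaves, %d merges, heights %.3g to %.3g\n",
              length(x$labels), length(x$height),
              min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.chi_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "1 - uncentered Pearson"),
            class = "hclust")
}

#' Two-way hierarchical clustering of a weighted interaction matrix
#'
#' Clusters the allele rows and the gene columns independently, each on
#' the uncentered Pearson similarity of their weight profiles with
#' average linkage. All-zero rows and columns (profiles with no
#' interaction at all, for which the similarity is undefined) are dropped
#' with a warning before clustering.
#'
#' @param w a weight-reversed matrix (see [reverse_weights()]), or any
#'   non-negative numeric matrix with row and column names.
#' @return A list of class `"chi_two_way"` with elements `rows` and
#'   `cols` (each a `"chi_dendrogram"`) and `matrix` (the clustered
#'   submatrix after dropping empty profiles).
#' @export
two_way_cluster <- function(w) {
  a <- unclass(w)
  empty_rows <- rowSums(a != 0) == 0L
  empty_cols <- colSums(a != 0) == 0L
  if (any(empty_rows)) {
    warning("dropping ", sum(empty_rows), " all-zero row(s): ",
            paste(utils::head(rownames(a)[empty_rows], 5), collapse = ", "),
            call. = FALSE)
  }
  if (any(empty_cols)) {
    warning("dropping ", sum(empty_cols), " all-zero column(s): ",
            paste(utils::head(colnames(a)[empty_cols], 5), collapse = ", "),
            call. = FALSE)
  }
  a <- a[!empty_rows, !empty_cols, drop = FALSE]
  if (nrow(a) < 2L || ncol(a) < 2L) {
    stop("need at least two nonzero rows and columns to cluster",
         call. = FALSE)
  }
  rows <- average_linkage(similarity_to_distance(row_similarity(a)))
  cols <- average_linkage(similarity_to_distance(row_similarity(t(a))))
  structure(list(rows = rows, cols = cols, matrix = a),
            class = "chi_two_way")
}

#' @export
print.chi_two_way <- function(x, ...) {
  cat(sprintf("two-way clustering of a %d x %d matrix\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; the connected components that remain
#' are the clusters. Labels are assigned 1..k in dendrogram leaf order
#' (the cluster containing the leftmost leaf is cluster 1).
#'
#' @param dend a `"chi_dendrogram"`.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return A named integer vector: leaf label -> cluster in `1..k`.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$labels)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  # leaves under each merge node, built first to last
  leaves_of <- vector("list", n - 1L)
  child_leaves <- function(id) {
    if (id < 0L) -id else leaves_of[[id]]
  }
  for (s in seq_len(n - 1L)) {
    leaves_of[[s]] <- c(child_leaves(dend$merge[s, 1]),
                        child_leaves(dend$merge[s, 2]))
  }
  # apply the first n - k merges only; the rest stay undone
  leaf_cluster <- seq_len(n)
  if (n - k >= 1L) {
    for (s in seq_len(n - k)) {
      lv <- leaves_of[[s]]
      leaf_cluster[lv] <- min(leaf_cluster[lv])
    }
  }
  # relabel 1..k by first appearance in dendrogram leaf order
  ord <- dend$order
  lev <- unique(leaf_cluster[ord])
  out <- match(leaf_cluster, lev)
  names(out) <- dend$labels
  out
}
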