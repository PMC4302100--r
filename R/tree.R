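#' Pearson correlation distance between sample profiles
#'
#' Computes the dissimilarity d(i, j) = 1 - r(x_i, x_j), where r is the
#' Pearson correlation of the two sample rows. This is the conventional
#' correlation distance for expression profiles: 0 for perfectly
#' positively correlated samples, 2 for perfectly anti-correlated ones.
#'
#' @param X numeric matrix, samples in rows, features in columns; at least
#'   2 samples and 2 features, all entries finite, no sample constant
#'   across features.
#' @return a symmetric n x n numeric matrix with zero diagonal and entries
#'   in [0, 2]; row/column names are the sample names of \code{X}.
#' @examples
#' X <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("s", 1:4), NULL))
#' D <- pearsonDistance(X)
#' range(D)
#' @export
pearsonDistance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("need at least 2 samples and 2 features")
  if (any(!is.finite(X)))
    stop("molecular matrix contains non-finite entries")
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  v <- apply(X, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(rownames(X)[v == 0], collapse = ", "))
  D <- 1 - stats::cor(t(X))
  D[D < 0] <- 0           # guard against -1e-17 round-off
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

.checkDistanceMatrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(D < -1e-12)) stop("distance matrix entries must be nonnegative")
  if (is.null(rownames(D))) rownames(D) <- paste0("S", seq_len(nrow(D)))
  colnames(D) <- rownames(D)
  D
}

.linkageMethod <- function(linkage) {
  switch(linkage,
    ward     = "ward.D",   # Lance-Williams Ward update on the given d
    average  = "average",
    complete = "complete",
    single   = "single",
    stop("unknown linkage: ", linkage)
  )
}

.leafSetsFromMerge <- function(merge) {
  nm <- nrow(merge)
  ls <- vector("list", nm)
  for (i in seq_len(nm)) {
    s <- integer(0)
    for (k in merge[i, ]) s <- c(s, if (k < 0) -k else ls[[k]])
    ls[[i]] <- sort.int(s)
  }
  ls
}

#' Build a hierarchical clustering tree for snipping
#'
#' Runs standard agglomerative clustering (Lance-Williams updates via
#' \code{\link[stats]{hclust}}) on a sample dissimilarity matrix and wraps
#' the result as a \linkS4class{SnipTree}. Either a molecular matrix
#' \code{X} (Pearson distance is computed) or a precomputed distance matrix
#' may be supplied; the latter covers dissimilarities produced by external
#' tools (e.g. copy-number-specific distances).
#'
#' @param X optional samples x features numeric matrix.
#' @param distance optional precomputed square dissimilarity matrix or
#'   \code{dist} object (ignored when \code{X} is given).
#' @param linkage one of \code{"ward"} (minimum-variance; the default used
#'   throughout), \code{"average"}, \code{"complete"}, \code{"single"}.
#' @return a \linkS4class{SnipTree}.
#' @examples
#' sim <- simulateMixture(3, 8, 20, meanScale = 5, noiseSD = 1, seed = 1)
#' tr <- buildSnipTree(sim$X)
#' tr
#' @export
buildSnipTree <- function(X = NULL, distance = NULL,
                          linkage = c("ward", "average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!is.null(X)) {
    D <- pearsonDistance(X)
  } else if (!is.null(distance)) {
    D <- .checkDistanceMatrix(if (inherits(distance, "dist"))
      as.matrix(distance) else distance)
  } else stop("supply either X or distance")
  if (nrow(D) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::as.dist(D), method = .linkageMethod(linkage))
  merge <- hc$merge
  storage.mode(merge) <- "integer"
  new("SnipTree",
      merge = merge, height = hc$height, labels = rownames(D),
      dist = D, linkage = linkage,
      leafSets = .leafSetsFromMerge(merge))
}

#' @rdname treeAccessors
#' @name treeAccessors
#' @title SnipTree accessors
#' @description Accessors for \linkS4class{SnipTree} objects: number of
#'   leaves, sample identifiers, merge heights, the merge table, the
#'   attached distance matrix, and the valid node ids (negative = leaf,
#'   positive = merge row; the root is node \code{nLeaves(tree) - 1}).
#' @param tree a \linkS4class{SnipTree}
#' @export
nLeaves <- function(tree) length(tree@labels)

#' @rdname treeAccessors
#' @export
sampleIDs <- function(tree) tree@labels

#' @rdname treeAccessors
#' @export
treeHeights <- function(tree) tree@height

#' @rdname treeAccessors
#' @export
treeMerge <- function(tree) tree@merge

#' @rdname treeAccessors
#' @export
treeDist <- function(tree) tree@dist

#' @rdname treeAccessors
#' @export
treeNodes <- function(tree) c(-seq_len(nLeaves(tree)), seq_len(nLeaves(tree) - 1L))

#' Convert a SnipTree to the base hclust representation
#'
#' @param x a \linkS4class{SnipTree}
#' @return an object of class \code{hclust}
#' @export
asHclust <- function(x) {
  stopifnot(is(x, "SnipTree"))
  n <- nLeaves(x)
  # leaf order for plotting, by DFS
  ord <- integer(0)
  dfs <- function(node) {
    if (node < 0) ord <<- c(ord, -node)
    else { dfs(x@merge[node, 1]); dfs(x@merge[node, 2]) }
  }
  dfs(n - 1L)
  structure(
    list(merge = x@merge, height = x@height, order = ord,
         labels = x@labels, method = x@linkage, call = NULL,
         dist.method = NULL),
    class = "hclust")
}

.leafIdx <- function(tree, node) {
  if (node < 0) {
    if (-node > nLeaves(tree)) stop("unknown node id: ", node)
    -node
  } else {
    if (node > nLeaves(tree) - 1L || node == 0) stop("unknown node id: ", node)
    tree@leafSets[[node]]
  }
}

#' Leaves under a tree node
#'
#' Returns the exact set of sample identifiers in the subtree rooted at
#' \code{node}. Leaf sets are memoized at construction, so the call is
#' O(1) after the tree is built.
#'
#' @param tree a \linkS4class{SnipTree}
#' @param node a node id: negative leaf index or positive merge row
#' @return character vector of sample ids
#' @export
subtreeLeaves <- function(tree, node) {
  tree@labels[.leafIdx(tree, node)]
}

#' Check a partition for tree-consistency
#'
#' A partition is tree-consistent when every cluster equals the exact leaf
#' set of one node of the tree. Coverage violations (the partition does not
#' cover the tree's leaf set exactly) raise an error rather than returning
#' \code{FALSE}.
#'
#' @param tree a \linkS4class{SnipTree}
#' @param partition a \linkS4class{TreePartition}, or a per-sample label
#'   vector named by (or aligned with) the tree's sample ids
#' @return \code{TRUE} or \code{FALSE}
#' @export
isTreeConsistent <- function(tree, partition) {
  n <- nLeaves(tree)
  if (is(partition, "TreePartition")) {
    ids <- partition@sampleIDs
    lab <- partition@labels
  } else {
    lab <- partition
    ids <- if (!is.null(names(lab))) names(lab) else tree@labels
  }
  if (!setequal(ids, tree@labels) || length(ids) != n)
    stop("partition does not cover the tree's samples exactly")
  idx <- match(tree@labels, ids)
  lab <- lab[idx]
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n))
    assign(as.character(i), TRUE, envir = keys)
  for (s in tree@leafSets)
    assign(paste(s, collapse = ","), TRUE, envir = keys)
  for (cl in split(seq_len(n), lab)) {
    key <- paste(sort.int(cl), collapse = ",")
    if (!exists(key, envir = keys, inherits = FALSE)) return(FALSE)
  }
  TRUE
}
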