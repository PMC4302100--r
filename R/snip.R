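#' @title Search-space construction by piecewise snipping
#' @description
#' The search space of piecewise snipping is the complete set of
#' tree-consistent partitions: antichains of tree nodes whose leaf sets are
#' disjoint and cover all samples. Every cluster must contain at least
#' \code{minClusterSize} samples (default 4), which suppresses trivial
#' partitions made of tiny outlier clusters. The set is generated by the
#' product recurrence P(v) = \{leaves(v)\} + \{pL x pR\} over the two
#' child subtrees, with subtrees smaller than the minimum size contributing
#' no decomposable partitions.
#' @name snipSearchSpace
NULL

.nodeSizes <- function(tree) {
  c(rep(1L, nLeaves(tree)), lengths(tree@leafSets))
}

.sizeOf <- function(tree, node) {
  if (node < 0) 1L else length(tree@leafSets[[node]])
}

#' Count tree-consistent partitions without materializing them
#'
#' Evaluates the recurrence C(v) = [|leaves(v)| >= m] + C(left) * C(right)
#' bottom-up; the result equals \code{length(enumeratePartitions(...))}.
#' Balanced trees yield many more partitions than skewed ones.
#'
#' @param tree a \linkS4class{SnipTree}
#' @param minClusterSize minimum samples per cluster (>= 1)
#' @return a count (double, since counts can exceed integer range)
#' @export
countPartitions <- function(tree, minClusterSize = 4) {
  m <- as.integer(minClusterSize)
  n <- nLeaves(tree)
  if (m < 1 || m > n) stop("minClusterSize must be in 1..n")
  cLeaf <- as.numeric(1L >= m)
  cnt <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- tree@merge[i, ]
    cv <- vapply(kids, function(k) if (k < 0) cLeaf else cnt[k], numeric(1))
    cnt[i] <- as.numeric(length(tree@leafSets[[i]]) >= m) + cv[1] * cv[2]
  }
  cnt[n - 1L]
}

#' Enumerate the complete piecewise-snipping search space
#'
#' Generates every tree-consistent partition of the samples whose clusters
#' all have at least \code{minClusterSize} members. Partitions are returned
#' as integer node-id antichains (hclust convention: negative = leaf,
#' positive = merge row); per-sample label vectors are reconstructed on
#' demand with \code{\link{partitionLabels}}, keeping memory proportional
#' to the number of clusters rather than samples.
#'
#' The output is duplicate-free and deterministically ordered by cluster
#' count, then lexicographically by the sorted node ids.
#'
#' @param tree a \linkS4class{SnipTree}
#' @param minClusterSize minimum samples per cluster (default 4)
#' @param maxPartitions safety cap; if the projected count exceeds it an
#'   error advises a larger \code{minClusterSize}
#' @return list of integer vectors (node antichains), with attribute
#'   \code{"minClusterSize"}
#' @examples
#' sim <- simulateMixture(2, 4, 10, meanScale = 4, noiseSD = 1, seed = 3)
#' tr <- buildSnipTree(sim$X)
#' length(enumeratePartitions(tr, minClusterSize = 2))
#' @export
enumeratePartitions <- function(tree, minClusterSize = 4,
                                maxPartitions = 1e6) {
  m <- as.integer(minClusterSize)
  n <- nLeaves(tree)
  if (m < 1 || m > n) stop("minClusterSize must be in 1..n")
  total <- countPartitions(tree, m)
  if (total > maxPartitions)
    stop("search space has ", format(total, big.mark = ","),
         " partitions, exceeding maxPartitions = ", maxPartitions,
         "; raise minClusterSize to restrict the space (the minimum",
         " cluster size constraint excludes partitions with tiny clusters)")
  memo <- vector("list", n - 1L)
  enumNode <- function(node) {
    if (node < 0) {
      return(if (m <= 1L) list(node) else list())
    }
    if (!is.null(memo[[node]])) return(memo[[node]])
    res <- list()
    if (length(tree@leafSets[[node]]) >= m) res <- list(node)
    L <- enumNode(tree@merge[node, 1])
    R <- enumNode(tree@merge[node, 2])
    if (length(L) && length(R)) {
      cross <- vector("list", length(L) * length(R))
      idx <- 1L
      for (l in L) for (r in R) {
        cross[[idx]] <- c(l, r)
        idx <- idx + 1L
      }
      res <- c(res, cross)
    }
    memo[[node]] <<- res
    res
  }
  parts <- enumNode(n - 1L)
  parts <- lapply(parts, sort.int)
  keys <- vapply(parts, paste, character(1), collapse = ",")
  ord <- order(lengths(parts), keys, method = "radix")
  parts <- parts[ord]
  attr(parts, "minClusterSize") <- m
  parts
}

#' Per-sample cluster labels for a node antichain
#'
#' Reconstructs the label vector of a partition stored as a node-id
#' antichain. Clusters are numbered 1..k by the smallest leaf index they
#' contain, so labels are deterministic.
#'
#' @param tree a \linkS4class{SnipTree}
#' @param nodes integer node antichain (or a \linkS4class{TreePartition})
#' @return integer labels named by sample id
#' @export
partitionLabels <- function(tree, nodes) {
  if (is(nodes, "TreePartition"))
    return(stats::setNames(nodes@labels, nodes@sampleIDs))
  n <- nLeaves(tree)
  lab <- integer(n)
  firsts <- integer(length(nodes))
  for (j in seq_along(nodes)) {
    idx <- .leafIdx(tree, nodes[j])
    if (any(lab[idx] != 0L)) stop("nodes overlap; not an antichain")
    lab[idx] <- j
    firsts[j] <- idx[1]
  }
  if (any(lab == 0L)) stop("node set does not cover all samples")
  relabel <- match(seq_along(nodes), order(firsts))
  stats::setNames(relabel[lab], tree@labels)
}

#' Wrap a node antichain as a TreePartition
#'
#' @param tree a \linkS4class{SnipTree}
#' @param nodes integer node antichain
#' @return a \linkS4class{TreePartition}
#' @export
asTreePartition <- function(tree, nodes) {
  lab <- partitionLabels(tree, nodes)
  firsts <- vapply(seq_along(nodes),
                   function(j) .leafIdx(tree, nodes[j])[1], integer(1))
  new("TreePartition", nodes = as.integer(nodes[order(firsts)]),
      labels = as.integer(lab), sampleIDs = names(lab))
}

#' Fixed-height-cut search space
#'
#' Cuts the tree with a horizontal line at every threshold strictly between
#' consecutive distinct merge heights (plus below all merges and above all
#' merges), de-duplicates the resulting partitions, and filters by the
#' minimum cluster size. The result is always a subset of the piecewise
#' search space of \code{\link{enumeratePartitions}}.
#'
#' @inheritParams enumeratePartitions
#' @return list of integer node antichains, ordered from coarse to fine
#' @export
fixedHeightPartitions <- function(tree, minClusterSize = 4) {
  m <- as.integer(minClusterSize)
  n <- nLeaves(tree)
  if (m < 1 || m > n) stop("minClusterSize must be in 1..n")
  h <- tree@height
  hs <- sort(unique(h))
  thr <- c(hs[1] - 1,
           if (length(hs) > 1) (hs[-1] + hs[-length(hs)]) / 2,
           hs[length(hs)] + 1)
  # parent height of every node (root gets +Inf)
  parentH <- rep(Inf, 2L * n - 1L)          # index: leaf i, merge n+j
  for (i in seq_len(n - 1L)) {
    for (k in tree@merge[i, ]) {
      idx <- if (k < 0) -k else n + k
      parentH[idx] <- h[i]
    }
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (t in thr) {
    nodes <- c(-(which(parentH[seq_len(n)] > t)),
               which(h <= t & parentH[(n + 1L):(2L * n - 1L)] > t))
    nodes <- sort.int(as.integer(nodes))
    sizes <- vapply(nodes, function(v) .sizeOf(tree, v), integer(1))
    if (any(sizes < m)) next
    key <- paste(nodes, collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <- nodes
    }
  }
  out <- rev(out)   # coarse (above-all cut) first
  attr(out, "minClusterSize") <- m
  out
}
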