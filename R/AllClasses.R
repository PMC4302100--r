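#' @import methods
NULL

#' Hierarchical clustering tree prepared for snipping
#'
#' An agglomerative clustering tree in \code{\link[stats]{hclust}} merge
#' encoding (negative entries are leaves, positive entries earlier merge
#' rows), carrying the sample dissimilarity matrix it was built from and a
#' memoized leaf-set table so that subtree queries are O(1).
#'
#' @slot merge integer matrix, (n-1) x 2, hclust merge encoding.
#' @slot height numeric, nondecreasing merge heights.
#' @slot labels character, unique sample identifiers in leaf order.
#' @slot dist numeric matrix, n x n symmetric dissimilarities (may be a
#'   0 x 0 matrix for trees deserialized without their distances).
#' @slot linkage character, the linkage used ("ward", "average",
#'   "complete" or "single").
#' @slot leafSets list of integer vectors, leaf indices under each merge
#'   node, in merge order.
#'
#' @seealso \code{\link{buildSnipTree}}, \code{\link{subtreeLeaves}},
#'   \code{\link{enumeratePartitions}}
#' @export
setClass("SnipTree",
  representation(
    merge    = "matrix",
    height   = "numeric",
    labels   = "character",
    dist     = "matrix",
    linkage  = "character",
    leafSets = "list"
  )
)

setValidity("SnipTree", function(object) {
  n <- length(object@labels)
  m <- object@merge
  msgs <- character(0)
  if (n < 2) msgs <- c(msgs, "a tree needs at least 2 leaves")
  if (!is.matrix(m) || nrow(m) != n - 1L || ncol(m) != 2L)
    msgs <- c(msgs, "merge must be an (n-1) x 2 matrix")
  if (length(object@height) != n - 1L)
    msgs <- c(msgs, "height must have n-1 entries")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "sample labels must be unique")
  if (length(msgs) == 0L) {
    kids <- as.integer(m)
    expected <- c(-(seq_len(n)), seq_len(nrow(m) - 1L))
    if (!setequal(kids, expected) || anyDuplicated(kids))
      msgs <- c(msgs, "every node except the root must appear as a child exactly once")
    if (any(m > 0 & m >= row(m)))
      msgs <- c(msgs, "positive merge entries must reference earlier rows")
    if (is.unsorted(object@height + 1e-8 * cummax(abs(object@height) + 1)))
      msgs <- c(msgs, "merge heights must be nondecreasing")
    if (length(object@leafSets) != n - 1L)
      msgs <- c(msgs, "leafSets must have one entry per merge")
  }
  d <- object@dist
  if (length(d) > 0L) {
    if (nrow(d) != n || ncol(d) != n)
      msgs <- c(msgs, "dist must be n x n")
    else {
      if (any(!is.finite(d))) msgs <- c(msgs, "dist entries must be finite")
      else {
        if (max(abs(d - t(d))) > 1e-8) msgs <- c(msgs, "dist must be symmetric")
        if (any(abs(diag(d)) > 1e-12)) msgs <- c(msgs, "dist diagonal must be zero")
        if (any(d < -1e-12)) msgs <- c(msgs, "dist entries must be nonnegative")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Tree-consistent partition of the samples
#'
#' A partition in which every cluster is the exact leaf set of one node of a
#' \linkS4class{SnipTree} (an antichain of nodes covering all leaves).
#' Node ids follow the hclust convention: negative for leaves, positive for
#' merge rows.
#'
#' @slot nodes integer, the node antichain (one id per cluster).
#' @slot labels integer, per-sample cluster index in 1..k, aligned with
#'   \code{sampleIDs}.
#' @slot sampleIDs character, sample identifiers.
#'
#' @seealso \code{\link{selectOptimal}}, \code{\link{partitionLabels}}
#' @export
setClass("TreePartition",
  representation(
    nodes     = "integer",
    labels    = "integer",
    sampleIDs = "character"
  )
)

setValidity("TreePartition", function(object) {
  msgs <- character(0)
  if (length(object@labels) != length(object@sampleIDs))
    msgs <- c(msgs, "labels and sampleIDs must have equal length")
  k <- length(object@nodes)
  if (k > 0 && !setequal(unique(object@labels), seq_len(k)))
    msgs <- c(msgs, "labels must use each cluster index 1..k at least once")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SnipTree-class compact display
#' @param object a \code{SnipTree}
#' @export
setMethod("show", "SnipTree", function(object) {
  cat("SnipTree with", length(object@labels), "leaves (linkage:",
      object@linkage, ")\n")
  cat("  merge heights: [", format(min(object@height), digits = 4), ", ",
      format(max(object@height), digits = 4), "]\n", sep = "")
  cat("  distance matrix:",
      if (length(object@dist)) "attached" else "absent", "\n")
})

#' @describeIn TreePartition-class compact display
#' @param object a \code{TreePartition}
#' @export
setMethod("show", "TreePartition", function(object) {
  sz <- tabulate(object@labels, nbins = length(object@nodes))
  cat("TreePartition:", length(object@nodes), "clusters over",
      length(object@sampleIDs), "samples\n")
  cat("  cluster sizes:", paste(sz, collapse = ", "), "\n")
})
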