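.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a samples x features molecular matrix
#'
#' Expects a header row of feature names and sample identifiers in the
#' first column; tab-separated unless the file ends in \code{.csv}.
#'
#' @param path file path
#' @return numeric matrix with sample ids as row names
#' @export
readMolecularMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
                          row.names = 1, check.names = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("molecular matrix must be numeric")
  X
}

#' Read a square sample-sample distance matrix
#'
#' Row and column identifiers must match.
#'
#' @param path file path
#' @return validated symmetric numeric matrix
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
                          row.names = 1, check.names = FALSE)
  D <- as.matrix(df)
  if (!identical(rownames(D), colnames(D)))
    stop("distance matrix row and column ids differ")
  .checkDistanceMatrix(D)
}

#' Read a clinical table with time-to-event follow-up
#'
#' Sample identifiers in the first column; follow-up time and 0/1 event
#' status in the columns named by \code{timeCol} and \code{eventCol}.
#'
#' @param path file path
#' @param timeCol,eventCol column names (defaults \code{"time"},
#'   \code{"status"})
#' @return data.frame with columns \code{time}, \code{event}; sample ids
#'   as row names
#' @export
readClinicalTable <- function(path, timeCol = "time", eventCol = "status") {
  df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
                          row.names = 1, check.names = FALSE)
  if (!all(c(timeCol, eventCol) %in% colnames(df)))
    stop("clinical table lacks columns '", timeCol, "' / '", eventCol, "'")
  out <- data.frame(time = as.numeric(df[[timeCol]]),
                    event = as.integer(df[[eventCol]]),
                    row.names = rownames(df))
  .checkSurvival(out$time, out$event)
  out
}

#' @rdname partitionIO
#' @name partitionIO
#' @title Partition and dendrogram serialization
#' @description Writers and readers for the package's plain-text formats:
#'   partitions as two-column TSV (sample_id, cluster_label), search spaces
#'   as a JSON list of node antichains, dendrograms as a four-column merge
#'   table (left, right, height, size) in merge order with children encoded
#'   as negative leaf indices / positive merge row indices, and scores
#'   tables as TSV. All round-trip losslessly.
#' @param labels named per-sample cluster labels (or a
#'   \linkS4class{TreePartition})
#' @param path file path
#' @export
writePartitionTSV <- function(labels, path) {
  if (is(labels, "TreePartition"))
    labels <- stats::setNames(labels@labels, labels@sampleIDs)
  df <- data.frame(sample_id = names(labels),
                   cluster_label = as.integer(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname partitionIO
#' @export
readPartitionTSV <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stats::setNames(as.integer(df$cluster_label), df$sample_id)
}

#' @rdname partitionIO
#' @param partitions list of integer node antichains
#' @export
writePartitionsJSON <- function(partitions, path) {
  jsonlite::write_json(lapply(partitions, as.integer), path)
  invisible(path)
}

#' @rdname partitionIO
#' @export
readPartitionsJSON <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = FALSE),
         function(p) as.integer(unlist(p)))
}

#' @rdname partitionIO
#' @param tree a \linkS4class{SnipTree}
#' @export
writeDendrogramTSV <- function(tree, path) {
  df <- data.frame(left = tree@merge[, 1], right = tree@merge[, 2],
                   height = tree@height,
                   size = lengths(tree@leafSets))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname partitionIO
#' @param labels2 leaf labels for the reconstructed tree (defaults to
#'   S1..Sn); the merge-table format itself does not carry them
#' @export
readDendrogramTSV <- function(path, labels2 = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  merge <- cbind(as.integer(df$left), as.integer(df$right))
  n <- nrow(merge) + 1L
  if (is.null(labels2)) labels2 <- paste0("S", seq_len(n))
  new("SnipTree", merge = merge, height = as.numeric(df$height),
      labels = labels2, dist = matrix(numeric(0), 0, 0),
      linkage = "ward", leafSets = .leafSetsFromMerge(merge))
}

#' @rdname partitionIO
#' @param scores scores data.frame (from \code{\link{selectOptimal}})
#' @export
writeScoresTSV <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' End-to-end snipping run with file input and output
#'
#' Reads a molecular matrix (or a precomputed distance matrix) and,
#' optionally, a clinical table; builds the tree, enumerates the requested
#' search space, selects the optimal partition, and writes
#' \code{partition.tsv}, \code{scores.tsv} and \code{metadata.json} to
#' \code{outDir}. Sample-id join between molecular and clinical tables is
#' strict: any id present in one input but not the other is an error. The
#' run is fully reproducible (and byte-identical) given the same inputs
#' and configuration.
#'
#' @param molecularFile,distanceFile exactly one must be given
#' @param clinicalFile required when \code{guided = TRUE}
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   writing
#' @param guided,measureM,criterionS,minClusterSize,linkage see
#'   \code{\link{selectOptimal}} / \code{\link{enumeratePartitions}}
#' @param searchSpace \code{"piecewise"} or \code{"fixed_height"}
#' @param timeCol,eventCol clinical column names
#' @return (invisibly) list with the tree, the selection result and the
#'   metadata record
#' @export
runSnip <- function(molecularFile = NULL, distanceFile = NULL,
                    clinicalFile = NULL, outDir = NULL,
                    guided = !is.null(clinicalFile),
                    searchSpace = c("piecewise", "fixed_height"),
                    measureM = "wss", criterionS = "aic",
                    minClusterSize = 4, linkage = "ward",
                    timeCol = "time", eventCol = "status") {
  searchSpace <- match.arg(searchSpace)
  if (is.null(molecularFile) == is.null(distanceFile))
    stop("supply exactly one of molecularFile / distanceFile")
  if (guided && is.null(clinicalFile))
    stop("guided mode requires a clinical file")
  tree <- if (!is.null(molecularFile))
    buildSnipTree(X = readMolecularMatrix(molecularFile), linkage = linkage)
  else
    buildSnipTree(distance = readDistanceMatrix(distanceFile),
                  linkage = linkage)
  surv <- NULL
  if (!is.null(clinicalFile)) {
    clin <- readClinicalTable(clinicalFile, timeCol, eventCol)
    missingClin <- setdiff(sampleIDs(tree), rownames(clin))
    missingMol <- setdiff(rownames(clin), sampleIDs(tree))
    if (length(missingClin) || length(missingMol))
      stop("sample id mismatch between molecular and clinical tables; ",
           "missing from clinical: ",
           paste(missingClin, collapse = ", "),
           "; missing from molecular: ",
           paste(missingMol, collapse = ", "))
    surv <- clin[sampleIDs(tree), ]
  }
  parts <- if (searchSpace == "piecewise")
    enumeratePartitions(tree, minClusterSize)
  else fixedHeightPartitions(tree, minClusterSize)
  sel <- selectOptimal(tree, parts,
                       time = if (guided) surv$time else NULL,
                       event = if (guided) surv$event else NULL,
                       measureM = measureM, criterionS = criterionS,
                       guided = guided)
  meta <- list(package = "dendrosnip",
               version = as.character(utils::packageVersion("dendrosnip")),
               guided = guided, searchSpace = searchSpace,
               measureM = measureM,
               criterionS = if (guided) criterionS else NULL,
               minClusterSize = minClusterSize, linkage = linkage,
               n_samples = nLeaves(tree),
               n_candidates = length(parts),
               n_clusters = length(sel$partition@nodes),
               inputs = list(molecular = molecularFile,
                             distance = distanceFile,
                             clinical = clinicalFile))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePartitionTSV(sel$partition, file.path(outDir, "partition.tsv"))
    writeScoresTSV(sel$scores, file.path(outDir, "scores.tsv"))
    jsonlite::write_json(meta, file.path(outDir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(tree = tree, selection = sel, metadata = meta))
}
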