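#' Simulate expression data from a Gaussian mixture of clusters
#'
#' Each cluster gets a mean vector with entries i.i.d. Normal(0,
#' meanScale^2); samples are the cluster mean plus i.i.d. Normal(0,
#' noiseSD^2) noise. The ratio noiseSD / meanScale controls cluster
#' heterogeneity (component overlap): small ratios give well-separated,
#' homogeneous clusters.
#'
#' @param nClusters number of mixture components
#' @param nPerCluster samples per component
#' @param nFeatures feature dimension
#' @param meanScale standard deviation of the cluster-mean entries
#' @param noiseSD within-cluster standard deviation
#' @param seed optional integer seed
#' @return list with \code{X} (samples x features matrix, rows
#'   "s1", "s2", ...) and \code{labels} (integer, true cluster per sample)
#' @export
simulateMixture <- function(nClusters, nPerCluster, nFeatures,
                            meanScale = 1, noiseSD = 1, seed = NULL) {
  if (nClusters < 1 || nPerCluster < 1 || nFeatures < 1)
    stop("degenerate dimensions")
  if (!is.null(seed)) set.seed(seed)
  mu <- matrix(stats::rnorm(nClusters * nFeatures, 0, meanScale),
               nClusters, nFeatures)
  labels <- rep(seq_len(nClusters), each = nPerCluster)
  n <- length(labels)
  X <- mu[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * nFeatures, 0, noiseSD), n, nFeatures)
  dimnames(X) <- list(paste0("s", seq_len(n)),
                      paste0("f", seq_len(nFeatures)))
  list(X = X, labels = labels)
}

#' Simulate cluster-linked exponential survival
#'
#' Event times are exponential with per-cluster rate baseRate *
#' hazardRatio; censoring times are independent exponentials with
#' per-cluster rate r/(1-r) times the event rate, so the expected censored
#' fraction equals \code{censorRate} exactly under the model.
#'
#' @param labels per-sample cluster labels (values 1..k)
#' @param hazardRatios one positive multiplicative hazard per cluster
#' @param censorRate expected censored fraction, in [0, 1)
#' @param baseRate baseline event rate (default 0.1; time unit arbitrary)
#' @param seed optional integer seed
#' @return list with \code{time} and \code{event} (1 = event, 0 = censored)
#' @export
simulateSurvival <- function(labels, hazardRatios, censorRate = 0,
                             baseRate = 0.1, seed = NULL) {
  k <- length(unique(labels))
  if (length(hazardRatios) != k)
    stop("need one hazard ratio per cluster")
  if (any(hazardRatios <= 0)) stop("hazard ratios must be positive")
  if (censorRate < 0 || censorRate >= 1) stop("censorRate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  lam <- baseRate * hazardRatios[match(labels, sort(unique(labels)))]
  tEvent <- stats::rexp(length(labels), rate = lam)
  if (censorRate > 0) {
    mu <- censorRate / (1 - censorRate) * lam
    tCens <- stats::rexp(length(labels), rate = mu)
  } else tCens <- rep(Inf, length(labels))
  list(time = pmin(tEvent, tCens), event = as.integer(tEvent <= tCens))
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' computed from the contingency table under the permutation model.
#' Equals 1 iff the partitions are identical up to relabeling. Degenerate
#' cases with a zero adjustment denominator (e.g. both partitions trivial)
#' return 1 when the partitions coincide and 0 otherwise.
#'
#' @param a,b label vectors of equal length >= 2 (any type)
#' @return scalar in [-1, 1]
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 samples")
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  denom <- (sumA + sumB) / 2 - expected
  if (denom == 0) {
    samePartition <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    return(if (samePartition) 1 else 0)
  }
  (sumij - expected) / denom
}

#' Simulation scenario presets
#'
#' Three heterogeneity presets mirror Gaussian-mixture scenarios with
#' increasing component overlap: \code{"low"} (meanScale/noiseSD = 5,
#' near-perfect separation), \code{"medium"} (1.2, partial overlap) and
#' \code{"high"} (0.5, heavy overlap); all use 4 clusters of 25 samples and
#' 50 features. The \code{"nested"} preset (see
#' \code{\link{simulateNested}}) plants two survival-distinct 25-sample
#' subclusters deep inside one molecular supercluster, next to a
#' block-structured background supercluster, with exponential hazard rates
#' proportional to (1, 8, 2) for (subcluster 1, subcluster 2, background)
#' and 20\% censoring: every fixed-height cut merges the two subclusters
#' while guided piecewise snipping can split them.
#'
#' @param name one of \code{"low"}, \code{"medium"}, \code{"high"},
#'   \code{"nested"}
#' @return a list of generator settings (class \code{"scenarioConfig"})
#' @export
scenarioPreset <- function(name = c("low", "medium", "high", "nested")) {
  name <- match.arg(name)
  cfg <- switch(name,
    low    = list(nClusters = 4, nPerCluster = 25, nFeatures = 50,
                  meanScale = 5,   noiseSD = 1,
                  hazardRatios = c(1, 1, 1, 1), censorRate = 0.2),
    medium = list(nClusters = 4, nPerCluster = 25, nFeatures = 50,
                  meanScale = 1.2, noiseSD = 1,
                  hazardRatios = c(1, 1, 1, 1), censorRate = 0.2),
    high   = list(nClusters = 4, nPerCluster = 25, nFeatures = 50,
                  meanScale = 0.5, noiseSD = 1,
                  hazardRatios = c(1, 1, 1, 1), censorRate = 0.2),
    nested = list(nPerGroup = 25, nFeatures = 100, superScale = 5,
                  subScale = 0.9, nBlocks = 16, blockSize = 3,
                  blockScale = 4, noiseSD = 1,
                  hazardRatios = c(1, 8, 2), censorRate = 0.2))
  cfg$scenario <- name
  class(cfg) <- "scenarioConfig"
  cfg
}

#' Simulate the nested (deep subcluster) scenario
#'
#' Emulates survival-distinct subclusters hidden deep in one branch of the
#' tree. One molecular supercluster holds two subclusters of
#' \code{nPerGroup} samples whose means differ only by a small offset (sd
#' \code{subScale}) around the shared supercluster mean, so under Ward
#' linkage they merge at a low height. A second, background supercluster
#' consists of \code{nBlocks} tight blocks of \code{blockSize} samples
#' whose block means are widely spread (sd \code{blockScale}) around the
#' background mean: every block-level merge towers above the subcluster
#' split, so any horizontal cut low enough to separate the two subclusters
#' fragments the background into blocks smaller than the usual minimum
#' cluster size of 4 — the fixed-height search space is then forced to
#' merge the survival-distinct pair, while piecewise snipping can snip it.
#'
#' True labels distinguish three groups: subcluster 1, subcluster 2, and
#' the background supercluster.
#'
#' @param nPerGroup samples per subcluster
#' @param nFeatures feature dimension
#' @param superScale sd of supercluster mean entries
#' @param subScale sd of the subcluster mean offsets
#' @param nBlocks,blockSize,blockScale background substructure: number of
#'   blocks, samples per block, sd of block-mean offsets
#' @param noiseSD within-cluster sd
#' @param seed optional integer seed
#' @return list with \code{X}, \code{labels} (1, 2, 3) and
#'   \code{superLabels} (1 = subcluster supercluster, 2 = background)
#' @export
simulateNested <- function(nPerGroup = 25, nFeatures = 100, superScale = 5,
                           subScale = 0.9, nBlocks = 16, blockSize = 3,
                           blockScale = 4, noiseSD = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  muA <- stats::rnorm(nFeatures, 0, superScale)
  muB <- stats::rnorm(nFeatures, 0, superScale)
  mu1 <- muA + stats::rnorm(nFeatures, 0, subScale)
  mu2 <- muA + stats::rnorm(nFeatures, 0, subScale)
  blockMu <- t(vapply(seq_len(nBlocks),
                      function(i) muB + stats::rnorm(nFeatures, 0, blockScale),
                      numeric(nFeatures)))
  nB <- nBlocks * blockSize
  labels <- rep(c(1L, 2L, 3L), times = c(nPerGroup, nPerGroup, nB))
  XA <- rbind(matrix(rep(mu1, each = nPerGroup), nPerGroup),
              matrix(rep(mu2, each = nPerGroup), nPerGroup))
  XB <- blockMu[rep(seq_len(nBlocks), each = blockSize), , drop = FALSE]
  X <- rbind(XA, XB) +
    matrix(stats::rnorm(length(labels) * nFeatures, 0, noiseSD),
           length(labels), nFeatures)
  dimnames(X) <- list(paste0("s", seq_along(labels)),
                      paste0("f", seq_len(nFeatures)))
  list(X = X, labels = labels, superLabels = ifelse(labels == 3L, 2L, 1L))
}

#' Run one simulation scenario and compare snipping to fixed-height cutting
#'
#' Simulates a data set from the preset (or an explicit configuration
#' list), builds the Pearson/Ward tree, selects the unguided WSS-optimal
#' partition from both the piecewise and the fixed-height search space,
#' and returns the Adjusted Rand Index of each against the planted labels.
#'
#' @param scenario a preset name or a \code{scenarioConfig} from
#'   \code{\link{scenarioPreset}}
#' @param minClusterSize minimum cluster size (default 4)
#' @param seed integer seed (drives the simulation)
#' @return named numeric: \code{ari_piecewise}, \code{ari_fixed_height}
#' @examples
#' runScenario("low", seed = 1)
#' @export
runScenario <- function(scenario = "low", minClusterSize = 4, seed = NULL) {
  cfg <- if (inherits(scenario, "scenarioConfig")) scenario
         else scenarioPreset(scenario)
  sim <- if (cfg$scenario == "nested")
    simulateNested(cfg$nPerGroup, cfg$nFeatures, cfg$superScale,
                   cfg$subScale, cfg$nBlocks, cfg$blockSize,
                   cfg$blockScale, cfg$noiseSD, seed = seed)
  else
    simulateMixture(cfg$nClusters, cfg$nPerCluster, cfg$nFeatures,
                    cfg$meanScale, cfg$noiseSD, seed = seed)
  tr <- buildSnipTree(sim$X)
  m <- min(minClusterSize, nLeaves(tr))
  pw <- selectOptimal(tr, enumeratePartitions(tr, m), guided = FALSE,
                      measureM = "wss")
  fh <- selectOptimal(tr, fixedHeightPartitions(tr, m), guided = FALSE,
                      measureM = "wss")
  c(ari_piecewise =
      adjustedRandIndex(sim$labels, partitionLabels(tr, pw$partition)),
    ari_fixed_height =
      adjustedRandIndex(sim$labels, partitionLabels(tr, fh$partition)))
}
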