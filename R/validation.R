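#' Cross-validation fold construction
#'
#' Splits samples 1..n into k disjoint test folds of sizes differing by at
#' most one, so every sample is a test sample exactly once.
#'
#' @param n sample count
#' @param k number of folds (default 3)
#' @param seed optional integer seed for reproducible folds
#' @return list of k sorted integer index vectors
#' @export
cvSplits <- function(n, k = 3, seed = NULL) {
  if (n < k || k < 2) stop("need n >= k >= 2")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  folds <- split(perm, rep(seq_len(k), times = sizes))
  lapply(unname(folds), sort.int)
}

#' @importFrom MASS ginv
NULL

#' k-sample log-rank test
#'
#' Standard log-rank test of survival-curve equality across clusters:
#' observed-minus-expected event counts over the pooled risk sets with the
#' hypergeometric covariance, chi-square with k-1 degrees of freedom.
#'
#' @param labels per-sample cluster labels (at least 2 nonempty groups)
#' @param time follow-up times
#' @param event event indicators (at least one event overall)
#' @return list with \code{statistic}, \code{df}, \code{p.value}
#' @export
logrankTest <- function(labels, time, event) {
  .checkSurvival(time, event, length(labels))
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least 2 nonempty groups")
  if (sum(event) < 1) stop("need at least one observed event")
  k <- nlevels(f)
  chisq <- tryCatch(unname(survdiff(Surv(time, event) ~ f)$chisq),
                    error = function(e) NULL)
  if (is.null(chisq)) {
    # degenerate risk sets (e.g. all records identical) make the
    # hypergeometric covariance singular; fall back to a generalized
    # inverse of the observed-minus-expected quadratic form
    O <- E <- rep(0, k)
    V <- matrix(0, k, k)
    for (t in sort(unique(time[event == 1]))) {
      atRisk <- time >= t
      nj <- vapply(levels(f), function(g) sum(atRisk & f == g), numeric(1))
      dj <- vapply(levels(f),
                   function(g) sum(time == t & event == 1 & f == g),
                   numeric(1))
      nTot <- sum(nj); dTot <- sum(dj)
      O <- O + dj
      E <- E + dTot * nj / nTot
      if (nTot > 1)
        V <- V + dTot * (nTot - dTot) / (nTot - 1) *
          (diag(nj / nTot, k) - tcrossprod(nj / nTot))
    }
    x <- (O - E)[-k]
    chisq <- drop(t(x) %*% MASS::ginv(V[-k, -k, drop = FALSE]) %*% x)
  }
  df <- k - 1L
  list(statistic = chisq, df = df,
       p.value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Cross-validated evaluation of tree snipping
#'
#' For each of \code{folds} splits, rebuilds the clustering tree on the
#' training samples only, enumerates the chosen search space, selects the
#' optimal training partition (guided by training survival or unguided),
#' assigns the held-out test samples to clusters using molecular data only
#' (plus training follow-up for the PNNC method), and log-rank-tests the
#' test assignments against the test samples' survival. Test survival is
#' used exclusively in that final test. A split whose test assignment
#' occupies fewer than 2 clusters contributes p = 1 with a warning. The
#' median of the per-split p-values is the summary measure of significance.
#'
#' @param D full sample dissimilarity matrix
#' @param time,event follow-up data for all samples
#' @param minClusterSize minimum cluster size in the training search space
#' @param folds number of CV folds (default 3)
#' @param searchSpace \code{"piecewise"} or \code{"fixed_height"}
#' @param guided guide training selection by survival?
#' @param measureM,criterionS see \code{\link{selectOptimal}}
#' @param assignMethod \code{"ward"} or \code{"pnnc"}
#' @param linkage linkage for the training trees
#' @param seed optional seed (controls fold membership)
#' @param kNN,kFU PNNC parameters
#' @return list with \code{p.values} (length \code{folds}),
#'   \code{median.p}, and \code{splits} (per-split details)
#' @examples
#' sim <- simulateMixture(3, 10, 30, meanScale = 5, noiseSD = 1, seed = 11)
#' sv <- simulateSurvival(sim$labels, c(1, 2, 6), censorRate = 0.2, seed = 12)
#' res <- runCV(pearsonDistance(sim$X), sv$time, sv$event,
#'              minClusterSize = 4, seed = 5)
#' res$median.p
#' @export
runCV <- function(D, time, event, minClusterSize = 4, folds = 3,
                  searchSpace = c("piecewise", "fixed_height"),
                  guided = TRUE,
                  measureM = c("wss", "cindex", "gk"),
                  criterionS = c("aic", "bic", "bic_events"),
                  assignMethod = c("ward", "pnnc"),
                  linkage = "ward", seed = NULL, kNN = 5, kFU = 2) {
  searchSpace <- match.arg(searchSpace)
  measureM <- match.arg(measureM)
  criterionS <- match.arg(criterionS)
  assignMethod <- match.arg(assignMethod)
  D <- .checkDistanceMatrix(D)
  n <- nrow(D)
  .checkSurvival(time, event, n)
  testSets <- cvSplits(n, folds, seed)
  pvals <- numeric(folds)
  details <- vector("list", folds)
  for (s in seq_len(folds)) {
    test <- testSets[[s]]
    train <- setdiff(seq_len(n), test)
    tr <- buildSnipTree(distance = D[train, train], linkage = linkage)
    parts <- if (searchSpace == "piecewise")
      enumeratePartitions(tr, minClusterSize)
    else fixedHeightPartitions(tr, minClusterSize)
    sel <- selectOptimal(tr, parts,
                         time = if (guided) time[train] else NULL,
                         event = if (guided) event[train] else NULL,
                         measureM = measureM, criterionS = criterionS,
                         guided = guided)
    labTrain <- partitionLabels(tr, sel$partition)
    # align labels to the row order of D[train, train]
    labTrain <- labTrain[rownames(D)[train]]
    assigned <- assignSamples(D[test, train, drop = FALSE],
                              labels = as.integer(labTrain),
                              D = D[train, train],
                              time = time[train], event = event[train],
                              method = assignMethod, kNN = kNN, kFU = kFU)
    if (length(unique(assigned)) < 2) {
      warning("split ", s, ": test assignment occupies < 2 clusters; p = 1")
      pvals[s] <- 1
      lr <- NULL
    } else {
      lr <- logrankTest(assigned, time[test], event[test])
      pvals[s] <- lr$p.value
    }
    details[[s]] <- list(test = test,
                         n_clusters = length(sel$partition@nodes),
                         assigned = assigned, logrank = lr)
  }
  list(p.values = pvals, median.p = stats::median(pvals), splits = details)
}
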