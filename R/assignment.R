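#' Distances from new samples to a training set
#'
#' Pearson correlation distances (1 - r) between each test profile and each
#' training profile, for use with \code{\link{wardAssign}} and
#' \code{\link{pnncAssign}}.
#'
#' @param Xtest test samples x features matrix (same features as training)
#' @param Xtrain training samples x features matrix
#' @return matrix, test samples in rows, training samples in columns
#' @export
crossDistance <- function(Xtest, Xtrain) {
  Xtest <- rbind(Xtest)  # keep a single profile a matrix
  if (ncol(Xtest) != ncol(Xtrain)) stop("feature mismatch")
  d <- 1 - stats::cor(t(Xtest), t(Xtrain))
  d[d < 0] <- 0
  rownames(d) <- rownames(Xtest)
  colnames(d) <- rownames(Xtrain)
  d
}

#' Assign a test sample to a cluster by Ward merge cost
#'
#' Computes, for every cluster C of the training partition, the Ward
#' increment of merging the singleton test sample into C,
#' \deqn{\Delta = \frac{|C|}{|C|+1}\Big[\frac{1}{|C|}\sum_{i \in C}
#'   d(s,i)^2 - \frac{1}{2|C|^2}\sum_{i,j \in C} d(i,j)^2\Big],}
#' and returns the cluster minimizing it. For Euclidean distances this is
#' exactly \eqn{|C|/(|C|+1)\,\|x_s - c_C\|^2} with \eqn{c_C} the centroid.
#' Ties go to the smaller cluster index.
#'
#' @param dTest distances from the test sample to the training samples
#' @param labels training cluster labels (integer 1..k), aligned with
#'   \code{dTest} and \code{D}
#' @param D training dissimilarity matrix
#' @return the assigned cluster index, with attribute \code{"cost"}
#'   holding all per-cluster Ward increments
#' @export
wardAssign <- function(dTest, labels, D) {
  D <- as.matrix(D)
  if (length(dTest) != nrow(D) || length(labels) != nrow(D))
    stop("dTest, labels and D must cover the same training samples")
  if (any(!is.finite(dTest))) stop("non-finite test distances")
  cl <- sort(unique(labels))
  cost <- vapply(cl, function(g) {
    idx <- which(labels == g)
    if (length(idx) == 0L) stop("empty cluster")
    a <- mean(dTest[idx]^2)
    b <- sum(D[idx, idx]^2) / (2 * length(idx)^2)
    (length(idx) / (length(idx) + 1)) * (a - b)
  }, numeric(1))
  ans <- cl[which.min(cost)]
  attr(ans, "cost") <- stats::setNames(cost, cl)
  ans
}

#' Harrell's concordance index
#'
#' Fraction of comparable sample pairs in which the sample with the higher
#' predictor value has the shorter survival, counting predictor ties as
#' one half. A pair is comparable when the smaller of the two follow-up
#' times carries an observed event (pairs with equal times are not
#' comparable). Predictors are risk scores: higher = worse prognosis.
#'
#' @param predictor per-sample real risk score
#' @param time follow-up times
#' @param event event indicators (1 = event, 0 = censored)
#' @return concordance in [0, 1]
#' @export
harrellC <- function(predictor, time, event) {
  .checkSurvival(time, event, length(predictor))
  n <- length(predictor)
  dt <- outer(time, time, "-")            # dt[i,j] = t_i - t_j
  comp <- (dt < 0 & event) | t(dt < 0 & event)  # min-time member has event
  comp[lower.tri(comp, diag = TRUE)] <- FALSE   # each unordered pair once
  nc <- sum(comp)
  if (nc == 0) stop("no comparable pairs")
  dp <- outer(predictor, predictor, "-")
  # concordant: shorter time goes with higher predictor
  agree <- sign(dp) * sign(dt) == -1
  tiesP <- dp == 0
  (sum(agree[comp]) + 0.5 * sum(tiesP[comp])) / nc
}

# follow-up-space distance: |t_i - t_j| when the pair ordering is
# informative under censoring (the earlier of the two times carries an
# event; equal times need an event on either side), else Inf
.followupDistance <- function(time, event) {
  n <- length(time)
  dt <- outer(time, time, "-")
  informative <- (dt < 0 & event) | t(dt < 0 & event) |
    (dt == 0 & outer(event == 1, event == 1, "|"))
  fd <- abs(dt)
  fd[!informative] <- Inf
  diag(fd) <- Inf
  fd
}

#' Assign a test sample by pseudo-nearest-neighbour concordance
#'
#' Projects the test sample into the follow-up space through its molecular
#' nearest neighbours: the PNN set consists of the \code{kNN} nearest
#' training samples in the molecular space plus, for each, its \code{kFU}
#' nearest neighbours in the follow-up space (absolute time difference for
#' pairs whose ordering is informative under censoring). For each cluster
#' the pooled follow-up records of the PNN set (group 0) and the cluster
#' (group 1) are compared via Harrell's concordance of the binary group
#' indicator; the sample is assigned to the cluster whose concordance is
#' closest to 0.5, i.e. whose survival is most exchangeable with the PNN
#' set. Ties go to the larger cluster, then the smaller index. When the
#' concordance is undefined for some cluster the assignment falls back to
#' \code{\link{wardAssign}} with a warning.
#'
#' @inheritParams wardAssign
#' @param time,event training follow-up data
#' @param kNN molecular nearest neighbours (default 5)
#' @param kFU extra follow-up-space neighbours per NN (default 2)
#' @return the assigned cluster index, with attribute \code{"score"}
#'   holding |C - 0.5| per cluster (or \code{"fallback"} = TRUE)
#' @export
pnncAssign <- function(dTest, labels, D, time, event, kNN = 5, kFU = 2) {
  D <- as.matrix(D)
  ntr <- nrow(D)
  if (length(dTest) != ntr || length(labels) != ntr)
    stop("dTest, labels and D must cover the same training samples")
  .checkSurvival(time, event, ntr)
  if (kNN < 1 || kNN > ntr) stop("kNN must be in 1..training size")
  if (kFU < 0 || kFU > ntr - 1) stop("kFU must be in 0..training size - 1")
  nn <- order(dTest, seq_len(ntr))[seq_len(kNN)]
  pnn <- nn
  if (kFU > 0) {
    fd <- .followupDistance(time, event)
    for (i in nn) {
      nb <- order(fd[i, ], seq_len(ntr))
      nb <- nb[is.finite(fd[i, nb])]
      pnn <- union(pnn, nb[seq_len(min(kFU, length(nb)))])
    }
  }
  pnn <- sort(pnn)
  cl <- sort(unique(labels))
  score <- rep(NA_real_, length(cl))
  for (g in seq_along(cl)) {
    idx <- which(labels == cl[g])
    tt <- c(time[pnn], time[idx])
    ee <- c(event[pnn], event[idx])
    pred <- c(rep(0, length(pnn)), rep(1, length(idx)))
    cval <- tryCatch(harrellC(pred, tt, ee), error = function(e) NA_real_)
    score[g] <- abs(cval - 0.5)
  }
  if (anyNA(score) || length(pnn) == 0) {
    warning("PNN concordance undefined for some cluster; ",
            "falling back to Ward assignment")
    ans <- wardAssign(dTest, labels, D)
    attr(ans, "fallback") <- TRUE
    return(ans)
  }
  sizes <- vapply(cl, function(g) sum(labels == g), numeric(1))
  o <- order(score, -sizes, cl, method = "radix")
  ans <- cl[o[1]]
  attr(ans, "score") <- stats::setNames(score, cl)
  ans
}

#' Assign several test samples at once
#'
#' @param dTestMat matrix of test-to-training distances (tests in rows)
#' @param labels,D,time,event training partition, distances and follow-up
#' @param method \code{"ward"} or \code{"pnnc"}
#' @param ... passed to \code{\link{pnncAssign}}
#' @return integer vector of assigned cluster indices
#' @export
assignSamples <- function(dTestMat, labels, D, time = NULL, event = NULL,
                          method = c("ward", "pnnc"), ...) {
  method <- match.arg(method)
  dTestMat <- rbind(dTestMat)
  out <- integer(nrow(dTestMat))
  for (i in seq_len(nrow(dTestMat))) {
    out[i] <- if (method == "ward")
      as.integer(wardAssign(dTestMat[i, ], labels, D))
    else
      as.integer(pnncAssign(dTestMat[i, ], labels, D, time, event, ...))
  }
  names(out) <- rownames(dTestMat)
  out
}
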