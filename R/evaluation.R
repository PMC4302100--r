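#' @importFrom survival coxph Surv coxph.control survdiff ridge
NULL

.labelsFor <- function(tree, part) {
  if (is(part, "TreePartition")) stats::setNames(part@labels, part@sampleIDs)
  else if (is.numeric(part) && is.null(names(part)) && all(part != 0) &&
           !is.null(tree)) partitionLabels(tree, part)
  else part
}

.checkSurvival <- function(time, event, n = NULL) {
  if (length(time) != length(event))
    stop("time and event must have equal length")
  if (!is.null(n) && length(time) != n)
    stop("survival data length does not match sample count")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and nonnegative")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)")
  invisible(TRUE)
}

#' Within-cluster sum of squares from a distance matrix
#'
#' For each cluster C the contribution is
#' (1 / (2|C|)) * sum over i,j in C of d(i,j)^2, summed over clusters.
#' For Euclidean distances this equals the classical sum of squared
#' deviations from cluster centroids exactly; for other dissimilarities
#' (e.g. Pearson) it is the standard distance-based surrogate. Smaller is
#' better.
#'
#' @param labels per-sample cluster labels (any type), aligned with the
#'   rows of \code{D}
#' @param D symmetric dissimilarity matrix
#' @return nonnegative scalar
#' @export
wss <- function(labels, D) {
  D <- as.matrix(D)
  if (length(labels) != nrow(D)) stop("labels do not match D")
  if (anyNA(labels)) stop("labels contain NA (empty cluster?)")
  tot <- 0
  for (idx in split(seq_len(nrow(D)), labels)) {
    if (length(idx) == 0L) stop("empty cluster")
    if (length(idx) > 1L)
      tot <- tot + sum(D[idx, idx]^2) / (2 * length(idx))
  }
  tot
}

.pairSums <- function(labels, D) {
  n <- nrow(D)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  list(within = D[ut & same], between = D[ut & !same])
}

#' Hubert-Levin C-index of a partition
#'
#' (S - Smin) / (Smax - Smin), where S is the sum of within-cluster
#' pairwise distances and Smin / Smax are the sums of the equally many
#' globally smallest / largest distances. Lies in [0, 1]; smaller is
#' better. (This is a cluster-quality index, distinct from Harrell's
#' concordance index for survival.)
#'
#' @inheritParams wss
#' @return scalar in [0, 1]
#' @export
cindexQuality <- function(labels, D) {
  D <- as.matrix(D)
  if (length(labels) != nrow(D)) stop("labels do not match D")
  ps <- .pairSums(labels, D)
  if (length(unique(labels)) < 2 || length(ps$between) == 0)
    stop("need at least 2 clusters with a between-cluster pair")
  nw <- length(ps$within)
  if (nw == 0) return(0)   # all clusters singletons: S = Smin = Smax = 0
  all_d <- sort(c(ps$within, ps$between))
  S <- sum(ps$within)
  Smin <- sum(all_d[seq_len(nw)])
  Smax <- sum(all_d[seq.int(length(all_d) - nw + 1L, length(all_d))])
  if (Smax - Smin <= 0) {
    warning("all pairwise distances equal; C-index defined as 0")
    return(0)
  }
  (S - Smin) / (Smax - Smin)
}

#' Goodman-Kruskal index of a partition
#'
#' Gamma = (s+ - s-) / (s+ + s-) over all pairs of one within-cluster and
#' one between-cluster distance, where s+ counts concordant comparisons
#' (within < between) and s- discordant ones (within > between). Lies in
#' [-1, 1]; larger is better.
#'
#' @inheritParams wss
#' @return scalar in [-1, 1]
#' @export
gkIndex <- function(labels, D) {
  D <- as.matrix(D)
  if (length(labels) != nrow(D)) stop("labels do not match D")
  ps <- .pairSums(labels, D)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  w <- ps$within; b <- sort(ps$between)
  if (length(w) == 0 || length(b) == 0)
    stop("no comparable within/between distance pairs")
  # for each within-distance, count between-distances strictly above/below
  nBelow <- findInterval(w, b, left.open = TRUE)          # b[j] <  w
  nAbove <- length(b) - findInterval(w, b)                # b[j] >  w
  splus <- sum(nAbove); sminus <- sum(nBelow)
  if (splus + sminus == 0) stop("no strictly ordered distance comparisons")
  (splus - sminus) / (splus + sminus)
}

#' Cox proportional-hazards information criterion of a partition
#'
#' Fits a Cox model with k-1 cluster-indicator covariates by maximizing the
#' Breslow partial likelihood and returns
#' -2 logPL(beta-hat) + penalty, with penalty 2(k-1) for \code{"aic"},
#' (k-1) log(n) for \code{"bic"}, and (k-1) log(#events) for
#' \code{"bic_events"}. A single-cluster partition returns the null model's
#' -2 logPL with zero penalty. Smaller is better.
#'
#' On non-convergence or monotone likelihood (a cluster whose risk sets
#' cannot separate the events) the fit falls back to a ridge-stabilized
#' model (penalty 1e-6 on the coefficients); the result then carries
#' attribute \code{"ridge" = TRUE}.
#'
#' @param labels per-sample cluster labels
#' @param time nonnegative follow-up times
#' @param event event indicators, 1 = event observed, 0 = censored
#' @param criterion \code{"aic"}, \code{"bic"} or \code{"bic_events"}
#' @return scalar criterion value (attributes: \code{df}, \code{loglik},
#'   possibly \code{ridge})
#' @export
coxScore <- function(labels, time, event,
                     criterion = c("aic", "bic", "bic_events")) {
  criterion <- match.arg(criterion)
  .checkSurvival(time, event, length(labels))
  if (sum(event) < 1) stop("need at least one observed event")
  f <- factor(labels)
  if (any(tabulate(f) == 0)) stop("empty cluster")
  k <- nlevels(f)
  n <- length(labels)
  pen <- switch(criterion,
    aic        = 2 * (k - 1),
    bic        = (k - 1) * log(n),
    bic_events = (k - 1) * log(sum(event)))
  if (k == 1) {
    ll0 <- coxph(Surv(time, event) ~ 1, ties = "breslow")$loglik
    return(structure(-2 * ll0, df = 0L, loglik = ll0))
  }
  ridgeUsed <- FALSE
  fit <- withCallingHandlers(
    tryCatch(coxph(Surv(time, event) ~ f, ties = "breslow",
                   control = coxph.control(eps = 1e-8, iter.max = 50)),
             error = function(e) NULL),
    warning = function(w) {
      ridgeUsed <<- TRUE
      invokeRestart("muffleWarning")
    })
  bad <- is.null(fit) || any(!is.finite(stats::coef(fit))) ||
    any(abs(stats::coef(fit)) > 15) || ridgeUsed
  if (bad) {
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    fit <- suppressWarnings(
      coxph(Surv(time, event) ~ ridge(mm, theta = 1e-6, scale = FALSE),
            ties = "breslow",
            control = coxph.control(eps = 1e-8, iter.max = 100)))
    ridgeUsed <- TRUE
  }
  ll <- fit$loglik[length(fit$loglik)]
  out <- structure(-2 * ll + pen, df = k - 1L, loglik = ll)
  if (ridgeUsed) attr(out, "ridge") <- TRUE
  out
}

#' Combine molecular and survival scores by rank summation
#'
#' Ranks the molecular scores and the survival scores separately from good
#' to bad (rank 1 = best, average ranks on ties) and sums the two ranks
#' into the final evaluation score; the partition with the smallest rank
#' sum is the optimum. Ranks put the two criteria on the same scale, so
#' the combination is invariant under any strictly monotone transform of
#' either raw score sequence.
#'
#' @param scoresM molecular quality scores, one per candidate partition
#' @param scoresS survival criterion scores (smaller = better)
#' @param orientationM \code{"min"} if smaller molecular scores are better
#'   (WSS, C-index), \code{"max"} if larger are better (Goodman-Kruskal)
#' @return data.frame with columns \code{score_m, score_s, rank_m, rank_s,
#'   score_ms}
#' @export
rankCombine <- function(scoresM, scoresS, orientationM = c("min", "max")) {
  orientationM <- match.arg(orientationM)
  if (length(scoresM) != length(scoresS)) stop("length mismatch")
  if (length(scoresM) < 1) stop("need at least one candidate")
  rm_ <- rank(if (orientationM == "min") scoresM else -scoresM,
              ties.method = "average")
  rs_ <- rank(scoresS, ties.method = "average")
  data.frame(score_m = as.numeric(scoresM), score_s = as.numeric(scoresS),
             rank_m = rm_, rank_s = rs_, score_ms = rm_ + rs_)
}

# per-node WSS contributions so a partition's WSS is a sum over its nodes
.nodeWSS <- function(tree, D) {
  n <- nLeaves(tree)
  w <- numeric(2L * n - 1L)          # leaves first, then merges
  for (i in seq_len(n - 1L)) {
    idx <- tree@leafSets[[i]]
    w[n + i] <- sum(D[idx, idx]^2) / (2 * length(idx))
  }
  w
}

.partitionWSS <- function(nodes, nodeW, n) {
  sum(nodeW[ifelse(nodes < 0, -nodes, n + nodes)])
}

.elbowPick <- function(ks, scores) {
  # per distinct cluster count keep the best (smallest) score, then pick
  # the count at the elbow of the best-score curve: the count whose step
  # from the previous count has the largest relative drop (equivalently,
  # the largest first difference of log WSS). Relative drops make the rule
  # invariant to the overall scale of the distances, which an absolute
  # second difference is not. A single available count is returned as is.
  uk <- sort(unique(ks))
  best <- vapply(uk, function(k) min(scores[ks == k]), numeric(1))
  if (length(uk) < 2) return(uk[1])
  eps <- 1e-12 * max(best[1], 1)
  ratio <- best[-length(best)] / pmax(best[-1], eps)
  uk[which.max(ratio) + 1L]
}

#' Select the optimal partition from a candidate search space
#'
#' Guided selection scores every candidate in the molecular space
#' (\code{measureM}) and in the follow-up space (a Cox information
#' criterion, \code{criterionS}), combines the two by rank summation and
#' returns the candidate with the smallest rank sum. Unguided selection
#' uses the molecular measure alone: for the monotone WSS the best
#' partition per cluster count is kept and the count is chosen at the
#' elbow of the per-count curve (largest relative drop from the previous
#' count); for the C-index and Goodman-Kruskal
#' index the direct optimum is taken. Ties are broken by fewer clusters,
#' then by candidate order.
#'
#' @param tree a \linkS4class{SnipTree}
#' @param partitions list of node antichains, e.g. from
#'   \code{\link{enumeratePartitions}} or \code{\link{fixedHeightPartitions}}
#' @param D dissimilarity matrix; defaults to the tree's own
#' @param time,event survival data, required when \code{guided = TRUE}
#' @param measureM molecular measure: \code{"wss"}, \code{"cindex"},
#'   \code{"gk"}
#' @param criterionS survival criterion: \code{"aic"}, \code{"bic"},
#'   \code{"bic_events"}
#' @param guided use survival guidance?
#' @return list with elements \code{partition} (a
#'   \linkS4class{TreePartition}), \code{index} (position among the
#'   candidates) and \code{scores} (data.frame: partition_id, n_clusters,
#'   score_m and, when guided, score_s / rank_m / rank_s / score_ms)
#' @examples
#' sim <- simulateMixture(3, 10, 30, meanScale = 5, noiseSD = 1, seed = 7)
#' tr <- buildSnipTree(sim$X)
#' parts <- enumeratePartitions(tr, minClusterSize = 4)
#' sel <- selectOptimal(tr, parts, guided = FALSE)
#' sel$partition
#' @export
selectOptimal <- function(tree, partitions, D = treeDist(tree),
                          time = NULL, event = NULL,
                          measureM = c("wss", "cindex", "gk"),
                          criterionS = c("aic", "bic", "bic_events"),
                          guided = TRUE) {
  measureM <- match.arg(measureM)
  criterionS <- match.arg(criterionS)
  if (length(partitions) < 1) stop("no candidate partitions")
  if (guided && (is.null(time) || is.null(event)))
    stop("guided selection requires survival data (time, event)")
  n <- nLeaves(tree)
  ks <- lengths(partitions)
  if (measureM == "wss") {
    nodeW <- .nodeWSS(tree, D)
    sm <- vapply(partitions, .partitionWSS, numeric(1), nodeW = nodeW, n = n)
  } else {
    fn <- if (measureM == "cindex") cindexQuality else gkIndex
    sm <- vapply(partitions, function(p) {
      if (length(p) < 2) return(NA_real_)
      fn(partitionLabels(tree, p), D)
    }, numeric(1))
  }
  orient <- if (measureM == "gk") "max" else "min"
  if (guided) {
    ss <- vapply(partitions, function(p)
      as.numeric(coxScore(partitionLabels(tree, p), time, event,
                          criterionS)), numeric(1))
    smR <- sm
    if (anyNA(smR))  # single-cluster candidates: worst molecular rank
      smR[is.na(smR)] <- if (orient == "max") -Inf else Inf
    tab <- rankCombine(smR, ss, orient)
    o <- order(tab$score_ms, ks, seq_along(partitions), method = "radix")
    best <- o[1]
    scores <- data.frame(partition_id = seq_along(partitions),
                         n_clusters = ks, tab)
  } else {
    if (measureM == "wss") {
      kStar <- .elbowPick(ks, sm)
      cand <- which(ks == kStar)
      best <- cand[which.min(sm[cand])]
    } else {
      smO <- if (orient == "max") -sm else sm
      smO[is.na(smO)] <- Inf
      o <- order(smO, ks, seq_along(partitions), method = "radix")
      best <- o[1]
    }
    scores <- data.frame(partition_id = seq_along(partitions),
                         n_clusters = ks, score_m = sm)
  }
  list(partition = asTreePartition(tree, partitions[[best]]),
       index = best, scores = scores)
}
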