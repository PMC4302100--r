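test_that("distance-based WSS equals the centroid sum of squares on Euclidean data", {
  # all singletons: 0; one pair at distance d: d^2/2
  D <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(wss(1:2, D), 0)
  expect_equal(wss(c(1, 1), D), 9 / 2)
  # 5-point Euclidean toy set, 2 clusters, vs direct centroid oracle
  set.seed(50)
  X <- matrix(rnorm(10), 5, 2)
  lab <- c(1, 1, 1, 2, 2)
  D5 <- euclidDistance(X)
  centroidSS <- sum(vapply(split(seq_len(5), lab), function(idx) {
    c0 <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, c0)^2)
  }, numeric(1)))
  expect_equal(wss(lab, D5), centroidSS)
  expect_error(wss(c(1, NA), D), "NA")
})

test_that("WSS never increases under refinement of a cluster (Euclidean)", {
  set.seed(51)
  for (rep in 1:10) {
    X <- matrix(rnorm(40), 10, 4)
    D <- euclidDistance(X)
    lab <- sample(1:2, 10, replace = TRUE)
    w0 <- wss(lab, D)
    # split cluster 1 arbitrarily
    idx <- which(lab == 1)
    if (length(idx) < 2) next
    lab2 <- lab
    lab2[idx[1:floor(length(idx) / 2)]] <- 3
    expect_lte(wss(lab2, D), w0 + 1e-12)
  }
})

test_that("Hubert-Levin C-index matches the exhaustive pair oracle and bounds", {
  # two tight clusters far apart: within-distances are the globally
  # smallest set -> 0
  X <- rbind(matrix(rnorm(8, 0, 0.01), 4, 2),
             matrix(rnorm(8, 50, 0.01), 4, 2))
  D <- euclidDistance(X)
  lab <- rep(1:2, each = 4)
  expect_equal(cindexQuality(lab, D), 0)
  # constructed dissimilarities whose within-distances are exactly the
  # globally largest set -> 1
  Dw <- matrix(1, 4, 4); diag(Dw) <- 0
  Dw[1, 2] <- Dw[2, 1] <- 10; Dw[3, 4] <- Dw[4, 3] <- 10
  expect_equal(cindexQuality(c(1, 1, 2, 2), Dw), 1)
  # random instance vs brute-force pair sums
  set.seed(52)
  D8 <- randomDistance(8)
  lab8 <- sample(1:3, 8, replace = TRUE)
  while (length(unique(lab8)) < 2) lab8 <- sample(1:3, 8, replace = TRUE)
  ut <- upper.tri(D8)
  same <- outer(lab8, lab8, "==")
  w <- D8[ut & same]
  allD <- sort(D8[ut])
  S <- sum(w); Smin <- sum(allD[seq_along(w)])
  Smax <- sum(rev(allD)[seq_along(w)])
  expect_equal(cindexQuality(lab8, D8), (S - Smin) / (Smax - Smin))
  expect_gte(cindexQuality(lab8, D8), 0)
  expect_lte(cindexQuality(lab8, D8), 1)
  # all-equal distances: defined as 0 with a warning
  Dc <- matrix(1, 4, 4); diag(Dc) <- 0
  expect_warning(v <- cindexQuality(rep(1:2, each = 2), Dc), "equal")
  expect_equal(v, 0)
})

test_that("Goodman-Kruskal index matches the exhaustive concordance oracle", {
  X <- rbind(matrix(rnorm(8, 0, 0.01), 4, 2),
             matrix(rnorm(8, 50, 0.01), 4, 2))
  D <- euclidDistance(X)
  expect_equal(gkIndex(rep(1:2, each = 4), D), 1)   # all within < between
  # invert: cluster across the gap so every within >= every between is false
  set.seed(53)
  D8 <- randomDistance(8)
  lab8 <- sample(1:2, 8, replace = TRUE)
  while (length(unique(lab8)) < 2) lab8 <- sample(1:2, 8, replace = TRUE)
  ut <- upper.tri(D8); same <- outer(lab8, lab8, "==")
  w <- D8[ut & same]; b <- D8[ut & !same]
  sp <- sum(outer(w, b, "<")); sm <- sum(outer(w, b, ">"))
  expect_equal(gkIndex(lab8, D8), (sp - sm) / (sp + sm))
  expect_error(gkIndex(rep(1, 8), D8), "2 clusters")
  # perfect anti-clustering gives -1
  Dg <- matrix(0.9, 4, 4); diag(Dg) <- 0
  Dg[1, 2] <- Dg[2, 1] <- 0.1; Dg[3, 4] <- Dg[4, 3] <- 0.1
  expect_equal(gkIndex(c(1, 2, 1, 2), Dg), -1)
  expect_equal(gkIndex(c(1, 1, 2, 2), Dg), 1)
})

test_that("cluster-relabeling leaves the quality indices unchanged", {
  set.seed(54)
  D <- randomDistance(9)
  lab <- sample(1:3, 9, replace = TRUE)
  while (length(unique(lab)) < 3) lab <- sample(1:3, 9, replace = TRUE)
  relab <- c(3, 1, 2)[lab]
  expect_equal(cindexQuality(lab, D), cindexQuality(relab, D))
  expect_equal(gkIndex(lab, D), gkIndex(relab, D))
  expect_equal(wss(lab, D), wss(relab, D))
})

test_that("Cox criterion matches the Breslow grid-search oracle", {
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(8:12, 1)
    z <- sample(0:1, n, replace = TRUE)
    while (length(unique(z)) < 2) z <- sample(0:1, n, replace = TRUE)
    time <- round(rexp(n, 0.2), 4)
    event <- rbinom(n, 1, 0.75)
    if (sum(event) == 0) event[1] <- 1
    got <- coxScore(z + 1, time, event, criterion = "aic")
    if (!is.null(attr(got, "ridge"))) next   # monotone-likelihood draw
    expect_equal(as.numeric(got) - 2, oracleCoxMin2LogPL(z, time, event),
                 tolerance = 1e-4)
  }
})

test_that("Cox criterion handles the null and symmetric cases exactly", {
  set.seed(56)
  time <- rexp(10); event <- rbinom(10, 1, 0.8); event[1] <- 1
  null2ll <- as.numeric(coxScore(rep(1, 10), time, event, "aic"))
  # one cluster: null partial likelihood, zero penalty (Breslow ties)
  expect_equal(null2ll, -2 * survival::coxph(
    survival::Surv(time, event) ~ 1, ties = "breslow")$loglik)
  # two groups carrying duplicated survival data: beta-hat = 0
  t2 <- c(time, time); e2 <- c(event, event)
  lab2 <- rep(1:2, each = 10)
  v <- coxScore(lab2, t2, e2, "aic")
  null2 <- -2 * survival::coxph(survival::Surv(t2, e2) ~ 1,
                                ties = "breslow")$loglik
  expect_equal(as.numeric(v), null2 + 2, tolerance = 1e-6)
  # penalties: aic 2(k-1), bic (k-1)log n, bic_events (k-1)log d
  set.seed(57)
  lab <- rep(1:3, length.out = 12)
  tt <- rexp(12); ee <- rep(1, 12)
  a <- as.numeric(coxScore(lab, tt, ee, "aic"))
  b <- as.numeric(coxScore(lab, tt, ee, "bic"))
  be <- as.numeric(coxScore(lab, tt, ee, "bic_events"))
  expect_equal(b - a, 2 * (log(12) - 2))
  expect_equal(be, b)    # all events observed: log d = log n
})

test_that("the fitted Cox model is never worse than the null model", {
  set.seed(58)
  for (rep in 1:10) {
    n <- 14
    lab <- sample(1:3, n, replace = TRUE)
    while (length(unique(lab)) < 3) lab <- sample(1:3, n, replace = TRUE)
    time <- rexp(n); event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    fit2ll <- as.numeric(coxScore(lab, time, event, "aic")) - 2 * 2
    null2ll <- as.numeric(coxScore(rep(1, n), time, event, "aic"))
    expect_lte(fit2ll, null2ll + 1e-6)
  }
})

test_that("rank combination follows the published rank-sum rule", {
  # single candidate: ranks (1,1), total 2
  one <- rankCombine(5, 10)
  expect_equal(one$score_ms, 2)
  # hand-ranked example
  tab <- rankCombine(c(5, 1, 3), c(10, 20, 30), orientationM = "min")
  expect_equal(tab$rank_m, c(3, 1, 2))
  expect_equal(tab$rank_s, c(1, 2, 3))
  expect_equal(tab$score_ms, c(4, 3, 5))
  # invariance under strictly monotone transforms of either score
  set.seed(59)
  sm <- runif(10); ss <- runif(10)
  base <- rankCombine(sm, ss)$score_ms
  expect_equal(rankCombine(exp(3 * sm), ss)$score_ms, base)
  expect_equal(rankCombine(sm, log(ss + 1))$score_ms, base)
  expect_equal(rankCombine(-sm, ss, orientationM = "max")$score_ms, base)
  # ties get average ranks
  tie <- rankCombine(c(1, 1, 2), c(3, 2, 1))
  expect_equal(tie$rank_m, c(1.5, 1.5, 3))
  expect_error(rankCombine(1:3, 1:2), "mismatch")
})

test_that("guided selection minimizes the rank sum over all candidates", {
  set.seed(60)
  sim <- simulateMixture(3, 8, 30, meanScale = 5, noiseSD = 1, seed = 61)
  sv <- simulateSurvival(sim$labels, c(1, 3, 9), censorRate = 0.1, seed = 62)
  tr <- buildSnipTree(sim$X)
  parts <- enumeratePartitions(tr, 4)
  sel <- selectOptimal(tr, parts, time = sv$time, event = sv$event,
                       guided = TRUE)
  expect_true(all(sel$scores$score_ms[sel$index] <= sel$scores$score_ms))
  expect_error(selectOptimal(tr, parts, guided = TRUE), "survival")
  # single candidate: returned as is
  selOne <- selectOptimal(tr, parts[1], time = sv$time, event = sv$event,
                          guided = TRUE)
  expect_equal(selOne$index, 1)
})

test_that("guided selection recovers a well-separated planted partition", {
  sim <- simulateMixture(3, 10, 40, meanScale = 6, noiseSD = 1, seed = 63)
  sv <- simulateSurvival(sim$labels, c(1, 4, 16), censorRate = 0.1, seed = 64)
  tr <- buildSnipTree(sim$X)
  parts <- enumeratePartitions(tr, 10)  # min size excludes sub-splits
  sel <- selectOptimal(tr, parts, time = sv$time, event = sv$event,
                       guided = TRUE)
  expect_equal(
    adjustedRandIndex(sim$labels, partitionLabels(tr, sel$partition)), 1)
})

test_that("unguided selection picks the obvious structure", {
  # strong 2-group structure, gk measure, fixed-height candidates
  set.seed(65)
  X <- rbind(matrix(rnorm(80, 0, 1), 8, 10),
             matrix(rnorm(80, 12, 1), 8, 10))
  rownames(X) <- paste0("s", 1:16)
  D <- euclidDistance(X)
  tr <- buildSnipTree(distance = D, linkage = "average")
  fh <- fixedHeightPartitions(tr, 2)
  selGK <- selectOptimal(tr, fh, guided = FALSE, measureM = "gk")
  expect_equal(length(selGK$partition@nodes), 2)
  expect_equal(
    adjustedRandIndex(rep(1:2, each = 8),
                      partitionLabels(tr, selGK$partition)), 1)
  # unguided WSS elbow on the same structure
  selW <- selectOptimal(tr, enumeratePartitions(tr, 2), guided = FALSE,
                        measureM = "wss")
  expect_equal(
    adjustedRandIndex(rep(1:2, each = 8),
                      partitionLabels(tr, selW$partition)), 1)
})
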