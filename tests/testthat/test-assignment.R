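test_that("Ward assignment matches the centroid-form increment on Euclidean data", {
  set.seed(70)
  for (rep in 1:8) {
    n <- sample(10:30, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    xs <- rnorm(3)
    lab <- sample(1:3, n, replace = TRUE)
    while (length(unique(lab)) < 3) lab <- sample(1:3, n, replace = TRUE)
    D <- euclidDistance(X)
    dTest <- sqrt(colSums((t(X) - xs)^2))
    got <- wardAssign(dTest, lab, D)
    # centroid oracle: (|C|/(|C|+1)) ||x_s - c_C||^2
    inc <- vapply(sort(unique(lab)), function(g) {
      idx <- which(lab == g)
      cC <- colMeans(X[idx, , drop = FALSE])
      (length(idx) / (length(idx) + 1)) * sum((xs - cC)^2)
    }, numeric(1))
    expect_equal(as.integer(got), which.min(inc))
    expect_equal(unname(attr(got, "cost")), inc, tolerance = 1e-10)
  }
})

test_that("Ward assignment handles the trivial geometries", {
  # at distance 0 to every member of cluster 1, far from cluster 2
  D <- matrix(0.1, 6, 6); diag(D) <- 0
  lab <- rep(1:2, each = 3)
  dTest <- c(0, 0, 0, 10, 10, 10)
  expect_equal(as.integer(wardAssign(dTest, lab, D)), 1L)
  # two singleton clusters: reduces to the nearer sample (d^2/2)
  D2 <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(as.integer(wardAssign(c(4, 1), 1:2, D2)), 2L)
  expect_error(wardAssign(c(1, Inf), 1:2, D2), "finite")
})

test_that("Harrell's concordance matches exhaustive pair enumeration", {
  # perfect concordance: predictor = -time, no censoring
  t0 <- c(5, 3, 8, 1, 9, 2)
  expect_equal(harrellC(-t0, t0, rep(1, 6)), 1)
  # constant predictor: all ties -> 1/2
  expect_equal(harrellC(rep(2, 6), t0, rep(1, 6)), 0.5)
  # censored instances vs the brute-force oracle
  set.seed(71)
  for (rep in 1:10) {
    n <- 6
    pred <- sample(1:4, n, replace = TRUE)
    time <- round(rexp(n, 0.3), 3)
    event <- rbinom(n, 1, 0.6)
    if (sum(event[time < max(time)]) == 0) next
    got <- tryCatch(harrellC(pred, time, event), error = function(e) NULL)
    want <- tryCatch(oracleHarrellC(pred, time, event),
                     error = function(e) NULL)
    if (is.null(got) || is.null(want) || is.nan(want)) next
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(harrellC(1:3, c(1, 1, 1), c(0, 0, 1)), "comparable")
})

test_that("concordance of a sign-flipped predictor is the complement", {
  set.seed(72)
  for (rep in 1:5) {
    n <- 8
    pred <- rnorm(n)   # continuous: no predictor ties a.s.
    time <- rexp(n); event <- rbinom(n, 1, 0.7)
    if (sum(event[time < max(time)]) == 0) next
    expect_equal(harrellC(pred, time, event) +
                   harrellC(-pred, time, event), 1)
  }
})

test_that("PNNC assignment follows exchangeable survival", {
  # PNN follow-up duplicated from cluster 1, drastically shorter than
  # cluster 2's: assign to cluster 1 (|C - 0.5| = 0 by symmetry)
  D <- matrix(0.5, 12, 12); diag(D) <- 0
  lab <- rep(1:2, each = 6)
  time <- c(1, 2, 3, 1, 2, 3, 50, 60, 70, 80, 90, 100)
  event <- rep(1, 12)
  dTest <- c(rep(0.01, 3), rep(0.9, 9))  # NNs are samples 1..3
  got <- pnncAssign(dTest, lab, D, time, event, kNN = 3, kFU = 1)
  expect_equal(as.integer(got), 1L)
  # kNN = training size, kFU = 0, single candidate cluster
  got1 <- pnncAssign(rep(0.2, 12), rep(1, 12), D, time, event,
                     kNN = 12, kFU = 0)
  expect_equal(as.integer(got1), 1L)
  expect_error(pnncAssign(dTest, lab, D, time, event, kNN = 99), "kNN")
})

test_that("PNNC resolves a constructed 2-cluster case by concordance", {
  # 12 training samples, 2 clusters with disjoint survival ranges; the
  # test sample is molecularly nearest to the long survivors
  set.seed(73)
  Xtr <- rbind(matrix(rnorm(60, 0, 1), 6, 10),     # cluster 1, short
               matrix(rnorm(60, 8, 1), 6, 10))     # cluster 2, long
  rownames(Xtr) <- paste0("s", 1:12)
  lab <- rep(1:2, each = 6)
  time <- c(runif(6, 1, 3), runif(6, 30, 60))
  event <- rep(1, 12)
  D <- pearsonDistance(Xtr)
  xTest <- rnorm(10, 8, 1)
  dTest <- drop(crossDistance(rbind(xTest), Xtr))
  got <- pnncAssign(dTest, lab, D, time, event, kNN = 3, kFU = 2)
  expect_equal(as.integer(got), 2L)
  # hand-check the winning concordance: PNN pooled with cluster 2 should
  # be near-exchangeable while PNN vs cluster 1 is near-separated
  sc <- attr(got, "score")
  expect_lt(sc["2"], sc["1"])
})

test_that("PNNC depends on follow-up only through orderings", {
  set.seed(74)
  n <- 15
  X <- matrix(rnorm(n * 8), n, 8)
  rownames(X) <- paste0("s", 1:n)
  D <- pearsonDistance(X)
  lab <- sample(1:3, n, replace = TRUE)
  while (min(table(factor(lab, 1:3))) < 2) lab <- sample(1:3, n, replace = TRUE)
  time <- rexp(n); event <- rbinom(n, 1, 0.8); event[which.min(time)] <- 1
  dTest <- runif(n, 0.2, 1.5)
  a <- pnncAssign(dTest, lab, D, time, event)
  b <- pnncAssign(dTest, lab, D, 1000 * time, event)
  expect_equal(as.integer(a), as.integer(b))
})

test_that("PNNC beats Ward when molecular structure masks survival structure", {
  # survival-distinct clusters with multi-modal molecular structure and
  # noisy test profiles: cluster 1 consists of two blobs whose centroid
  # coincides with cluster 2's blob, so the centroid-based Ward increment
  # is uninformative for blob members while nearest neighbours (and their
  # follow-up projection) remain informative. Over replicates PNNC must
  # agree with the planted labels at least as often as Ward (small
  # statistical slack for sampling noise).
  p <- 10; nPer <- 8
  blobA <- rep(0, p); blobB <- rep(8, p); blobC <- rep(4, p)
  accP <- accW <- 0; total <- 0
  for (rep in 1:20) {
    set.seed(700 + rep)
    X <- rbind(matrix(rnorm(nPer * p, 0, 1), nPer, p) +
                 matrix(blobA, nPer, p, byrow = TRUE),
               matrix(rnorm(nPer * p, 0, 1), nPer, p) +
                 matrix(blobB, nPer, p, byrow = TRUE),
               matrix(rnorm(2 * nPer * p, 0, 1), 2 * nPer, p) +
                 matrix(blobC, 2 * nPer, p, byrow = TRUE))
    lab <- rep(1:2, each = 2 * nPer)
    time <- c(rexp(2 * nPer, 1), rexp(2 * nPer, 1 / 20))
    event <- rep(1, 4 * nPer)
    D <- unname(as.matrix(stats::dist(X)))
    for (g in 1:2) {
      centre <- list(blobA, blobC)[[g]]       # a blob of group g
      xs <- centre + rnorm(p, 0, 1.5)
      dT <- sqrt(colSums((t(X) - xs)^2))
      aP <- suppressWarnings(
        as.integer(pnncAssign(dT, lab, D, time, event, kNN = 5, kFU = 2)))
      aW <- as.integer(wardAssign(dT, lab, D))
      accP <- accP + (aP == g); accW <- accW + (aW == g)
      total <- total + 1
    }
  }
  expect_gte(accP / total, accW / total - 0.02)
})
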