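# Independent oracles used across the suite. Each reimplements the quantity
# it checks from first principles (direct formulas, exhaustive enumeration),
# never by calling the package's own code path.

# --- naive O(n^3) agglomeration with Lance-Williams updates ---------------
# linkage coefficients applied to the raw dissimilarities; "ward" is the
# Ward update on d (hclust's ward.D convention)
oracleAgglomerate <- function(D, linkage) {
  n <- nrow(D)
  active <- as.list(seq_len(n))          # current clusters as leaf sets
  ids <- -seq_len(n)                     # node ids, hclust convention
  sizes <- rep(1, n)
  d <- D
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]
    merges[step, ] <- sort(c(ids[i], ids[j]))
    heights[step] <- best[1]
    sets[[step]] <- sort(c(active[[i]], active[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    newd <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      newd[k] <- switch(linkage,
        ward = ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] -
                  nk * d[i, j]) / (ni + nj + nk),
        average = (ni * d[i, k] + nj * d[j, k]) / (ni + nj),
        complete = max(d[i, k], d[j, k]),
        single = min(d[i, k], d[j, k]))
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], ni + nj)
  }
  list(merge = merges, height = heights, sets = sets)
}

# --- exhaustive tree-consistent-partition oracle --------------------------
# enumerates all parent-closed subsets S of internal nodes ("split sets");
# cluster roots are the nodes whose parent is split but which are not split
# themselves (the root when S is empty). Bijective with the set of
# tree-consistent partitions, by a mechanism unrelated to the product
# recurrence under test. Returns canonical partition keys.
oracleAntichains <- function(merge, minSize) {
  nm <- nrow(merge)
  n <- nm + 1L
  leafSets <- vector("list", nm)
  for (i in seq_len(nm)) {
    s <- integer(0)
    for (k in merge[i, ]) s <- c(s, if (k < 0) -k else leafSets[[k]])
    leafSets[[i]] <- sort(s)
  }
  parent <- rep(NA_integer_, nm)           # parent merge row of merge row
  for (i in seq_len(nm)) for (k in merge[i, ]) if (k > 0) parent[k] <- i
  keys <- character(0)
  for (code in 0:(2^nm - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(nm) - 1)) > 0)
    ok <- all(vapply(S, function(v) is.na(parent[v]) || parent[v] %in% S,
                     logical(1)))
    if (!ok) next
    clusters <- list()
    for (v in seq_len(nm)) {
      if (v %in% S) next
      par <- parent[v]
      if (is.na(par) || par %in% S)
        clusters[[length(clusters) + 1L]] <- leafSets[[v]]
    }
    for (i in seq_len(nm)) if (i %in% S)
      for (k in merge[i, ]) if (k < 0)
        clusters[[length(clusters) + 1L]] <- -k
    if (any(lengths(clusters) < minSize)) next
    key <- paste(sort(vapply(clusters, paste, character(1), collapse = " ")),
                 collapse = "|")
    keys <- c(keys, key)
  }
  sort(keys)
}

partitionKey <- function(labels) {
  paste(sort(vapply(split(seq_along(labels), labels), paste, character(1),
                    collapse = " ")), collapse = "|")
}

# --- Breslow log partial likelihood (binary group), grid oracle -----------
oracleBreslowLogPL <- function(beta, z, time, event) {
  vapply(beta, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      atRisk <- which(time >= time[i])
      ll <- ll + b * z[i] - log(sum(exp(b * z[atRisk])))
    }
    ll
  }, numeric(1))
}

oracleCoxMin2LogPL <- function(z, time, event) {
  grid <- seq(-8, 8, by = 1e-3)
  ll <- oracleBreslowLogPL(grid, z, time, event)
  b0 <- grid[which.max(ll)]
  opt <- stats::optimize(function(b) oracleBreslowLogPL(b, z, time, event),
                         c(b0 - 0.01, b0 + 0.01), maximum = TRUE,
                         tol = 1e-10)
  -2 * opt$objective
}

# --- Harrell concordance by exhaustive pair enumeration -------------------
oracleHarrellC <- function(predictor, time, event) {
  num <- 0; den <- 0
  n <- length(predictor)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    s <- if (time[i] < time[j]) i else j   # shorter survival
    l <- if (time[i] < time[j]) j else i
    if (event[s] != 1) next
    den <- den + 1
    if (predictor[s] > predictor[l]) num <- num + 1
    else if (predictor[s] == predictor[l]) num <- num + 0.5
  }
  num / den
}

# --- k-sample log-rank statistic from the risk-set table ------------------
oracleLogrank <- function(labels, time, event) {
  f <- factor(labels)
  k <- nlevels(f)
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    nj <- vapply(levels(f), function(g) sum(atRisk & f == g), numeric(1))
    dj <- vapply(levels(f), function(g) sum(time == t & event == 1 & f == g),
                 numeric(1))
    nTot <- sum(nj); dTot <- sum(dj)
    O <- O + dj
    E <- E + dTot * nj / nTot
    if (nTot > 1) {
      c1 <- dTot * (nTot - dTot) / (nTot - 1)
      V <- V + c1 * (diag(nj / nTot, k) - tcrossprod(nj / nTot))
    }
  }
  x <- (O - E)[-k]
  drop(t(x) %*% solve(V[-k, -k, drop = FALSE]) %*% x)
}

# --- adjusted Rand index via the explicit contingency-table formula -------
oracleARI <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  nij <- sum(tab * (tab - 1) / 2)
  ai <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  bj <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  nc2 <- n * (n - 1) / 2
  (nij - ai * bj / nc2) / ((ai + bj) / 2 - ai * bj / nc2)
}

# --- misc generators ------------------------------------------------------
randomDistance <- function(n) {
  M <- matrix(stats::runif(n * n), n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("s", seq_len(n))
  D
}

euclidDistance <- function(X) {
  D <- as.matrix(stats::dist(X))
  rownames(D) <- colnames(D) <- paste0("s", seq_len(nrow(X)))
  D
}
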