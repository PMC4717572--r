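# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, brute force, or a textbook algorithm) kept
# separate from the package's own code paths.

# AUC by exhaustive pair counting with the tie convention
# P(pos > neg) + 0.5 * P(pos == neg).
bruteAuc <- function(scores, isPos) {
  pos <- scores[isPos]
  neg <- scores[!isPos]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exhaustive interval-overlap SNP-to-gene assignment: O(genes x SNPs).
bruteAssign <- function(snps, genesDf, windowBp) {
  out <- list()
  for (i in seq_len(nrow(genesDf))) {
    hit <- snps$CHR == genesDf$chrom[i] &
      snps$BP >= genesDf$start[i] - windowBp &
      snps$BP <= genesDf$end[i] + windowBp
    ids <- snps$SNP[hit]
    out[[genesDf$gene[i]]] <- ids[order(snps$BP[hit])]
  }
  out
}

# Textbook SMO solver for the weighted C-SVC dual:
#   max sum(a) - 0.5 t(a*y) K (a*y),  0 <= a_i <= Cvec_i,  sum(a*y) = 0.
# Returns the decision values f(x) = K[x, ] %*% (a*y) + b for the rows of
# Kfull (kernel of every point against the training points).
smoSvmOracle <- function(K, y, Cvec, Kfull = K, maxSweeps = 5000,
                         eps = 1e-12) {
  n <- length(y)
  a <- numeric(n)
  f <- numeric(n)  # K %*% (a*y), maintained incrementally
  for (sweep in seq_len(maxSweeps)) {
    maxDelta <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (eta <= 1e-14) next
      Ei <- f[i] - y[i]
      Ej <- f[j] - y[j]
      s <- y[i] * y[j]
      gamma <- a[i] + s * a[j]
      ajNew <- a[j] + y[j] * (Ei - Ej) / eta
      if (s == 1) {
        L <- max(0, gamma - Cvec[i]); H <- min(Cvec[j], gamma)
      } else {
        L <- max(0, -gamma); H <- min(Cvec[j], Cvec[i] - gamma)
      }
      if (L > H) next
      ajNew <- min(max(ajNew, L), H)
      dj <- ajNew - a[j]
      if (abs(dj) < eps) next
      aiNew <- gamma - s * ajNew
      di <- aiNew - a[i]
      f <- f + K[, i] * di * y[i] + K[, j] * dj * y[j]
      a[i] <- aiNew; a[j] <- ajNew
      maxDelta <- max(maxDelta, abs(dj))
    }
    if (maxDelta < 1e-11) break
  }
  free <- which(a > 1e-7 * max(Cvec) & a < Cvec - 1e-7 * max(Cvec))
  b <- if (length(free)) mean(y[free] - f[free]) else {
    # no free SVs: b is any value in the KKT interval; take its midpoint
    up <- min(c((y - f)[(y == 1 & a < Cvec - eps) | (y == -1 & a > eps)], Inf))
    lo <- max(c((y - f)[(y == -1 & a < Cvec - eps) | (y == 1 & a > eps)], -Inf))
    (lo + up) / 2
  }
  list(alpha = a, b = b, decision = drop(Kfull %*% (a * y)) + b)
}

# Monte Carlo oracle for the LD-aware gene statistic: survival probability
# of sum(z^2), z ~ MVN(0, R), estimated from nDraws fresh draws.
mvnSumSqOracle <- function(stat, R, nDraws, seed) {
  ch <- chol(R)
  k <- nrow(R)
  withr::with_seed(seed, {
    exceed <- 0
    done <- 0
    while (done < nDraws) {
      m <- min(2e5, nDraws - done)
      z <- matrix(rnorm(m * k), m, k) %*% ch
      exceed <- exceed + sum(rowSums(z * z) >= stat)
      done <- done + m
    }
    exceed / nDraws
  })
}
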