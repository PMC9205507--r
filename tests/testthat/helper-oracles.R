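## Independent oracles used across the suite. These deliberately avoid the
## package's own grouping/recursion code paths.

## O(n^2) pairwise-comparison grouping: for each row, count the rows equal
## to it on every quasi-identifier.
bruteForceClassSizes <- function(df, qi) {
  n <- nrow(df)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (all(trimws(as.character(df[i, qi])) ==
                trimws(as.character(df[j, qi])))) cnt <- cnt + 1L
    }
    sizes[i] <- cnt
  }
  sizes
}

## Literal attack simulation: the adversary picks a sample record, finds
## every candidate in the population matching it on the QIs, and succeeds
## with probability 1/candidates. The mean success probability over all
## sample records is the sample-to-population match rate.
bruteForceAttackB <- function(sampleDf, popDf, qi) {
  probs <- vapply(seq_len(nrow(sampleDf)), function(i) {
    cand <- 0L
    for (j in seq_len(nrow(popDf))) {
      if (all(as.character(sampleDf[i, qi]) == as.character(popDf[j, qi])))
        cand <- cand + 1L
    }
    1 / cand
  }, numeric(1))
  mean(probs)
}

## Convert d-vine partial-correlation parameters (path order 1..m) to the
## implied joint correlation matrix, by the standard recursive inversion of
## the partial-correlation identity. Independent of the package's sampler.
dvineParamsToCorrelation <- function(pairParams, m) {
  pc <- matrix(NA_real_, m, m)
  for (t in seq_along(pairParams))
    for (i in seq_along(pairParams[[t]]))
      pc[i, i + t] <- pairParams[[t]][i]
  R <- diag(1, m)
  for (t in seq_len(m - 1)) {
    for (i in seq_len(m - t)) {
      j <- i + t
      ## pc[i,j] is rho_{i,j | i+1..j-1}; peel the conditioning variables
      ## one at a time (k = i+1, ..., j-1) using the partial-correlation
      ## identity; the partials needed involve only pairs closer than t,
      ## whose unconditional correlations are already in R.
      rho <- pc[i, j]
      for (k in if (t > 1) seq(i + 1, j - 1) else integer(0)) {
        S <- if (k + 1 <= j - 1) seq(k + 1, j - 1) else integer(0)
        r1 <- partialCor(R, i, k, S)
        r2 <- partialCor(R, k, j, S)
        rho <- rho * sqrt((1 - r1^2) * (1 - r2^2)) + r1 * r2
      }
      R[i, j] <- R[j, i] <- rho
    }
  }
  R
}

## partial correlation of variables a,b given index set S, from a joint
## correlation matrix (via matrix inversion on the submatrix)
partialCor <- function(R, a, b, S) {
  if (length(S) == 0) return(R[a, b])
  idx <- c(a, b, S)
  P <- solve(R[idx, idx])
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

## A microdata table whose sample equivalence-class sizes are exactly the
## given multiset (one synthetic QI, one class per entry).
tableWithClassSizes <- function(sizes) {
  vals <- rep(sprintf("c%02d", seq_along(sizes)), times = sizes)
  microdata(data.frame(qi = vals, stringsAsFactors = FALSE))
}

## Random categorical data.frame for property-style loops.
randomCatFrame <- function(n, levelsPerCol, seed) {
  withr::with_seed(seed, {
    cols <- lapply(seq_along(levelsPerCol), function(j)
      sample(sprintf("v%d_%d", j, seq_len(levelsPerCol[j])), n,
             replace = TRUE))
    names(cols) <- sprintf("q%d", seq_along(levelsPerCol))
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
}
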