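#' @include gaussian-copula.R
NULL

.clampU <- function(u) pmin(pmax(u, 1e-12), 1 - 1e-12)

## Gaussian pair-copula h-function: h(u | v; rho) = conditional CDF of U
## given V = v, and its inverse in the first argument.
.hGauss <- function(u, v, rho) {
  stats::pnorm((stats::qnorm(.clampU(u)) - rho * stats::qnorm(.clampU(v))) /
                 sqrt(1 - rho^2))
}

.hGaussInv <- function(w, v, rho) {
  stats::pnorm(stats::qnorm(.clampU(w)) * sqrt(1 - rho^2) +
                 rho * stats::qnorm(.clampU(v)))
}

## Greedy maximum-weight Hamiltonian path on the pairwise dependence
## weights: start from the strongest pair, repeatedly extend whichever path
## endpoint has the strongest edge to an unused variable.
.dvineOrder <- function(w) {
  m <- nrow(w)
  if (m == 1L) return(1L)
  diag(w) <- -Inf
  best <- which(w == max(w), arr.ind = TRUE)[1, ]
  path <- as.integer(best)
  while (length(path) < m) {
    rest <- setdiff(seq_len(m), path)
    ends <- c(path[1L], path[length(path)])
    cand <- expand.grid(end = ends, v = rest)
    scores <- w[cbind(cand$end, cand$v)]
    pick <- cand[which.max(scores), ]
    if (pick$end == path[1L]) path <- c(pick$v, path) else path <- c(path, pick$v)
  }
  as.integer(path)
}

#' Fit a d-vine copula to the quasi-identifiers of a sample
#'
#' Variables are arranged on a path (chosen greedily by absolute
#' normal-scores correlation, extending from the strongest pair) and all
#' pair-copulas are bivariate Gaussian. Tree 1 couples path neighbours;
#' tree t couples variables t apart conditionally on the variables between
#' them, with conditional pseudo-observations propagated by the Gaussian
#' h-function recursion.
#'
#' Tree-1 parameters are calibrated by the same mutual-information matching
#' used in [fitGaussianCopula()]: the plain correlation of jittered
#' pseudo-observations is attenuated by the within-category jitter, while
#' the MI match recovers the latent parameter that reproduces the observed
#' contingency-table dependence. Higher-tree parameters are the
#' correlations of the normal scores of the conditional pseudo-observations.
#'
#' For m = 1 the model degenerates to marginal resampling.
#'
#' @param sample a [MicrodataTable-class]
#' @param qi quasi-identifier column names
#' @param seed integer seed for the distributional-transform jitter and the
#'   MI-calibration draws
#' @param calibrationSize rows in the tree-1 calibration draw (default
#'   10000)
#' @return a [DVineCopulaModel-class]
#' @export
fitDVineCopula <- function(sample, qi, seed, calibrationSize = 10000L) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  marginals <- fitMarginals(sample, qi)
  m <- length(qi)
  if (m == 1L)
    return(new("DVineCopulaModel", marginals = marginals, order = 1L,
               pairParams = list(), seed = as.integer(seed)))
  seeds <- .deriveSeeds(seed, 2L, salt = 202L)
  z <- .normalScores(sample, marginals, seeds[1])
  calib <- withr::with_seed(seeds[2],
    matrix(stats::rnorm(2 * calibrationSize), ncol = 2))
  constant <- vapply(marginals, function(mt)
    length(mt@categories) < 2L, logical(1))
  if (any(constant))
    warning(sprintf("constant quasi-identifier(s) %s: pair parameters fixed at 0",
                    paste(qi[constant], collapse = ", ")))
  corZ <- suppressWarnings(stats::cor(z))
  corZ[is.na(corZ)] <- 0
  ord <- .dvineOrder(abs(corZ))
  u <- stats::pnorm(z[, ord, drop = FALSE])
  isConst <- constant[ord]

  ## L[[i]][[j]] = F(u_i | u_{i+1..j}), Rg[[i]][[j]] = F(u_j | u_{i..j-1})
  L <- Rg <- lapply(seq_len(m), function(i) vector("list", m))
  for (i in seq_len(m)) L[[i]][[i]] <- Rg[[i]][[i]] <- u[, i]
  pairParams <- vector("list", m - 1L)
  for (t in seq_len(m - 1L)) {
    pairParams[[t]] <- numeric(m - t)
    for (i in seq_len(m - t)) {
      j <- i + t
      a <- L[[i]][[j - 1L]]
      b <- Rg[[i + 1L]][[j]]
      theta <- if (isConst[i] || isConst[j]) {
        0
      } else if (t == 1L) {
        vi <- qi[ord[i]]
        vj <- qi[ord[j]]
        .calibratePairRho(
          mutualInformation(sample@data[[vi]], sample@data[[vj]]),
          marginals[[vi]], marginals[[vj]],
          calib[, 1], calib[, 2],
          init = stats::cor(z[, ord[i]], z[, ord[j]]))
      } else {
        stats::cor(stats::qnorm(.clampU(a)), stats::qnorm(.clampU(b)))
      }
      theta <- max(min(theta, 0.999), -0.999)
      pairParams[[t]][i] <- theta
      L[[i]][[j]] <- .hGauss(a, b, theta)
      Rg[[i]][[j]] <- .hGauss(b, a, theta)
    }
  }
  new("DVineCopulaModel", marginals = marginals, order = ord,
      pairParams = pairParams, seed = as.integer(seed))
}

#' @describeIn sampleCopula draw from a d-vine model by inverse-Rosenblatt
#'   traversal: each path variable is generated by inverting the cascade of
#'   h-functions that condition it on the variables already drawn
#' @export
setMethod("sampleCopula", "DVineCopulaModel", function(model, N, seed) {
  N <- as.integer(round(N))
  if (N < 1L) validationError("N must be a positive integer")
  m <- length(model@marginals)
  w <- withr::with_seed(as.integer(seed), matrix(stats::runif(N * m), N, m))
  if (m == 1L) return(.uniformsToTable(w, model@marginals))
  th <- model@pairParams
  u <- matrix(0, N, m)
  L <- Rg <- lapply(seq_len(m), function(i) vector("list", m))
  u[, 1L] <- w[, 1L]
  L[[1L]][[1L]] <- Rg[[1L]][[1L]] <- u[, 1L]
  for (j in 2:m) {
    x <- w[, j]
    for (k in seq_len(j - 1L)) {
      ## invert pair (k, j) of tree j-k: from F(u_j | u_{k..j-1}) to
      ## F(u_j | u_{k+1..j-1}), conditioning on F(u_k | u_{k+1..j-1})
      x <- .hGaussInv(x, L[[k]][[j - 1L]], th[[j - k]][k])
      Rg[[k + 1L]][[j]] <- x
    }
    u[, j] <- x
    L[[j]][[j]] <- Rg[[j]][[j]] <- x
    for (k in seq_len(j - 1L))
      L[[k]][[j]] <- .hGauss(L[[k]][[j - 1L]], Rg[[k + 1L]][[j]],
                             th[[j - k]][k])
  }
  ## u columns follow the vine path; restore the original QI order
  inv <- order(model@order)
  .uniformsToTable(u[, inv, drop = FALSE], model@marginals)
})

#' Pair-copula parameters of a fitted d-vine
#' @param model a [DVineCopulaModel-class]
#' @return list over trees of numeric parameter vectors
#' @export
dvinePairParams <- function(model) {
  stopifnot(is(model, "DVineCopulaModel"))
  model@pairParams
}

#' Path order of a fitted d-vine
#' @param model a [DVineCopulaModel-class]
#' @return integer permutation of the quasi-identifier indices
#' @export
dvineOrder <- function(model) {
  stopifnot(is(model, "DVineCopulaModel"))
  model@order
}

setMethod("show", "DVineCopulaModel", function(object) {
  m <- length(object@marginals)
  cat(sprintf("DVineCopulaModel over %d quasi-identifier(s)\n", m))
  if (m >= 2L) {
    cat("  path:", paste(names(object@marginals)[object@order],
                         collapse = " - "), "\n")
    cat(sprintf("  tree-1 parameters: %s\n",
                paste(sprintf("%.3f", object@pairParams[[1]]), collapse = ", ")))
  }
})
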