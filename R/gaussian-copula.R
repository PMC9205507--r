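#' @include marginals.R
NULL

#' Mutual information of two categorical vectors
#'
#' Plug-in estimate from the contingency table, in nats, with the
#' Miller-Madow bias correction (r-1)(c-1)/(2n) subtracted (floored at 0).
#' The correction keeps mutual-information comparisons between samples of
#' different sizes honest, which matters when matching a model's synthetic
#' mutual information to a sample's.
#'
#' @param x,y equal-length vectors treated as categorical
#' @return non-negative numeric, nats
#' @export
mutualInformation <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  mm <- (nrow(tab) - 1) * (ncol(tab) - 1) / (2 * n)
  max(mi - mm, 0)
}

## Repair a pairwise-assembled matrix into a valid correlation matrix:
## clip eigenvalues at 1e-6, then renormalize to unit diagonal.
.psdRepair <- function(r) {
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

## Calibrate one pairwise latent correlation by mutual-information matching:
## find rho such that a seeded calibration draw from the bivariate Gaussian
## copula, pushed through the two marginals, has the same (bias-corrected)
## contingency-table mutual information as the sample pair. The search runs
## on the half-interval whose sign the normal-scores correlation indicates;
## synthetic MI is monotone in |rho| there, so the |difference| objective is
## unimodal and Brent's method applies.
.calibratePairRho <- function(miTarget, margI, margJ, e1, e2, init) {
  u1 <- stats::pnorm(e1)
  c1 <- .marginalInverse(margI, u1)
  synthMi <- function(rho) {
    z2 <- rho * e1 + sqrt(1 - rho^2) * e2
    c2 <- .marginalInverse(margJ, stats::pnorm(z2))
    mutualInformation(c1, c2)
  }
  obj <- function(rho) abs(synthMi(rho) - miTarget)
  interval <- if (init >= 0) c(0, 0.99) else c(-0.99, 0)
  opt <- stats::optimize(obj, interval = interval, tol = 0.005)
  opt$minimum
}

#' Fit a Gaussian copula to the quasi-identifiers of a sample
#'
#' Marginals are empirical CDFs of the sample. Each pairwise latent
#' correlation rho_ij is calibrated so that the mutual information of a
#' synthetic draw from the fitted pair matches the mutual information
#' observed in the sample, searched over rho by Brent's method on a
#' fixed-size seeded calibration draw. The assembled matrix is repaired to
#' a valid (PSD, unit-diagonal) correlation matrix by eigenvalue clipping.
#'
#' @param sample a [MicrodataTable-class]
#' @param qi quasi-identifier column names
#' @param seed integer seed for the calibration draws (fit is deterministic
#'   given (sample, qi, seed))
#' @param calibrationSize rows in the calibration draw used to evaluate the
#'   synthetic mutual information (default 10000)
#' @return a [GaussianCopulaModel-class]
#' @export
fitGaussianCopula <- function(sample, qi, seed, calibrationSize = 10000L) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  marginals <- fitMarginals(sample, qi)
  m <- length(qi)
  rho <- diag(1, m)
  if (m >= 2L) {
    seeds <- .deriveSeeds(seed, 2L, salt = 101L)
    z <- .normalScores(sample, marginals, seeds[1])
    calib <- withr::with_seed(seeds[2],
      matrix(stats::rnorm(2 * calibrationSize), ncol = 2))
    constant <- vapply(marginals, function(mt)
      length(mt@categories) < 2L, logical(1))
    if (any(constant))
      warning(sprintf("constant quasi-identifier(s) %s: correlations fixed at 0",
                      paste(qi[constant], collapse = ", ")))
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (constant[i] || constant[j]) next
        miTarget <- mutualInformation(sample@data[[qi[i]]],
                                      sample@data[[qi[j]]])
        init <- stats::cor(z[, i], z[, j])
        r <- .calibratePairRho(miTarget, marginals[[i]], marginals[[j]],
                               calib[, 1], calib[, 2], init)
        rho[i, j] <- rho[j, i] <- r
      }
    }
    rho <- .psdRepair(rho)
  }
  new("GaussianCopulaModel", marginals = marginals, rho = rho,
      seed = as.integer(seed))
}

#' @describeIn sampleCopula draw from a Gaussian copula model: multivariate
#'   normal draw, probability-integral transform, inverse empirical CDF per
#'   column
#' @export
setMethod("sampleCopula", "GaussianCopulaModel", function(model, N, seed) {
  N <- as.integer(round(N))
  if (N < 1L) validationError("N must be a positive integer")
  m <- length(model@marginals)
  z <- withr::with_seed(as.integer(seed),
    matrix(stats::rnorm(N * m), N, m))
  if (m >= 2L) z <- z %*% chol(model@rho)
  .uniformsToTable(stats::pnorm(z), model@marginals)
})

#' Latent correlation matrix of a fitted Gaussian copula
#' @param model a [GaussianCopulaModel-class]
#' @return m x m correlation matrix
#' @export
copulaCorrelation <- function(model) {
  stopifnot(is(model, "GaussianCopulaModel"))
  model@rho
}

setMethod("show", "GaussianCopulaModel", function(object) {
  m <- length(object@marginals)
  cat(sprintf("GaussianCopulaModel over %d quasi-identifier(s): %s\n", m,
              paste(names(object@marginals), collapse = ", ")))
  if (m >= 2L) {
    off <- object@rho[upper.tri(object@rho)]
    cat(sprintf("  latent correlations in [%.3f, %.3f]\n", min(off), max(off)))
  }
})
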