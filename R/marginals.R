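#' @include baselines.R
NULL

## Deterministic sub-seed derivation. Every stochastic routine draws its
## randomness inside withr::with_seed() on a seed derived here, so the
## global RNG state is never touched and (inputs, seed) fixes every output.
.deriveSeeds <- function(seed, n, salt = 0L) {
  base <- (as.numeric(seed) * 1000003 + as.numeric(salt) * 7919) %% 2147483647
  withr::with_seed(as.integer(base), sample.int(2147483646L, n))
}

#' Fit empirical-CDF marginal transforms
#'
#' One [MarginalTransform-class] per quasi-identifier: the observed category
#' proportions in domain (first-appearance) order and their cumulative sums.
#' These marginals are the univariate halves of both copula models.
#'
#' @param sample a [MicrodataTable-class]
#' @param qi quasi-identifier column names
#' @return named list of [MarginalTransform-class], one per QI
#' @export
fitMarginals <- function(sample, qi) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  n <- rowCount(sample)
  out <- lapply(qi, function(cn) {
    col <- sample@data[[cn]]
    cats <- sample@domains[[cn]]
    cats <- cats[cats %in% col]  # observed categories only, domain order
    counts <- as.integer(table(factor(col, levels = cats)))
    probs <- counts / n
    new("MarginalTransform", column = cn, categories = cats,
        probs = probs, cumProbs = cumsum(probs))
  })
  names(out) <- qi
  out
}

#' @describeIn categoryDomains ordered categories of a MarginalTransform
#' @export
setMethod("categoryDomains", "MarginalTransform", function(x) x@categories)

## Distributional transform: category i occupies the cumulative-mass
## interval (cum[i-1], cum[i]]; a value in category i maps to a uniform
## draw in that interval ("jitter"), making the discrete column usable as a
## continuous pseudo-observation. u01 supplies the uniforms.
.marginalForward <- function(marginal, values, u01) {
  idx <- match(values, marginal@categories)
  if (anyNA(idx))
    validationError(sprintf("value outside the fitted categories of '%s'",
                            marginal@column))
  lo <- c(0, marginal@cumProbs)[idx]
  hi <- marginal@cumProbs[idx]
  lo + u01 * (hi - lo)
}

## Inverse: u maps to the first category whose cumulative mass >= u.
.marginalInverse <- function(marginal, u) {
  breaks <- c(0, marginal@cumProbs)
  breaks[length(breaks)] <- 1  # guard the top edge against rounding
  idx <- cut(pmin(pmax(u, 0), 1), breaks = breaks, labels = FALSE,
             include.lowest = TRUE)
  marginal@categories[idx]
}

## Continuous pseudo-observations for a whole table: seeded jitter, then
## the standard normal quantile. Returns an n x m matrix of normal scores.
.normalScores <- function(sample, marginals, seed) {
  n <- rowCount(sample)
  m <- length(marginals)
  u <- withr::with_seed(as.integer(seed), matrix(stats::runif(n * m), n, m))
  z <- matrix(0, n, m)
  for (j in seq_len(m)) {
    uj <- .marginalForward(marginals[[j]], sample@data[[marginals[[j]]@column]],
                           u[, j])
    z[, j] <- stats::qnorm(pmin(pmax(uj, 1e-12), 1 - 1e-12))
  }
  z
}

## Map a matrix of copula uniforms (columns in `marginals` order) back to a
## MicrodataTable in the original data space.
.uniformsToTable <- function(u, marginals) {
  cols <- lapply(seq_along(marginals), function(j)
    .marginalInverse(marginals[[j]], u[, j]))
  names(cols) <- vapply(marginals, function(mt) mt@column, character(1))
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE,
                      optional = TRUE)
  domains <- lapply(marginals, function(mt) mt@categories)
  names(domains) <- names(cols)
  new("MicrodataTable", data = df, domains = domains)
}
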