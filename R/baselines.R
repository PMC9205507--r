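#' @include risk-metrics.R
NULL

## The three literature baselines estimate B = (1/n) sum 1/F_k from the
## sample alone plus the known population size N. All three assume simple
## random sampling, so every record shares the sampling fraction pi = n/N.

#' Entropy (independence) estimator of the sample-to-population risk
#'
#' Assumes the quasi-identifiers are independent: each record's population
#' cell probability is estimated as the product of its sample marginal
#' proportions, giving an expected population class size F_hat = N * prod(p_j).
#' F_hat is clamped below at the record's sample class size f_k (a population
#' class cannot be smaller than its sample class), then
#' B_hat = (1/n) sum 1/F_hat_k. When the quasi-identifiers are actually
#' dependent the product underestimates cell probabilities, so this
#' estimator tends to overestimate the risk.
#'
#' @param sample a [MicrodataTable-class]
#' @param qi quasi-identifier column names
#' @param N population size (>= sample size)
#' @return a [RiskEstimate-class] (metric "B_hat", method "entropy")
#' @export
entropyEstimator <- function(sample, qi, N) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  n <- rowCount(sample)
  N <- as.integer(round(N))
  if (N < n) validationError("N must be at least the sample size")
  pHat <- rep(1, n)
  for (cn in qi) {
    col <- sample@data[[cn]]
    prop <- table(col) / n
    pHat <- pHat * as.numeric(prop[col])
  }
  if (any(pHat <= 0))
    stop("internal error: zero marginal proportion for an observed record")
  classes <- equivalenceClasses(sample, qi)
  f <- .classSizesFor(classes, sample)$sizes
  Fhat <- pmax(f, N * pHat)
  perRec <- 1 / Fhat
  .riskEstimate(mean(perRec), "B_hat", "entropy", n, N, perRecord = perRec)
}

#' Hypothesis-test (zero-truncated Poisson) estimator
#'
#' Assumes population equivalence-class sizes follow a zero-truncated
#' Poisson distribution. Under simple random sampling with fraction
#' pi = n/N, a class observed with sample size f has Poisson rate estimate
#' lambda_hat = f / pi; the expected population class size under zero
#' truncation is F_hat = lambda_hat / (1 - exp(-lambda_hat)), and
#' B_hat = (1/n) sum over records of 1/F_hat_k. In the census limit
#' (pi = 1, large f) the truncation correction vanishes and F_hat -> f.
#'
#' @inheritParams entropyEstimator
#' @return a [RiskEstimate-class] (metric "B_hat", method "hypothesis_test")
#' @export
hypothesisTestEstimator <- function(sample, qi, N) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  n <- rowCount(sample)
  N <- as.integer(round(N))
  if (N < n) validationError("N must be at least the sample size")
  piHat <- n / N
  if (piHat <= 0) validationError("sampling fraction must be positive")
  classes <- equivalenceClasses(sample, qi)
  f <- .classSizesFor(classes, sample)$sizes
  lambda <- f / piHat
  Fhat <- lambda / (1 - exp(-lambda))
  perRec <- 1 / Fhat
  .riskEstimate(mean(perRec), "B_hat", "hypothesis_test", n, N,
                perRecord = perRec)
}

#' Expected inverse population class size under the Benedetti-Franconi model
#'
#' For a record whose sample class size is f, the Benedetti-Franconi model
#' under simple random sampling with fraction pi takes the unobserved part
#' of the population class as negative binomial:
#' P(F = f + j | f) = choose(f + j - 1, j) * pi^f * (1 - pi)^j, j >= 0.
#' The per-record risk is the posterior mean r = E\[1/F | f\], computed by
#' truncated series summation carried until the remaining negative-binomial
#' tail mass is below 1e-12. Closed forms exist for small f, e.g.
#' r(f = 1) = (pi/(1-pi)) * log(1/pi) and
#' r(f = 2) = pi/(1-pi) - (pi/(1-pi))^2 * log(1/pi); the series agrees with
#' them and they are used as cross-checks in the test suite. At pi = 1 the
#' census limit r = 1/f is returned.
#'
#' @param f integer vector of sample class sizes (>= 1)
#' @param pi sampling fraction in (0, 1\]
#' @return numeric vector of E\[1/F | f\]
#' @export
bfExpectedInverseF <- function(f, pi) {
  if (pi <= 0 || pi > 1) validationError("pi must lie in (0, 1]")
  f <- as.integer(f)
  if (any(f < 1L)) validationError("sample class sizes must be >= 1")
  if (pi == 1) return(1 / f)
  vapply(f, function(fk) {
    logPmf <- function(j) lchoose(fk + j - 1, j) + fk * log(pi) + j * log1p(-pi)
    total <- 0
    cum <- 0
    j <- 0
    repeat {
      p <- exp(logPmf(j))
      total <- total + p / (fk + j)
      cum <- cum + p
      if (1 - cum < 1e-12) break
      j <- j + 1
      if (j > 5e6) break  # unreachable for pi bounded away from 0
    }
    total
  }, numeric(1))
}

#' Benedetti-Franconi (Bayesian) estimator
#'
#' Treats each record's unknown population class size F as a random variable
#' given its sample class size f and the sampling fraction pi = n/N, with
#' (F - f) | f negative binomial (see [bfExpectedInverseF()]). The dataset
#' risk is the mean posterior per-record risk:
#' B_hat = (1/n) sum over records of E\[1/F | f_k\].
#'
#' @inheritParams entropyEstimator
#' @return a [RiskEstimate-class] (metric "B_hat",
#'   method "benedetti_franconi")
#' @export
benedettiFranconiEstimator <- function(sample, qi, N) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  n <- rowCount(sample)
  N <- as.integer(round(N))
  if (N < n) validationError("N must be at least the sample size")
  piHat <- n / N
  classes <- equivalenceClasses(sample, qi)
  f <- .classSizesFor(classes, sample)$sizes
  rByF <- bfExpectedInverseF(sort(unique(f)), piHat)
  names(rByF) <- sort(unique(f))
  perRec <- unname(rByF[as.character(f)])
  .riskEstimate(mean(perRec), "B_hat", "benedetti_franconi", n, N,
                perRecord = perRec)
}
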