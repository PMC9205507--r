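#' @include dvine.R
NULL

## Named sub-seed streams for one estimator invocation. A documented
## deterministic split of the root seed: fitting and synthesis of each
## copula and the simple-random-sampling draw each get their own stream.
.estimatorSeeds <- function(seed, salt = 0L) {
  s <- .deriveSeeds(seed, 5L, salt = salt)
  names(s) <- c("gaussianFit", "gaussianSample", "dvineFit", "dvineSample",
                "srs")
  s
}

## Fit both copula models once; reused by the estimator and by the
## N-sensitivity analysis (the fit does not depend on N).
.fitCopulaModels <- function(sample, qi, seeds) {
  list(
    gaussian = fitGaussianCopula(sample, qi, seed = seeds[["gaussianFit"]]),
    dvine = fitDVineCopula(sample, qi, seed = seeds[["dvineFit"]])
  )
}

## Synthesize a population of size N from `model`, draw a synthetic sample
## of size n by SRS without replacement, and replay the attack: B computed
## from the synthetic pair.
.syntheticB <- function(model, N, n, sampleSeed, srsSeed, qi) {
  pop <- sampleCopula(model, N, seed = sampleSeed)
  popClasses <- equivalenceClasses(pop, qi)
  idx <- withr::with_seed(as.integer(srsSeed), sample.int(N, n))
  sampleToPopulationRisk(pop[idx, ], popClasses)
}

#' Synthetic-population estimator of the sample-to-population risk
#'
#' Estimates B = (1/n) sum 1/F_k when the population class sizes F_k are
#' unknown: a generative copula model is fitted to the quasi-identifiers of
#' the sample, a synthetic population of the known size N is drawn from it,
#' a synthetic sample of size n is drawn from the synthetic population by
#' simple random sampling without replacement, and B is computed exactly on
#' the synthetic pair. `method = "average"` runs both the Gaussian-copula
#' and d-vine variants (each on its own derived sub-seed streams) and
#' returns their unweighted arithmetic mean, which is the recommended
#' estimator.
#'
#' @param sample a [MicrodataTable-class], the real microdata sample
#' @param qi quasi-identifier column names; synthesis uses only these
#' @param N population size (>= sample size)
#' @param method "average" (default), "gaussian_copula" or "dvine_copula"
#' @param seed integer root seed; the estimate is deterministic given
#'   (sample, qi, N, method, seed)
#' @param fit optional precomputed model list from a previous run (internal
#'   use by [sensitivityToN()]); when supplied the fitting step is skipped
#' @param .seedSalt internal salt added to the sub-seed derivation so that
#'   related runs (e.g. the per-delta rows of a sensitivity analysis) get
#'   distinct but reproducible streams
#' @return a [RiskEstimate-class] (metric "B_hat")
#' @export
estimateSampleToPopulation <- function(sample, qi, N,
                                       method = c("average",
                                                  "gaussian_copula",
                                                  "dvine_copula"),
                                       seed, fit = NULL,
                                       .seedSalt = 0L) {
  stopifnot(is(sample, "MicrodataTable"))
  method <- match.arg(method)
  n <- rowCount(sample)
  N <- as.integer(round(N))
  if (N < n)
    validationError(sprintf("population size N = %d below sample size n = %d",
                            N, n))
  .checkQi(sample, qi)
  seeds <- .estimatorSeeds(seed, salt = .seedSalt)
  if (is.null(fit)) {
    fit <- switch(method,
      average = .fitCopulaModels(sample, qi, seeds),
      gaussian_copula = list(
        gaussian = fitGaussianCopula(sample, qi, seeds[["gaussianFit"]])),
      dvine_copula = list(
        dvine = fitDVineCopula(sample, qi, seeds[["dvineFit"]])))
  }
  bOf <- function(which) {
    .syntheticB(fit[[which]], N, n,
                sampleSeed = seeds[[paste0(which, "Sample")]],
                srsSeed = seeds[["srs"]], qi = qi)
  }
  value <- switch(method,
    gaussian_copula = riskValue(bOf("gaussian")),
    dvine_copula = riskValue(bOf("dvine")),
    average = (riskValue(bOf("gaussian")) + riskValue(bOf("dvine"))) / 2)
  .riskEstimate(value, "B_hat", method, n, N, seed = seed)
}

#' Sensitivity of the synthetic estimator to errors in N
#'
#' In practice the population size is rarely known exactly. This reruns the
#' average-copula estimator with the population-size input perturbed to
#' N_used = round(N_true * (1 + delta)) for each requested relative
#' perturbation delta. The copula fit depends only on the sample, so the
#' models are fitted once (with the base sub-seeds); each nonzero delta
#' re-synthesizes with its own derived sub-seeds, while delta = 0 uses the
#' base sub-seeds and therefore reproduces the unperturbed estimate exactly.
#'
#' @param sample a [MicrodataTable-class]
#' @param qi quasi-identifier column names
#' @param NTrue the believed true population size
#' @param deltas numeric vector of relative perturbations (e.g. -0.3 .. 0.3)
#' @param seed integer root seed
#' @param method estimator variant, default "average"
#' @return data.frame with one row per delta: `delta`, `N_used`, `value`
#'   (the B_hat estimate), `method`
#' @export
sensitivityToN <- function(sample, qi, NTrue, deltas, seed,
                           method = c("average", "gaussian_copula",
                                      "dvine_copula")) {
  stopifnot(is(sample, "MicrodataTable"))
  method <- match.arg(method)
  n <- rowCount(sample)
  NUsed <- as.integer(round(NTrue * (1 + deltas)))
  if (any(NUsed < n))
    validationError(sprintf(
      "perturbation delta = %g yields N_used = %d below the sample size %d",
      deltas[which(NUsed < n)[1]], min(NUsed), n))
  baseSeeds <- .estimatorSeeds(seed)
  fit <- switch(method,
    average = .fitCopulaModels(sample, qi, baseSeeds),
    gaussian_copula = list(
      gaussian = fitGaussianCopula(sample, qi, baseSeeds[["gaussianFit"]])),
    dvine_copula = list(
      dvine = fitDVineCopula(sample, qi, baseSeeds[["dvineFit"]])))
  rows <- lapply(seq_along(deltas), function(d) {
    salt <- if (deltas[d] == 0) 0L else d
    est <- estimateSampleToPopulation(sample, qi, NUsed[d], method = method,
                                      seed = seed, fit = fit,
                                      .seedSalt = salt)
    data.frame(delta = deltas[d], N_used = NUsed[d], value = riskValue(est),
               method = method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
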