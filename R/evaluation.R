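#' @include synthetic-estimator.R
NULL

#' Specification of a synthetic study population
#'
#' Describes a categorical population generated from a latent Gaussian
#' copula: per-variable marginal distributions over a fixed number of
#' categories, and a latent correlation matrix (or independence). Used by
#' the evaluation harness as a generator-known stand-in for real population
#' datasets, so that the true risk B of any sample is computable exactly.
#'
#' @param N population size
#' @param vars list of per-variable specs; each element is a list with
#'   `name`, `levels` (category count) and either `dist = "uniform"`,
#'   `dist = "zipf"` with exponent `s` (probabilities proportional to
#'   rank^-s), or `dist = "explicit"` with a `probs` vector summing to 1
#' @param dependence "independent" or a valid latent correlation matrix
#'   (symmetric, PSD, unit diagonal) of dimension length(vars)
#' @param seed integer generation seed
#' @return an object of class "PopulationSpec"
#' @export
populationSpec <- function(N, vars, dependence = "independent", seed) {
  m <- length(vars)
  if (m < 1L) validationError("need at least one variable")
  vars <- lapply(vars, function(v) {
    if (is.null(v$name) || is.null(v$levels))
      validationError("every variable needs a name and a level count")
    k <- as.integer(v$levels)
    if (k < 1L) validationError("level count must be >= 1")
    dist <- if (is.null(v$dist)) "uniform" else v$dist
    probs <- switch(dist,
      uniform = rep(1 / k, k),
      zipf = {
        s <- if (is.null(v$s)) 1 else v$s
        p <- seq_len(k)^(-s)
        p / sum(p)
      },
      explicit = {
        p <- v$probs
        if (length(p) != k || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
          validationError(sprintf(
            "explicit probabilities for '%s' must be %d positive values summing to 1",
            v$name, k))
        p
      },
      validationError(sprintf("unknown marginal distribution '%s'", dist)))
    list(name = v$name, levels = k, probs = probs)
  })
  if (is.character(dependence) && identical(dependence, "independent")) {
    R <- diag(1, m)
  } else {
    R <- as.matrix(dependence)
    if (!all(dim(R) == c(m, m)) || max(abs(R - t(R))) > 1e-8 ||
        max(abs(diag(R) - 1)) > 1e-8 ||
        min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      validationError("dependence must be a valid correlation matrix")
  }
  structure(list(N = as.integer(N), vars = vars, R = R,
                 seed = as.integer(seed)),
            class = "PopulationSpec")
}

#' Generate a synthetic population from a PopulationSpec
#'
#' Draws latent multivariate normals with the spec's correlation matrix,
#' applies the probability-integral transform, and maps each uniform to a
#' category by the inverse CDF of the variable's marginal. Deterministic
#' given the spec (which carries its seed).
#'
#' @param spec a [populationSpec()] object
#' @return a [MicrodataTable-class] with `spec$N` rows
#' @export
generateSyntheticPopulation <- function(spec) {
  stopifnot(inherits(spec, "PopulationSpec"))
  m <- length(spec$vars)
  z <- withr::with_seed(spec$seed,
    matrix(stats::rnorm(spec$N * m), spec$N, m))
  if (m >= 2L) z <- z %*% chol(spec$R)
  u <- stats::pnorm(z)
  cols <- lapply(seq_len(m), function(j) {
    v <- spec$vars[[j]]
    labels <- sprintf("%s%02d", v$name, seq_len(v$levels))
    breaks <- c(0, cumsum(v$probs))
    breaks[length(breaks)] <- 1
    labels[cut(u[, j], breaks = breaks, labels = FALSE, include.lowest = TRUE)]
  })
  names(cols) <- vapply(spec$vars, `[[`, character(1), "name")
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE,
                      optional = TRUE)
  ## explicit domains in rank order (not first-appearance) so the marginal
  ## ordering is reproducible regardless of which category appears first
  domains <- lapply(spec$vars, function(v)
    sprintf("%s%02d", v$name, seq_len(v$levels)))
  names(domains) <- names(cols)
  domains <- lapply(names(cols), function(cn)
    domains[[cn]][domains[[cn]] %in% df[[cn]]])
  names(domains) <- names(cols)
  new("MicrodataTable", data = df, domains = domains)
}

#' Reference study population for estimator evaluation
#'
#' The package's default generator-known study design: a hospital-style
#' categorical population with five quasi-identifiers of mixed cardinality
#' and skew -- region (30 levels, Zipf(1)), age band (12, uniform),
#' diagnosis group (25, Zipf(1.2)), education (5, Zipf(1)) and sex (2,
#' uniform) -- coupled through an AR(1)-style latent correlation (0.5 between
#' neighbouring variables). At N = 50,000 this yields a population whose
#' true sample-to-population risk spans from ~1e-4 (one broad QI) to ~0.4
#' (all five QIs, ~24% population uniques), so simulation runs populate a
#' range of true-risk bins.
#'
#' @param N population size, default 50000
#' @param seed integer generation seed
#' @return a [populationSpec()] object
#' @export
studyPopulationSpec <- function(N = 50000L, seed) {
  R <- outer(1:5, 1:5, function(i, j) 0.5^abs(i - j))
  populationSpec(N, list(
    list(name = "region", levels = 30, dist = "zipf", s = 1),
    list(name = "ageband", levels = 12),
    list(name = "diagnosis", levels = 25, dist = "zipf", s = 1.2),
    list(name = "education", levels = 5, dist = "zipf", s = 1),
    list(name = "sex", levels = 2)),
    dependence = R, seed = seed)
}

.builtinEstimators <- c("entropy", "hypothesis_test", "benedetti_franconi",
                        "gaussian_copula", "dvine_copula", "average")

## Dispatch one estimator by name. Estimators see only the sample, the QI
## names, N and a seed -- never the population.
.runEstimator <- function(name, sample, qi, N, seed) {
  switch(name,
    entropy = riskValue(entropyEstimator(sample, qi, N)),
    hypothesis_test = riskValue(hypothesisTestEstimator(sample, qi, N)),
    benedetti_franconi = riskValue(benedettiFranconiEstimator(sample, qi, N)),
    validationError(sprintf("unknown estimator '%s'", name)))
}

#' Run the estimator-error simulation
#'
#' Replays the evaluation design: each run picks a quasi-identifier subset
#' size uniformly from 1..m, a uniformly random subset of that size, and a
#' sampling fraction from Uniform(0.01, 0.99); draws a simple random sample
#' of size n = round(fraction * N) from the population (redrawing the
#' fraction if rounding gives n < 1); computes the true risk B exactly from
#' the population's equivalence classes; and computes every requested
#' estimate from the sample, the QI names and N alone. The signed error is
#' B_hat - B (positive = overestimation).
#'
#' The three copula-based methods share their fits within a run: "average"
#' is the arithmetic mean of the two single-copula estimates.
#'
#' @param population a [MicrodataTable-class], the generator-known
#'   population
#' @param qiPool character vector: the pool of quasi-identifier columns
#' @param nRuns number of simulation runs (the reference design uses 1000
#'   study points; smaller counts give a faster, noisier summary)
#' @param methods character vector from `entropy`, `hypothesis_test`,
#'   `benedetti_franconi`, `gaussian_copula`, `dvine_copula`, `average`,
#'   and/or named list entries of custom functions
#'   `function(sample, qi, N, seed)` returning a probability
#' @param seed integer root seed; run r uses a derived sub-seed
#' @return a "SimulationResult": long-format data.frame with columns
#'   `run_id`, `qi_subset`, `m`, `sampling_fraction`, `n`, `true_B`,
#'   `method`, `estimate`, `error`
#' @export
runSimulation <- function(population, qiPool, nRuns, methods = "average",
                          seed) {
  stopifnot(is(population, "MicrodataTable"))
  .checkQi(population, qiPool)
  if (nRuns < 1L) validationError("nRuns must be >= 1")
  custom <- Filter(is.function, as.list(methods))
  methodNames <- vapply(seq_along(methods), function(i) {
    if (is.function(methods[[i]])) {
      nm <- names(methods)[i]
      if (is.null(nm) || nm == "")
        validationError("custom estimator functions must be named")
      nm
    } else as.character(methods[[i]])
  }, character(1))
  unknown <- setdiff(setdiff(methodNames, names(custom)), .builtinEstimators)
  if (length(unknown))
    validationError(sprintf("unknown estimator(s): %s",
                            paste(unknown, collapse = ", ")))
  N <- rowCount(population)
  mPool <- length(qiPool)
  runSeeds <- .deriveSeeds(seed, nRuns, salt = 303L)
  classCache <- new.env(parent = emptyenv())
  needGauss <- any(methodNames %in% c("gaussian_copula", "average"))
  needDvine <- any(methodNames %in% c("dvine_copula", "average"))
  out <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    rs <- runSeeds[r]
    design <- withr::with_seed(rs, {
      mSel <- sample.int(mPool, 1L)
      qi <- sort(sample(qiPool, mSel))
      frac <- stats::runif(1, 0.01, 0.99)
      n <- as.integer(round(frac * N))
      while (n < 1L) {
        frac <- stats::runif(1, 0.01, 0.99)
        n <- as.integer(round(frac * N))
      }
      idx <- sample.int(N, n)
      list(qi = qi, frac = frac, n = n, idx = idx)
    })
    qi <- design$qi
    key <- paste(qi, collapse = "|")
    if (is.null(classCache[[key]]))
      classCache[[key]] <- equivalenceClasses(population, qi)
    popClasses <- classCache[[key]]
    smp <- population[design$idx, ]
    trueB <- riskValue(sampleToPopulationRisk(smp, popClasses))
    estSeeds <- .deriveSeeds(rs, length(methodNames) + 2L, salt = 404L)
    copulaSeed <- estSeeds[length(methodNames) + 1L]
    bGauss <- bDvine <- NA_real_
    if (needGauss)
      bGauss <- riskValue(estimateSampleToPopulation(
        smp, qi, N, method = "gaussian_copula", seed = copulaSeed))
    if (needDvine)
      bDvine <- riskValue(estimateSampleToPopulation(
        smp, qi, N, method = "dvine_copula", seed = copulaSeed,
        .seedSalt = 1L))
    est <- vapply(seq_along(methodNames), function(i) {
      nm <- methodNames[i]
      if (nm %in% names(custom))
        return(custom[[nm]](smp, qi, N, estSeeds[i]))
      switch(nm,
        gaussian_copula = bGauss,
        dvine_copula = bDvine,
        average = (bGauss + bDvine) / 2,
        .runEstimator(nm, smp, qi, N, estSeeds[i]))
    }, numeric(1))
    out[[r]] <- data.frame(
      run_id = r, qi_subset = key, m = length(qi),
      sampling_fraction = design$frac, n = design$n, true_B = trueB,
      method = methodNames, estimate = est, error = est - trueB,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("SimulationResult", "data.frame")
  res
}

#' Signed estimation error
#'
#' The convention used throughout the evaluation: estimate minus truth, so
#' positive values mean overestimation.
#'
#' @param estimate a [RiskEstimate-class] or numeric probability
#' @param trueB the true risk B in \[0, 1\]
#' @return signed numeric error
#' @export
computeError <- function(estimate, trueB) {
  v <- if (is(estimate, "RiskEstimate")) riskValue(estimate) else estimate
  if (any(v < 0 | v > 1) || any(trueB < 0 | trueB > 1))
    validationError("both arguments must be probabilities in [0, 1]")
  v - trueB
}

#' Summarize simulation errors in true-risk bins
#'
#' Bins the runs by true risk into ten 0.1-wide intervals
#' \[0, 0.1), ..., \[0.9, 1\] (the last bin closed above) and reports, per
#' bin and method, the count and the median and quartiles of the signed
#' error. The median uses the midpoint-of-two convention for even counts
#' and the quartiles use the inclusive linear-interpolation convention
#' (`stats::quantile` type 7). Empty bins are reported with count 0 and NA
#' statistics.
#'
#' @param result a "SimulationResult" from [runSimulation()]
#' @return an "ErrorSummary" data.frame: `method`, `bin_lo`, `bin_hi`,
#'   `count`, `median_error`, `q1`, `q3`
#' @export
summarizeErrors <- function(result) {
  stopifnot(inherits(result, "data.frame"),
            all(c("method", "true_B", "error") %in% colnames(result)))
  lo <- seq(0, 0.9, by = 0.1)
  binOf <- function(b) pmin(findInterval(b, lo), 10L)
  result$.bin <- binOf(result$true_B)
  methods <- unique(result$method)
  grid <- expand.grid(method = methods, bin = 1:10,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e <- result$error[result$method == grid$method[i] &
                        result$.bin == grid$bin[i]]
    b <- grid$bin[i]
    if (length(e) == 0L)
      data.frame(method = grid$method[i], bin_lo = lo[b], bin_hi = lo[b] + 0.1,
                 count = 0L, median_error = NA_real_, q1 = NA_real_,
                 q3 = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(method = grid$method[i], bin_lo = lo[b], bin_hi = lo[b] + 0.1,
                 count = length(e), median_error = stats::median(e),
                 q1 = unname(stats::quantile(e, 0.25, type = 7)),
                 q3 = unname(stats::quantile(e, 0.75, type = 7)),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$bin_lo), ]
  rownames(out) <- NULL
  class(out) <- c("ErrorSummary", "data.frame")
  out
}
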