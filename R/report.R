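#' @include evaluation.R
NULL

#' Build a JSON-serializable risk report
#'
#' Assembles, for a microdata sample that is about to be shared: a dataset
#' fingerprint (record count, quasi-identifier names, per-QI category
#' counts), the exact population-to-sample match rate A, one estimated
#' sample-to-population match rate B_hat per requested method, and a verdict
#' per estimate against the acceptable-risk threshold (default 0.09, the
#' value commonly recommended by data custodians). The verdict is "below"
#' iff the estimate is strictly less than the threshold; an estimate equal
#' to the threshold is "above".
#'
#' @param sample a [MicrodataTable-class]
#' @param qi quasi-identifier column names
#' @param N population size
#' @param methods estimator labels for B_hat: any of "average",
#'   "gaussian_copula", "dvine_copula", "entropy", "hypothesis_test",
#'   "benedetti_franconi"
#' @param threshold acceptable-risk threshold in (0, 1), default 0.09
#' @param seed integer root seed for the stochastic estimators
#' @return a list of class "RiskReport"
#' @export
buildRiskReport <- function(sample, qi, N, methods = "average",
                            threshold = 0.09, seed) {
  stopifnot(is(sample, "MicrodataTable"))
  .checkQi(sample, qi)
  if (threshold <= 0 || threshold >= 1)
    validationError("threshold must lie in (0, 1)")
  N <- as.integer(round(N))
  a <- populationToSampleRisk(sample, qi, N)
  catCounts <- vapply(qi, function(cn)
    length(unique(sample@data[[cn]])), integer(1))
  estSeeds <- .deriveSeeds(seed, length(methods), salt = 505L)
  estimates <- lapply(seq_along(methods), function(i) {
    nm <- methods[i]
    value <- if (nm %in% c("average", "gaussian_copula", "dvine_copula"))
      riskValue(estimateSampleToPopulation(sample, qi, N, method = nm,
                                           seed = estSeeds[i]))
    else
      .runEstimator(nm, sample, qi, N, estSeeds[i])
    list(method = nm, metric = "B_hat", value = value,
         seed = estSeeds[i],
         verdict = if (value < threshold) "below" else "above")
  })
  names(estimates) <- methods
  structure(list(
    fingerprint = list(
      n = rowCount(sample),
      quasi_identifiers = as.character(qi),
      category_counts = as.list(catCounts)),
    N = N,
    A = list(metric = "A", method = "exact", value = riskValue(a),
             verdict = if (riskValue(a) < threshold) "below" else "above"),
    estimates = estimates,
    threshold = threshold,
    seed = as.integer(seed),
    tool_version = as.character(utils::packageVersion("reidrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "RiskReport")
}

#' Write a risk report to pretty-printed JSON
#' @param report a "RiskReport" from [buildRiskReport()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeRiskReport <- function(report, path) {
  stopifnot(inherits(report, "RiskReport"))
  ## 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a risk report back from JSON
#' @param path path written by [writeRiskReport()]
#' @return a "RiskReport" list identical in content to the one written
#' @export
readRiskReport <- function(path) {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  raw$fingerprint$n <- as.integer(raw$fingerprint$n)
  raw$fingerprint$quasi_identifiers <-
    as.character(unlist(raw$fingerprint$quasi_identifiers))
  raw$fingerprint$category_counts <-
    lapply(raw$fingerprint$category_counts, as.integer)
  raw$N <- as.integer(raw$N)
  raw$seed <- as.integer(raw$seed)
  raw$estimates <- lapply(raw$estimates, function(e) {
    e$seed <- as.integer(e$seed)
    e
  })
  structure(raw, class = "RiskReport")
}

#' @export
print.RiskReport <- function(x, ...) {
  cat(sprintf("RiskReport: n = %d, N = %d, QIs: %s\n", x$fingerprint$n, x$N,
              paste(x$fingerprint$quasi_identifiers, collapse = ", ")))
  cat(sprintf("  A (population-to-sample, exact) = %.6f [%s threshold %.3g]\n",
              x$A$value, x$A$verdict, x$threshold))
  for (e in x$estimates)
    cat(sprintf("  B_hat (%s) = %.6f [%s threshold %.3g]\n",
                e$method, e$value, e$verdict, x$threshold))
  invisible(x)
}
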