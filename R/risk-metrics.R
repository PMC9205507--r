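#' @include equivalence.R
NULL

.riskEstimate <- function(value, metric, method, n, N = NA_integer_,
                          seed = NA_integer_, perRecord = numeric(0)) {
  new("RiskEstimate", value = value, metric = metric, method = method,
      n = as.integer(n), N = as.integer(N), seed = as.integer(seed),
      perRecord = perRecord)
}

#' Population-to-sample match rate (A)
#'
#' Models the attack where the adversary selects an individual from the
#' population and tries to match them to a record in the released sample:
#' A = (1/N) * sum over sample records k of 1/f_k, with f_k the size of
#' record k's equivalence class in the sample. The sum is taken per record,
#' so it equals the number of sample equivalence classes; dividing by N
#' reflects that a selected individual may not be in the sample at all.
#'
#' @param sample a [MicrodataTable-class], the released microdata sample
#' @param qi quasi-identifier column names
#' @param N population size, must be >= the sample size
#' @return a [RiskEstimate-class] with metric "A"; `perRecordRisk()` gives
#'   the per-record 1/f_k values
#' @export
populationToSampleRisk <- function(sample, qi, N) {
  stopifnot(is(sample, "MicrodataTable"))
  n <- rowCount(sample)
  N <- as.integer(round(N))
  if (N < n)
    validationError(sprintf("population size N = %d below sample size n = %d",
                            N, n))
  classes <- equivalenceClasses(sample, qi)
  f <- .classSizesFor(classes, sample)$sizes
  perRec <- 1 / f
  .riskEstimate(sum(perRec) / N, "A", "exact", n, N, perRecord = perRec)
}

#' Sample-to-population match rate (B)
#'
#' Models the attack where the adversary selects a record from the released
#' sample and matches it against the population: B = (1/n) * sum over sample
#' records k of 1/F_k, with F_k the size of record k's equivalence class in
#' the population. The sum runs over records (not classes), matching the
#' per-record indexing of the attack.
#'
#' @param sample a [MicrodataTable-class], the (real or synthetic) sample
#' @param populationClasses an [EquivalenceClasses-class] built from the
#'   population on the same quasi-identifiers
#' @return a [RiskEstimate-class] with metric "B"; `perRecordRisk()` gives
#'   the per-record 1/F_k values, so the maximum record risk is
#'   `max(perRecordRisk(x))`
#' @export
sampleToPopulationRisk <- function(sample, populationClasses) {
  stopifnot(is(sample, "MicrodataTable"),
            is(populationClasses, "EquivalenceClasses"))
  qi <- populationClasses@qiNames
  .checkQi(sample, qi)
  lk <- .classSizesFor(populationClasses, sample)
  if (any(lk$sizes == 0L)) {
    bad <- which(lk$sizes == 0L)[1L]
    tuple <- paste(unlist(sample@data[bad, qi]), collapse = ", ")
    validationError(sprintf(
      "sample record %d with quasi-identifier values (%s) is absent from the population classes",
      bad, tuple))
  }
  n <- rowCount(sample)
  perRec <- 1 / lk$sizes
  .riskEstimate(mean(perRec), "B", "exact", n, classTotal(populationClasses),
                perRecord = perRec)
}

#' @describeIn riskValue point value of a RiskEstimate
#' @export
setMethod("riskValue", "RiskEstimate", function(x) x@value)

#' @describeIn perRecordRisk per-record probabilities of a RiskEstimate
#' @export
setMethod("perRecordRisk", "RiskEstimate", function(x) x@perRecord)

#' Estimation method of a RiskEstimate
#' @param x a [RiskEstimate-class]
#' @return character label
#' @export
riskMethod <- function(x) {
  stopifnot(is(x, "RiskEstimate"))
  x@method
}

#' Metric of a RiskEstimate ("A", "B" or "B_hat")
#' @param x a [RiskEstimate-class]
#' @return character label
#' @export
riskMetric <- function(x) {
  stopifnot(is(x, "RiskEstimate"))
  x@metric
}

setMethod("show", "RiskEstimate", function(object) {
  cat(sprintf("RiskEstimate %s = %.6f  (method: %s, n = %d, N = %s%s)\n",
              object@metric, object@value, object@method, object@n,
              ifelse(is.na(object@N), "?", as.character(object@N)),
              ifelse(is.na(object@seed), "",
                     sprintf(", seed = %d", object@seed))))
})
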