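#' @include AllClasses.R
NULL

#' Number of records in a table
#' @param x a [MicrodataTable-class]
#' @return integer row count
#' @export
setGeneric("rowCount", function(x) standardGeneric("rowCount"))

#' Column names of a table
#' @param x a [MicrodataTable-class]
#' @return character vector
#' @export
setGeneric("columnNames", function(x) standardGeneric("columnNames"))

#' Ordered category domains
#' @param x a [MicrodataTable-class] or [MarginalTransform-class]
#' @return named list of character vectors (table) or a character vector
#' @export
setGeneric("categoryDomains", function(x) standardGeneric("categoryDomains"))

#' Size of the equivalence class a record belongs to
#'
#' @param classes an [EquivalenceClasses-class] table
#' @param record a character vector of quasi-identifier values, in the
#'   order of `qiNames(classes)`
#' @return the stored class size, or 0 for a tuple never observed
#' @export
setGeneric("classSize", function(classes, record) standardGeneric("classSize"))

#' Quasi-identifier names used to build an object
#' @param x an [EquivalenceClasses-class]
#' @return character vector
#' @export
setGeneric("qiNames", function(x) standardGeneric("qiNames"))

#' Class sizes
#' @param x an [EquivalenceClasses-class]
#' @return integer vector parallel to `classKeys(x)`
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' Distinct quasi-identifier value tuples
#' @param x an [EquivalenceClasses-class]
#' @return data.frame of key tuples
#' @export
setGeneric("classKeys", function(x) standardGeneric("classKeys"))

#' Point value of a risk estimate
#' @param x a [RiskEstimate-class]
#' @return numeric probability
#' @export
setGeneric("riskValue", function(x) standardGeneric("riskValue"))

#' Per-record match probabilities of a risk estimate
#' @param x a [RiskEstimate-class]
#' @return numeric vector (1/f_k or 1/F_k per sample record)
#' @export
setGeneric("perRecordRisk", function(x) standardGeneric("perRecordRisk"))

#' Draw a synthetic population from a fitted copula model
#'
#' @param model a fitted [GaussianCopulaModel-class] or
#'   [DVineCopulaModel-class]
#' @param N number of synthetic records to draw
#' @param seed integer seed; the draw is deterministic given (model, N, seed)
#' @return a [MicrodataTable-class] with N rows over the model's columns
#' @export
setGeneric("sampleCopula", function(model, N, seed) standardGeneric("sampleCopula"))
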