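#' @import methods
NULL

## Condition helpers used across the package: validation errors (bad user
## input), format errors (malformed files) and I/O errors map onto the CLI
## exit codes 2 / 2 / 3.

validationError <- function(msg, call. = FALSE) {
  stop(errorCondition(msg,
    class = c("reidrisk_validation_error", "reidrisk_error")))
}

formatError <- function(msg) {
  stop(errorCondition(msg,
    class = c("reidrisk_format_error", "reidrisk_error")))
}

ioError <- function(msg) {
  stop(errorCondition(msg,
    class = c("reidrisk_io_error", "reidrisk_error")))
}

#' MicrodataTable: a table of categorical microdata records
#'
#' Holds one row per individual. All cells are stored as canonicalized
#' character values (leading/trailing whitespace stripped, case preserved)
#' and every column carries an ordered domain of admissible category labels,
#' by default the distinct observed values in first-appearance order. The
#' domain order is load-bearing: it defines the empirical-CDF ordering used
#' by the copula marginals.
#'
#' @slot data a data.frame of character columns, one row per individual
#' @slot domains named list of character vectors, one per column, giving the
#'   ordered admissible category labels
#' @export
setClass("MicrodataTable",
  representation(data = "data.frame", domains = "list"),
  validity = function(object) {
    df <- object@data
    msgs <- character(0)
    if (nrow(df) < 1L) msgs <- c(msgs, "table must contain at least one row")
    if (anyDuplicated(colnames(df)))
      msgs <- c(msgs, "column names must be unique")
    if (!identical(names(object@domains), colnames(df)))
      msgs <- c(msgs, "domains must be named after the columns, in order")
    for (cn in colnames(df)) {
      col <- df[[cn]]
      if (!is.character(col))
        msgs <- c(msgs, sprintf("column '%s' must be character", cn))
      else if (!all(col %in% object@domains[[cn]]))
        msgs <- c(msgs, sprintf(
          "column '%s' contains values outside its domain", cn))
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' EquivalenceClasses: equivalence-class sizes on the quasi-identifiers
#'
#' Records sharing identical values on all quasi-identifiers form an
#' equivalence class. Built from a sample this table carries the f_k class
#' sizes; built from a population it carries the F_k sizes.
#'
#' @slot qiNames the quasi-identifier columns used, in order
#' @slot keys data.frame of distinct quasi-identifier value tuples
#' @slot counts integer vector of class sizes, parallel to keys
#' @slot total number of rows summarized (sum of counts)
#' @export
setClass("EquivalenceClasses",
  representation(qiNames = "character", keys = "data.frame",
                 counts = "integer", total = "integer"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@counts) != nrow(object@keys))
      msgs <- c(msgs, "counts and keys must be parallel")
    if (!identical(colnames(object@keys), object@qiNames))
      msgs <- c(msgs, "keys columns must equal qiNames")
    if (any(object@counts < 1L)) msgs <- c(msgs, "all counts must be >= 1")
    if (sum(object@counts) != object@total)
      msgs <- c(msgs, "counts must sum to total")
    if (length(msgs)) msgs else TRUE
  }
)

#' RiskEstimate: a re-identification match-rate value with provenance
#'
#' @slot value probability in \[0, 1\]
#' @slot metric "A" (population-to-sample), "B" (sample-to-population,
#'   exact) or "B_hat" (estimated sample-to-population)
#' @slot method how the value was obtained: "exact", "entropy",
#'   "hypothesis_test", "benedetti_franconi", "gaussian_copula",
#'   "dvine_copula" or "average"
#' @slot n sample size
#' @slot N population size (NA when not applicable)
#' @slot seed integer seed used, NA for deterministic methods
#' @slot perRecord per-record match probabilities (1/f_k or 1/F_k scale)
#' @export
setClass("RiskEstimate",
  representation(value = "numeric", metric = "character",
                 method = "character", n = "integer", N = "integer",
                 seed = "integer", perRecord = "numeric"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@value) != 1L || is.na(object@value) ||
        object@value < 0 || object@value > 1)
      msgs <- c(msgs, "value must be a single probability in [0, 1]")
    if (!object@metric %in% c("A", "B", "B_hat"))
      msgs <- c(msgs, "metric must be one of A, B, B_hat")
    if (!is.na(object@N) && !is.na(object@n) && object@n > object@N)
      msgs <- c(msgs, "n must not exceed N")
    if (length(msgs)) msgs else TRUE
  }
)

#' MarginalTransform: empirical CDF of one categorical column
#'
#' Stores the ordered categories and their cumulative sample proportions.
#' The distributional transform maps category i (cumulative mass interval
#' (cum\[i-1\], cum\[i\]\]) to a uniform draw within that interval; its
#' inverse maps u to the first category whose cumulative mass is >= u.
#'
#' @slot column column name
#' @slot categories ordered category labels (domain order)
#' @slot probs category proportions (all > 0, sum to 1)
#' @slot cumProbs cumulative proportions, ending at 1
#' @export
setClass("MarginalTransform",
  representation(column = "character", categories = "character",
                 probs = "numeric", cumProbs = "numeric"),
  validity = function(object) {
    msgs <- character(0)
    if (length(object@categories) != length(object@probs) ||
        length(object@probs) != length(object@cumProbs))
      msgs <- c(msgs, "categories, probs, cumProbs must be parallel")
    if (any(object@probs <= 0))
      msgs <- c(msgs, "every observed category must have positive mass")
    if (abs(object@cumProbs[length(object@cumProbs)] - 1) > 1e-8)
      msgs <- c(msgs, "cumProbs must end at 1")
    if (is.unsorted(object@cumProbs, strictly = TRUE))
      msgs <- c(msgs, "cumProbs must be strictly increasing")
    if (length(msgs)) msgs else TRUE
  }
)

#' GaussianCopulaModel: Gaussian copula over the quasi-identifiers
#'
#' Marginals are empirical CDFs; dependence is an m x m latent correlation
#' matrix whose pairwise entries are calibrated so that synthetic mutual
#' information matches the sample's.
#'
#' @slot marginals list of [MarginalTransform-class], one per QI
#' @slot rho m x m correlation matrix (symmetric, PSD, unit diagonal)
#' @slot seed integer seed used for fitting (calibration draws)
#' @export
setClass("GaussianCopulaModel",
  representation(marginals = "list", rho = "matrix", seed = "integer"),
  validity = function(object) {
    m <- length(object@marginals)
    r <- object@rho
    msgs <- character(0)
    if (!all(dim(r) == c(m, m))) msgs <- c(msgs, "rho must be m x m")
    else {
      if (max(abs(r - t(r))) > 1e-8) msgs <- c(msgs, "rho must be symmetric")
      if (max(abs(diag(r) - 1)) > 1e-8)
        msgs <- c(msgs, "rho must have unit diagonal")
      if (any(abs(r) > 1 + 1e-8))
        msgs <- c(msgs, "rho entries must lie in [-1, 1]")
      ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-6) msgs <- c(msgs, "rho must be positive semi-definite")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' DVineCopulaModel: d-vine pair-copula construction over the QIs
#'
#' A path-structured cascade of bivariate Gaussian pair-copulas: tree t
#' couples variables t apart along the path, conditionally on the variables
#' between them. For m = 1 the model degenerates to marginal resampling.
#'
#' @slot marginals list of [MarginalTransform-class], one per QI (original
#'   column order)
#' @slot order integer permutation of 1..m giving the d-vine path
#' @slot pairParams list of numeric vectors; element t holds the m - t
#'   Gaussian pair-copula parameters of tree t, each in (-1, 1)
#' @slot seed integer fitting seed
#' @export
setClass("DVineCopulaModel",
  representation(marginals = "list", order = "integer",
                 pairParams = "list", seed = "integer"),
  validity = function(object) {
    m <- length(object@marginals)
    msgs <- character(0)
    if (!identical(sort(object@order), seq_len(m)))
      msgs <- c(msgs, "order must be a permutation of 1..m")
    if (m >= 2L) {
      if (length(object@pairParams) != m - 1L)
        msgs <- c(msgs, "need m - 1 trees of pair parameters")
      else {
        for (t in seq_len(m - 1L)) {
          th <- object@pairParams[[t]]
          if (length(th) != m - t)
            msgs <- c(msgs, sprintf("tree %d must hold %d parameters", t, m - t))
          if (any(abs(th) >= 1))
            msgs <- c(msgs, sprintf("tree %d parameters must lie in (-1, 1)", t))
        }
      }
    }
    if (length(msgs)) msgs else TRUE
  }
)
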