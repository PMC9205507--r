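#' @include AllGenerics.R
NULL

.canonicalize <- function(x) trimws(as.character(x))

#' Construct a MicrodataTable from a data.frame
#'
#' Cells are canonicalized (leading/trailing whitespace stripped, case
#' preserved) and coerced to character; matching throughout the package is
#' exact string equality on these canonical values. Column domains default
#' to the distinct observed values in first-appearance order, which fixes
#' the empirical-CDF ordering used by the copula marginals.
#'
#' @param df a data.frame, one row per individual
#' @param domains optional named list of ordered category labels per column;
#'   when supplied, every observed value must be a member
#' @param qi optional character vector of quasi-identifier columns to
#'   validate: they must exist and contain no missing (NA or empty) cells
#' @return a [MicrodataTable-class]
#' @examples
#' md <- microdata(data.frame(sex = c("M", "F"), age = c("20", "30")))
#' rowCount(md)
#' @export
microdata <- function(df, domains = NULL, qi = NULL) {
  if (!is.data.frame(df)) validationError("df must be a data.frame")
  if (nrow(df) < 1L) validationError("microdata must contain at least one row")
  if (anyDuplicated(colnames(df)))
    formatError(sprintf("duplicate column names: %s",
      paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", ")))
  out <- as.data.frame(lapply(df, .canonicalize),
                       stringsAsFactors = FALSE, check.names = FALSE,
                       optional = TRUE)
  colnames(out) <- colnames(df)
  if (!is.null(qi)) {
    missingCols <- setdiff(qi, colnames(out))
    if (length(missingCols))
      validationError(sprintf("quasi-identifier column(s) not present: %s",
                              paste(missingCols, collapse = ", ")))
    for (cn in qi) {
      bad <- which(is.na(out[[cn]]) | out[[cn]] == "")
      if (length(bad))
        validationError(sprintf(
          "missing value in quasi-identifier '%s' at row %d", cn, bad[1L]))
    }
  }
  if (is.null(domains)) {
    domains <- lapply(out, function(col) unique(col))
  } else {
    if (!identical(sort(names(domains)), sort(colnames(out))))
      validationError("domains must be named after every column")
    domains <- domains[colnames(out)]
  }
  new("MicrodataTable", data = out, domains = domains)
}

#' Read a microdata CSV file
#'
#' Expects an RFC-4180 style file: header row required, comma delimiter by
#' default, quoted fields supported, UTF-8. All cells are read as text and
#' canonicalized; no numeric coercion is performed, so "007" and "7" are
#' distinct categories.
#'
#' @param path path to the CSV file
#' @param qi optional character vector of quasi-identifier column names;
#'   when given they must occur in the header and contain no missing cells
#' @param delim field delimiter, default ","
#' @return a [MicrodataTable-class]
#' @export
readMicrodata <- function(path, qi = NULL, delim = ",") {
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      na.strings = character(0), fill = FALSE,
                      comment.char = "", fileEncoding = "UTF-8",
                      stringsAsFactors = FALSE),
    error = function(e) formatError(sprintf(
      "malformed CSV '%s': %s", path, conditionMessage(e))))
  if (nrow(df) < 1L)
    formatError(sprintf("'%s' contains a header but no data rows", path))
  microdata(df, qi = qi)
}

#' @describeIn rowCount number of records in a MicrodataTable
#' @export
setMethod("rowCount", "MicrodataTable", function(x) nrow(x@data))

#' @describeIn columnNames column names of a MicrodataTable
#' @export
setMethod("columnNames", "MicrodataTable", function(x) colnames(x@data))

#' @describeIn categoryDomains ordered per-column domains of a MicrodataTable
#' @export
setMethod("categoryDomains", "MicrodataTable", function(x) x@domains)

#' Extract the underlying data.frame
#' @param x a [MicrodataTable-class]
#' @return data.frame of character columns
#' @export
microdataFrame <- function(x) {
  stopifnot(is(x, "MicrodataTable"))
  x@data
}

#' Subset the rows of a MicrodataTable
#' @param x a [MicrodataTable-class]
#' @param i row indices
#' @param j,drop,... ignored (rows only)
#' @return a [MicrodataTable-class] with the selected rows; domains are kept
#' @export
setMethod("[", "MicrodataTable", function(x, i, j, ..., drop = FALSE) {
  new("MicrodataTable", data = x@data[i, , drop = FALSE], domains = x@domains)
})

setMethod("show", "MicrodataTable", function(object) {
  cat(sprintf("MicrodataTable: %d records x %d columns\n",
              nrow(object@data), ncol(object@data)))
  sizes <- vapply(object@domains, length, integer(1))
  cat("  columns:",
      paste(sprintf("%s(%d)", names(sizes), sizes), collapse = ", "), "\n")
})
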