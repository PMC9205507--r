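#' @include microdata.R
NULL

## Collapse QI tuples to single keys; \x1F (unit separator) cannot occur in
## canonicalized cells read from CSV text in practice, and a collision would
## require a cell containing the separator itself.
.keySep <- "\x1F"

.rowKeys <- function(tbl, qi) {
  df <- tbl@data[qi]
  do.call(paste, c(df, list(sep = .keySep)))
}

.checkQi <- function(tbl, qi) {
  if (length(qi) < 1L) validationError("need at least one quasi-identifier")
  if (anyDuplicated(qi)) validationError("duplicate quasi-identifier names")
  missingCols <- setdiff(qi, columnNames(tbl))
  if (length(missingCols))
    validationError(sprintf("unknown quasi-identifier column(s): %s",
                            paste(missingCols, collapse = ", ")))
  for (cn in qi) {
    col <- tbl@data[[cn]]
    if (anyNA(col) || any(col == ""))
      validationError(sprintf("missing values in quasi-identifier '%s'", cn))
  }
  invisible(qi)
}

#' Compute equivalence classes on the quasi-identifiers
#'
#' Groups the records of a table by their quasi-identifier value tuple.
#' Records with identical values on all quasi-identifiers form one
#' equivalence class; the class sizes are the f_k (sample) or F_k
#' (population) quantities of the match-rate formulas.
#'
#' @param table a [MicrodataTable-class]
#' @param qi character vector of quasi-identifier column names
#' @return an [EquivalenceClasses-class]
#' @examples
#' md <- microdata(data.frame(sex = c("M", "M", "F"), age = c("a", "a", "a")))
#' ec <- equivalenceClasses(md, c("sex", "age"))
#' classCounts(ec)
#' @export
equivalenceClasses <- function(table, qi) {
  stopifnot(is(table, "MicrodataTable"))
  .checkQi(table, qi)
  keys <- .rowKeys(table, qi)
  first <- !duplicated(keys)
  counts <- as.integer(table(factor(keys, levels = keys[first])))
  keyDf <- table@data[first, qi, drop = FALSE]
  rownames(keyDf) <- NULL
  new("EquivalenceClasses", qiNames = qi, keys = keyDf,
      counts = counts, total = nrow(table@data))
}

#' @describeIn qiNames quasi-identifiers of an EquivalenceClasses table
#' @export
setMethod("qiNames", "EquivalenceClasses", function(x) x@qiNames)

#' @describeIn classCounts class sizes of an EquivalenceClasses table
#' @export
setMethod("classCounts", "EquivalenceClasses", function(x) x@counts)

#' @describeIn classKeys distinct tuples of an EquivalenceClasses table
#' @export
setMethod("classKeys", "EquivalenceClasses", function(x) x@keys)

#' Number of records summarized by an EquivalenceClasses table
#' @param x an [EquivalenceClasses-class]
#' @return integer
#' @export
classTotal <- function(x) {
  stopifnot(is(x, "EquivalenceClasses"))
  x@total
}

## class size for every row of a table, looked up in `classes`
.classSizesFor <- function(classes, tbl) {
  keyStrings <- do.call(paste, c(classes@keys, list(sep = .keySep)))
  rowKeys <- .rowKeys(tbl, classes@qiNames)
  idx <- match(rowKeys, keyStrings)
  size <- classes@counts[idx]
  size[is.na(size)] <- 0L
  list(sizes = size, rowKeys = rowKeys)
}

#' @describeIn classSize look up one record's class size (0 if absent)
#' @export
setMethod("classSize", "EquivalenceClasses", function(classes, record) {
  record <- .canonicalize(record)
  if (length(record) != length(classes@qiNames))
    validationError(sprintf(
      "record has %d values but %d quasi-identifiers were used",
      length(record), length(classes@qiNames)))
  keyStrings <- do.call(paste, c(classes@keys, list(sep = .keySep)))
  idx <- match(paste(record, collapse = .keySep), keyStrings)
  if (is.na(idx)) 0L else classes@counts[idx]
})

setMethod("show", "EquivalenceClasses", function(object) {
  cat(sprintf(
    "EquivalenceClasses: %d classes over (%s), %d records\n",
    length(object@counts), paste(object@qiNames, collapse = ", "),
    object@total))
  cat(sprintf("  sizes: min %d / median %g / max %d; uniques: %d\n",
              min(object@counts), stats::median(object@counts),
              max(object@counts), sum(object@counts == 1L)))
})

#' Population uniqueness
#'
#' Proportion of records whose equivalence class has size 1.
#'
#' @param classes an [EquivalenceClasses-class]
#' @return numeric in \[0, 1\]
#' @export
uniquenessRate <- function(classes) {
  stopifnot(is(classes, "EquivalenceClasses"))
  sum(classes@counts == 1L) / classes@total
}
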