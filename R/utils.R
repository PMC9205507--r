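#' @include report.R
NULL

#' Cramer's V association between two categorical vectors
#'
#' Chi-squared based association in \[0, 1\]; 0 for independence, 1 for a
#' deterministic relationship. Used to check dependence fidelity of
#' synthetic draws against the data they were fitted to.
#'
#' @param x,y equal-length vectors treated as categorical
#' @return numeric in \[0, 1\]
#' @export
cramersV <- function(x, y) {
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  n <- sum(tab)
  sqrt(as.numeric(chi2) / (n * (min(nrow(tab), ncol(tab)) - 1)))
}
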