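# Elementary statistics with the deletion and error conventions used
# throughout the data-quality metrics: correlations are pairwise-complete,
# Cronbach's alpha is listwise-complete on its items, and degenerate inputs
# raise classed conditions rather than returning zeros.

undefined_stat <- function(msg) {
  abort(paste0("undefined statistic: ", msg), class = "raiqc_undefined_stat")
}

complete_pairs <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Pearson product-moment correlation
#'
#' Pairwise deletion of incomplete pairs; requires at least three complete
#' pairs and nonzero variance in both vectors.
#'
#' @param x,y Paired numeric vectors.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  p <- complete_pairs(x, y)
  if (p$n < 3) undefined_stat("fewer than 3 complete pairs")
  if (var(p$x) == 0 || var(p$y) == 0) {
    undefined_stat("zero variance in one of the paired vectors")
  }
  cor(p$x, p$y)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive mean ranks),
#' with the same deletion and degeneracy rules as [pearson_r()].
#'
#' @inheritParams pearson_r
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  p <- complete_pairs(x, y)
  if (p$n < 3) undefined_stat("fewer than 3 complete pairs")
  if (var(p$x) == 0 || var(p$y) == 0) {
    undefined_stat("zero variance in one of the paired vectors")
  }
  cor(p$x, p$y, method = "spearman")
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i var(item_i)/var(total))}
#' computed on rows complete for all items (listwise deletion), with the
#' sample (n-1) variance throughout.
#'
#' @param item_matrix Numeric matrix or data frame, persons x items.
#' @return Alpha (at most 1; can be negative, which callers flag).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) undefined_stat("Cronbach's alpha needs at least 2 items")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) undefined_stat("fewer than 3 listwise-complete rows")
  total_var <- var(rowSums(m))
  if (total_var == 0) undefined_stat("zero total-score variance")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Relative change between two values, in percent
#'
#' `100 * (to - from) / from`; the convention used when summarising, for
#' example, the relative growth of a mean case-mix index across a study
#' period.
#'
#' @param from,to Numeric values (vectors recycle).
#' @return Percent change.
#' @export
pct_change <- function(from, to) {
  100 * (to - from) / from
}

# Mean and sample SD of a vector of annual values, NA-dropped.
trend_summary_stats <- function(values) {
  v <- values[!is.na(values)]
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_)
}
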