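#' Reconstruct contingency counts from printed group percentages
#'
#' Clinical tables often print per-group percentages rather than counts. This
#' rounds each `n * pct / 100` to the nearest integer and, if the rounded pair
#' misses `n` by one, adjusts the cell with the largest rounding error by one
#' so the pair sums to `n` exactly. Percentages that cannot be reconciled
#' (off by more than one after adjustment) are rejected.
#'
#' @param n group size (positive integer).
#' @param percentages length-2 non-negative vector summing to ~100.
#' @return integer vector of two counts summing to `n`.
#' @examples
#' counts_from_percentages(39, c(77, 23))  # 30 9
#' counts_from_percentages(37, c(5, 95))   # 2 35
#' @export
counts_from_percentages <- function(n, percentages) {
  stopifnot(n > 0, length(percentages) == 2, all(percentages >= 0))
  raw <- n * percentages / 100
  counts <- round(raw)
  gap <- n - sum(counts)
  if (abs(gap) > 1) {
    stop("percentages ", paste(percentages, collapse = "/"),
         " are irreconcilable with n = ", n, call. = FALSE)
  }
  if (gap != 0) {
    err <- abs(raw - counts)
    i <- which.max(err)
    counts[i] <- counts[i] + gap
  }
  as.integer(counts)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 contingency table. The
#' default rule is the conventional point-probability method — the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed the observed table's (as in
#' [stats::fisher.test()], which computes it). The `"doubling"` alternative
#' doubles the smaller one-sided tail probability (capped at 1).
#'
#' @param table 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = categories); alternatively supply the four cells `a, b, c, d`
#'   row-wise.
#' @param a,b,c,d individual cells, used when `table` is missing.
#' @param rule `"point_probability"` (default) or `"doubling"`.
#' @return two-sided p-value in (0, 1\]. A table with an all-zero margin has
#'   no evidence either way and returns 1 with a warning.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisher_exact_2x2 <- function(table = NULL, a, b, c, d,
                             rule = "point_probability") {
  rule <- match.arg(rule, base::c("point_probability", "doubling"))
  # the third cell is an argument named `c`, so base::c must be explicit here
  if (is.null(table)) table <- matrix(base::c(a, b, c, d), 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == base::c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("a margin of the table is zero; p = 1", call. = FALSE)
    return(1)
  }
  if (rule == "point_probability") {
    # fisher.test can overshoot 1 by floating-point accumulation
    return(min(1, stats::fisher.test(table)$p.value))
  }
  # doubling rule: twice the smaller hypergeometric tail, capped at 1
  m <- sum(table[1, ]); nn <- sum(table[2, ]); k <- sum(table[, 1])
  x <- table[1, 1]
  lower <- stats::phyper(x, m, nn, k)
  upper <- 1 - stats::phyper(x - 1, m, nn, k)
  min(1, 2 * min(lower, upper))
}

#' Fisher tests for the Lynch-vs-FCCTX clinical contrasts
#'
#' Convenience wrapper reproducing the clinical-association workflow: counts
#' are reconstructed from per-group percentages with
#' [counts_from_percentages()] and tested with [fisher_exact_2x2()].
#'
#' @param n1,n2 group sizes.
#' @param pct1,pct2 length-2 percentage pairs for the two groups.
#' @return tibble with the reconstructed counts and the two-sided p-value.
#' @examples
#' # tumor location (proximal/distal) in Lynch (n=39) vs FCCTX (n=37)
#' fisher_from_percentages(39, c(77, 23), 37, c(5, 95))
#' @export
fisher_from_percentages <- function(n1, pct1, n2, pct2) {
  c1 <- counts_from_percentages(n1, pct1)
  c2 <- counts_from_percentages(n2, pct2)
  p <- fisher_exact_2x2(rbind(c1, c2))
  tibble::tibble(group = c("group1", "group2"),
                 category1 = c(c1[1], c2[1]),
                 category2 = c(c1[2], c2[2]),
                 p_value = p)
}
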