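#' Cross-product odds ratio of a 2x2 table
#'
#' For a table `((a, b), (c, d))` returns `(a*d) / (b*c)` with the boundary
#' conventions: `Inf` when `b*c = 0` and `a*d > 0`; `0` when `a*d = 0` and
#' `b*c > 0`; `1` when both products are 0. This is the unconditional
#' cross-product ratio, not the conditional maximum-likelihood estimate
#' reported by [stats::fisher.test()].
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @return a nonnegative number (possibly `Inf`).
#' @examples
#' odds_ratio(matrix(c(1, 20, 17, 62), 2, 2))  # 0.182
#' @export
odds_ratio <- function(table) {
  tab <- check_2x2(table)
  ad <- tab[1, 1] * tab[2, 2]
  bc <- tab[1, 2] * tab[2, 1]
  if (ad == 0 && bc == 0) return(1)
  if (bc == 0) return(Inf)
  ad / bc
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: conditioning on the
#' margins, the hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance for ties) are summed. The reported effect size is the
#' cross-product [odds_ratio()].
#'
#' @param table 2x2 matrix of nonnegative integer counts with at least one
#'   positive margin, e.g. from [count_positive_by_stage()] or
#'   [tabulate_by_positivity()].
#' @return an object of class `"association_result"`: list with `odds_ratio`,
#'   `p_value` and `table`.
#' @examples
#' fisher_exact(matrix(c(1, 20, 17, 62), 2, 2))
#' @export
fisher_exact <- function(table) {
  tab <- check_2x2(table, integer_counts = TRUE)
  structure(list(odds_ratio = odds_ratio(tab),
                 p_value = fisher_p2(tab[1, 1], tab[1, 2],
                                     tab[2, 1], tab[2, 2]),
                 table = tab),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Fisher's exact test on a 2x2 table\n")
  print(x$table)
  cat(sprintf("odds ratio (cross-product): %.4g\np-value (two-sided): %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

# two-sided probability-mass p-value for counts a,b / c,d
fisher_p2 <- function(a, b, c, d) {
  m <- a + c          # first-column margin
  n <- b + d          # second-column margin
  k <- a + b          # first-row margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

check_2x2 <- function(table, integer_counts = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)))
    stop("a 2x2 table is required")
  if (anyNA(tab) || any(tab < 0))
    stop("table entries must be nonnegative and non-missing")
  if (integer_counts) {
    if (any(tab != round(tab))) stop("table entries must be integer counts")
    if (sum(tab) == 0) stop("all-zero table")
  }
  tab
}
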