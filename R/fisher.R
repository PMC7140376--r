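#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test of association in a 2x2 contingency table, computed by
#' full enumeration of the conditional (hypergeometric) distribution given the
#' table margins: the p-value is the sum of the probabilities of all tables
#' with the same margins whose probability does not exceed that of the
#' observed table. The odds ratio reported is the sample odds ratio ad/bc
#' (infinite when bc = 0 with ad > 0).
#'
#' @param a,b,c2,d the four cell counts, laid out as rows (a, b) / (c2, d).
#' @return an object of class `fisher_result` with fields `table`,
#'   `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(a, b, c2, d) {
  cells <- c(a = a, b = b, c = c2, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  n <- sum(cells)
  if (n == 0) stop("at least one margin must be positive", call. = FALSE)
  m1 <- a + b        # row 1 margin
  m2 <- c2 + d       # row 2 margin
  k <- a + c2        # column 1 margin
  lo <- max(0, k - m2)
  hi <- min(m1, k)
  x <- lo:hi
  pr <- stats::dhyper(x, m1, m2, k)
  pobs <- stats::dhyper(a, m1, m2, k)
  # relative tolerance guards against ties broken by floating-point noise
  p <- min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  or <- if (a * d == 0 && b * c2 == 0) NaN
        else if (b * c2 == 0) Inf
        else (a * d) / (b * c2)
  structure(list(table = matrix(c(a, c2, b, d), nrow = 2,
                                dimnames = list(c("row1", "row2"),
                                                c("col1", "col2"))),
                 odds_ratio = or, p_value = p),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (two-sided)\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, p = %.4g\n", x$odds_ratio, x$p_value))
  invisible(x)
}
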