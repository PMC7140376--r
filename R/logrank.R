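#' Log-rank test for k survival groups
#'
#' Standard k-group log-rank test: at each distinct pooled event time, each
#' group's expected event count is its at-risk share of the total events at
#' that time; the chi-square statistic contrasts observed minus expected
#' against the hypergeometric (conditional) variance-covariance of the event
#' counts, with k - 1 degrees of freedom. P-values are reported unclipped
#' (they can be far below machine-printable "significance stars" in large
#' cohorts).
#'
#' @param groups a list of two or more groups, each either a
#'   `list(times =, events =)` pair or a data.frame with columns `time_days`
#'   (or `times`) and `event` (or `events`).
#' @return an object of class `logrank_test` with fields `chi_square`, `df`,
#'   `p_value`, `observed`, `expected` and `n` (per group).
#' @export
logrank <- function(groups) {
  g <- .parse_groups(groups)
  k <- length(g$sizes)
  if (k < 2) stop("log-rank needs at least 2 groups", call. = FALSE)
  res <- .logrank_core(g$times, g$events, g$grp, k)
  structure(c(res, list(groups = names(g$sizes), n = g$sizes)),
            class = "logrank_test")
}

.parse_groups <- function(groups) {
  if (!is.list(groups) || !length(groups))
    stop("`groups` must be a non-empty list", call. = FALSE)
  times <- list()
  events <- list()
  for (i in seq_along(groups)) {
    gi <- groups[[i]]
    if (is.data.frame(gi)) {
      tcol <- intersect(c("time_days", "times", "time"), names(gi))[1]
      ecol <- intersect(c("event", "events"), names(gi))[1]
      if (is.na(tcol) || is.na(ecol))
        stop("group ", i, ": need time and event columns", call. = FALSE)
      times[[i]] <- as.numeric(gi[[tcol]])
      events[[i]] <- as.numeric(gi[[ecol]])
    } else if (is.list(gi)) {
      times[[i]] <- as.numeric(gi$times)
      events[[i]] <- as.numeric(gi$events)
    } else stop("group ", i, ": unsupported group representation", call. = FALSE)
    if (!length(times[[i]]))
      stop("group ", i, " has zero subjects", call. = FALSE)
    if (length(times[[i]]) != length(events[[i]]))
      stop("group ", i, ": times/events length mismatch", call. = FALSE)
    if (any(times[[i]] < 0) || !all(events[[i]] %in% c(0, 1)))
      stop("group ", i, ": invalid times or event indicators", call. = FALSE)
  }
  sizes <- lengths(times)
  names(sizes) <- if (!is.null(names(groups)) && all(nzchar(names(groups))))
    names(groups) else as.character(seq_along(groups))
  list(times = unlist(times), events = unlist(events),
       grp = rep(seq_along(groups), sizes), sizes = sizes)
}

# core statistic on pooled vectors; kept lean because the permutation oracle
# and calibration simulations call it tens of thousands of times
.logrank_core <- function(times, events, grp, k) {
  tau <- sort(unique(times[events == 1]))
  m <- length(tau)
  if (!m)
    return(list(chi_square = 0, df = k - 1L, p_value = 1,
                observed = rep(0, k), expected = rep(0, k)))
  nmat <- matrix(0, k, m)   # at risk per group per event time
  dmat <- matrix(0, k, m)   # deaths per group per event time
  for (i in seq_len(k)) {
    ti <- times[grp == i]
    ei <- events[grp == i]
    cmp <- outer(ti, tau, ">=")
    nmat[i, ] <- colSums(cmp)
    dmat[i, ] <- colSums(outer(ti, tau, "==") * ei)
  }
  dj <- colSums(dmat)
  nj <- colSums(nmat)
  P <- sweep(nmat, 2, nj, "/")
  O <- rowSums(dmat)
  E <- rowSums(sweep(P, 2, dj, "*"))
  cfac <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
  Pc <- sweep(P, 2, cfac, "*")
  V <- diag(rowSums(Pc), nrow = k) - Pc %*% t(P)
  z <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(crossprod(z, solve(Vs, z))),
                  error = function(e) drop(t(z) %*% MASS::ginv(Vs) %*% z))
  chi <- max(0, chi)
  list(chi_square = chi, df = k - 1L,
       p_value = stats::pchisq(chi, df = k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  df <- data.frame(group = x$groups, n = as.integer(x$n),
                   observed = x$observed, expected = round(x$expected, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pairwise log-rank tests
#'
#' One two-group log-rank test per unordered pair of groups. Raw p-values are
#' primary (matching how pairwise comparisons are customarily reported in this
#' literature); Benjamini-Hochberg adjusted p-values are reported alongside
#' whenever three or more groups are compared.
#'
#' @param groups as in [logrank()], with optional names.
#' @return a data.frame of class `pairwise_logrank` with columns `group1`,
#'   `group2`, `chi_square`, `p_value` and (for >= 3 groups) `p_bh`. The
#'   individual `logrank_test` objects are attached as attribute `"tests"`.
#' @export
pairwise_logrank <- function(groups) {
  g <- .parse_groups(groups)
  k <- length(g$sizes)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  nms <- names(g$sizes)
  pairs <- utils::combn(k, 2)
  tests <- vector("list", ncol(pairs))
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    sel <- g$grp %in% c(i1, i2)
    res <- .logrank_core(g$times[sel], g$events[sel],
                         match(g$grp[sel], c(i1, i2)), 2L)
    tests[[j]] <- structure(
      c(res, list(groups = nms[c(i1, i2)], n = g$sizes[c(i1, i2)])),
      class = "logrank_test")
    rows[[j]] <- data.frame(group1 = nms[i1], group2 = nms[i2],
                            chi_square = res$chi_square, p_value = res$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (k >= 3) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "tests") <- tests
  class(out) <- c("pairwise_logrank", "data.frame")
  out
}
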