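test_that("product-limit estimator matches the hand-computed worked example", {
  # 5 subjects: deaths at 1, 2, 4, 5; censoring at 3
  cv <- km_estimate(times = 1:5, events = c(1, 1, 0, 1, 1))
  expect_identical(cv$event_times, c(1, 2, 4, 5))
  expect_identical(cv$at_risk, c(5, 4, 2, 1))
  expect_equal(cv$survival, c(0.8, 0.6, 0.3, 0.0))
  med <- km_median(cv)
  expect_true(med$reached)
  expect_identical(med$value_days, 4)
})

test_that("KM handles degenerate inputs per the defining conventions", {
  # all events tied at one time: survival drops to zero in one step
  tied <- km_estimate(rep(10, 4), rep(1, 4))
  expect_identical(tied$event_times, 10)
  expect_equal(tied$survival, 0)

  # all censored: survival stays at 1; median not reached
  cens <- km_estimate(c(100, 200, 4500), c(0, 0, 0))
  expect_identical(length(cens$event_times), 0L)
  med <- km_median(cens)
  expect_false(med$reached)
  expect_identical(med$lower_bound_days, 4500)
  expect_identical(format(med), "> 4500 days")

  # survival hitting exactly 0.5 defines the median (<= 0.5 convention)
  half <- km_estimate(c(10, 10, 20, 20), c(1, 1, 0, 0))
  expect_equal(half$survival, 0.5)
  expect_identical(km_median(half)$value_days, 10)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(1, -2), c(1, 1)), "negative")
  expect_error(km_estimate(c(1, 2), c(1, 2)), "0 or 1")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(21)
  for (r in 1:5) {
    tt <- rexp(40, 1 / 500)
    cv <- km_estimate(tt, rep(1, 40))
    emp <- vapply(cv$event_times, function(t) mean(tt > t), numeric(1))
    expect_equal(cv$survival, emp, tolerance = 1e-12)
  }
})

test_that("KM agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(33)
  for (r in 1:20) {
    n <- 60
    tt <- round(rexp(n, 1 / 800), 1)
    ev <- rbinom(n, 1, 0.7)
    cv <- km_estimate(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    ref <- summary(sf, times = cv$event_times)
    expect_equal(cv$survival, ref$surv, tolerance = 1e-12)
    expect_equal(cv$at_risk, ref$n.risk, tolerance = 1e-12)
  }
})

test_that("median of exponential survival concentrates at ln2/lambda", {
  # n = 500, lambda = ln2/1000: the KM median is asymptotically normal
  # around 1000 days with sd 1/(2 f(m) sqrt(n)) ~ 64.5 days, so the
  # (900, 1100) band captures ~88% of replicates; assert coverage within a
  # 99.9% binomial band of that prediction and the replicate mean within
  # 3 standard errors of the true median
  lambda <- log(2) / 1000
  set.seed(55)
  meds <- numeric(100)
  ok <- 0L
  for (r in 1:100) {
    tt <- rexp(500, lambda)
    med <- km_median(km_estimate(tt, rep(1, 500)))
    meds[r] <- med$value_days
    if (med$reached && med$value_days > 900 && med$value_days < 1100)
      ok <- ok + 1L
  }
  expect_gte(ok, 77L)
  expect_lte(abs(mean(meds) - 1000), 3 * 64.5 / sqrt(100))
})

test_that("log-rank statistic behaves at its symmetry points", {
  g <- list(times = c(5, 10, 15, 20), events = c(1, 0, 1, 1))
  res <- logrank(list(g, g))
  expect_equal(res$chi_square, 0)
  expect_equal(res$p_value, 1)
  expect_identical(res$df, 1L)
  expect_equal(sum(res$expected), sum(res$observed))

  # zero events in either group
  nodeath <- list(times = c(10, 20), events = c(0, 0))
  res0 <- logrank(list(nodeath, nodeath))
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$p_value, 1)

  expect_error(logrank(list(g)), "at least 2")
  expect_error(logrank(list(g, list(times = numeric(0), events = numeric(0)))),
               "zero subjects")
})

test_that("log-rank agrees with survival::survdiff across group counts", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (k in 2:4) {
    for (r in 1:10) {
      n <- 40 * k
      tt <- rexp(n, 1 / (600 + 200 * rep(seq_len(k), each = 40)))
      ev <- rbinom(n, 1, 0.75)
      grp <- rep(seq_len(k), each = 40)
      groups <- lapply(seq_len(k), function(i)
        list(times = tt[grp == i], events = ev[grp == i]))
      mine <- logrank(groups)
      ref <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
      expect_equal(mine$chi_square, ref$chisq, tolerance = 1e-8)
      expect_equal(mine$observed, unname(ref$obs), tolerance = 1e-8)
      expect_equal(mine$expected, unname(ref$exp), tolerance = 1e-8)
    }
  }
})

test_that("log-rank is invariant to group order and monotone time transforms", {
  set.seed(88)
  a <- list(times = rexp(50, 1 / 500), events = rbinom(50, 1, 0.8))
  b <- list(times = rexp(50, 1 / 900), events = rbinom(50, 1, 0.8))
  c_ <- list(times = rexp(50, 1 / 700), events = rbinom(50, 1, 0.8))
  base <- logrank(list(a, b, c_))
  perm <- logrank(list(c_, a, b))
  expect_equal(base$chi_square, perm$chi_square, tolerance = 1e-12)

  tf <- function(g) list(times = sqrt(g$times) + log1p(g$times),
                         events = g$events)
  trans <- logrank(lapply(list(a, b, c_), tf))
  expect_equal(base$chi_square, trans$chi_square, tolerance = 1e-9)
})

test_that("pairwise log-rank enumerates pairs consistently", {
  set.seed(99)
  mk <- function(rate) list(times = rexp(30, rate), events = rbinom(30, 1, 0.8))
  same <- mk(1 / 500)
  trip <- pairwise_logrank(list(same, same, same))
  expect_identical(nrow(trip), 3L)
  expect_true(all(trip$p_value == 1))
  expect_true("p_bh" %in% names(trip))

  two <- list(A = mk(1 / 400), B = mk(1 / 900))
  pw <- pairwise_logrank(two)
  expect_identical(nrow(pw), 1L)
  expect_false("p_bh" %in% names(pw))
  single <- logrank(two)
  expect_equal(pw$chi_square, single$chi_square, tolerance = 1e-12)
  expect_equal(pw$p_value, single$p_value, tolerance = 1e-12)

  four <- lapply(c(400, 600, 800, 1000), function(m) mk(1 / m))
  expect_identical(nrow(pairwise_logrank(four)), 6L)
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  r1 <- fisher_exact_2x2(3, 1, 1, 3)
  expect_equal(r1$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(r1$odds_ratio, 9)

  r2 <- fisher_exact_2x2(5, 0, 0, 5)
  expect_equal(r2$p_value, 2 / 252, tolerance = 1e-12)
  expect_identical(r2$odds_ratio, Inf)

  r3 <- fisher_exact_2x2(2, 2, 2, 2)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$odds_ratio, 1)

  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "margin")
  expect_true(is.nan(fisher_exact_2x2(0, 3, 0, 4)$odds_ratio))
})

test_that("Fisher exact p agrees with stats::fisher.test on random tables", {
  set.seed(123)
  for (r in 1:200) {
    cells <- rpois(4, sample(c(2, 5, 12), 1))
    if (sum(cells) == 0) next
    mine <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})
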