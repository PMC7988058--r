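test_that("product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$event_times, c(1, 2))
  expect_equal(km$survival_probs, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5, 3)),
               c(1, 2 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)

  expect_equal(km_survival_at(km_estimate(c(4, 6), c(0, 0)), c(1, 10)), c(1, 1))
  expect_equal(km_survival_at(km_estimate(5, 1), 5), 0)
  expect_error(km_estimate(-1, 1), "non-negative")
})

test_that("KM with no censoring is one minus the empirical CDF", {
  set.seed(31)
  t <- sample(1:20, 40, replace = TRUE)
  km <- km_estimate(t, rep(1, 40))
  grid <- 0:21
  expect_equal(km_survival_at(km, grid), 1 - ecdf(t)(grid), tolerance = 1e-12)
})

test_that("KM agrees with survival::survfit under censoring", {
  set.seed(8)
  t <- ceiling(rexp(60, 0.05)); e <- rbinom(60, 1, 0.6)
  km <- km_estimate(t, e)
  sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1),
                times = km$event_times)
  expect_equal(km$survival_probs, sf$surv, tolerance = 1e-12)
  expect_equal(km$at_risk, sf$n.risk, tolerance = 1e-12)
})

test_that("log-rank: identical groups give chi-square 0, p 1", {
  t <- c(2, 4, 6, 8); e <- c(1, 0, 1, 1)
  lr <- log_rank(t, e, t, e)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
})

test_that("log-rank matches a hand-tallied risk table on a 6-subject example", {
  # group A: events at 1, 3; censored 4.  group B: event at 2; censored 5, 6
  # t=1: n=6, nA=3, d=1, dA=1 -> E=0.5, V=0.25
  # t=2: n=5, nA=2, d=1, dA=0 -> E=0.4, V=0.24
  # t=3: n=4, nA=2, d=1, dA=1 -> E=0.5, V=0.25
  # O-E = 2 - 1.4 = 0.6; V = 0.74; chi2 = 0.36/0.74
  lr <- log_rank(c(1, 3, 4), c(1, 1, 0), c(2, 5, 6), c(1, 0, 0))
  expect_equal(lr$chi_square, 0.36 / 0.74, tolerance = 1e-12)
  expect_equal(lr$observed[["a"]], 2)
  expect_equal(lr$expected[["a"]], 1.4, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff and is invariant to
           label swap and monotone time rescaling", {
  set.seed(14)
  ta <- ceiling(rexp(25, 0.02)); ea <- rbinom(25, 1, 0.7)
  tb <- ceiling(rexp(30, 0.04)); eb <- rbinom(30, 1, 0.7)
  lr <- log_rank(ta, ea, tb, eb)
  g <- rep(0:1, c(25, 30))
  sd <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~ g)
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)

  swapped <- log_rank(tb, eb, ta, ea)
  expect_equal(swapped$chi_square, lr$chi_square, tolerance = 1e-12)

  resc <- log_rank(sqrt(ta), ea, sqrt(tb), eb) # strictly monotone map
  expect_equal(resc$chi_square, lr$chi_square, tolerance = 1e-12)

  expect_error(log_rank(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)), "no events")
})

test_that("optimal cut-off isolates the poor-prognosis side of a separable
           cohort", {
  feature <- c(1, 2, 3, 4, 11, 12, 13, 14)
  times <- c(5, 6, 7, 8, 50, 60, 70, 80)
  events <- c(1, 1, 1, 1, 0, 0, 0, 0)
  res <- optimal_cutoff_km(feature, times, events, min_group_frac = 0.2)
  # every low-group subject comes from the early-event half; the log-rank
  # statistic is maximised by an extreme admissible split, so the threshold
  # need not sit exactly between the halves
  expect_lt(res$threshold, 11)
  expect_true(all(feature[feature <= res$threshold] <= 4))
  expect_true(res$exploratory)
  expect_equal(min(res$candidates$p_value), res$logrank$p_value)
  # the <=-threshold convention sends boundary subjects to the low group
  low_n <- sum(feature <= res$threshold)
  expect_equal(res$logrank$group_sizes[["a"]], low_n)
})

test_that("optimal cut-off equals exhaustive split enumeration on a toy set", {
  set.seed(3)
  feature <- c(2.5, 1.0, 4.0, 3.1, 0.5, 5.2)
  times <- c(10, 3, 40, 22, 2, 55)
  events <- c(1, 1, 0, 1, 1, 0)
  res <- optimal_cutoff_km(feature, times, events, min_group_frac = 1 / 6)
  u <- sort(unique(feature))
  mids <- (u[-1] + u[-length(u)]) / 2
  ps <- vapply(mids, function(c) {
    lo <- feature <= c
    log_rank(times[lo], events[lo], times[!lo], events[!lo])$p_value
  }, 0)
  expect_equal(res$logrank$p_value, min(ps), tolerance = 1e-12)
  expect_equal(res$threshold, mids[which.min(ps)])
})

test_that("searched cut-off p is anti-conservative versus a median split", {
  # feature independent of survival: the searched minimum p undercuts the
  # single prespecified median split on average
  set.seed(99)
  ratio <- replicate(40, {
    n <- 40
    f <- rnorm(n)
    t <- ceiling(rexp(n, 0.05)); e <- rbinom(n, 1, 0.8)
    best <- optimal_cutoff_km(f, t, e)$logrank$p_value
    lo <- f <= stats::median(f)
    med <- log_rank(t[lo], e[lo], t[!lo], e[!lo])$p_value
    best <= med
  })
  expect_gt(mean(ratio), 0.9)

  expect_error(optimal_cutoff_km(rep(1, 8), 1:8, rep(1, 8)), "equal")
})
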