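#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up durations.
#' @param events binary flags (1 = event observed, 0 = censored).
#' @return object of class `km_curve` with `event_times` (distinct times at
#'   which at least one event occurred), `survival_probs` (the product-limit
#'   estimate just after each of those times), `at_risk` and `n_events`
#'   counts, plus total `n`. With no events the curve is flat at 1.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times); events <- as.numeric(events)
  if (length(times) < 1L) stop("need at least one subject", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be non-negative and finite", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1", call. = FALSE)

  et <- sort(unique(times[events == 1]))
  at_risk <- vapply(et, function(t) sum(times >= t), 0)
  n_ev <- vapply(et, function(t) sum(times == t & events == 1), 0)
  surv <- cumprod(1 - n_ev / at_risk)
  structure(
    list(event_times = et, survival_probs = surv, at_risk = at_risk,
         n_events = n_ev, n = length(times)),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param curve a `km_curve`.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities S(t).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(ti) {
    idx <- which(curve$event_times <= ti)
    if (!length(idx)) 1 else curve$survival_probs[max(idx)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square from observed-minus-expected event
#' counts over the pooled risk sets at each distinct event time, with the
#' hypergeometric variance.
#'
#' @param times_a,events_a follow-up and event flags for group A.
#' @param times_b,events_b follow-up and event flags for group B.
#' @return object of class `logrank_result`: `chi_square`, `p_value`,
#'   `observed`, `expected` (per group), `group_sizes`.
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  ta <- as.numeric(times_a); ea <- as.numeric(events_a)
  tb <- as.numeric(times_b); eb <- as.numeric(events_b)
  if (length(ta) < 1L || length(tb) < 1L) {
    stop("each group needs at least one subject", call. = FALSE)
  }
  if (!all(c(ea, eb) %in% c(0, 1))) stop("events must be binary 0/1", call. = FALSE)
  if (sum(ea) + sum(eb) < 1) stop("no events in either group", call. = FALSE)

  times <- c(ta, tb); events <- c(ea, eb)
  # risk-set and tied-event tallies at each distinct event time, vectorised:
  # the at-risk count at t is n minus the number of subjects with time < t
  et <- sort(unique(times[events == 1]))
  st <- sort(times)
  st_a <- sort(ta)
  n_at <- length(times) - findInterval(et, st, left.open = TRUE)
  n_a <- length(ta) - findInterval(et, st_a, left.open = TRUE)
  d <- tabulate(match(times[events == 1], et), length(et))
  d_a <- tabulate(match(ta[ea == 1], et), length(et))
  o_a <- sum(d_a)
  e_a <- sum(d * n_a / n_at)
  vterm <- d * (n_a / n_at) * (1 - n_a / n_at) * (n_at - d) / (n_at - 1)
  v <- sum(vterm[n_at > 1])
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  structure(
    list(
      chi_square = chi, p_value = p,
      observed = c(a = o_a, b = sum(ea) + sum(eb) - o_a),
      expected = c(a = e_a, b = sum(ea) + sum(eb) - e_a),
      group_sizes = c(a = length(ta), b = length(tb))
    ),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf(
    "<logrank_result> chi-square %.4f (1 df), P = %.4g; n = %d vs %d\n",
    x$chi_square, x$p_value, x$group_sizes[1L], x$group_sizes[2L]
  ))
  invisible(x)
}

#' Optimal-threshold Kaplan-Meier split of a feature
#'
#' Grid search over the midpoints between consecutive sorted unique feature
#' values: each candidate threshold dichotomises the cohort (value <=
#' threshold goes to the LOW group, matching the "<= cut-off" reporting
#' convention), subject to both groups keeping at least a fraction
#' `min_group_frac` of subjects, and the threshold minimising the log-rank
#' p-value is returned. Because the threshold is searched to minimise p, the
#' resulting p-value is exploratory: it is optimistically biased relative to
#' a pre-specified threshold and is flagged as such in the result.
#'
#' @param feature numeric feature values.
#' @param times,events survival data aligned with `feature`.
#' @param min_group_frac minimum fraction of subjects per group (default 0.1).
#' @return object of class `cutoff_result`: `threshold`, `logrank`
#'   (a `logrank_result`), `km_low`, `km_high` (the two `km_curve`s),
#'   `exploratory = TRUE`, and the searched `candidates` with their p-values.
#' @export
optimal_cutoff_km <- function(feature, times, events, min_group_frac = 0.1) {
  feature <- as.numeric(feature)
  n <- length(feature)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (length(unique(feature)) < 2L) {
    stop("all feature values are equal; no threshold exists", call. = FALSE)
  }
  u <- sort(unique(feature))
  cand <- (u[-1L] + u[-length(u)]) / 2
  floor_n <- max(1L, ceiling(min_group_frac * n))
  keep <- vapply(cand, function(c) {
    sum(feature <= c) >= floor_n && sum(feature > c) >= floor_n
  }, logical(1L))
  cand <- cand[keep]
  if (!length(cand)) stop("no admissible threshold under the group-size floor",
                          call. = FALSE)
  pvals <- vapply(cand, function(c) {
    low <- feature <= c
    log_rank(times[low], events[low], times[!low], events[!low])$p_value
  }, 0)
  best <- which.min(pvals) # ties: lowest threshold
  thr <- cand[best]
  low <- feature <= thr
  structure(
    list(
      threshold = thr,
      logrank = log_rank(times[low], events[low], times[!low], events[!low]),
      km_low = km_estimate(times[low], events[low]),
      km_high = km_estimate(times[!low], events[!low]),
      exploratory = TRUE,
      candidates = data.frame(threshold = cand, p_value = pvals)
    ),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> threshold %.4g (low: n = %d, high: n = %d); log-rank P = %.4g [exploratory: threshold searched to minimise p]\n",
    x$threshold, x$logrank$group_sizes[1L], x$logrank$group_sizes[2L],
    x$logrank$p_value
  ))
  invisible(x)
}
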