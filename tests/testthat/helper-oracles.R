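# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# direct nested-loop 2D correlation with reflect ('d c b a | a b c d')
# boundary padding
oracle_correlate <- function(slice, coeff) {
  h <- (nrow(coeff) - 1L) %/% 2L
  refl <- function(idx, n) {
    period <- 2L * n
    j <- (idx - 1L) %% period
    ifelse(j < n, j + 1L, period - j)
  }
  ri <- refl((1L - h):(nrow(slice) + h), nrow(slice))
  ci <- refl((1L - h):(ncol(slice) + h), ncol(slice))
  p <- slice[ri, ci, drop = FALSE]
  out <- matrix(0, nrow(slice), ncol(slice))
  for (a in 0:(2L * h)) {
    for (b in 0:(2L * h)) {
      out <- out + coeff[a + 1L, b + 1L] *
        p[(1L + a):(nrow(slice) + a), (1L + b):(ncol(slice) + b)]
    }
  }
  out
}

# direct-formula first-order features (moment definitions written out)
oracle_features <- function(x, bins = 256L) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  sdev <- if (n == 1L) 0 else sqrt(sum((x - mu)^2) / (n - 1))
  ent <- if (min(x) == max(x)) {
    0
  } else {
    br <- seq(min(x), max(x), length.out = bins + 1L)
    cnt <- hist(x, breaks = br, plot = FALSE, right = FALSE,
                include.lowest = TRUE)$counts
    # hist(right=FALSE) puts max in the last bin via include.lowest
    p <- cnt[cnt > 0] / n
    -sum(p * log2(p))
  }
  pos <- x[x > 0]
  c(
    mean = mu, sd = sdev, entropy = ent,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_,
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    mpp = if (length(pos)) sum(pos) / length(pos) else NA_real_
  )
}

# all-pairs Mann-Whitney concordance AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small deterministic textured phantom for I/O and pipeline tests
tiny_phantom <- function(seed = 1L, id = "tiny") {
  generate_phantom(
    phantom_spec(grid_shape = c(8L, 24L, 24L), spacing_mm = c(2.5, 1, 1),
                 lesion_diameter_mm = 12),
    seed = seed, patient_id = id
  )
}

small_cohort_spec <- function(n, seed, ...) {
  cohort_spec(
    n_patients = n, seed = seed,
    phantom = phantom_spec(grid_shape = c(14L, 40L, 40L),
                           spacing_mm = c(2.5, 1, 1)),
    ...
  )
}
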