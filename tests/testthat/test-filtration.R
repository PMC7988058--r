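test_that("kernel construction follows the SSF-to-sigma convention", {
  k <- build_log_kernel(2, c(1, 1))
  expect_equal(k$sigma_px, rep(2 / (2 * sqrt(2)), 2), tolerance = 1e-12)
  expect_equal(k$sigma_px[1], 0.7071, tolerance = 1e-4)

  # anisotropic pixels: sigma in px differs per axis, kernel stays square
  k2 <- build_log_kernel(4, c(0.7, 1.0))
  expect_equal(k2$sigma_px[1] * 0.7, k2$sigma_px[2] * 1.0, tolerance = 1e-12)
  expect_equal(nrow(k2$coefficients), ncol(k2$coefficients))

  # the support half-width follows the largest per-axis sigma
  expect_equal(nrow(k2$coefficients), 2 * ceiling(4 * max(k2$sigma_px)) + 1)

  expect_error(build_log_kernel(3, c(0, 1)), "positive")
  expect_error(build_log_kernel(-1, c(1, 1)), ">= 0")
})

test_that("kernels are zero-sum and symmetric under 180-degree rotation", {
  for (ssf in c(2, 3, 4, 5, 6)) {
    for (sp in list(c(1, 1), c(0.7, 0.7), c(0.7, 1.2))) {
      k <- build_log_kernel(ssf, sp)$coefficients
      expect_lte(abs(sum(k)), 1e-10 * max(abs(k)))
      expect_equal(k, k[nrow(k):1, ncol(k):1], tolerance = 1e-15)
    }
  }
})

test_that("SSF 0 is the identity: no filtration at all", {
  k0 <- build_log_kernel(0, c(0.7, 0.7))
  expect_null(k0$coefficients)
  sl <- matrix(rnorm(30 * 20, 50, 30), 30, 20)
  expect_identical(filter_slice(sl, k0), sl)
})

test_that("filtered output matches a nested-loop correlation oracle", {
  set.seed(101)
  for (ssf in c(2, 4, 6)) {
    k <- build_log_kernel(ssf, c(0.8, 1.1))
    sl <- matrix(rnorm(32 * 32, 40, 25), 32, 32)
    got <- filter_slice(sl, k)
    want <- oracle_correlate(sl, k$coefficients)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
})

test_that("constant slices map to zero for every filtered scale", {
  for (ssf in c(2, 3, 4, 5, 6)) {
    k <- build_log_kernel(ssf, c(0.7, 0.7))
    out <- filter_slice(matrix(50, 24, 24), k)
    expect_lte(max(abs(out)), 1e-8 * 50)
  }
})

test_that("filtration is linear and kills any DC offset", {
  set.seed(7)
  sl <- matrix(rnorm(28 * 28, 0, 10), 28, 28)
  k <- build_log_kernel(3, c(1, 1))
  f1 <- filter_slice(sl, k)
  f2 <- filter_slice(2.5 * sl + 100, k)
  expect_lt(max(abs(f2 - 2.5 * f1)), 1e-8 * max(abs(f1)))
})

test_that("a centred unit impulse reproduces the kernel coefficients", {
  k <- build_log_kernel(3, c(1, 1))
  h <- (nrow(k$coefficients) - 1) / 2
  n <- 2 * h + 21
  sl <- matrix(0, n, n)
  centre <- h + 11
  sl[centre, centre] <- 1
  f <- filter_slice(sl, k)
  got <- f[(centre - h):(centre + h), (centre - h):(centre + h)]
  expect_equal(got, k$coefficients, tolerance = 1e-12)
})

test_that("slice smaller than the kernel still filters via reflected context", {
  k <- build_log_kernel(6, c(1, 1)) # support wider than the slice
  sl <- matrix(rnorm(9, 50, 10), 3, 3)
  expect_silent(f <- filter_slice(sl, k))
  expect_identical(dim(f), dim(sl))
  expect_error(filter_slice(matrix(c(1, NA, 3, 4), 2, 2), k), "non-finite")
})

test_that("VOI extraction pools whole-slice filtered values inside the mask", {
  ph <- tiny_phantom(seed = 5)
  # SSF 0 returns raw HU of the masked voxels, in slice order
  v0 <- extract_voi_values(ph$volume, ph$mask, 0)
  expect_equal(v0$n, mask_foreground_count(ph$mask))
  expect_equal(sort(v0$values), sort(ph$volume$voxels[ph$mask$voxels > 0.5]))

  # pooled sample equals the concatenation of per-slice samples
  v3 <- extract_voi_values(ph$volume, ph$mask, 3)
  per <- filtrad:::extract_voi_slices(ph$volume, ph$mask, 3)
  expect_identical(v3$values, unlist(per, use.names = FALSE))
  expect_equal(v3$n, sum(lengths(per)))

  # constant volume: every filtered value is zero
  flat <- ct_volume(array(30, dim(ph$volume$voxels)), ph$volume$spacing_mm)
  vflat <- extract_voi_values(flat, lesion_mask(ph$mask$voxels, flat), 4)
  expect_lte(max(abs(vflat$values)), 1e-8 * 30)
})

test_that("mismatched mask geometry is rejected", {
  ph <- tiny_phantom()
  short <- ph$mask$voxels[-1, , ]
  expect_error(lesion_mask(short, ph$volume), "does not match")
})

test_that("scale selectivity: coarser blobs peak at coarser SSF", {
  blob_argmax <- function(d_mm, spacing = 0.7) {
    n <- 96
    sigma_blob <- d_mm / (2 * sqrt(2))
    xy <- ((1:n) - (n + 1) / 2) * spacing
    r2 <- outer(xy^2, xy^2, `+`)
    blob <- 100 * exp(-r2 / (2 * sigma_blob^2))
    voi <- r2 <= d_mm^2
    resp <- vapply(2:6, function(s) {
      mean(abs(filter_slice(blob, build_log_kernel(s, c(spacing, spacing)))[voi]))
    }, 0)
    (2:6)[which.max(resp)]
  }
  arg <- vapply(c(2, 4, 6), blob_argmax, 0)
  expect_true(all(diff(arg) >= 0))
})

test_that("features are stable under resampling to a different pixel size", {
  # same smooth anatomy sampled at 0.7 mm and 1.0 mm: mm-based scaling keeps
  # each filtered-scale mean-absolute response within 10%
  sample_field <- function(spacing) {
    n <- round(42 / spacing)
    xy <- ((1:n) - (n + 1) / 2) * spacing
    outer(sin(xy / 3), cos(xy / 4)) * 20 + 50
  }
  for (ssf in c(2, 4, 6)) {
    f1 <- filter_slice(sample_field(0.7), build_log_kernel(ssf, c(0.7, 0.7)))
    f2 <- filter_slice(sample_field(1.0), build_log_kernel(ssf, c(1, 1)))
    trim <- function(m, k) m[k:(nrow(m) - k), k:(ncol(m) - k)]
    m1 <- mean(abs(trim(f1, 10)))
    m2 <- mean(abs(trim(f2, 7)))
    expect_lt(abs(m1 - m2) / m1, 0.10)
  }
})
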