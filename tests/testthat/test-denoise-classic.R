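# --- component-selection criteria ---------------------------------------

test_that("the median rule keeps eigenvalues above twice the median", {
  expect_identical(select_k_median(c(100, 1, 1, 1, 1)), 1L)
  expect_identical(select_k_median(rep(3, 6)), 0L)           # none exceed
  expect_identical(select_k_median(c(100, 1, 1, 1, 1, 0, 0)),
                   select_k_median(c(100, 1, 1, 1, 1)))      # zeros ignored
  expect_identical(select_k_median(c(50, 40, 1, 1, 1)), 2L)
})

test_that("the Malinowski indicator finds the elbow", {
  # brute-force oracle for IND on a spectrum with a sharp elbow at 3
  ev <- c(1000, 500, 200, rep(0.5, 17))
  nv <- 400; dyn <- 20
  ind_oracle <- vapply(1:(dyn - 1), function(n)
    sqrt(sum(ev[(n + 1):dyn]) / (nv * (dyn - n))) / (dyn - n)^2, 0)
  expect_identical(select_k_malinowski(ev, nv, dyn),
                   which.min(ind_oracle))
  expect_identical(select_k_malinowski(ev, nv, dyn), 3L)
  # monotone geometric spectrum: total function, no crash
  evg <- 2^(20:1)
  kg <- select_k_malinowski(evg, 100, 20)
  expect_within(kg, 1L, 19L)
  # exact ties break toward smaller n
  expect_identical(select_k_malinowski(c(4, 4, 4), 1, 3),
                   which.min(vapply(1:2, function(n)
                     sqrt(sum(c(4, 4, 4)[(n + 1):3]) / (3 - n)) / (3 - n)^2, 0)))
})

test_that("the Nelson rule counts smooth leading loadings", {
  t <- seq(0, 2 * pi, length.out = 50)
  smooth <- cbind(sin(t), cos(t / 2))
  set.seed(1)
  noise <- matrix(rnorm(100), 50, 2)
  expect_identical(select_k_nelson(cbind(smooth, noise)), 2L)
  expect_identical(select_k_nelson(noise), 0L)
  expect_identical(select_k_nelson(smooth), 2L)   # all smooth: k = ncol
  # stop-at-first-failure: smooth after a noisy one is not counted
  expect_identical(select_k_nelson(cbind(smooth[, 1], noise[, 1], smooth[, 2])), 1L)
})

# --- PCA denoiser -------------------------------------------------------

test_that("full-rank PCA reconstruction is the identity", {
  v <- phantom_volume_48()
  out <- pca_denoise(v, k_override = v$dyn)
  expect_equal(out$volume$data, v$data, tolerance = 1e-10)
  expect_identical(out$k, 50L)
})

test_that("PCA matches a brute-force truncated SVD oracle", {
  set.seed(7)
  for (rep in 1:3) {
    dat <- array(runif(8 * 8 * 10), c(8, 8, 10))
    v <- cest_volume(dat, seq(-2, 2, length.out = 10))
    for (k in c(1L, 3L, 7L)) {
      got <- pca_denoise(v, k_override = k)$volume$data
      # oracle: centre, truncated SVD, reconstruct (independent path)
      X <- t(apply(dat, 3, as.vector))           # dyn x voxels
      mu <- rowMeans(X)
      sv <- svd(t(X - mu))
      Xk <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
        t(sv$v[, 1:k, drop = FALSE])
      want <- array(t(t(Xk) + mu), c(8, 8, 10))
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("PCA-median improves rank-1 spectra under noise", {
  fx <- make_fixture("rank-1", grid = c(32, 32), sigma = 0.05, seed = 5)
  out <- pca_denoise(fx$noisy, "median")
  expect_gt(psnr(fx$clean, out$volume), psnr(fx$clean, fx$noisy))
})

test_that("Nelson retains at least as many components as median on noise", {
  fx <- make_fixture("pure-noise", grid = c(32, 32), sigma = 0.1, seed = 6)
  k_med <- suppressWarnings(pca_denoise(fx$noisy, "median")$k)   # clamp expected
  k_nel <- suppressWarnings(pca_denoise(fx$noisy, "nelson")$k)
  expect_gte(k_nel, k_med)
})

test_that("degenerate criteria are clamped to one component", {
  v <- cest_volume(array(0.5, c(8, 8, 5)), seq(-2, 2, length.out = 5))
  expect_warning(out <- pca_denoise(v, "nelson"), "clamping")
  expect_identical(out$k, 1L)
})

# --- NLM ----------------------------------------------------------------

test_that("NLM leaves constant images unchanged and smooths plateaus", {
  const <- cest_volume(array(0.7, c(24, 24, 2)), c(-1, 1))
  out <- nlm_denoise(const, 11, 3, h = 0.1, sigma = 0.1)
  expect_equal(out$data, const$data, tolerance = 1e-12)
  # noisy step edge: variance within each plateau strictly decreases
  img <- array(0.3, c(24, 24, 1)); img[, 13:24, ] <- 0.8
  v <- cest_volume(img, 0)
  n <- add_kspace_noise(v, 0.08, seed = 3)
  d <- nlm_denoise(n, 11, 3, sigma = 0.08)
  expect_lt(stats::sd(d$data[, 1:10, 1]), stats::sd(n$data[, 1:10, 1]))
  expect_lt(stats::sd(d$data[, 15:24, 1]), stats::sd(n$data[, 15:24, 1]))
  expect_error(nlm_denoise(const, 31, 5), "larger")
  expect_error(nlm_denoise(const, 10, 3))      # windows must be odd
})

test_that("NLM naming follows the benchmark convention", {
  expect_identical(nlm_method_name(21, 5), "NLM BW_21_SW_5")
  expect_identical(resolve_method("nlm-21-5")$name, "NLM BW_21_SW_5")
})

# --- BM3D ---------------------------------------------------------------

test_that("BM3D approaches the identity as sigma vanishes", {
  fx <- ladder_fixture()
  sub <- cest_volume(fx$clean$data[, , 1:3], fx$clean$offsets_ppm[1:3],
                     m0 = fx$clean$m0, mask = fx$clean$mask)
  out <- bm3d_denoise(sub, 11, 4, sigma = 1e-6)
  expect_equal(out$data, sub$data, tolerance = 1e-4)
})

test_that("BM3D WS_11_BS_4 denoises a noisy piecewise-constant image", {
  img <- array(0.25, c(32, 32, 2))
  img[9:24, 9:24, ] <- 0.75
  v <- cest_volume(img, c(-1, 1))
  n <- add_kspace_noise(v, 0.1, seed = 8)
  d <- bm3d_denoise(n, 11, 4, sigma = 0.1)
  expect_gt(psnr(v, d), psnr(v, n))
  expect_error(bm3d_denoise(v, 4, 11), "smaller")
})

test_that("BM3D naming follows the benchmark convention", {
  expect_identical(bm3d_method_name(11, 4), "BM3D WS_11_BS_4")
  expect_identical(resolve_method("bm3d-11-4")$name, "BM3D WS_11_BS_4")
})

# --- cross-cutting safety properties ------------------------------------

test_that("denoisers do not destroy noiseless volumes", {
  fx <- ladder_fixture()
  clean <- cest_volume(fx$clean$data[, , seq(1, 50, by = 5)],
                       fx$clean$offsets_ppm[seq(1, 50, by = 5)],
                       m0 = fx$clean$m0, mask = fx$clean$mask)
  for (out in list(pca_denoise(clean, "median")$volume,
                   nlm_denoise(clean, 11, 3, sigma = 0.01),
                   bm3d_denoise(clean, 11, 4, sigma = 0.01))) {
    expect_gt(psnr(clean, out), 30)
  }
})

test_that("PCA-median gain is positive for sigma of 0.05 and above", {
  fx <- ladder_fixture()
  for (sg in c(0.05, 0.1, 0.2)) {
    noisy <- add_kspace_noise(fx$clean, sg, seed = 11)
    den <- suppressWarnings(pca_denoise(noisy, "median")$volume)
    expect_gt(psnr(fx$clean, den), psnr(fx$clean, noisy))
  }
})
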