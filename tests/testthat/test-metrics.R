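test_that("PSNR matches its closed form", {
  a <- cest_volume(array(0.5, c(8, 8, 3)), c(-1, 0, 1))
  expect_identical(psnr(a, a), Inf)
  b <- a; b$data <- a$data + 0.1
  expect_equal(psnr(a, b), 20, tolerance = 1e-9)
  expect_equal(psnr(b, a), psnr(a, b))                   # symmetric
  c <- a; c$data <- a$data + 0.01
  expect_equal(psnr(a, c), 40, tolerance = 1e-9)
  # masked pooling uses only masked voxels
  m <- matrix(FALSE, 8, 8); m[1:4, ] <- TRUE
  d <- a; d$data[5:8, , ] <- 9
  expect_identical(psnr(a, d, mask = m), Inf)
})

test_that("per-voxel PSNR maps pool along offsets only", {
  a <- cest_volume(array(0.5, c(4, 4, 5)), seq(-2, 2, length.out = 5))
  b <- a
  b$data[1, 1, ] <- 0.6
  pm <- psnr(a, b, per_voxel = TRUE)
  expect_equal(dim(pm), c(4, 4))
  expect_equal(pm[1, 1], 20, tolerance = 1e-9)
  expect_identical(pm[2, 2], Inf)
  msk <- matrix(FALSE, 4, 4); msk[1, ] <- TRUE
  expect_true(is.na(psnr(a, b, mask = msk, per_voxel = TRUE)[2, 2]))
})

test_that("PSNR decreases with the noise level", {
  v <- phantom_volume_48()
  ps <- vapply(c(0.02, 0.05, 0.1, 0.2),
               function(sg) psnr(v, add_kspace_noise(v, sg, seed = 2)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("WASSR leaves centred spectra unchanged and is idempotent", {
  sq <- cest_sequence(b1_uT = 0.9, offsets_ppm = seq(-5, 5, length.out = 50))
  z <- simulate_zspectrum(list(water_pool(2, 100)), sq)
  zc <- wassr_correct(z)
  expect_lt(max(abs(zc$z - z$z)), 1e-6)
  z2 <- wassr_correct(zc)
  expect_lt(abs(attr(z2, "b0_shift_ppm")), 0.02)
})

test_that("WASSR recovers injected field shifts", {
  sq <- cest_sequence(b1_uT = 0.9, offsets_ppm = seq(-5, 5, length.out = 50))
  for (sh in c(0.3, -0.15)) {
    z <- simulate_zspectrum(list(water_pool(2, 100)), sq, b0_shift_ppm = sh)
    zc <- wassr_correct(z)
    expect_lt(abs(attr(zc, "b0_shift_ppm") - sh), 0.01)
    # after correction the asymmetry bias is largely removed
    expect_lt(abs(mtr_asym(zc, c(1.5, 2.5))), abs(mtr_asym(z, c(1.5, 2.5))))
  }
  # a solute pool skews the self-referenced minimum only slightly
  pools <- list(water_pool(2, 100), pool_params(1.2, 10, 1.9, 950, 100))
  z <- simulate_zspectrum(pools, sq, b0_shift_ppm = -0.15)
  expect_lt(abs(attr(wassr_correct(z), "b0_shift_ppm") + 0.15), 0.05)
})

test_that("boundary minima warn and apply no shift", {
  z <- zspectrum(seq(1, 0.2, length.out = 10), seq(-5, 5, length.out = 10))
  expect_warning(zc <- wassr_correct(z), "boundary")
  expect_equal(zc$z, z$z)
})

test_that("MTR asymmetry matches closed forms and is antisymmetric", {
  off <- seq(-4, 4, length.out = 41)
  sym <- zspectrum(1 - 0.5 * exp(-off^2), off)
  expect_equal(mtr_asym(sym, c(1.5, 2.5)), 0, tolerance = 1e-8)
  # Z(-dw) = 0.8, Z(+dw) = 0.7 on the window -> 10%
  zz <- 0.9 - 0.05 * sign(off)
  expect_equal(mtr_asym(zspectrum(zz, off), c(1.5, 2.5)), 10, tolerance = 1e-5)
  asym <- zspectrum(1 - 0.5 * exp(-off^2) - 0.1 * exp(-(off - 2)^2), off)
  mirr <- zspectrum(rev(asym$z), off)
  expect_equal(mtr_asym(mirr, c(1.5, 2.5)), -mtr_asym(asym, c(1.5, 2.5)),
               tolerance = 1e-8)
})

test_that("MTR asymmetry grows with solute concentration", {
  sq <- cest_sequence(b1_uT = 0.9, offsets_ppm = seq(-5, 5, length.out = 50))
  vals <- vapply(c(50, 100, 150, 200), function(conc) {
    pools <- list(water_pool(2, 300), pool_params(1.2, 10, 1.9, 950, conc))
    mtr_asym(simulate_zspectrum(pools, sq), c(1.5, 2.5))
  }, 0)
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))
})

test_that("asymmetry maps summarise ROIs and denoising shrinks their SD", {
  fx <- ladder_fixture()
  labs <- fx$truth$label_map$labels
  rois <- lapply(1:4, function(l) labs == l)
  m_clean <- mtr_asym_map(fx$clean, c(1.5, 2.5), rois, wassr = FALSE)
  expect_s3_class(m_clean, "mtr_asym_map")
  expect_equal(nrow(m_clean$roi_stats), 4L)
  expect_true(all(m_clean$roi_stats$sd < 1e-8))     # homogeneous regions
  expect_true(all(diff(m_clean$roi_stats$mean) > 0))
  m_noisy <- mtr_asym_map(fx$noisy, c(1.5, 2.5), rois, wassr = FALSE)
  den <- suppressWarnings(pca_denoise(fx$noisy, "median")$volume)
  m_den <- mtr_asym_map(den, c(1.5, 2.5), rois, wassr = FALSE)
  expect_lt(mean(m_den$roi_stats$sd), mean(m_noisy$roi_stats$sd))
  # the glycosaminoglycan window is accepted as a range preset
  g <- mtr_asym_map(fx$clean, c(0.9, 1.9), rois[1], wassr = FALSE)
  expect_true(is.finite(g$roi_stats$mean))
})
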