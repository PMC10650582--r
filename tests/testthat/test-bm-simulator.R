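test_that("the generator matrix reduces to Bloch relaxation for one pool", {
  g <- bm_matrix(list(water_pool(t1_s = 2, t2_ms = 100)), 0, 0)
  expect_equal(dim(g$A), c(3, 3))
  expect_equal(diag(g$A), c(-10, -10, -0.5))
  expect_equal(g$A[lower.tri(g$A)], rep(0, 3))
  expect_equal(g$A[upper.tri(g$A)], rep(0, 3))
  # equilibrium: A M + b = 0 at M = (0, 0, M0)
  expect_equal(as.numeric(solve(g$A, -g$b)), c(0, 0, 1))
})

test_that("zero-concentration solutes leave the water rows unchanged", {
  w <- water_pool(1.5, 80)
  sol <- pool_params(1.2, 10, 2, 1000, 0)   # f = 0
  g1 <- bm_matrix(list(w), 100, 50)
  g2 <- bm_matrix(list(w, sol), 100, 50)
  wrows <- c(1, 3, 5)  # water x, y, z in the interleaved-by-component order
  expect_equal(g2$A[wrows, wrows], g1$A)
  expect_equal(g2$b[wrows], g1$b)
})

test_that("generator eigenvalues have nonpositive real part", {
  set.seed(42)
  rg <- protocol_ranges()
  for (rep in 1:20) {
    n_sol <- sample(1:4, 1)
    pools <- c(list(water_pool(runif(1, 0.5, 2.5), runif(1, 40, 500))),
               replicate(n_sol, pool_params(
                 runif(1, 0.5, 2.5), runif(1, 1, 20), runif(1, 0.5, 5),
                 runif(1, 50, 4000), runif(1, 0, 800)), simplify = FALSE))
    g <- bm_matrix(pools, runif(1, 0, 1000), runif(1, -4000, 4000))
    expect_lte(max(Re(eigen(g$A, only.values = TRUE)$values)), 1e-9)
  }
  expect_error(water_pool(-1, 100), "t1_s")
})

test_that("no saturation leaves the spectrum at unity", {
  s0 <- cest_sequence(b1_uT = 0, offsets_ppm = seq(-4, 4, length.out = 9))
  z <- simulate_zspectrum(list(water_pool()), s0)
  expect_equal(z$z, rep(1, 9), tolerance = 1e-9)
})

test_that("continuous-wave limit matches the closed-form steady state", {
  # grid over (T1, T2, B1, offset); tolerance 1% of the closed form
  for (t1 in c(0.8, 2.0)) for (t2 in c(0.05, 0.2)) for (b1 in c(0.5, 1.5))
    for (off in c(0, 1.5)) {
      sq <- cest_sequence(b1_uT = b1, tp_ms = 5000, td_ms = 0, n_pulses = 3,
                          offsets_ppm = off, pulse_shape = "block")
      z <- simulate_zspectrum(list(water_pool(t1, 1000 * t2)), sq)$z
      w1 <- 2 * pi * 42.5774785 * b1
      dw <- 2 * pi * 42.5774785 * 3 * off
      r1 <- 1 / t1; r2 <- 1 / t2
      closed <- r1 * (r2^2 + dw^2) / (r1 * (r2^2 + dw^2) + w1^2 * r2)
      expect_lt(abs(z - closed) / closed, 0.01)
    }
})

test_that("an exchange pool deepens the labeled side of the spectrum", {
  sq <- cest_sequence(b1_uT = 0.9, offsets_ppm = seq(-5, 5, length.out = 50))
  pools <- list(water_pool(1.5, 200),
                pool_params(1.2, 10, delta_ppm = 2, k_hz = 1000, conc_mM = 300))
  z <- simulate_zspectrum(pools, sq)
  at <- function(x) z$z[which.min(abs(z$offsets_ppm - x))]
  expect_lt(at(2), at(-2))
  expect_gt(mtr_asym(z, c(1.5, 2.5)), 0)
  expect_true(all(z$z >= 0 & z$z <= 1 + 1e-6))
})

test_that("zero-exchange solutes do not perturb the water spectrum", {
  sq <- cest_sequence(b1_uT = 1, offsets_ppm = seq(-4, 4, length.out = 11))
  zw <- simulate_zspectrum(list(water_pool(1.5, 80)), sq)
  zm <- simulate_zspectrum(list(water_pool(1.5, 80),
                                pool_params(1.2, 10, 2, 0, 400),
                                pool_params(0.9, 5, -3, 0, 200)), sq)
  expect_lt(max(abs(zw$z - zm$z)), 1e-6)
})

test_that("mirrored chemical shifts mirror the Z-spectrum", {
  sq <- cest_sequence(b1_uT = 0.9, offsets_ppm = seq(-4, 4, length.out = 21))
  zp <- simulate_zspectrum(list(water_pool(1.5, 100),
                                pool_params(1.2, 10, 2.5, 800, 300)), sq)
  zm <- simulate_zspectrum(list(water_pool(1.5, 100),
                                pool_params(1.2, 10, -2.5, 800, 300)), sq)
  expect_equal(zp$z, rev(zm$z), tolerance = 1e-8)
})

test_that("datasets have the stated geometry and are deterministic", {
  lm <- sample_label_map(21, grid = c(128, 128), n_layers = 6)
  ph <- sample_pool_maps(lm, rng_seed = 22)
  v1 <- simulate_dataset(ph, rng_seed = 23)
  expect_equal(dim(v1$data), c(128, 128, 50))
  expect_equal(v1$dyn, 50L)
  v2 <- simulate_dataset(ph, rng_seed = 23)
  expect_identical(v1$data, v2$data)
  expect_true(all(v1$data[!v1$mask] == 0))
  expect_true(all(v1$data[v1$mask] >= 0 & v1$data[v1$mask] <= 1 + 1e-6))
})

test_that("the per-region cache equals voxel-wise computation bit-for-bit", {
  lm <- as_label_map(matrix(c(0L, 1L, 1L, 2L), 2, 2) %x% matrix(1L, 4, 4))
  ph <- sample_pool_maps(lm, rng_seed = 5)
  sq <- cest_sequence(offsets_ppm = seq(-4, 4, length.out = 5))
  a <- simulate_dataset(ph, seq = sq, cache = TRUE)
  b <- simulate_dataset(ph, seq = sq, cache = FALSE)
  expect_identical(a$data, b$data)
})

test_that("optional TE scaling attenuates only the reference image", {
  lm <- as_label_map(matrix(1L, 16, 16))
  ph <- build_phantom(lm, list(list(id = 1L, pools = list(water_pool(1.5, 100)))))
  sq <- cest_sequence(offsets_ppm = c(-2, 2), te_ms = 25)
  plain <- simulate_dataset(ph, seq = sq)
  scaled <- simulate_dataset(ph, seq = sq, te_scale_m0 = TRUE)
  expect_identical(plain$data, scaled$data)
  expect_equal(unique(scaled$m0[lm$foreground]), exp(-25 / 100))
})

test_that("uniform phantoms yield identical spectra everywhere", {
  fx <- water_fixture()
  vox <- which(fx$clean$mask, arr.ind = TRUE)
  ref <- fx$clean$data[vox[1, 1], vox[1, 2], ]
  for (r in c(5L, 20L, nrow(vox))) {
    expect_identical(fx$clean$data[vox[r, 1], vox[r, 2], ], ref)
  }
})
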