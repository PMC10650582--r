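#' Deterministic test fixtures
#'
#' Small, fully specified synthetic datasets used across the test suite
#' and examples. Canonical names:
#'
#' * `"water-only"`: homogeneous single-pool foreground; the Z-spectrum
#'   is symmetric, so MTR_asym is ~0 everywhere.
#' * `"creatine-ladder"`: four equal regions carrying a creatine-like
#'   amine pool (+1.9 ppm) at concentrations 50/100/150/200 mM, emulating
#'   the classical in vitro tube ladder.
#' * `"rank-1"`: a separable (spatial pattern x single spectrum) stack,
#'   exactly rank one, for PCA oracle tests.
#' * `"pure-noise"`: constant 0.5 stack; after corruption it contains
#'   noise only.
#'
#' @param name fixture name (above) or a `fixture_spec`.
#' @param grid `c(H, W)`; default 32 x 32.
#' @param dyn number of offsets (default 50, half-range 5 ppm).
#' @param sigma noise level of the returned `noisy` volume.
#' @param seed RNG seed (noise and any sampled parameters).
#' @return list with elements `clean` ([cest_volume()]), `noisy`
#'   ([cest_volume()]) and `truth` (the `cest_phantom`, or `NULL` for
#'   synthetic non-physical stacks).
#' @examples
#' fx <- make_fixture("creatine-ladder", grid = c(16, 16), sigma = 0.05)
#' fx$clean
#' @export
make_fixture <- function(name, grid = c(32L, 32L), dyn = 50L,
                         sigma = 0.1, seed = 7L) {
  H <- grid[1]; W <- grid[2]
  offsets <- seq(-5, 5, length.out = dyn)
  seq_fix <- cest_sequence(b1_uT = 0.9, tp_ms = 100, td_ms = 100,
                           n_pulses = 10L, offsets_ppm = offsets)
  out <- switch(name,
    "water-only" = {
      lm <- full_ellipse_map(H, W)
      ph <- build_phantom(lm, list(list(id = 1L, pools = list(
        water_pool(t1_s = 1.5, t2_ms = 100)))))
      list(clean = simulate_dataset(ph, seq_fix), truth = ph)
    },
    "creatine-ladder" = {
      lm <- quadrant_map(H, W)
      mk <- function(id, conc) list(id = id, pools = list(
        water_pool(t1_s = 2.0, t2_ms = 300),
        pool_params(t1_s = 1.2, t2_ms = 10, delta_ppm = 1.9,
                    k_hz = 950, conc_mM = conc)))
      ph <- build_phantom(lm, list(mk(1L, 50), mk(2L, 100),
                                   mk(3L, 150), mk(4L, 200)))
      list(clean = simulate_dataset(ph, seq_fix), truth = ph)
    },
    "rank-1" = {
      a <- outer(seq(0.5, 1, length.out = H), seq(0.8, 1, length.out = W))
      s <- 1 - 0.6 * exp(-offsets^2 / 0.5)
      data <- array(0, c(H, W, dyn))
      for (o in seq_len(dyn)) data[, , o] <- a * s[o]
      list(clean = cest_volume(data, offsets), truth = NULL)
    },
    "pure-noise" = {
      list(clean = cest_volume(array(0.5, c(H, W, dyn)), offsets),
           truth = NULL)
    },
    stop("unknown fixture: ", name)
  )
  out$noisy <- add_kspace_noise(out$clean, sigma, seed = seed)
  out[c("clean", "noisy", "truth")]
}

# single elliptical foreground, one region
full_ellipse_map <- function(H, W) {
  as_label_map(matrix(1L, H, W) *
                 (raster_ellipse(H, W, H / 2 + 0.5, W / 2 + 0.5,
                                 0.45 * H, 0.45 * W, 0) * 1L))
}

# elliptical foreground split into four quadrant regions
quadrant_map <- function(H, W) {
  fg <- raster_ellipse(H, W, H / 2 + 0.5, W / 2 + 0.5, 0.45 * H, 0.45 * W, 0)
  i <- matrix(seq_len(H), H, W); j <- matrix(seq_len(W), H, W, byrow = TRUE)
  labs <- 1L + (i > H / 2) + 2L * (j > W / 2)
  labs[!fg] <- 0L
  as_label_map(labs)
}
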