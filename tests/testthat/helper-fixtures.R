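# Shared fixtures are generated once per test run and cached here; all of
# them are built in code (no binary fixtures on disk).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small random phantom volume (48 x 48 x 50) used across modules
phantom_volume_48 <- function(seed = 301L) {
  cached(paste0("ph48_", seed), {
    lm <- sample_label_map(seed, grid = c(48L, 48L), n_layers = 8L)
    ph <- sample_pool_maps(lm, rng_seed = seed + 1L)
    simulate_dataset(ph, rng_seed = seed + 2L)
  })
}

# full-size phantom volume for noise-calibration properties
phantom_volume_128 <- function(seed = 401L) {
  cached("ph128", {
    lm <- sample_label_map(seed, grid = c(128L, 128L), n_layers = 30L)
    ph <- sample_pool_maps(lm, rng_seed = seed + 1L)
    simulate_dataset(ph, rng_seed = seed + 2L)
  })
}

ladder_fixture <- function() {
  cached("ladder", make_fixture("creatine-ladder", grid = c(32L, 32L),
                                sigma = 0.1, seed = 77L))
}

water_fixture <- function() {
  cached("water", make_fixture("water-only", grid = c(32L, 32L),
                               sigma = 0.1, seed = 78L))
}

# training corpus and evaluation volumes for the NN criteria; geometry is
# scaled so the region pixel area matches the full-scale generator
smoke_phantoms <- function(n = 24L) {
  cached("smoke_phantoms", lapply(seq_len(n), function(i) {
    lm <- sample_label_map(i, grid = c(48L, 48L), n_layers = 8L)
    simulate_dataset(sample_pool_maps(lm, rng_seed = 1000L + i),
                     rng_seed = 2000L + i)
  }))
}

heldout_phantoms <- function(n = 4L) {
  cached("heldout_phantoms", lapply(seq_len(n), function(i) {
    lm <- sample_label_map(900L + i, grid = c(48L, 48L), n_layers = 8L)
    simulate_dataset(sample_pool_maps(lm, rng_seed = 910L + i),
                     rng_seed = 920L + i)
  }))
}

# the smoke-trained ResUNet-NE-yes; trained once, shared by the NN
# invariants and the acceptance criterion
smoke_trained_resunet <- function() {
  cached("smoke_model", {
    set.seed(11)
    model <- build_model(model_config("resunet", noise_estimation = TRUE,
                                      depth = 2L, in_channels = 41L,
                                      base_channels = 48L))
    train_denoiser(model, smoke_phantoms(), smoke_train_config(seed = 11L))$model
  })
}

# baseline / denoised PSNR of the smoke model on held-out phantoms
smoke_model_psnr <- function(sigma) {
  key <- paste0("smoke_eval_", sigma)
  cached(key, {
    model <- smoke_trained_resunet()
    res <- vapply(seq_along(heldout_phantoms()), function(i) {
      cl <- heldout_phantoms()[[i]]
      no <- add_kspace_noise(cl, sigma, seed = 930L + i)
      no41 <- random_offset_crop(no, start = 5L)
      cl41 <- random_offset_crop(cl, start = 5L)
      den <- apply_denoiser(model, no41)
      c(base = psnr(cl41, no41), den = psnr(cl41, den))
    }, c(base = 0, den = 0))
    rowMeans(res)
  })
}

expect_within <- function(value, lo, hi) {
  expect_gte(value, lo)
  expect_lte(value, hi)
}
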