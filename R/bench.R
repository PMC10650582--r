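#' Benchmark configuration
#'
#' The `full` preset reproduces the full in silico sweep: noise levels
#' 0.01, 0.02, 0.03, 0.04, 0.05, 0.075, 0.1, 0.15, 0.2 and 0.25 over 200
#' phantoms of 128 x 128. The `smoke` preset is a minutes-scale
#' down-scaling (same code path) for continuous testing.
#'
#' @param preset `"smoke"` or `"full"`.
#' @param sigmas,n_phantoms,grid,n_layers overrides of the preset.
#' @param methods character vector of method identifiers, see
#'   [resolve_method()].
#' @param seed master seed.
#' @return a `bench_config`.
#' @export
bench_config <- function(preset = c("smoke", "full"), sigmas = NULL,
                         n_phantoms = NULL, methods = NULL, grid = NULL,
                         n_layers = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(sigmas = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.075, 0.1, 0.15, 0.2, 0.25),
         n_phantoms = 200L, grid = c(128L, 128L), n_layers = 60L,
         methods = c("identity", "pca-median", "pca-malinowski", "pca-nelson",
                     "nlm-21-5", "bm3d-11-4"))
  } else {
    list(sigmas = c(0.05, 0.1, 0.2), n_phantoms = 4L, grid = c(32L, 32L),
         n_layers = 12L,
         methods = c("identity", "pca-median", "nlm-11-3", "bm3d-7-4"))
  }
  structure(list(preset = preset,
                 sigmas = sigmas %||% def$sigmas,
                 n_phantoms = as.integer(n_phantoms %||% def$n_phantoms),
                 methods = methods %||% def$methods,
                 grid = grid %||% def$grid,
                 n_layers = as.integer(n_layers %||% def$n_layers),
                 seed = as.integer(seed)),
            class = "bench_config")
}

#' Resolve a method identifier to a denoising function
#'
#' Identifiers: `identity`; `pca-median` / `pca-nelson` /
#' `pca-malinowski`; `nlm-<big>-<small>`; `bm3d-<window>-<block>`;
#' `unet-ne-yes|no` / `resunet-ne-yes|no` (require a checkpoint in
#' `checkpoints`). Each resolves to `function(vol, sigma)` returning the
#' denoised volume, plus a display name following the benchmark naming
#' convention (`PCA-Median`, `NLM BW_21_SW_5`, `BM3D WS_11_BS_4`,
#' `ResUNet-NE-yes`, ...).
#'
#' @param id method identifier string.
#' @param checkpoints named list mapping NN method ids to `cest_model`
#'   objects or checkpoint paths.
#' @return list with `name` and `fn`, or `NULL` when an NN checkpoint is
#'   missing (callers should warn and skip).
#' @export
resolve_method <- function(id, checkpoints = list()) {
  p <- strsplit(id, "-")[[1]]
  if (id == "identity")
    return(list(name = "No denoising", fn = function(vol, sigma) vol))
  if (p[1] == "pca" && length(p) == 2)
    return(list(
      name = paste0("PCA-", toupper(substring(p[2], 1, 1)), substring(p[2], 2)),
      fn = function(vol, sigma) pca_denoise(vol, p[2])$volume))
  if (p[1] == "nlm" && length(p) == 3) {
    bw <- as.integer(p[2]); sw <- as.integer(p[3])
    return(list(name = nlm_method_name(bw, sw),
                fn = function(vol, sigma)
                  nlm_denoise(vol, bw, sw, sigma = sigma)))
  }
  if (p[1] == "bm3d" && length(p) == 3) {
    ws <- as.integer(p[2]); bs <- as.integer(p[3])
    return(list(name = bm3d_method_name(ws, bs),
                fn = function(vol, sigma)
                  bm3d_denoise(vol, ws, bs, sigma = sigma)))
  }
  if (p[1] %in% c("unet", "resunet")) {
    ck <- checkpoints[[id]]
    if (is.null(ck)) return(NULL)
    model <- if (inherits(ck, "cest_model")) ck else load_checkpoint(ck)
    nm <- sprintf("%s-NE-%s", if (p[1] == "resunet") "ResUNet" else "UNet",
                  if (isTRUE(model$cfg$noise_estimation)) "yes" else "no")
    return(list(name = nm, fn = function(vol, sigma) apply_denoiser(model, vol)))
  }
  stop("unknown method identifier: ", id)
}

#' Run the in silico denoising benchmark
#'
#' For every phantom: simulate the clean volume, then for every noise
#' level corrupt it, run every method and record the PSNR against the
#' clean volume (pooled over the image, see [psnr()]). Returns per-
#' (method, sigma) mean and standard deviation across phantoms. Fully
#' seeded and reproducible; NN methods without a checkpoint are skipped
#' with a warning.
#'
#' @param cfg a [bench_config()].
#' @param checkpoints see [resolve_method()].
#' @param verbose print progress.
#' @return data frame with columns `method`, `sigma`, `psnr_mean`,
#'   `psnr_sd`, `n_datasets`.
#' @export
run_benchmark <- function(cfg, checkpoints = list(), verbose = FALSE) {
  stopifnot(inherits(cfg, "bench_config"))
  methods <- list()
  for (id in cfg$methods) {
    m <- resolve_method(id, checkpoints)
    if (is.null(m)) warning("no checkpoint for ", id, "; method skipped")
    else methods[[id]] <- m
  }
  res <- array(NA_real_,
               c(length(methods), length(cfg$sigmas), cfg$n_phantoms))
  for (ph in seq_len(cfg$n_phantoms)) {
    seed_ph <- cfg$seed + 1000L * ph
    lm <- sample_label_map(seed_ph, grid = cfg$grid, n_layers = cfg$n_layers)
    phant <- sample_pool_maps(lm, rng_seed = seed_ph + 1L)
    clean <- simulate_dataset(phant, seq = NULL, rng_seed = seed_ph + 2L)
    for (si in seq_along(cfg$sigmas)) {
      sg <- cfg$sigmas[si]
      noisy <- add_kspace_noise(clean, sg, seed = seed_ph + 10L + si)
      for (mi in seq_along(methods)) {
        den <- methods[[mi]]$fn(noisy, sg)
        res[mi, si, ph] <- psnr(clean, den)
      }
    }
    if (verbose) message(sprintf("phantom %d/%d done", ph, cfg$n_phantoms))
  }
  out <- expand.grid(mi = seq_along(methods), si = seq_along(cfg$sigmas))
  data.frame(method = vapply(methods[out$mi], `[[`, "", "name"),
             sigma = cfg$sigmas[out$si],
             psnr_mean = mapply(function(m, s) mean(res[m, s, ]), out$mi, out$si),
             psnr_sd = mapply(function(m, s) stats::sd(res[m, s, ]), out$mi, out$si),
             n_datasets = cfg$n_phantoms,
             row.names = NULL)
}
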