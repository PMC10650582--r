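#' Configure a U-Net / ResU-Net denoising autoencoder
#'
#' Both architectures take the Z-spectral offsets as input channels of a
#' 2D convolutional encoder-decoder. The encoder is `depth` "down" blocks
#' of two 3x3 convolutions (the ResU-Net adds an identity shortcut, with
#' a 1x1 channel-matching convolution where channel counts differ),
#' followed by 2x2 max pooling. The latent space is two residual blocks
#' that double the feature count. The decoder mirrors with nearest-
#' neighbour upsampling, a 3x3 halving convolution, skip concatenation
#' and a two-convolution block per level; a final linear 3x3 convolution
#' maps back to the input channel count. In noise-estimation mode
#' (`NE-yes`) the network predicts the noise, which [apply_denoiser()]
#' subtracts from the input; otherwise (`NE-no`) it predicts the clean
#' image directly.
#'
#' @param arch `"unet"` or `"resunet"`.
#' @param noise_estimation logical; `TRUE` for NE-yes mode.
#' @param depth number of encoder levels (the full-scale models use 4).
#' @param in_channels number of offsets fed as channels (full scale: 41).
#' @param base_channels feature count of the first level.
#' @return a `model_config`.
#' @export
model_config <- function(arch = c("resunet", "unet"), noise_estimation = TRUE,
                         depth = 4L, in_channels = 41L, base_channels = 16L) {
  arch <- match.arg(arch)
  stopifnot(depth >= 1, in_channels >= 1, base_channels >= 1)
  structure(list(arch = arch, noise_estimation = noise_estimation,
                 depth = as.integer(depth), in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels)),
            class = "model_config")
}

conv_init <- function(cin, cout, k) {
  list(w = matrix(stats::rnorm(cout * k * k * cin, sd = sqrt(2 / (k * k * cin))),
                  cout, k * k * cin),
       b = numeric(cout), k = as.integer(k), cin = cin, cout = cout)
}

#' Instantiate a denoising model
#'
#' Allocates and He-initializes all convolution weights for the
#' architecture described by `cfg`. Initialization uses the current RNG
#' stream (seed it for reproducibility).
#'
#' @param cfg a [model_config()].
#' @return an object of class `cest_model` holding the named layer list.
#' @examples
#' set.seed(1)
#' m <- build_model(model_config("resunet", depth = 2, in_channels = 8,
#'                               base_channels = 4))
#' model_num_params(m)
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  res <- cfg$arch == "resunet"
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)
  L <- list()
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    L[[sprintf("e%d.c1", i)]] <- conv_init(cin, ch[i], 3L)
    L[[sprintf("e%d.c2", i)]] <- conv_init(ch[i], ch[i], 3L)
    if (res) L[[sprintf("e%d.sc", i)]] <- conv_init(cin, ch[i], 1L)
    cin <- ch[i]
  }
  cd <- ch[cfg$depth]
  # latent: two residual blocks, doubling the feature count
  L[["l1.c1"]] <- conv_init(cd, 2L * cd, 3L)
  L[["l1.c2"]] <- conv_init(2L * cd, 2L * cd, 3L)
  L[["l1.sc"]] <- conv_init(cd, 2L * cd, 1L)
  L[["l2.c1"]] <- conv_init(2L * cd, 2L * cd, 3L)
  L[["l2.c2"]] <- conv_init(2L * cd, 2L * cd, 3L)
  for (i in rev(seq_len(cfg$depth))) {
    L[[sprintf("d%d.up", i)]] <- conv_init(2L * ch[i], ch[i], 3L)
    L[[sprintf("d%d.c1", i)]] <- conv_init(2L * ch[i], ch[i], 3L)
    L[[sprintf("d%d.c2", i)]] <- conv_init(ch[i], ch[i], 3L)
    if (res) L[[sprintf("d%d.sc", i)]] <- conv_init(2L * ch[i], ch[i], 1L)
  }
  # near-zero output head: the initial prediction is then ~0 (no noise /
  # dark image), which avoids the early loss blow-up and ReLU die-off
  # that a full He-scale head causes at these learning rates
  L[["out"]] <- conv_init(ch[1], cfg$in_channels, 3L)
  L[["out"]]$w <- L[["out"]]$w * 0.01
  structure(list(cfg = cfg, layers = L), class = "cest_model")
}

#' @export
print.cest_model <- function(x, ...) {
  cat(sprintf("%s (%s), depth %d, %d -> %d channels, %s parameters\n",
              toupper(x$cfg$arch),
              if (x$cfg$noise_estimation) "NE-yes" else "NE-no",
              x$cfg$depth, x$cfg$in_channels, x$cfg$base_channels,
              format(model_num_params(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#' @param model a `cest_model`.
#' @return integer count of weights and biases.
#' @export
model_num_params <- function(model) {
  sum(vapply(model$layers, function(l) length(l$w) + length(l$b), 0))
}

relu <- function(a) {
  a[a < 0] <- 0
  a
}

conv_fw <- function(x, l) cpp_conv_fw(x, l$w, l$b, l$k)

# forward pass; returns y and the caches needed for the backward sweep
nn_forward <- function(model, x, keep_cache = TRUE) {
  cfg <- model$cfg
  L <- model$layers
  d <- dim(x)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop(sprintf("spatial size %dx%d not divisible by 2^depth = %d",
                 d[1], d[2], 2^cfg$depth))
  if (d[3] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[3]))
  res <- cfg$arch == "resunet"
  cache <- list()
  block_fw <- function(x, id, resid) {
    c1 <- L[[paste0(id, ".c1")]]; c2 <- L[[paste0(id, ".c2")]]
    a1 <- conv_fw(x, c1); r1 <- relu(a1)
    a2 <- conv_fw(r1, c2)
    sc <- NULL
    if (resid) {
      sc <- L[[paste0(id, ".sc")]]
      a2 <- a2 + if (is.null(sc)) x else conv_fw(x, sc)
    }
    y <- relu(a2)
    if (keep_cache)
      cache[[id]] <<- list(x = x, a1 = a1, r1 = r1, a2 = a2, resid = resid)
    y
  }
  h <- x
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    h <- block_fw(h, sprintf("e%d", i), res)
    skips[[i]] <- h
    mp <- cpp_maxpool_fw(h)
    if (keep_cache) cache[[sprintf("pool%d", i)]] <- list(idx = mp$idx, H = dim(h)[1], W = dim(h)[2])
    h <- mp$y
  }
  h <- block_fw(h, "l1", TRUE)
  h <- block_fw(h, "l2", TRUE)
  for (i in rev(seq_len(cfg$depth))) {
    hu <- cpp_upsample_fw(h)
    up <- L[[sprintf("d%d.up", i)]]
    au <- conv_fw(hu, up); ru <- relu(au)
    if (keep_cache) cache[[sprintf("up%d", i)]] <- list(x = hu, a = au)
    hcat <- abind3(ru, skips[[i]])
    h <- block_fw(hcat, sprintf("d%d", i), res)
  }
  y <- conv_fw(h, L[["out"]])
  if (keep_cache) cache[["out"]] <- list(x = h)
  list(y = y, cache = cache)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# backward pass: gradient of the scalar loss wrt every layer parameter
nn_backward <- function(model, cache, dy) {
  cfg <- model$cfg
  L <- model$layers
  res <- cfg$arch == "resunet"
  grads <- list()
  conv_bw <- function(id, x, dy) {
    l <- L[[id]]
    g <- cpp_conv_bw(x, l$w, dy, l$k)
    grads[[id]] <<- list(w = g$dw, b = as.numeric(g$db))
    g$dx
  }
  block_bw <- function(id, dyb) {
    cb <- cache[[id]]
    da2 <- dyb * (cb$a2 > 0)
    dr1 <- conv_bw(paste0(id, ".c2"), cb$r1, da2)
    da1 <- dr1 * (cb$a1 > 0)
    dx <- conv_bw(paste0(id, ".c1"), cb$x, da1)
    if (cb$resid) {
      scid <- paste0(id, ".sc")
      dx <- dx + if (is.null(L[[scid]])) da2 else conv_bw(scid, cb$x, da2)
    }
    dx
  }
  dh <- conv_bw("out", cache[["out"]]$x, dy)
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    dcat <- block_bw(sprintf("d%d", i), dh)
    cu <- cache[[sprintf("up%d", i)]]
    nru <- dim(cu$a)[3]
    dru <- dcat[, , seq_len(nru), drop = FALSE]
    dskips[[i]] <- dcat[, , nru + seq_len(dim(dcat)[3] - nru), drop = FALSE]
    dau <- dru * (cu$a > 0)
    dhu <- conv_bw(sprintf("d%d.up", i), cu$x, dau)
    dh <- cpp_upsample_bw(dhu)
  }
  dh <- block_bw("l2", dh)
  dh <- block_bw("l1", dh)
  for (i in rev(seq_len(cfg$depth))) {
    p <- cache[[sprintf("pool%d", i)]]
    dh <- cpp_maxpool_bw(dh, p$idx, p$H, p$W) + dskips[[i]]
    dh <- block_bw(sprintf("e%d", i), dh)
  }
  grads
}

#' Apply a trained denoiser to a CEST volume
#'
#' Runs the network on the offset stack (offsets as channels). In NE-yes
#' mode the predicted noise is subtracted from the input; in NE-no mode
#' the network output is returned directly. The result is clamped to
#' `[0, 1.5]`.
#'
#' @param model a `cest_model`.
#' @param vol a [cest_volume()] whose `dyn` equals the model's input
#'   channel count and whose spatial size is divisible by `2^depth`.
#' @return the denoised [cest_volume()].
#' @export
apply_denoiser <- function(model, vol) {
  stopifnot(inherits(model, "cest_model"), inherits(vol, "cest_volume"))
  y <- nn_forward(model, vol$data, keep_cache = FALSE)$y
  out <- if (model$cfg$noise_estimation) vol$data - y else y
  out <- pmin(pmax(out, 0), 1.5)
  update_data(vol, out)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the [model_config()] alongside the weights.
#'
#' @param model a `cest_model`.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the `cest_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cest_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "cest_model"))
  m
}
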