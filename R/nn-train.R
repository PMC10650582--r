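#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam with learning rate 0.01
#' and weight decay 1e-6, ReduceLROnPlateau scheduling (patience 3,
#' factor 0.1) on the validation loss, 30 epochs, batches of 40, MSE
#' loss, per-sample noise level drawn uniformly from 0 to 0.2 afresh
#' every epoch, and a random 50-to-41 offset crop. The `smoke` preset
#' scales the same loop down to desk hardware.
#'
#' @param epochs,batch_size,lr,weight_decay optimizer settings.
#' @param scheduler_patience,scheduler_factor plateau scheduler settings.
#' @param sigma_range `c(low, high)` of the uniform noise-level draw.
#' @param crop_width offset-window width fed to the network.
#' @param patch_size optional spatial patch edge for training samples
#'   (noise is injected on the full image first, then a random square
#'   patch is cut); `NULL` trains on full images. Patching buys many
#'   cheap optimizer steps on desk hardware.
#' @param patches_per_phantom training patches drawn per phantom per
#'   epoch (only with `patch_size`).
#' @param val_fraction held-out phantom fraction for validation.
#' @param seed RNG seed controlling init order, shuffling and noise.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 40L, lr = 0.01,
                         weight_decay = 1e-6, scheduler_patience = 3L,
                         scheduler_factor = 0.1, sigma_range = c(0, 0.2),
                         crop_width = 41L, patch_size = NULL,
                         patches_per_phantom = 1L, val_fraction = 0.1,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_factor = scheduler_factor,
                 sigma_range = sigma_range, crop_width = as.integer(crop_width),
                 patch_size = if (!is.null(patch_size)) as.integer(patch_size),
                 patches_per_phantom = as.integer(patches_per_phantom),
                 val_fraction = val_fraction, loss = "mse",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... overrides of the preset's fields.
#' @export
smoke_train_config <- function(...) {
  modifyList(train_config(epochs = 50L, batch_size = 2L, lr = 1e-3,
                          scheduler_patience = 8L, patch_size = 16L,
                          patches_per_phantom = 4L),
             list(...))
}

# ReduceLROnPlateau state machine: multiply lr by `factor` once the
# monitored loss has failed to improve for `patience` consecutive epochs
plateau_init <- function(lr) list(lr = lr, best = Inf, stall = 0L)

plateau_step <- function(st, loss, patience, factor) {
  if (loss < st$best - 1e-12) {
    st$best <- loss
    st$stall <- 0L
  } else {
    st$stall <- st$stall + 1L
    if (st$stall >= patience) {
      st$lr <- st$lr * factor
      st$stall <- 0L
    }
  }
  st
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(model, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]; l <- model$layers[[nm]]
    gw <- g$w + wd * l$w
    s$mw <- beta1 * s$mw + (1 - beta1) * gw
    s$vw <- beta2 * s$vw + (1 - beta2) * gw^2
    l$w <- l$w - lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    model$layers[[nm]] <- l
    state[[nm]] <- s
  }
  list(model = model, state = state)
}

# noisy input / training target for one clean volume, using the live RNG
make_training_pair <- function(vol, tc, noise_estimation) {
  sigma <- stats::runif(1, tc$sigma_range[1], tc$sigma_range[2])
  noisy <- add_kspace_noise(vol, sigma,
                            seed = sample.int(.Machine$integer.max, 1))
  start <- if (vol$dyn > tc$crop_width)
    sample.int(vol$dyn - tc$crop_width + 1L, 1L) else 1L
  noisy <- random_offset_crop(noisy, width = tc$crop_width, start = start)
  clean <- random_offset_crop(vol, width = tc$crop_width, start = start)
  target <- if (noise_estimation) noisy$data - clean$data else clean$data
  list(x = noisy$data, target = target, sigma = sigma)
}

# random square spatial crop of a training pair
cut_patch <- function(pair, ps) {
  d <- dim(pair$x)
  i0 <- sample.int(d[1] - ps + 1L, 1L)
  j0 <- sample.int(d[2] - ps + 1L, 1L)
  ii <- i0:(i0 + ps - 1L); jj <- j0:(j0 + ps - 1L)
  list(x = pair$x[ii, jj, , drop = FALSE],
       target = pair$target[ii, jj, , drop = FALSE], sigma = pair$sigma)
}

#' Train a denoising autoencoder
#'
#' Runs the supervised loop: for every clean phantom volume, a fresh
#' noise level is drawn each epoch, k-space noise is injected and a
#' random offset crop is taken; the network regresses the injected noise
#' (NE-yes) or the clean crop (NE-no) under MSE loss. Adam updates use
#' mean minibatch gradients; a plateau scheduler multiplies the learning
#' rate by `scheduler_factor` when the validation loss has not improved
#' for `scheduler_patience` epochs. Aborts on a non-finite loss.
#'
#' @param model a `cest_model` from [build_model()].
#' @param phantoms list of clean [cest_volume()] objects with equal `dyn`
#'   (at least `crop_width`).
#' @param tc a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`, `lr`).
#' @export
train_denoiser <- function(model, phantoms, tc = train_config(),
                           verbose = FALSE) {
  stopifnot(inherits(model, "cest_model"), length(phantoms) >= 2)
  dyns <- vapply(phantoms, function(v) v$dyn, 0L)
  stopifnot(all(dyns == dyns[1]), dyns[1] >= tc$crop_width)
  ne <- model$cfg$noise_estimation
  with_seed(tc$seed, {
    n <- length(phantoms)
    n_val <- max(1L, round(tc$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    # fixed validation pairs: the scheduler needs a low-variance signal,
    # so validation noise/crops are drawn once, not re-drawn per epoch,
    # with noise levels stratified evenly across the training range
    val_sigmas <- seq(tc$sigma_range[1], tc$sigma_range[2],
                      length.out = n_val + 2L)[-c(1L, n_val + 2L)]
    val_pairs <- lapply(seq_along(val_idx), function(vi) {
      tc_v <- tc
      tc_v$sigma_range <- rep(val_sigmas[vi], 2)
      make_training_pair(phantoms[[val_idx[vi]]], tc_v, ne)
    })
    state <- adam_init(model$layers)
    sched <- plateau_init(tc$lr)
    t_adam <- 0L
    history <- data.frame()
    best_model <- model
    best_val <- Inf
    use_patch <- !is.null(tc$patch_size)
    reps <- if (use_patch) tc$patches_per_phantom else 1L
    for (epoch in seq_len(tc$epochs)) {
      # with patching, noise is injected once per phantom per epoch and
      # all of that epoch's patches are cut from the same corrupted image
      epoch_pairs <- if (use_patch)
        stats::setNames(lapply(train_idx, function(s)
          make_training_pair(phantoms[[s]], tc, ne)), train_idx)
      order_idx <- sample(rep(train_idx, reps))
      batches <- split(order_idx, ceiling(seq_along(order_idx) / tc$batch_size))
      tr_losses <- c()
      for (bt in batches) {
        grads <- NULL
        loss_acc <- 0
        for (s in bt) {
          pair <- if (use_patch)
            cut_patch(epoch_pairs[[as.character(s)]], tc$patch_size)
          else make_training_pair(phantoms[[s]], tc, ne)
          fw <- nn_forward(model, pair$x)
          resid <- fw$y - pair$target
          loss_acc <- loss_acc + mean(resid^2)
          g <- nn_backward(model, fw$cache, 2 * resid / length(resid))
          grads <- if (is.null(grads)) g else
            mapply(function(a, b) list(w = a$w + b$w, b = a$b + b$b),
                   grads, g, SIMPLIFY = FALSE)
        }
        nb <- length(bt)
        grads <- lapply(grads, function(g) list(w = g$w / nb, b = g$b / nb))
        loss <- loss_acc / nb
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d (lr=%g); ",
                       epoch, sched$lr),
               "reduce the learning rate or check the input scaling")
        tr_losses <- c(tr_losses, loss)
        t_adam <- t_adam + 1L
        upd <- adam_step(model, grads, state, sched$lr, tc$weight_decay, t_adam)
        model <- upd$model; state <- upd$state
      }
      val_losses <- vapply(val_pairs, function(pair) {
        fw <- nn_forward(model, pair$x, keep_cache = FALSE)
        mean((fw$y - pair$target)^2)
      }, 0)
      val_loss <- mean(val_losses)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(tr_losses), val_loss = val_loss,
        lr = sched$lr))
      if (verbose)
        message(sprintf("epoch %2d  train %.5f  val %.5f  lr %g",
                        epoch, mean(tr_losses), val_loss, sched$lr))
      sched <- plateau_step(sched, val_loss, tc$scheduler_patience,
                            tc$scheduler_factor)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_model <- model
      }
    }
    # return the weights with the best validation loss, so a late
    # destabilised epoch cannot degrade the delivered model
    list(model = best_model, history = history)
  })
}
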