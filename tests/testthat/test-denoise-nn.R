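tiny_cfg <- function(arch = "resunet", ne = TRUE)
  model_config(arch, noise_estimation = ne, depth = 2L, in_channels = 3L,
               base_channels = 2L)

test_that("the builder lays out encoder, latent and decoder stages", {
  set.seed(1)
  m <- build_model(model_config("resunet", TRUE, depth = 4L,
                                in_channels = 8L, base_channels = 2L))
  nms <- names(m$layers)
  expect_length(grep("^e[0-9]+\\.c1$", nms), 4L)   # 4 down stages
  expect_length(grep("^d[0-9]+\\.up$", nms), 4L)   # 4 up stages
  expect_length(grep("^l[0-9]+\\.c1$", nms), 2L)   # 2 latent residual blocks
  expect_length(grep("^e[0-9]+\\.sc$", nms), 4L)   # shortcuts on every stage
  # latent doubles the features
  expect_equal(m$layers[["l1.c1"]]$cout, 2L * m$layers[["e4.c2"]]$cout)
})

test_that("forward passes preserve shape and reject bad sizes", {
  set.seed(2)
  m <- build_model(model_config("resunet", TRUE, depth = 2L,
                                in_channels = 41L, base_channels = 4L))
  x <- array(runif(16 * 16 * 41), c(16, 16, 41))
  y <- cestlab:::nn_forward(m, x, keep_cache = FALSE)$y
  expect_equal(dim(y), c(16, 16, 41))
  expect_error(cestlab:::nn_forward(m, array(0, c(15, 16, 41))), "divisible")
  expect_error(cestlab:::nn_forward(m, array(0, c(16, 16, 40))), "channels")
})

test_that("residual shortcuts add parameters over the plain U-Net", {
  set.seed(3)
  pu <- model_num_params(build_model(tiny_cfg("unet")))
  pr <- model_num_params(build_model(tiny_cfg("resunet")))
  expect_gt(pr, pu)
  # NE mode changes the target, not the backbone
  expect_equal(model_num_params(build_model(tiny_cfg("resunet", TRUE))),
               model_num_params(build_model(tiny_cfg("resunet", FALSE))))
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(4)
  m <- build_model(tiny_cfg())
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  tgt <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  fw <- cestlab:::nn_forward(m, x)
  g <- cestlab:::nn_backward(m, fw$cache, 2 * (fw$y - tgt) / length(tgt))
  loss_of <- function(mm) {
    f <- cestlab:::nn_forward(mm, x, keep_cache = FALSE)
    mean((f$y - tgt)^2)
  }
  eps <- 1e-5
  for (nm in names(m$layers)) {
    # every layer receives gradient somewhere
    expect_gt(max(abs(g[[nm]]$w)), 0, label = paste("grad", nm))
    i <- which.max(abs(g[[nm]]$w))
    m2 <- m; m2$layers[[nm]]$w[i] <- m$layers[[nm]]$w[i] + eps
    m3 <- m; m3$layers[[nm]]$w[i] <- m$layers[[nm]]$w[i] - eps
    num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
    expect_equal(g[[nm]]$w[i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("a zero-weight NE-yes head is the identity denoiser", {
  set.seed(5)
  m <- build_model(model_config("resunet", TRUE, depth = 2L,
                                in_channels = 5L, base_channels = 2L))
  m$layers[["out"]]$w[] <- 0
  m$layers[["out"]]$b[] <- 0
  v <- cest_volume(array(runif(16 * 16 * 5), c(16, 16, 5)),
                   seq(-2, 2, length.out = 5))
  out <- apply_denoiser(m, v)
  expect_equal(out$data, v$data, tolerance = 1e-12)
  expect_identical(out$offsets_ppm, v$offsets_ppm)
  # NE-no keeps metadata too
  m2 <- build_model(model_config("resunet", FALSE, depth = 2L,
                                 in_channels = 5L, base_channels = 2L))
  out2 <- apply_denoiser(m2, v)
  expect_equal(dim(out2$data), dim(v$data))
  expect_true(all(out2$data >= 0 & out2$data <= 1.5))
})

test_that("training reduces validation loss and is seed-deterministic", {
  ph <- lapply(1:6, function(i) {
    fx <- make_fixture("creatine-ladder", grid = c(16, 16), dyn = 44,
                       sigma = 0, seed = i)
    fx$clean
  })
  tc <- train_config(epochs = 3L, batch_size = 2L, lr = 1e-3,
                     crop_width = 41L, seed = 21L)
  set.seed(31)
  m <- build_model(model_config("resunet", TRUE, depth = 2L,
                                in_channels = 41L, base_channels = 2L))
  fit1 <- train_denoiser(m, ph, tc)
  expect_named(fit1$history, c("epoch", "train_loss", "val_loss", "lr"))
  expect_lt(fit1$history$val_loss[3], fit1$history$val_loss[1] * 1.5)
  fit2 <- train_denoiser(m, ph, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$layers, fit2$model$layers)
})

test_that("the plateau scheduler decimates the learning rate", {
  st <- cestlab:::plateau_init(0.01)
  losses <- c(1.0, 0.5, 0.5, 0.5, 0.5, 0.4, 0.4, 0.4, 0.4)
  lrs <- numeric(0)
  for (l in losses) {
    st <- cestlab:::plateau_step(st, l, patience = 3L, factor = 0.1)
    lrs <- c(lrs, st$lr)
  }
  # three stalls after the epoch-2 improvement fire the first decimation;
  # the later improvement to 0.4 resets the counter before the second
  expect_equal(lrs, c(0.01, 0.01, 0.01, 0.01, 0.001, 0.001, 0.001, 0.001,
                      1e-4))
  # an improving sequence never decimates
  st2 <- cestlab:::plateau_init(0.01)
  for (l in c(1, 0.9, 0.8, 0.7, 0.6))
    st2 <- cestlab:::plateau_step(st2, l, 3L, 0.1)
  expect_equal(st2$lr, 0.01)
})

test_that("the smoke-trained network beats the noisy baseline broadly", {
  for (sg in c(0.05, 0.2)) {
    p <- smoke_model_psnr(sg)
    expect_gt(p["den"], p["base"])
  }
})
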