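test_that("network configuration is validated", {
  expect_error(unet_config(depth = 1), "depth")
  expect_error(unet_config(depth = 3, input_size = 60), "divisible")
  expect_s3_class(unet_config(2, 4, 32), "unet_config")
})

test_that("architecture geometry: bottleneck size and shape preservation", {
  m <- build_unet(unet_config(depth = 3, base_channels = 4, input_size = 64))
  x <- array(runif(64 * 64), c(64, 64, 1))
  fw <- lithogate:::unet_forward(m, x, keep_cache = TRUE)
  # 64 / 2^3 = 8: the bottleneck feature map is 8x8
  expect_equal(dim(fw$caches$bott$blk$out)[1:2], c(8L, 8L))
  # output logits have the input geometry and one channel per class
  expect_equal(dim(fw$logits), c(64L, 64L, 2L))

  m2 <- build_unet(unet_config(depth = 2, base_channels = 3, input_size = 32))
  x2 <- array(runif(32 * 32), c(32, 32, 1))
  expect_equal(dim(lithogate:::unet_forward(m2, x2)$logits), c(32L, 32L, 2L))
})

test_that("parameter count follows the convolution arithmetic", {
  # closed-form count for a 2-stage net with base channels c:
  # enc1: (9*1+1)c + (9c+1)c; enc2: (9c+1)2c + (18c+1)2c
  # bottleneck: (18c+1)4c + (36c+1)4c
  # dec2: (54c+1)2c + (18c+1)2c; dec1: (27c+1)c + (9c+1)c; head: 2c+2
  count2 <- function(c) {
    (9 + 1) * c + (9 * c + 1) * c +
      (9 * c + 1) * 2 * c + (18 * c + 1) * 2 * c +
      (18 * c + 1) * 4 * c + (36 * c + 1) * 4 * c +
      (54 * c + 1) * 2 * c + (18 * c + 1) * 2 * c +
      (27 * c + 1) * c + (9 * c + 1) * c +
      2 * c + 2
  }
  for (c in c(2, 4)) {
    m <- build_unet(unet_config(depth = 2, base_channels = c, input_size = 16))
    expect_equal(n_parameters(m), count2(c))
  }
  # doubling base channels grows the count ~4x (quadratic in width)
  ratio <- count2(8) / count2(4)
  expect_gt(ratio, 3.5); expect_lt(ratio, 4.1)
})

test_that("backpropagated gradients match finite differences", {
  m <- build_unet(unet_config(depth = 2, base_channels = 2, input_size = 8),
                  seed = 3)
  # move biases off zero so no pre-activation sits exactly on a ReLU kink
  m$params <- withr::with_seed(50, lapply(m$params, function(l) {
    l$b <- rnorm(length(l$b), sd = 0.1); l
  }))
  set.seed(4)
  x <- array(runif(64), c(8, 8, 1))
  y <- array(rbinom(128, 1, 0.4), c(8, 8, 2))
  eps <- 1e-6
  for (pw in list(NULL, c(4, 1))) {   # unweighted and stone-weighted loss
    fw <- lithogate:::unet_forward(m, x, keep_cache = TRUE)
    lz <- lithogate:::bce_logits(fw$logits, y, pw)
    g <- lithogate:::unet_backward(m, fw, lz$dz)
    loss_at <- function(m2) lithogate:::bce_logits(
      lithogate:::unet_forward(m2, x)$logits, y, pw)$loss
    for (nm in names(m$params)) {
      for (slot in c("W", "b")) {
        idx <- withr::with_seed(7, sample(length(m$params[[nm]][[slot]]),
                                          min(2, length(m$params[[nm]][[slot]]))))
        for (i in idx) {
          m2 <- m
          m2$params[[nm]][[slot]][i] <- m2$params[[nm]][[slot]][i] + eps
          up <- loss_at(m2)
          m2$params[[nm]][[slot]][i] <- m2$params[[nm]][[slot]][i] - 2 * eps
          dn <- loss_at(m2)
          numeric_grad <- (up - dn) / (2 * eps)
          expect_lt(abs(g[[nm]][[slot]][i] - numeric_grad) /
                      max(1e-6, abs(numeric_grad)), 1e-4)
        }
      }
    }
  }
})

test_that("cross-validation plan rotates validation and test patients", {
  ids <- sprintf("P%02d", 1:11)
  plan <- make_cv_splits(ids)
  expect_length(plan, 11L)
  for (fold in plan) {
    expect_setequal(c(fold$train, fold$val, fold$test), ids)
    expect_length(intersect(fold$train, c(fold$val, fold$test)), 0L)
    expect_false(fold$val == fold$test)
    expect_length(fold$train, 9L)
  }
  expect_setequal(vapply(plan, `[[`, character(1), "val"), ids)
  expect_setequal(vapply(plan, `[[`, character(1), "test"), ids)
  # each patient is validation exactly once and test exactly once
  expect_equal(anyDuplicated(vapply(plan, `[[`, character(1), "val")), 0L)
  expect_equal(anyDuplicated(vapply(plan, `[[`, character(1), "test")), 0L)
  expect_error(make_cv_splits(c("a", "b")), "at least 3")
  expect_error(make_cv_splits(c("a", "b", "b", "c")), "distinct")
})

test_that("training converges on synthetic masks with early stopping", {
  co <- simulate_cohort(4, small_sim_config(duration = 4), jitter = 0.5,
                        seed = 21)
  pick <- function(p, idx) lapply(p$frames[idx], function(f)
    list(image = f$image, stone_mask = f$stone_mask,
         kidney_mask = f$kidney_mask))
  # 57 delineated training images, 6 validation, from disjoint patients
  train_frames <- c(pick(co[[1]], seq(1, 57, 3)), pick(co[[2]], seq(1, 57, 3)),
                    pick(co[[3]], seq(1, 57, 3)))
  val_frames <- pick(co[[4]], seq(1, 60, 10))
  expect_length(train_frames, 57L)

  cfg <- unet_config(depth = 2, base_channels = 6, input_size = 32)
  model <- build_unet(cfg, seed = 21)
  fit <- train_unet(model, train_frames, val_frames,
                    train_config(max_epochs = 30, patience = 5, seed = 21))

  # early stopping contract: returned weights minimise the validation curve
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  expect_lte(fit$history$train_loss[fit$best_epoch],
             fit$history$train_loss[1])

  # validation Dice for the stone channel reaches 0.5 within 30 epochs
  dices <- vapply(val_frames, function(f) {
    pm <- predict_mask(fit$model, f$image)
    dice_coefficient(pm$stone_mask, f$stone_mask)
  }, numeric(1))
  expect_gte(mean(dices), 0.5)

  # inference is deterministic
  pm1 <- predict_mask(fit$model, val_frames[[1]]$image)
  pm2 <- predict_mask(fit$model, val_frames[[1]]$image)
  expect_identical(pm1, pm2)

  # a pure-background frame yields an (almost) empty stone mask
  blank <- withr::with_seed(99, matrix(30 * rgamma(32 * 32, 8, 8), 32, 32))
  pm_blank <- predict_mask(fit$model, blank)
  expect_lt(sum(pm_blank$stone_mask), 5)

  # predicted stone centroid lands within the stone axes of the true
  # centroid on at least 80% of held-out frames
  test_frames <- pick(co[[4]], seq(2, 60, 3))
  centroid <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
  }
  hits <- vapply(test_frames, function(f) {
    pm <- predict_mask(fit$model, f$image)
    if (sum(pm$stone_mask) == 0) return(FALSE)
    d <- abs(centroid(pm$stone_mask) - centroid(f$stone_mask))
    all(d <= co[[4]]$config$stone_axes)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate training configurations behave as specified", {
  expect_error(train_config(max_epochs = 1, patience = 1), "patience")
  co <- simulate_cohort(3, small_sim_config(duration = 2), seed = 31)
  fr <- lapply(co[[1]]$frames[1:3], function(f)
    list(image = f$image, stone_mask = f$stone_mask,
         kidney_mask = f$kidney_mask))
  model <- build_unet(unet_config(2, 2, 32), seed = 31)
  expect_error(train_unet(model, list(), fr, train_config(2, patience = 0)),
               "empty training set")
  # patience 0, max_epochs 1: exactly one epoch, its weights returned
  fit <- train_unet(model, fr, fr[1],
                    train_config(max_epochs = 1, patience = 0, seed = 31))
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$best_epoch, 1L)

  # training is reproducible under identical seeds
  fit2 <- train_unet(model, fr, fr[1],
                     train_config(max_epochs = 1, patience = 0, seed = 31))
  expect_identical(fit$model$params, fit2$model$params)
})
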