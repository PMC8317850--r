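#' Training configuration
#'
#' @param max_epochs Maximum number of passes over the training set.
#' @param learning_rate Adam step size.
#' @param batch_size Images per gradient step (gradients are averaged).
#' @param patience Epochs of non-improving validation loss tolerated before
#'   training stops early; must be smaller than `max_epochs`. The returned
#'   weights always come from the epoch with the minimum validation loss,
#'   the optimal stopping point on the validation curve.
#' @param pos_weight Length-2 positive-class weights (stone, kidney) of the
#'   per-pixel binary cross-entropy. The stone occupies well under 1% of
#'   the pixels, so an unweighted loss lets the stone channel stay
#'   under-confident; weighting stone pixels (default 8) keeps detections
#'   above the 0.5 decision threshold without hurting the kidney channel.
#' @param seed Integer seed controlling shuffling (weight initialisation is
#'   seeded separately in [build_unet()]).
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 30L, learning_rate = 1e-3,
                         batch_size = 8L, patience = 5L,
                         pos_weight = c(8, 1), seed = 1L) {
  max_epochs <- as.integer(max_epochs); patience <- as.integer(patience)
  if (max_epochs < 1L || batch_size < 1L || learning_rate <= 0)
    stop("max_epochs, batch_size and learning_rate must be positive")
  if (patience < 0L || patience >= max_epochs)
    stop("patience must satisfy 0 <= patience < max_epochs")
  if (length(pos_weight) != 2L || any(pos_weight <= 0))
    stop("pos_weight must be two positive values (stone, kidney)")
  structure(list(max_epochs = max_epochs, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), patience = patience,
                 pos_weight = as.numeric(pos_weight),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Leave-one-patient-out cross-validation plan
#'
#' Builds one fold per patient. In each fold one patient is held out for
#' validation (early stopping), a second distinct patient is held out as the
#' test set, and the remaining patients form the training set, mirroring the
#' train-on-nine / validate-on-one / test-on-one rotation used for an
#' 11-patient cohort. Across the plan every patient serves as validation
#' exactly once and as test exactly once.
#'
#' @param patient_ids Character vector of at least 3 distinct patient ids.
#' @return A list of folds, each a list with `train`, `val`, `test`.
#' @export
make_cv_splits <- function(patient_ids) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (n < 3L) stop("patient-based cross-validation needs at least 3 patients")
  if (anyDuplicated(patient_ids)) stop("patient_ids must be distinct")
  folds <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L   # test patient: next in rotation
    list(train = patient_ids[-c(i, j)], val = patient_ids[i],
         test = patient_ids[j])
  })
  class(folds) <- "cv_split_plan"
  folds
}

# One Adam update over the full parameter list; state carries m, v, t.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / bc1
      vhat <- state$v[[nm]][[slot]] / bc2
      params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

.zero_like <- function(params)
  lapply(params, function(l) list(W = l$W * 0, b = l$b * 0))

# Mean loss of a set of samples under the current weights (no gradients).
.eval_loss <- function(model, samples, pos_weight) {
  mean(vapply(samples, function(s) {
    z <- unet_forward(model, s$x)$logits
    bce_logits(z, s$y, pos_weight)$loss
  }, numeric(1)))
}

# Coerce a frame (matrix in [0,255] or [0,1]) + masks into a training sample
# at the network input size.
.as_sample <- function(image, stone_mask, kidney_mask, size) {
  img <- image
  if (max(img) > 1) img <- img / 255
  if (!all(dim(img) == c(size, size))) {
    img <- EBImage::resize(img, w = size, h = size)
    stone_mask <- round(EBImage::resize(stone_mask, w = size, h = size,
                                        filter = "none"))
    kidney_mask <- round(EBImage::resize(kidney_mask, w = size, h = size,
                                         filter = "none"))
  }
  list(x = array(img, c(size, size, 1L)),
       y = array(c(stone_mask, kidney_mask), c(size, size, 2L)))
}

#' Train a U-Net with early stopping
#'
#' Minimises per-pixel binary cross-entropy over the two sigmoid output
#' channels with the Adam optimizer. The validation loss is evaluated after
#' every epoch; training stops once it has failed to improve for more than
#' `patience` consecutive epochs, and the returned model carries the weights
#' of the epoch with minimum validation loss (early stopping at the lowest
#' point of the validation curve, guarding against overfitting).
#'
#' @param model A `unet_model` from [build_unet()].
#' @param train_frames,val_frames Lists of frames, each a list with `image`
#'   (grayscale matrix), `stone_mask` and `kidney_mask` (0/1 matrices).
#'   Train and validation sets must come from disjoint patients; this
#'   function trusts the split plan and does not re-check identities.
#' @param config A [train_config()].
#' @return A list of class `unet_fit` with elements `model` (best weights),
#'   `history` (data.frame: epoch, train_loss, val_loss) and `best_epoch`.
#' @export
train_unet <- function(model, train_frames, val_frames, config) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(train_frames) == 0L) stop("empty training set")
  if (length(val_frames) == 0L) stop("empty validation set")
  size <- model$config$input_size
  tr <- lapply(train_frames, function(f)
    .as_sample(f$image, f$stone_mask, f$kidney_mask, size))
  va <- lapply(val_frames, function(f)
    .as_sample(f$image, f$stone_mask, f$kidney_mask, size))

  params <- model$params
  state <- list(m = .zero_like(params), v = .zero_like(params), t = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(tr))
      epoch_losses <- numeric(0)
      for (start in seq(1L, length(tr), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(tr))]
        gacc <- NULL; lacc <- 0
        for (k in idx) {
          model$params <- params
          fw <- unet_forward(model, tr[[k]]$x, keep_cache = TRUE)
          lz <- bce_logits(fw$logits, tr[[k]]$y, config$pos_weight)
          g <- unet_backward(model, fw, lz$dz)
          lacc <- lacc + lz$loss
          gacc <- if (is.null(gacc)) g else mapply(function(a, b)
            list(W = a$W + b$W, b = a$b + b$b), gacc, g, SIMPLIFY = FALSE)
        }
        nb <- length(idx)
        gacc <- lapply(gacc, function(l) list(W = l$W / nb, b = l$b / nb))
        upd <- .adam_step(params, gacc, state, config$learning_rate)
        params <- upd$params; state <- upd$state
        epoch_losses <- c(epoch_losses, lacc / nb)
      }
      model$params <- params
      vloss <- .eval_loss(model, va, config$pos_weight)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(epoch_losses),
                                           val_loss = vloss))
      if (vloss < best$loss)
        best <- list(loss = vloss, params = params, epoch = epoch)
      if (epoch - best$epoch > config$patience) break
    }
  })
  model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch),
            class = "unet_fit")
}

#' Soft Dice coefficient between a predicted and a reference binary mask
#'
#' @param pred,truth 0/1 matrices of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(pred, truth) {
  a <- sum(pred); b <- sum(truth)
  if (a + b == 0) return(1)
  2 * sum(pred * truth) / (a + b)
}

#' Write a loss history to CSV
#'
#' @param fit A `unet_fit`.
#' @param path Output CSV path (columns epoch, train_loss, val_loss).
#' @export
write_loss_history <- function(fit, path) {
  stopifnot(inherits(fit, "unet_fit"))
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
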