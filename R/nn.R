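# Minimal dense neural network in base R matrix code: three fully connected
# layers (sigmoid activations after the first two), dropout between layers,
# softmax cross-entropy loss, and a decoupled-weight-decay Adam optimizer.
# Written by hand because the sparse-input classifier and its training
# procedure are the core method of this package.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model architecture specification
#'
#' Three fully connected layers; the first two (256 and 128 units by
#' default) are followed by sigmoid activations, the last is linear with one
#' unit per class. Dropout is applied between layers during training.
#'
#' @param n_in Input size = probe-universe cardinality (428,643 for the
#'   450K-intersected reference setting).
#' @param n_out Number of classes (91 general, 30 brainstem-specific).
#' @param hidden Hidden layer widths.
#' @param dropout Dropout rate in \[0,1).
#' @return A `model_spec` list.
#' @export
model_spec <- function(n_in, n_out, hidden = c(256L, 128L), dropout = 0.5) {
  stopifnot(n_in >= 1, n_out >= 1, all(hidden >= 1))
  assert_scalar_number(dropout, "dropout", 0, 1 - 1e-12)
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 hidden = as.integer(hidden), dropout = dropout),
            class = "model_spec")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize a model
#'
#' Reproducible Glorot-uniform weight initialization; the calibration
#' temperature starts at 1 (uncalibrated).
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @param labels Optional class label order (length `n_out`).
#' @param taxonomy Optional `class_taxonomy` carried with the model.
#' @return A `model_state` list: `W`, `b`, `temperature`, `labels`,
#'   `taxonomy`, `spec`, `provenance`.
#' @export
init_model <- function(spec, seed, labels = NULL, taxonomy = NULL) {
  dims <- c(spec$n_in, spec$hidden, spec$n_out)
  ws <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(i)
    glorot(dims[i], dims[i + 1L])))
  bs <- lapply(seq_len(length(dims) - 1L), function(i) numeric(dims[i + 1L]))
  if (is.null(labels)) labels <- paste0("class_", seq_len(spec$n_out))
  if (length(labels) != spec$n_out) stopf("labels length must equal n_out")
  structure(list(W = ws, b = bs, temperature = 1, labels = labels,
                 taxonomy = taxonomy, spec = spec,
                 provenance = list(init_seed = seed)),
            class = "model_state")
}

# Forward pass. X: n x n_in. When training, dropout masks are drawn from the
# current RNG state and activations are scaled (inverted dropout).
nn_forward <- function(model, X, training = FALSE) {
  p <- model$spec$dropout
  H1 <- sigmoid(sweep(X %*% model$W[[1L]], 2L, model$b[[1L]], "+"))
  if (training && p > 0) {
    M1 <- matrix(stats::runif(length(H1)) >= p, nrow(H1)) / (1 - p)
    H1 <- H1 * M1
  } else M1 <- NULL
  H2 <- sigmoid(sweep(H1 %*% model$W[[2L]], 2L, model$b[[2L]], "+"))
  if (training && p > 0) {
    M2 <- matrix(stats::runif(length(H2)) >= p, nrow(H2)) / (1 - p)
    H2 <- H2 * M2
  } else M2 <- NULL
  logits <- sweep(H2 %*% model$W[[3L]], 2L, model$b[[3L]], "+")
  list(logits = logits, X = X, H1 = H1, H2 = H2, M1 = M1, M2 = M2)
}

#' Uncalibrated logits for a batch of encoded inputs
#'
#' @param model A `model_state`.
#' @param X Matrix (n x input size) of encoded runs (or a single vector).
#' @return n x n_classes logit matrix (dropout disabled).
#' @export
predict_logits <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$spec$n_in)
    stopf("input has %d columns, model expects %d", ncol(X), model$spec$n_in)
  nn_forward(model, X, training = FALSE)$logits
}

#' Calibrated class scores
#'
#' Softmax of the logits divided by the model's calibration temperature.
#' Rows sum to 1; temperature never changes the argmax.
#'
#' @inheritParams predict_logits
#' @return n x n_classes matrix of scores, columns named by class label.
#' @export
predict_scores <- function(model, X) {
  s <- softmax_rows(predict_logits(model, X) / model$temperature)
  colnames(s) <- model$labels
  s
}

# Mean cross-entropy of softmax(logits) against integer labels (1-based),
# with uniform class weights.
cross_entropy <- function(logits, y) {
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_along(y), y)])
}

# Backward pass for softmax cross-entropy; returns gradients matching W/b.
nn_backward <- function(model, fwd, y) {
  n <- nrow(fwd$logits)
  P <- softmax_rows(fwd$logits)
  P[cbind(seq_len(n), y)] <- P[cbind(seq_len(n), y)] - 1
  dL <- P / n
  gW3 <- crossprod(fwd$H2, dL); gb3 <- colSums(dL)
  dH2 <- tcrossprod(dL, model$W[[3L]])
  if (!is.null(fwd$M2)) dH2 <- dH2 * fwd$M2
  dZ2 <- dH2 * fwd$H2 * (1 - fwd$H2)
  gW2 <- crossprod(fwd$H1, dZ2); gb2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, model$W[[2L]])
  if (!is.null(fwd$M1)) dH1 <- dH1 * fwd$M1
  dZ1 <- dH1 * fwd$H1 * (1 - fwd$H1)
  gW1 <- crossprod(fwd$X, dZ1); gb1 <- colSums(dZ1)
  list(W = list(gW1, gW2, gW3), b = list(gb1, gb2, gb3))
}

adamw_init <- function(model) {
  list(t = 0L,
       mW = lapply(model$W, function(w) w * 0), vW = lapply(model$W, function(w) w * 0),
       mb = lapply(model$b, function(b) b * 0), vb = lapply(model$b, function(b) b * 0))
}

# One decoupled-weight-decay Adam step (beta1 0.9, beta2 0.999, eps 1e-8,
# lambda 0.0005 by default). Weight decay is not applied to biases.
adamw_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 5e-4) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(model$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$W[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    model$W[[i]] <- model$W[[i]] -
      lr * ((state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps) +
              weight_decay * model$W[[i]])
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    model$b[[i]] <- model$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(model = model, state = state)
}

#' Learning rate at a given training batch and epoch
#'
#' Piecewise schedule: linear warmup from `lr_start` to `lr_peak` over the
#' first `warmup_batches` batches, then cosine decay (in epochs) to
#' `lr_floor` at `decay_epochs`, constant `lr_floor` afterwards.
#'
#' @param schedule A [training_schedule()].
#' @param batch Zero-based global batch index.
#' @param epoch Zero-based epoch index.
#' @return Learning rate.
#' @export
lr_at <- function(schedule, batch, epoch) {
  stopifnot(batch >= 0, epoch >= 0)
  if (isTRUE(schedule$constant_lr)) return(schedule$lr_floor)
  if (batch < schedule$warmup_batches)
    return(schedule$lr_start +
             (schedule$lr_peak - schedule$lr_start) * batch / schedule$warmup_batches)
  if (epoch >= schedule$decay_epochs) return(schedule$lr_floor)
  schedule$lr_floor + (schedule$lr_peak - schedule$lr_floor) *
    0.5 * (1 + cos(pi * epoch / schedule$decay_epochs))
}

#' Training schedule constants
#'
#' Defaults are the reference-setting values: batch size 256, 3,000 epochs
#' per stage, warmup from 1e-5 to 1e-3 over 1,000 batches, cosine decay to
#' 1e-4 at epoch 1,000, checkpoint/validation every 2,000 training batches on
#' 50 validation batches, AdamW with beta1 0.9, beta2 0.999, eps 1e-8 and
#' weight decay 0.0005. Scale these down for desk-sized experiments.
#'
#' @param batch_size Samples per batch.
#' @param epochs Epochs for the stage being run.
#' @param lr_start,lr_peak,lr_floor Warmup start, peak, and floor rates.
#' @param warmup_batches Batches of linear warmup.
#' @param decay_epochs Epoch at which the cosine decay reaches `lr_floor`.
#' @param checkpoint_every Checkpoint/validation cadence in training batches.
#' @param val_batches Validation batches evaluated per checkpoint.
#' @param beta1,beta2,eps,weight_decay Optimizer constants.
#' @param constant_lr If TRUE the whole stage runs at `lr_floor` (the
#'   fine-tuning stage trains at a constant 1e-4).
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(batch_size = 256L, epochs = 3000L,
                              lr_start = 1e-5, lr_peak = 1e-3, lr_floor = 1e-4,
                              warmup_batches = 1000L, decay_epochs = 1000L,
                              checkpoint_every = 2000L, val_batches = 50L,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                              weight_decay = 5e-4, constant_lr = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 1, checkpoint_every >= 1, val_batches >= 1)
  structure(as.list(environment()), class = "training_schedule")
}
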