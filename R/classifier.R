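# Curriculum training of the sparse-methylation classifier: input encoding,
# adaptive class-by-sparsity sample balancing, checkpoint selection, class
# merging, ensembling and location-specific transfer.

#' Encode a run or profile as a dense input vector
#'
#' One slot per manifest probe in manifest order. Default ("signed")
#' encoding: methylated -> +1, unmethylated -> -1, uncovered -> 0. The
#' alternative "masked" encoding stacks a 0/1 call channel and a 0/1
#' coverage-mask channel (input size doubles).
#'
#' @param run A `simulated_run`, or a named binary call vector.
#' @param manifest A `probe_manifest`.
#' @param encoding `"signed"` or `"masked"`.
#' @return Numeric vector of length `nrow(manifest)` (or twice that).
#' @export
encode_run <- function(run, manifest, encoding = c("signed", "masked")) {
  encoding <- match.arg(encoding)
  calls <- if (inherits(run, "simulated_run")) run$calls else run
  i <- match(names(calls), manifest$probe_id)
  if (anyNA(i))
    stopf("run contains probe '%s' not in the manifest",
          names(calls)[which(is.na(i))[1L]])
  n <- nrow(manifest)
  if (encoding == "signed") {
    x <- numeric(n)
    x[i] <- ifelse(calls == 1L, 1, -1)
    x
  } else {
    x <- numeric(2L * n)
    x[i] <- as.numeric(calls)
    x[n + i] <- 1
    x
  }
}

#' Decode a signed input vector back to a call vector
#'
#' @param x Signed-encoded vector (length `nrow(manifest)`).
#' @param manifest A `probe_manifest`.
#' @return Named binary call vector over the covered probes.
#' @export
decode_run <- function(x, manifest) {
  cov <- which(x != 0)
  stats::setNames(as.integer(x[cov] > 0), manifest$probe_id[cov])
}

#' Per-epoch sample count for a training cohort
#'
#' One epoch is defined as the number of reference samples in the most
#' abundant class multiplied by the number of output classes (13,013 in the
#' reference setting: largest class 143 samples x 91 classes).
#'
#' @param labels Character/factor vector of class labels (one per training
#'   sample).
#' @param n_classes Number of output classes; defaults to the number of
#'   distinct labels.
#' @return Integer epoch size.
#' @export
epoch_size <- function(labels, n_classes = length(unique(labels))) {
  if (!length(labels)) stopf("empty cohort")
  as.integer(max(table(labels)) * n_classes)
}

#' Initialize a balance state
#'
#' Uniform allocation of the per-epoch budget over (sparsity level, class)
#' cells, integerized by largest-remainder rounding with a floor of 1.
#'
#' @param n_levels,n_classes Grid dimensions.
#' @param total Per-epoch sample budget (kept constant across epochs).
#' @param correction Additive constant applied to errors so no cell is ever
#'   starved; default 0.3.
#' @return A `balance_state` list with an `alloc` (levels x classes) matrix.
#' @export
balance_state <- function(n_levels, n_classes, total, correction = 0.3) {
  # the >= 1 floor applies whenever the budget covers the grid (it always
  # does at reference scale: 13,013 >= 12 x 91); tiny desk cohorts fall
  # back to a 0 floor rather than overdrawing the epoch budget
  floor_min <- if (total >= n_levels * n_classes) 1L else 0L
  alloc <- matrix(largest_remainder(rep(1, n_levels * n_classes), total,
                                    floor_min = floor_min),
                  n_levels, n_classes)
  structure(list(alloc = alloc, total = as.integer(total),
                 correction = correction, floor_min = floor_min, error = NULL),
            class = "balance_state")
}

#' Update sample allocations from per-cell errors
#'
#' Allocations for the next epoch are proportional to (error + correction),
#' normalized to the fixed per-epoch total and integerized by
#' largest-remainder rounding with every cell kept >= 1 (whenever the epoch
#' budget covers the level-by-class grid, as it always does at reference
#' scale).
#'
#' @param state A [balance_state()].
#' @param error Matrix (levels x classes) of error estimates in \[0,1\]
#'   (1 - per-cell top-1 accuracy on the just-finished epoch).
#' @return Updated `balance_state`.
#' @export
update_balance <- function(state, error) {
  if (!all(dim(error) == dim(state$alloc)))
    stopf("error matrix must be %d x %d", nrow(state$alloc), ncol(state$alloc))
  if (any(error < 0 | error > 1, na.rm = TRUE)) stopf("errors must be in [0,1]")
  error[is.na(error)] <- 1  # unvisited cells count as fully wrong
  w <- error + state$correction
  state$alloc <- matrix(largest_remainder(as.numeric(w), state$total,
                                          floor_min = state$floor_min %||% 1L),
                        nrow(error), ncol(error))
  state$error <- error
  state
}

# Simulate one training/validation example directly into encoded (idx, val)
# form; same two-substream seed policy as simulate_run but skipping the
# named-vector surface for speed.
.sim_encode <- function(state_vec, manifest, genome, length_model, n_reads,
                        noise_rate, seed) {
  res <- with_seed(derive_seed(seed, 1L),
                   .sim_calls(list(state_vec), manifest, genome, length_model,
                              n_reads))
  calls <- res$calls
  if (noise_rate > 0 && length(calls)) {
    flip <- with_seed(derive_seed(seed, 2L),
                      stats::runif(length(calls)) < noise_rate)
    calls[flip] <- 1L - calls[flip]
  }
  list(idx = res$idx, val = ifelse(calls == 1L, 1, -1))
}

# Deterministic per-role seed streams derived from a submodel seed.
seed_stream <- function(role, submodel_seed) {
  rng <- seed_policy()[[role]]
  span <- rng[2L] - rng[1L] + 1L
  offset <- floor(derive_seed(submodel_seed, 7L)) %% span
  k <- 0L
  function() {
    k <<- k + 1L
    as.integer(rng[1L] + (offset + k) %% span)
  }
}

#' Train one submodel with the sparsity curriculum
#'
#' Two training folds supply the source profiles; simulations are drawn
#' fresh every epoch with training-range seeds, classes upsampled to
#' equality and the (level x class) allocation re-balanced from the previous
#' epoch's training error. The pretraining stage uses the full sparsity
#' range; fine-tuning restricts to the sparse (difficult) sub-range and a
#' constant learning rate. Checkpoints (weights + validation loss +
#' macro-averaged sensitivity) are recorded at a fixed cadence on
#' validation-fold simulations with validation-range seeds.
#'
#' @param cohort A `reference_cohort` (see [make_cohort()]) or any list with
#'   `profiles` (named list of binary profiles), `labels` (named), `taxonomy`,
#'   `manifest`, `genome`.
#' @param folds A `fold_assignment` from [stratified_folds()].
#' @param rotation Rotation index in `0:(k-1)`; fold `rotation` is the test
#'   fold, the next fold is validation, the rest train.
#' @param schedule A [training_schedule()].
#' @param stage `"pretrain"` or `"finetune"`.
#' @param model Starting `model_state` (required for `"finetune"`).
#' @param config A [sim_config()]; its depth levels define the curriculum
#'   grid (fine-tuning keeps levels <= `finetune_max`).
#' @param seed Submodel seed controlling initialization, shuffling, dropout
#'   and the derived simulation-seed streams.
#' @param finetune_max Upper sparsity bound of the fine-tuning stage.
#' @param verbose Print per-epoch progress.
#' @return List: `model` (best checkpoint), `final_model`, `history`
#'   (checkpoint table), `balance_trace`, `loss_by_epoch`.
#' @export
train_submodel <- function(cohort, folds, rotation, schedule, stage = c("pretrain", "finetune"),
                           model = NULL, config = sim_config(), seed = 1L,
                           finetune_max = 0.063, verbose = FALSE) {
  stage <- match.arg(stage)
  if (stage == "finetune" && is.null(model))
    stopf("fine-tuning needs a pretrained model")
  roles <- fold_roles(folds, rotation)
  train_samples <- names(folds$fold)[folds$fold %in% roles$train]
  val_samples <- names(folds$fold)[folds$fold == roles$validation]
  taxonomy <- cohort$taxonomy
  classes <- taxonomy$classes
  labels <- cohort$labels
  levels <- config$depth_levels
  if (stage == "finetune") levels <- levels[levels <= finetune_max]
  if (!length(levels)) stopf("no depth levels in the fine-tuning range")
  manifest <- cohort$manifest; genome <- cohort$genome
  n_probes <- nrow(manifest)
  n_reads_lvl <- vapply(levels, reads_for_depth, integer(1), genome = genome,
                        length_model = config$length_model)

  aligned <- lapply(cohort$profiles, align_profile, manifest = manifest)
  by_class <- split(train_samples, factor(labels[train_samples], levels = classes))
  if (any(!lengths(by_class)))
    stopf("class '%s' has no training samples in rotation %d",
          classes[which(!lengths(by_class))[1L]], rotation)
  val_by_class <- split(val_samples, factor(labels[val_samples], levels = classes))
  val_by_class <- val_by_class[lengths(val_by_class) > 0L]

  total <- epoch_size(labels[train_samples], length(classes))
  bal <- balance_state(length(levels), length(classes), total)
  train_seed <- seed_stream("training", seed)
  val_seed <- seed_stream("validation", seed)

  if (is.null(model))
    model <- init_model(model_spec(n_probes, length(classes)),
                        seed = floor(derive_seed(seed, 11L)) %% 2147483647,
                        labels = classes, taxonomy = taxonomy)
  opt <- adamw_init(model)
  history <- list()
  balance_trace <- list(bal$alloc)
  loss_by_epoch <- numeric(schedule$epochs)
  global_batch <- 0L

  make_validation_batch <- function(n) {
    X <- matrix(0, n, n_probes)
    cls <- sample(names(val_by_class), n, replace = TRUE)
    y <- integer(n)
    for (i in seq_len(n)) {
      smp <- sample(val_by_class[[cls[i]]], 1L)
      lvl <- sample.int(length(levels), 1L)
      enc <- .sim_encode(aligned[[smp]], manifest, genome, config$length_model,
                         n_reads_lvl[lvl], config$noise_rate, val_seed())
      X[i, enc$idx] <- enc$val
      y[i] <- match(cls[i], classes)
    }
    list(X = X, y = y)
  }

  checkpoint <- function() {
    vloss <- 0; conf <- matrix(0, length(classes), 2L)  # TP, FN per class
    for (b in seq_len(schedule$val_batches)) {
      vb <- make_validation_batch(schedule$batch_size)
      lg <- nn_forward(model, vb$X, training = FALSE)$logits
      vloss <- vloss + cross_entropy(lg, vb$y)
      pred <- max.col(lg, ties.method = "first")
      for (cl in unique(vb$y)) {
        conf[cl, 1L] <- conf[cl, 1L] + sum(pred == cl & vb$y == cl)
        conf[cl, 2L] <- conf[cl, 2L] + sum(pred != cl & vb$y == cl)
      }
    }
    seen <- rowSums(conf) > 0
    sens <- mean(conf[seen, 1L] / rowSums(conf)[seen])
    history[[length(history) + 1L]] <<- list(
      W = model$W, b = model$b, step = global_batch,
      val_loss = vloss / schedule$val_batches, sensitivity = sens)
  }

  set.seed(floor(derive_seed(seed, 13L)) %% 2147483647)  # shuffle + dropout stream
  for (epoch in seq_len(schedule$epochs) - 1L) {
    alloc <- bal$alloc
    n_epoch <- sum(alloc)
    X <- matrix(0, n_epoch, n_probes)
    y <- integer(n_epoch); t_id <- integer(n_epoch)
    row <- 0L
    for (ci in seq_along(classes)) {
      pool <- by_class[[ci]]
      for (ti in seq_along(levels)) {
        ns <- alloc[ti, ci]
        if (ns == 0L) next
        srcs <- pool[(sample.int(length(pool), 1L) + seq_len(ns) - 2L) %% length(pool) + 1L]
        for (s in srcs) {
          row <- row + 1L
          enc <- .sim_encode(aligned[[s]], manifest, genome, config$length_model,
                             n_reads_lvl[ti], config$noise_rate, train_seed())
          X[row, enc$idx] <- enc$val
          y[row] <- ci; t_id[row] <- ti
        }
      }
    }
    ord <- sample.int(n_epoch)
    correct <- logical(n_epoch)
    eloss <- 0; nb <- 0L
    for (b0 in seq(1L, n_epoch, by = schedule$batch_size)) {
      rows <- ord[b0:min(b0 + schedule$batch_size - 1L, n_epoch)]
      fwd <- nn_forward(model, X[rows, , drop = FALSE], training = TRUE)
      eloss <- eloss + cross_entropy(fwd$logits, y[rows]); nb <- nb + 1L
      grads <- nn_backward(model, fwd, y[rows])
      lr <- lr_at(schedule, global_batch, epoch)
      upd <- adamw_step(model, grads, opt, lr,
                        beta1 = schedule$beta1, beta2 = schedule$beta2,
                        eps = schedule$eps, weight_decay = schedule$weight_decay)
      model <- upd$model; opt <- upd$state
      correct[rows] <- max.col(fwd$logits, ties.method = "first") == y[rows]
      global_batch <- global_batch + 1L
      if (global_batch %% schedule$checkpoint_every == 0L) checkpoint()
    }
    loss_by_epoch[epoch + 1L] <- eloss / nb
    err <- matrix(NA_real_, length(levels), length(classes))
    agg <- tapply(correct, list(factor(t_id, seq_along(levels)),
                                factor(y, seq_along(classes))), mean)
    err[] <- 1 - agg
    bal <- update_balance(bal, err)
    balance_trace[[length(balance_trace) + 1L]] <- bal$alloc
    if (verbose)
      message(sprintf("[%s] epoch %d/%d loss %.4f", stage, epoch + 1L,
                      schedule$epochs, loss_by_epoch[epoch + 1L]))
  }
  checkpoint()  # final state always eligible
  best <- select_best_checkpoint(history)
  best_model <- model
  best_model$W <- best$W; best_model$b <- best$b
  best_model$provenance <- c(model$provenance,
                             list(stage = stage, rotation = rotation,
                                  submodel_seed = seed, checkpoint_step = best$step))
  list(model = best_model, final_model = model,
       history = data.table::rbindlist(lapply(history, function(h)
         data.table::data.table(step = h$step, val_loss = h$val_loss,
                                sensitivity = h$sensitivity))),
       checkpoints = history,
       balance_trace = balance_trace, loss_by_epoch = loss_by_epoch)
}

#' Select the best checkpoint
#'
#' Lowest validation loss; ties broken by higher sensitivity, then by later
#' training step.
#'
#' @param history List of checkpoints (each with `val_loss`, `sensitivity`,
#'   `step`).
#' @return The winning checkpoint element.
#' @export
select_best_checkpoint <- function(history) {
  if (!length(history)) stopf("empty checkpoint history")
  loss <- vapply(history, `[[`, numeric(1), "val_loss")
  sens <- vapply(history, `[[`, numeric(1), "sensitivity")
  step <- vapply(history, `[[`, numeric(1), "step")
  ord <- order(loss, -sens, -step)
  history[[ord[1L]]]
}

#' Sum scores over merge groups
#'
#' Each merge group in the taxonomy is replaced by a single entry equal to
#' the group sum (e.g. the two pilocytic astrocytoma classes); the total
#' score mass is conserved.
#'
#' @param scores Named score vector (or 1-row matrix) over subclass labels.
#' @param taxonomy A `class_taxonomy`.
#' @return Named score vector over [merged_labels()].
#' @export
merge_scores <- function(scores, taxonomy) {
  if (is.matrix(scores)) scores <- scores[1L, ]
  if (!length(taxonomy$merge_groups)) return(scores)
  group_of <- stats::setNames(rep(names(scores), 1L), names(scores))
  for (g in names(taxonomy$merge_groups))
    group_of[taxonomy$merge_groups[[g]]] <- g
  out <- c(tapply(scores, group_of[names(scores)], sum))
  out[merged_labels(taxonomy)]
}

#' Control flags on the post-merge label set
#'
#' A merged class is a control class iff all of its members are controls.
#'
#' @param taxonomy A `class_taxonomy`.
#' @return Named logical vector over [merged_labels()].
#' @export
merged_control_flags <- function(taxonomy) {
  ctrl <- stats::setNames(taxonomy$control, taxonomy$classes)
  out <- stats::setNames(logical(0), character(0))
  for (lab in merged_labels(taxonomy)) {
    out[lab] <- if (lab %in% names(taxonomy$merge_groups))
      all(ctrl[taxonomy$merge_groups[[lab]]]) else ctrl[[lab]]
  }
  out
}

#' Ensemble prediction: most confident submodel wins
#'
#' Each submodel's calibrated, merge-summed scores are computed; the model
#' whose maximum score is largest supplies the final score vector (ties go
#' to the lowest model index).
#'
#' @param models List of `model_state` sharing input size and taxonomy.
#' @param x Encoded input vector.
#' @param taxonomy Optional `class_taxonomy` (defaults to the models').
#' @return List: `scores` (named, merged), `model_id`, `per_model_max`.
#' @export
ensemble_predict <- function(models, x, taxonomy = NULL) {
  if (!length(models)) stopf("empty ensemble")
  n_in <- vapply(models, function(m) m$spec$n_in, integer(1))
  if (length(unique(n_in)) != 1L) stopf("models have heterogeneous input sizes")
  if (is.null(taxonomy)) taxonomy <- models[[1L]]$taxonomy
  per <- lapply(models, function(m) merge_scores(predict_scores(m, x)[1L, ], taxonomy))
  maxima <- vapply(per, max, numeric(1))
  id <- which.max(maxima)  # first max wins ties
  list(scores = per[[id]], model_id = id, per_model_max = maxima)
}

#' Transfer a trained model to a new (location-specific) head
#'
#' The first two layers are copied; the final layer is re-initialized at the
#' new class count (e.g. the 30-class brainstem head, with irrelevant
#' classes collapsed into one). The returned model is uncalibrated (T = 1).
#'
#' @param model A trained `model_state`.
#' @param new_taxonomy The collapsed `class_taxonomy`.
#' @param seed Seed for the new head's initialization.
#' @return A `model_state` with the new output dimensionality.
#' @export
specialize_model <- function(model, new_taxonomy, seed = 1L) {
  n_out <- length(new_taxonomy$classes)
  spec <- model$spec; spec$n_out <- as.integer(n_out)
  n_h <- tail(spec$hidden, 1L)
  model$W[[3L]] <- with_seed(seed, glorot(n_h, n_out))
  model$b[[3L]] <- numeric(n_out)
  model$spec <- spec
  model$labels <- new_taxonomy$classes
  model$taxonomy <- new_taxonomy
  model$temperature <- 1
  model$provenance$specialized_seed <- seed
  model
}

#' Save / load a model archive
#'
#' Weights and metadata in one RDS archive with a JSON provenance sidecar
#' (labels, temperature, provenance, taxonomy hash).
#'
#' @param model A `model_state`.
#' @param path Archive path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(labels = model$labels, temperature = model$temperature,
               input_size = model$spec$n_in,
               taxonomy_hash = taxonomy_hash(model$taxonomy),
               provenance = model$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

taxonomy_hash <- function(taxonomy) {
  if (is.null(taxonomy)) return(NA_character_)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(taxonomy), auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}
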