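# High-level cross-validation pipeline: train the four submodels with the
# two-stage curriculum, temperature-calibrate each on its validation fold,
# and evaluate on the held-out test folds.

#' Simulate encoded runs for a set of samples
#'
#' @param cohort A `reference_cohort`.
#' @param samples Sample ids.
#' @param levels Depth levels to draw from (one run per (sample, replicate),
#'   level cycling).
#' @param n_per_sample Replicates per sample.
#' @param config A [sim_config()].
#' @param role Seed role.
#' @param seed Stream seed (role-range seeds are derived deterministically).
#' @return List: `X` (encoded matrix), `labels`, `sample_id`, `level`.
#' @export
simulate_encoded <- function(cohort, samples, levels, n_per_sample,
                             config = sim_config(), role, seed = 1L) {
  manifest <- cohort$manifest; genome <- cohort$genome
  aligned <- lapply(cohort$profiles[samples], align_profile, manifest = manifest)
  n_reads_lvl <- vapply(levels, reads_for_depth, integer(1), genome = genome,
                        length_model = config$length_model)
  stream <- seed_stream(role, seed)
  n <- length(samples) * n_per_sample
  X <- matrix(0, n, nrow(manifest))
  lab <- character(n); sid <- character(n); lvl <- numeric(n)
  row <- 0L
  for (s in samples) for (r in seq_len(n_per_sample)) {
    row <- row + 1L
    li <- (row - 1L) %% length(levels) + 1L
    enc <- .sim_encode(aligned[[s]], manifest, genome, config$length_model,
                       n_reads_lvl[li], config$noise_rate, stream())
    X[row, enc$idx] <- enc$val
    lab[row] <- cohort$labels[[s]]; sid[row] <- s; lvl[row] <- levels[li]
  }
  list(X = X, labels = lab, sample_id = sid, level = lvl)
}

#' Calibrate a submodel on its validation fold
#'
#' Validation-fold samples are simulated across the full sparsity range
#' (pooled into one fit, one scalar per submodel) with validation-range
#' seeds, and the temperature is fitted on the resulting logits.
#'
#' @param model A trained `model_state`.
#' @param cohort,folds,rotation Cross-validation context.
#' @param config A [sim_config()].
#' @param n_per_sample Simulated runs per validation sample.
#' @param seed Stream seed.
#' @return The calibrated model (temperature set).
#' @export
calibrate_submodel <- function(model, cohort, folds, rotation,
                               config = sim_config(), n_per_sample = 12L,
                               seed = 1L) {
  roles <- fold_roles(folds, rotation)
  val_samples <- names(folds$fold)[folds$fold == roles$validation]
  sim <- simulate_encoded(cohort, val_samples, config$depth_levels,
                          n_per_sample, config, role = "validation", seed = seed)
  logits <- predict_logits(model, sim$X)
  y <- match(sim$labels, model$labels)
  calibrate_model(model, logits, y)
}

#' Train the cross-validated submodel ensemble
#'
#' For each rotation: pretrain over the full sparsity range, fine-tune over
#' the sparse sub-range at constant learning rate, then calibrate on the
#' validation fold.
#'
#' @param cohort A `reference_cohort`.
#' @param folds A [stratified_folds()] assignment (built from the cohort
#'   labels if `NULL`).
#' @param rotations Rotations to train (default all).
#' @param schedule_pre,schedule_fine [training_schedule()]s for the two
#'   stages (`schedule_fine = NULL` skips fine-tuning).
#' @param config A [sim_config()].
#' @param seed Base seed; each rotation derives its own.
#' @param calibrate Temperature-calibrate each submodel.
#' @param n_cal_per_sample Calibration simulations per validation sample.
#' @param verbose Print progress.
#' @return List: `models` (one calibrated `model_state` per rotation),
#'   `folds`, `fits` (full training results).
#' @export
train_ensemble <- function(cohort, folds = NULL, rotations = NULL,
                           schedule_pre, schedule_fine = NULL,
                           config = sim_config(), seed = 1L, calibrate = TRUE,
                           n_cal_per_sample = 12L, verbose = FALSE) {
  if (is.null(folds)) folds <- stratified_folds(cohort$labels, k = 4L, seed = seed)
  if (is.null(rotations)) rotations <- 0:(folds$k - 1L)
  models <- list(); fits <- list()
  for (rot in rotations) {
    rot_seed <- floor(derive_seed(seed, 100L + rot)) %% 2147483647
    fit <- train_submodel(cohort, folds, rot, schedule_pre, stage = "pretrain",
                          config = config, seed = rot_seed, verbose = verbose)
    if (!is.null(schedule_fine))
      fit <- train_submodel(cohort, folds, rot, schedule_fine, stage = "finetune",
                            model = fit$model, config = config,
                            seed = rot_seed + 1L, verbose = verbose)
    model <- fit$model
    if (calibrate)
      model <- calibrate_submodel(model, cohort, folds, rot, config,
                                  n_per_sample = n_cal_per_sample,
                                  seed = rot_seed)
    models[[as.character(rot)]] <- model
    fits[[as.character(rot)]] <- fit
  }
  list(models = models, folds = folds, fits = fits)
}

#' Evaluate submodels on their held-out test folds
#'
#' Every sample is classified by the submodel of the rotation in which it
#' sits in the test fold, using test-range seeds; results are pooled across
#' rotations (the cross-validated test-set evaluation).
#'
#' @param ensemble Result of [train_ensemble()].
#' @param cohort A `reference_cohort`.
#' @param depth_level Coverage fraction the test runs are simulated at.
#' @param n_per_sample Runs per test sample.
#' @param config A [sim_config()].
#' @param threshold Confidence cut-off for the outcome tallies.
#' @param seed Stream seed.
#' @return List: `report` (an `eval_report`), `accuracy` (top-1),
#'   `predictions` (data.table: sample, rotation, truth, predicted, score,
#'   outcome).
#' @export
evaluate_heldout <- function(ensemble, cohort, depth_level,
                             n_per_sample = 10L, config = sim_config(),
                             threshold = 0.95, seed = 1L) {
  taxonomy <- cohort$taxonomy
  folds <- ensemble$folds
  cfg <- config; cfg$depth_level <- depth_level; cfg$n_reads <- NULL
  labs <- merged_labels(taxonomy)
  all_scores <- list(); all_truth <- list(); preds <- list()
  for (rot in names(ensemble$models)) {
    model <- ensemble$models[[rot]]
    roles <- fold_roles(folds, as.integer(rot))
    test_samples <- names(folds$fold)[folds$fold == roles$test]
    if (!length(test_samples)) next
    sim <- simulate_encoded(cohort, test_samples, depth_level, n_per_sample,
                            cfg, role = "test",
                            seed = floor(derive_seed(seed, 200L + as.integer(rot))) %% 2147483647)
    sc <- predict_scores(model, sim$X)
    merged <- t(apply(sc, 1L, merge_scores, taxonomy = taxonomy))
    colnames(merged) <- labs
    all_scores[[rot]] <- merged
    all_truth[[rot]] <- sim$labels
    out <- vapply(seq_len(nrow(merged)), function(i) {
      cls <- classify_with_threshold(merged[i, ], taxonomy, threshold)
      paste(cls$outcome, cls$class, sep = ":")
    }, character(1))
    preds[[rot]] <- data.table::data.table(
      sample = sim$sample_id, rotation = as.integer(rot), truth = sim$labels,
      predicted = labs[max.col(merged, ties.method = "first")],
      score = apply(merged, 1L, max), outcome = out)
  }
  scores <- do.call(rbind, all_scores)
  truth <- unlist(all_truth, use.names = FALSE)
  report <- evaluate_scores(scores, truth, taxonomy, threshold)
  list(report = report,
       accuracy = mean(colnames(scores)[max.col(scores, ties.method = "first")] == truth),
       predictions = data.table::rbindlist(preds))
}
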