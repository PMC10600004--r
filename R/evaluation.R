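# Cross-validation folds, F1/TPR/top-k metrics, family aggregation,
# pseudotime, read-order robustness resampling and purity sweeps.

#' Class-stratified fold assignment
#'
#' Splits samples into k folds while keeping class proportions: within each
#' class, fold counts differ by at most one. Classes with fewer than k
#' samples are placed into the folds that currently hold the fewest of that
#' class's samples (so some test folds may lack rare classes; the
#' assignment records this in its `small_classes` attribute).
#'
#' @param labels Named character/factor vector, sample id -> class.
#' @param k Number of folds (default 4).
#' @param seed Seed; the assignment is deterministic given it.
#' @return A `fold_assignment`: list with `fold` (named integer vector in
#'   `0:(k-1)`) and `k`.
#' @export
stratified_folds <- function(labels, k = 4L, seed = 1L) {
  if (k < 2L) stopf("k must be >= 2")
  if (is.null(names(labels))) stopf("labels must be named by sample id")
  fold <- stats::setNames(integer(length(labels)), names(labels))
  with_seed(seed, {
    start <- 0L
    for (cl in unique(labels)) {
      ids <- sample(names(labels)[labels == cl])
      fold[ids] <- (start + seq_along(ids) - 1L) %% k
      start <- (start + length(ids)) %% k  # rotate so remainders spread out
    }
  })
  small <- names(table(labels))[table(labels) < k]
  structure(list(fold = fold, k = as.integer(k), small_classes = small),
            class = "fold_assignment")
}

#' Role map for one cross-validation rotation
#'
#' Fold `rotation` is the test fold, the next fold (mod k) is the
#' validation fold, and the remaining folds train. Rotating through
#' `0:(k-1)` covers every fold as test exactly once.
#'
#' @param folds A `fold_assignment`.
#' @param rotation Integer in `0:(k-1)`.
#' @return List: `test`, `validation`, `train` (fold indices).
#' @export
fold_roles <- function(folds, rotation) {
  k <- folds$k
  if (rotation < 0L || rotation >= k) stopf("rotation must be in 0:%d", k - 1L)
  test <- rotation
  validation <- (rotation + 1L) %% k
  list(test = test, validation = validation,
       train = setdiff(0:(k - 1L), c(test, validation)))
}

#' F1 score and true-positive rate from confusion counts
#'
#' F1 = 2 TP / (2 TP + FP + FN); TPR = TP / (TP + FN). Both return 0 when
#' the denominator is 0.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Value in \[0,1\].
#' @export
f1_score <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  d <- 2 * TP + FP + FN
  ifelse(d == 0, 0, 2 * TP / d)
}

#' @rdname f1_score
#' @export
tpr <- function(TP, FN) {
  stopifnot(TP >= 0, FN >= 0)
  d <- TP + FN
  ifelse(d == 0, 0, TP / d)
}

#' Top-k confusion counts
#'
#' A sample is a TP for its true class if the true class ranks among the k
#' highest scores; otherwise it is an FN for the true class and an FP
#' charged to the top-1 predicted class.
#'
#' @param scores n x n_classes score matrix (columns named by class).
#' @param labels True class labels (character, matching column names).
#' @param k Rank cut-off (1 for top-1, 3 for top-3).
#' @return data.table (class, TP, FP, FN).
#' @export
topk_confusion <- function(scores, labels, k = 1L) {
  stopifnot(k >= 1L, nrow(scores) == length(labels))
  classes <- colnames(scores)
  TP <- FP <- FN <- stats::setNames(integer(length(classes)), classes)
  for (i in seq_len(nrow(scores))) {
    ord <- order(scores[i, ], decreasing = TRUE)
    topk <- classes[ord[seq_len(min(k, length(classes)))]]
    truth <- labels[i]
    if (truth %in% topk) TP[truth] <- TP[truth] + 1L
    else {
      FN[truth] <- FN[truth] + 1L
      FP[classes[ord[1L]]] <- FP[classes[ord[1L]]] + 1L
    }
  }
  data.table::data.table(class = classes, TP = TP, FP = FP, FN = FN)
}

#' Aggregate subclass scores to family level
#'
#' Family score = sum of member-subclass scores; the total is conserved.
#'
#' @param scores Named score vector over subclass labels.
#' @param taxonomy A `class_taxonomy`.
#' @return Named score vector over family labels.
#' @export
family_aggregate <- function(scores, taxonomy) {
  fam <- stats::setNames(taxonomy$families, taxonomy$classes)
  out <- c(tapply(scores, fam[names(scores)], sum))
  out[unique(unname(fam[names(scores)]))]
}

#' Pseudotime lookup table
#'
#' Per-5-minute-interval CpG call counts; the defaults are the median
#' throughput of representative fresh MinION runs (non-cumulative counts
#' for the first twelve 5-min intervals). Cumulative thresholds are
#' derived; sequencing "pseudotime" is read off them, making washed,
#' multiplexed or higher-throughput runs comparable to a fresh single-sample
#' MinION run.
#'
#' @param counts Per-interval (non-cumulative) CpG call counts.
#' @param interval_min Minutes per interval.
#' @return A `pseudotime_table` list with `counts`, `cumulative`,
#'   `interval_min`.
#' @export
pseudotime_table <- function(counts = c(51924, 104073, 124078, 149111, 173504,
                                        194399, 207456, 217193, 232101, 241278,
                                        247600, 258197),
                             interval_min = 5) {
  if (any(counts <= 0)) stopf("interval counts must be > 0")
  structure(list(counts = counts, cumulative = cumsum(counts),
                 interval_min = interval_min),
            class = "pseudotime_table")
}

#' Pseudotime from a cumulative CpG call count
#'
#' Step function: the largest interval whose cumulative threshold is <= the
#' input, times the interval length. Counts beyond the table extrapolate at
#' the final interval's rate and carry attribute `extrapolated = TRUE`.
#'
#' @param cumulative_calls Cumulative number of CpG calls (>= 0).
#' @param table A [pseudotime_table()].
#' @return Minutes of equivalent fresh-flowcell sequencing.
#' @export
pseudotime <- function(cumulative_calls, table = pseudotime_table()) {
  stopifnot(all(cumulative_calls >= 0))
  cum <- table$cumulative
  K <- length(cum)
  iv <- findInterval(cumulative_calls, cum)  # count of thresholds <= input
  mins <- iv * table$interval_min
  over <- cumulative_calls > cum[K]
  if (any(over)) {
    extra <- floor((cumulative_calls[over] - cum[K]) / table$counts[K])
    mins[over] <- (K + extra) * table$interval_min
    attr(mins, "extrapolated") <- TRUE
  }
  mins
}

#' Evaluate score vectors: per-class F1/TPR and threshold outcome tallies
#'
#' @param scores n x n_classes matrix of merged scores (columns named).
#' @param labels True (merged) class labels.
#' @param taxonomy A `class_taxonomy`.
#' @param threshold Confidence cut-off for the outcome tallies.
#' @return An `eval_report` list: `per_class` (class, TP/FP/FN at top-1 and
#'   top-3, F1s, TPR), `outcomes` (correct_confident, wrong_confident,
#'   unclear counts), `n`.
#' @export
evaluate_scores <- function(scores, labels, taxonomy, threshold = 0.95) {
  c1 <- topk_confusion(scores, labels, 1L)
  c3 <- topk_confusion(scores, labels, 3L)
  per <- data.table::data.table(
    class = c1$class,
    TP1 = c1$TP, FP1 = c1$FP, FN1 = c1$FN,
    TP3 = c3$TP, FP3 = c3$FP, FN3 = c3$FN)
  per[, `:=`(f1_top1 = f1_score(TP1, FP1, FN1),
             f1_top3 = f1_score(TP3, FP3, FN3),
             tpr_top1 = tpr(TP1, FN1))]
  out <- c(correct_confident = 0L, wrong_confident = 0L, unclear = 0L)
  for (i in seq_len(nrow(scores))) {
    cls <- classify_with_threshold(scores[i, ], taxonomy, threshold)
    out[if (cls$outcome == "unclear") "unclear"
        else if (cls$class == labels[i]) "correct_confident"
        else "wrong_confident"] <-
      out[if (cls$outcome == "unclear") "unclear"
          else if (cls$class == labels[i]) "correct_confident"
          else "wrong_confident"] + 1L
  }
  structure(list(per_class = per, outcomes = out, n = nrow(scores),
                 threshold = threshold),
            class = "eval_report")
}

#' Write an evaluation report (TSV per-class table + JSON summary)
#'
#' @param report An `eval_report`.
#' @param path Output stem; writes `<path>.tsv` and `<path>.json`.
#' @export
write_eval_report <- function(report, path) {
  data.table::fwrite(report$per_class, paste0(path, ".tsv"), sep = "\t")
  jsonlite::write_json(list(n = report$n, threshold = report$threshold,
                            outcomes = as.list(report$outcomes),
                            mean_f1_top1 = mean(report$per_class$f1_top1),
                            mean_f1_top3 = mean(report$per_class$f1_top3)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read-order robustness resampling
#'
#' The sequenced read order is randomized `n_perm` times; reads are
#' accumulated in each order, the cumulative CpG call count is converted to
#' pseudotime, and the sample is classified at the end of every pseudotime
#' interval. Deterministic given the seed.
#'
#' @param read_records data.table (read_id, probe_id, call): per-read probe
#'   calls, e.g. from per-read grouping of [map_calls_to_probes()] input.
#' @param models Ensemble (list of `model_state`).
#' @param manifest A `probe_manifest`.
#' @param taxonomy A `class_taxonomy`.
#' @param true_label True merged class label.
#' @param table A [pseudotime_table()] (scaled to the cohort at hand).
#' @param n_perm Number of read-order permutations (default 100).
#' @param threshold Confidence cut-off.
#' @param seed Seed for the permutations.
#' @return `n_perm` x n_intervals character matrix with entries
#'   `"correct_confident"`, `"wrong_confident"` or `"below_threshold"`.
#' @export
robustness_resample <- function(read_records, models, manifest, taxonomy,
                                true_label, table, n_perm = 100L,
                                threshold = 0.95, seed = 1L) {
  reads <- unique(read_records$read_id)
  n_int <- length(table$cumulative)
  out <- matrix(NA_character_, n_perm, n_int)
  calls_by_read <- split(read_records, by = "read_id", keep.by = FALSE)
  n_calls <- vapply(calls_by_read, nrow, integer(1))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample(reads)
      cum <- cumsum(n_calls[ord])
      for (iv in seq_len(n_int)) {
        k <- sum(cum <= table$cumulative[iv])
        if (k == 0L) { out[p, iv] <- "below_threshold"; next }
        acc <- data.table::rbindlist(calls_by_read[ord[seq_len(k)]])
        prof <- majority_call(acc)
        x <- encode_run(prof, manifest)
        pred <- ensemble_predict(models, x, taxonomy)
        cls <- classify_with_threshold(pred$scores, taxonomy, threshold)
        out[p, iv] <- if (cls$outcome != "confident") "below_threshold"
        else if (cls$class == true_label) "correct_confident"
        else "wrong_confident"
      }
    }
  })
  out
}

# Per-probe majority over call rows (probe_id, call); ties discarded.
majority_call <- function(dt) {
  agg <- dt[, .(m = sum(call == 1L), u = sum(call == 0L)), by = probe_id]
  agg <- agg[m != u]
  stats::setNames(as.integer(agg$m > agg$u), agg$probe_id)
}

#' Purity sweep
#'
#' For every (control-read fraction, depth) cell, tumour/control read
#' mixtures are simulated and classified; tallies of correct/wrong above
#' the confidence threshold, unclear outcomes, and control-class top-1
#' predictions are returned (the structure of the purity robustness
#' panels).
#'
#' @param models Ensemble (list of `model_state`).
#' @param tumor_profiles Named list of binary tumour profiles.
#' @param tumor_labels Named vector: true merged class per tumour profile.
#' @param control_profile Binary profile of control (non-tumour) tissue.
#' @param manifest,genome,config Simulation context ([sim_config()]).
#' @param fractions Control-read fractions to sweep.
#' @param depths Depth levels (coverage fractions) to sweep.
#' @param n_rep Replicate runs per (profile, fraction, depth).
#' @param taxonomy A `class_taxonomy`.
#' @param threshold Confidence cut-off.
#' @param seed_start First test-range seed to use (consumed sequentially).
#' @param role Seed role for the simulations.
#' @return data.table: fraction, depth, n, correct_confident,
#'   wrong_confident, unclear, control_predicted.
#' @export
purity_sweep <- function(models, tumor_profiles, tumor_labels, control_profile,
                         manifest, genome, config = sim_config(),
                         fractions = seq(0.05, 0.95, by = 0.05),
                         depths = default_depth_levels()[c(6L, 9L)],
                         n_rep = 5L, taxonomy = NULL, threshold = 0.95,
                         seed_start = 0L, role = "test") {
  if (is.null(taxonomy)) taxonomy <- models[[1L]]$taxonomy
  ctrl_flags <- merged_control_flags(taxonomy)
  rng <- seed_policy()[[role]]
  span <- rng[2L] - rng[1L] + 1L
  k <- seed_start
  next_seed <- function() {
    k <<- k + 1L
    as.integer(rng[1L] + (k - 1L) %% span)
  }
  rows <- list()
  for (fr in fractions) for (dp in depths) {
    tall <- c(correct_confident = 0L, wrong_confident = 0L, unclear = 0L,
              control_predicted = 0L)
    n <- 0L
    for (s in names(tumor_profiles)) for (r in seq_len(n_rep)) {
      cfg <- config; cfg$depth_level <- dp; cfg$n_reads <- NULL
      run <- simulate_mixture(tumor_profiles[[s]], control_profile, fr,
                              original_tumor_fraction = 1, manifest = manifest,
                              genome = genome, config = cfg,
                              seed = next_seed(), role = role)
      pred <- ensemble_predict(models, encode_run(run$calls, manifest), taxonomy)
      cls <- classify_with_threshold(pred$scores, taxonomy, threshold)
      n <- n + 1L
      if (isTRUE(ctrl_flags[[cls$class]]))
        tall["control_predicted"] <- tall["control_predicted"] + 1L
      key <- if (cls$outcome != "confident") "unclear"
      else if (cls$class == tumor_labels[[s]]) "correct_confident"
      else "wrong_confident"
      tall[key] <- tall[key] + 1L
    }
    rows[[length(rows) + 1L]] <-
      data.table::data.table(fraction = fr, depth = dp, n = n,
                             correct_confident = tall[["correct_confident"]],
                             wrong_confident = tall[["wrong_confident"]],
                             unclear = tall[["unclear"]],
                             control_predicted = tall[["control_predicted"]])
  }
  data.table::rbindlist(rows)
}
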