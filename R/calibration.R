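# Temperature-scaling calibration, expected calibration error, and the
# threshold-based clinical outcome rule.

weighted_nll <- function(logits, y, w) {
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  nll <- lse - logits[cbind(seq_along(y), y)]
  sum(w * nll) / sum(w)
}

#' Fit a calibration temperature
#'
#' Finds the scalar T > 0 minimizing the class-weighted cross-entropy of
#' softmax(logits / T) against the labels, with a bounded quasi-Newton
#' search (L-BFGS-B on log T, at most 500 iterations). Default class weights
#' are inverse class frequency on the calibration set, normalized to mean 1.
#' Dividing by a temperature never changes any sample's argmax.
#'
#' @param logits n x n_classes matrix of uncalibrated (pre-softmax) logits.
#' @param labels Integer true-class indices (1-based), length n.
#' @param class_weights Optional per-class weight vector (length n_classes).
#' @return Fitted temperature (scalar > 0), with the per-sample weights and
#'   achieved NLL as attributes.
#' @export
fit_temperature <- function(logits, labels, class_weights = NULL) {
  if (is.null(dim(logits))) stopf("logits must be a matrix")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("temperature fitting needs at least two distinct classes")
  if (is.null(class_weights)) {
    freq <- tabulate(labels, nbins = ncol(logits))
    inv <- ifelse(freq > 0, 1 / freq, 0)
    class_weights <- inv / mean(inv[freq > 0])
  }
  w <- class_weights[labels]
  obj <- function(logT) weighted_nll(logits / exp(logT), labels, w)
  fit <- stats::optim(0, obj, method = "L-BFGS-B", lower = log(1e-3),
                      upper = log(1e3), control = list(maxit = 500L))
  T_hat <- exp(fit$par)
  # never return a temperature that calibrates worse than T = 1
  if (fit$value > obj(0) + 1e-12) T_hat <- 1
  structure(T_hat, nll = min(fit$value, obj(0)), nll_at_1 = obj(0),
            class_weights = class_weights)
}

#' Calibrate a model on labelled logits
#'
#' @param model A `model_state`.
#' @param logits,labels,class_weights As in [fit_temperature()].
#' @return The model with its `temperature` set.
#' @export
calibrate_model <- function(model, logits, labels, class_weights = NULL) {
  model$temperature <- as.numeric(fit_temperature(logits, labels, class_weights))
  model
}

#' Expected calibration error
#'
#' Bin-weighted average of |accuracy - confidence| over M confidence bins:
#' ECE = sum_m |B_m|/n * |acc(B_m) - con(B_m)|. Bins are equal-width on
#' \[0,1\] by default; equal-count binning is available as an option.
#'
#' @param confidence Per-sample top-score confidences in \[0,1\].
#' @param correct Logical vector: was the top prediction correct.
#' @param n_bins Number of bins (default 10).
#' @param binning `"width"` (equal-width, standard) or `"count"`
#'   (equal-count).
#' @return ECE in \[0,1\], with the per-bin reliability table as attribute
#'   `"bins"` (bin, count, accuracy, confidence).
#' @export
compute_ece <- function(confidence, correct, n_bins = 10L,
                        binning = c("width", "count")) {
  binning <- match.arg(binning)
  n <- length(confidence)
  if (n == 0L) stopf("empty input")
  stopifnot(length(correct) == n, all(confidence >= 0 & confidence <= 1))
  bin <- if (binning == "width") {
    pmax(ceiling(confidence * n_bins), 1L)
  } else {
    as.integer(cut(rank(confidence, ties.method = "first"),
                   breaks = seq(0, n, length.out = n_bins + 1L),
                   include.lowest = TRUE))
  }
  tab <- data.table::data.table(bin = bin, conf = confidence,
                                ok = as.logical(correct))
  per <- tab[, .(count = .N, accuracy = mean(ok), confidence = mean(conf)),
             keyby = bin]
  ece <- sum(per$count / n * abs(per$accuracy - per$confidence))
  structure(ece, bins = per)
}

#' Threshold-based clinical outcome
#'
#' A sample is confidently classified iff the top merged score reaches the
#' threshold AND the top class is not a control (non-tumour) class.
#' Otherwise the outcome is "unclear", with the sub-reason recorded:
#' below-threshold, or control-confident (a control class itself exceeded
#' the threshold).
#'
#' @param scores Named, normalized (post-merge) score vector.
#' @param taxonomy A `class_taxonomy` (control flags are looked up on the
#'   post-merge label set).
#' @param threshold Confidence cut-off in (0,1); default 0.95.
#' @return List: `outcome` ("confident" or "unclear"), `class` (top class),
#'   `score` (top score), `reason` (NA, "below_threshold" or
#'   "control_confident").
#' @export
classify_with_threshold <- function(scores, taxonomy, threshold = 0.95) {
  assert_scalar_number(threshold, "threshold", 1e-12, 1 - 1e-12)
  top <- which.max(scores)
  lab <- names(scores)[top]
  ctrl <- merged_control_flags(taxonomy)
  is_ctrl <- isTRUE(ctrl[[lab]])
  if (scores[top] >= threshold && !is_ctrl)
    return(list(outcome = "confident", class = lab,
                score = unname(scores[top]), reason = NA_character_))
  list(outcome = "unclear", class = lab, score = unname(scores[top]),
       reason = if (scores[top] >= threshold) "control_confident" else "below_threshold")
}

#' Export a calibration report
#'
#' JSON summary (temperature, ECE before/after) plus a reliability-diagram
#' table (TSV: bin, count, accuracy, confidence).
#'
#' @param temperature Fitted temperature.
#' @param ece_before,ece_after ECE values (as from [compute_ece()], the
#'   `after` one carrying the bin table used for the TSV).
#' @param path Output stem; writes `<path>.json` and `<path>_bins.tsv`.
#' @export
write_calibration_report <- function(temperature, ece_before, ece_after, path) {
  jsonlite::write_json(list(temperature = as.numeric(temperature),
                            ece_before = as.numeric(ece_before),
                            ece_after = as.numeric(ece_after)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  bins <- attr(ece_after, "bins")
  if (!is.null(bins)) data.table::fwrite(bins, paste0(path, "_bins.tsv"), sep = "\t")
  invisible(path)
}
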