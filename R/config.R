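# Flat plain-text run configuration, provenance stamping and logging, so
# every artifact records the constants and seed that produced it. One flat
# key=value file with command-line overrides: intraoperative use demands
# zero-interaction invocation.

#' Default run configuration
#'
#' Every tunable constant of the pipeline with its reference-setting
#' default: binarization cut-off 0.6, noise rate 0.10, 12 depth levels over
#' 0.6-14% (fine-tune cap 6.3%), median read length 5 kb, batch size 256,
#' 3,000 epochs per stage, warmup 1e-5 to 1e-3 over 1,000 batches, cosine
#' decay to 1e-4 at epoch 1,000, AdamW constants, checkpoint cadence 2,000
#' batches / 50 validation batches, balance correction 0.3, probability
#' cut-offs 0.3/0.7, 100-bp probe windows, 5-kb flanks merged within 25 kb,
#' 2-Mb CNV bins, confidence threshold 0.95.
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    beta_cutoff = 0.6,
    noise_rate = 0.10,
    depth_min = 0.006, depth_max = 0.14, n_depth_levels = 12L,
    finetune_max = 0.063,
    read_length_median_bp = 5000, read_length_sdlog = 0.35,
    read_length_min_bp = 100,
    batch_size = 256L, pretrain_epochs = 3000L, finetune_epochs = 3000L,
    lr_start = 1e-5, lr_peak = 1e-3, lr_floor = 1e-4,
    warmup_batches = 1000L, decay_epochs = 1000L,
    adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
    weight_decay = 5e-4,
    checkpoint_every = 2000L, val_batches = 50L,
    balance_correction = 0.3,
    dropout = 0.5,
    prob_lower = 0.3, prob_upper = 0.7, probe_window_bp = 100,
    flank_bp = 5000, merge_within_bp = 25000,
    cnv_bin_bp = 2e6,
    confidence_threshold = 0.95,
    ece_bins = 10L,
    k_folds = 4L,
    seed = 1L, verbosity = 1L
  )
}

#' Read / write a flat key=value configuration file
#'
#' Lines of `key = value`; blank lines and `#` comments ignored. Values are
#' parsed as numbers where possible. Unknown keys are kept; missing keys
#' fall back to [default_run_config()].
#'
#' @param path Configuration file path.
#' @return Named configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' @rdname read_run_config
#' @param config Named configuration list.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, scientific = FALSE),
                            character(1))),
             path)
  invisible(path)
}

#' Hash of a configuration
#'
#' @param config Named configuration list.
#' @return MD5 hex digest of the canonical serialized form.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  ord <- order(names(config))
  writeLines(jsonlite::toJSON(config[ord], auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Stamp an artifact with its provenance
#'
#' Writes `<path>.provenance.json` carrying the config hash, the seed, the
#' package version and a timestamp, so any artifact can be reproduced
#' bit-for-bit from its sidecar.
#'
#' @param path Artifact path.
#' @param config Configuration that produced it.
#' @param seed Seed that produced it.
#' @param extra Optional named list of additional fields.
#' @export
stamp_provenance <- function(path, config, seed, extra = list()) {
  side <- c(list(config_hash = config_hash(config), seed = seed,
                 package = as.character(utils::packageVersion("sparsemeth")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Timestamped, level-tagged log line
#'
#' @param level `"INFO"`, `"WARN"` or `"ERROR"`.
#' @param fmt,... sprintf-style message.
#' @param verbosity Messages print when `verbosity >= 1`.
#' @export
log_msg <- function(level = "INFO", fmt, ..., verbosity = 1L) {
  if (verbosity < 1L) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  sprintf(fmt, ...)))
}

#' Build the derived parameter objects from a run configuration
#'
#' @param config Named list from [read_run_config()] /
#'   [default_run_config()].
#' @return List: `sim_config`, `schedule_pre`, `schedule_fine`.
#' @export
config_objects <- function(config = default_run_config()) {
  lm <- read_length_model(median_bp = config$read_length_median_bp,
                          sdlog = config$read_length_sdlog,
                          min_bp = config$read_length_min_bp)
  levels <- exp(seq(log(config$depth_min), log(config$depth_max),
                    length.out = config$n_depth_levels))
  sc <- sim_config(noise_rate = config$noise_rate, depth_levels = levels,
                   length_model = lm)
  pre <- training_schedule(
    batch_size = as.integer(config$batch_size),
    epochs = as.integer(config$pretrain_epochs),
    lr_start = config$lr_start, lr_peak = config$lr_peak,
    lr_floor = config$lr_floor,
    warmup_batches = as.integer(config$warmup_batches),
    decay_epochs = as.integer(config$decay_epochs),
    checkpoint_every = as.integer(config$checkpoint_every),
    val_batches = as.integer(config$val_batches),
    beta1 = config$adam_beta1, beta2 = config$adam_beta2,
    eps = config$adam_eps, weight_decay = config$weight_decay)
  fine <- pre
  fine$epochs <- as.integer(config$finetune_epochs)
  fine$constant_lr <- TRUE
  list(sim_config = sc, schedule_pre = pre, schedule_fine = fine)
}
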