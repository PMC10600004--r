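#' @import data.table
#' @importFrom stats rbinom runif rnorm rlnorm setNames optim pt cor
#' @importFrom utils head tail
NULL

utils::globalVariables(c(
  ".", ".N", "probe_id", "chromosome", "position", "chrom", "pos", "strand",
  "call", "prob", "read_id", "probe", "state", "count", "width", "end",
  "start", "m", "u", "ok", "conf", "log_ratio", "TP1", "FP1", "FN1",
  "TP3", "FP3", "FN3", "f1_top1", "f1_top3", "tpr_top1", "read"))

# Internal assertions ---------------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  invisible(x)
}

# Deterministic derived seeds. A single user-facing seed drives several
# independent substreams (read placement, noise, shuffling); each substream
# seed is a fixed mix of the parent seed and a role tag, kept below 2^31.
derive_seed <- function(seed, stream) {
  ((as.double(seed) + 1) * 48271 + stream * 1664525) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Largest-remainder rounding: integer vector summing exactly to `total`,
# proportional to `weights`, with every entry >= floor_min.
largest_remainder <- function(weights, total, floor_min = 0L) {
  stopifnot(all(weights >= 0), total >= length(weights) * floor_min)
  raw <- weights / sum(weights) * total
  out <- pmax(floor(raw), floor_min)
  rem <- raw - floor(raw)
  deficit <- total - sum(out)
  if (deficit > 0) {
    ord <- order(rem, decreasing = TRUE)
    idx <- rep_len(ord, deficit)
    for (i in idx) out[i] <- out[i] + 1L
  } else if (deficit < 0) {
    # floors pushed us over; shave from cells with the most slack
    ord <- order(out - floor_min, decreasing = TRUE)
    i <- 1L
    while (deficit < 0) {
      j <- ord[(i - 1L) %% length(ord) + 1L]
      if (out[j] > floor_min) {
        out[j] <- out[j] - 1L
        deficit <- deficit + 1L
      }
      i <- i + 1L
    }
  }
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}
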