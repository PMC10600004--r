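# Shared tiny fixtures and independent brute-force oracles. Oracles are
# deliberately naive (exhaustive loops) and never reuse package internals.

tiny_genome <- function() genome_layout(c(chr1 = 1e6, chr2 = 5e5))

tiny_manifest <- function(n = 50, seed = 1) make_manifest(n, tiny_genome(), seed)

# Brute-force probe coverage: all-pairs overlap test on 1-based cytosines
# against half-open 0-based intervals.
bf_covered <- function(intervals, manifest) {
  hit <- vapply(seq_len(nrow(manifest)), function(i) {
    p0 <- manifest$pos[i] - 1L
    any(intervals$chrom == manifest$chrom[i] &
          intervals$start <= p0 & p0 < intervals$end)
  }, logical(1))
  manifest$probe_id[hit]
}

# Brute-force top-k confusion bookkeeping.
bf_topk <- function(scores, labels, k) {
  classes <- colnames(scores)
  out <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L)
  for (i in seq_len(nrow(scores))) {
    ranked <- classes[order(scores[i, ], decreasing = TRUE)]
    if (labels[i] %in% ranked[seq_len(k)]) {
      out$TP[out$class == labels[i]] <- out$TP[out$class == labels[i]] + 1L
    } else {
      out$FN[out$class == labels[i]] <- out$FN[out$class == labels[i]] + 1L
      out$FP[out$class == ranked[1]] <- out$FP[out$class == ranked[1]] + 1L
    }
  }
  out
}

# Brute-force equal-width ECE.
bf_ece <- function(conf, ok, n_bins = 10) {
  tot <- 0
  for (m in seq_len(n_bins)) {
    lo <- (m - 1) / n_bins; hi <- m / n_bins
    inb <- if (m == 1) conf >= lo & conf <= hi else conf > lo & conf <= hi
    if (!any(inb)) next
    tot <- tot + sum(inb) / length(conf) * abs(mean(ok[inb]) - mean(conf[inb]))
  }
  tot
}

# Brute-force region design: expand every probe by the flank, clip, then
# sweep left to right merging any gap <= merge_within.
bf_regions <- function(manifest, genome, flank, merge_within) {
  out <- NULL
  for (chrom in unique(manifest$chrom)) {
    p0 <- sort(manifest$pos[manifest$chrom == chrom] - 1)
    start <- pmax(p0 - flank, 0)
    end <- pmin(p0 + flank + 1, genome[[chrom]])
    cs <- start[1]; ce <- end[1]
    for (i in seq_along(p0)[-1]) {
      if (start[i] - ce <= merge_within) ce <- max(ce, end[i])
      else { out <- rbind(out, data.frame(chrom = chrom, start = cs, end = ce))
             cs <- start[i]; ce <- end[i] }
    }
    out <- rbind(out, data.frame(chrom = chrom, start = cs, end = ce))
  }
  out[order(out$chrom, out$start), ]
}

# Brute-force per-read-then-per-probe majority voting over thresholded
# calls; ties discard the unit.
bf_map_calls <- function(calls, manifest, window = 100) {
  thr <- function(p) if (p < 0.3) 0L else if (p > 0.7) 1L else NA_integer_
  res <- setNames(integer(0), character(0))
  for (i in seq_len(nrow(manifest))) {
    votes <- integer(0)
    for (rd in unique(calls$read_id)) {
      sub <- calls[calls$read_id == rd & calls$chrom == manifest$chrom[i], ]
      cc <- integer(0)
      for (j in seq_len(nrow(sub))) {
        if (abs(sub$pos[j] - manifest$pos[i]) <= window / 2) {
          v <- thr(sub$prob[j])
          if (!is.na(v)) cc <- c(cc, v)
        }
      }
      if (length(cc) && sum(cc == 1) != sum(cc == 0))
        votes <- c(votes, as.integer(sum(cc == 1) > sum(cc == 0)))
    }
    if (length(votes) && sum(votes == 1) != sum(votes == 0))
      res[manifest$probe_id[i]] <- as.integer(sum(votes == 1) > sum(votes == 0))
  }
  res
}

# Logits whose softmax is exactly the class-generating distribution, so the
# calibrated optimum is T = scale by construction.
synthetic_logits <- function(n, K, scale = 1, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * K), n, K) * 2
  p <- exp(z) / rowSums(exp(z))
  y <- vapply(seq_len(n), function(i) sample.int(K, 1, prob = p[i, ]), integer(1))
  list(logits = z * scale, y = y)
}

# Desk-scale curriculum used by the end-to-end suites: batch 8, peak rate
# 1e-2 decaying to 2e-3, 30 pretraining + 20 fine-tuning epochs, checkpoint
# every 50 batches on 3 validation batches.
desk_schedules <- function() {
  list(pre = training_schedule(batch_size = 8L, epochs = 30L, lr_peak = 1e-2,
                               lr_floor = 2e-3, warmup_batches = 20L,
                               decay_epochs = 30L, checkpoint_every = 50L,
                               val_batches = 3L),
       fine = training_schedule(batch_size = 8L, epochs = 20L, lr_floor = 2e-3,
                                checkpoint_every = 50L, val_batches = 3L,
                                constant_lr = TRUE))
}
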