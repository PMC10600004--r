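# Shallow-coverage copy-number profiles: fixed 2-Mb binning, reference
# normalization, log ratios, and a simplified deterministic segmentation.

#' Tile a genome into fixed-width bins
#'
#' Bins are half-open 0-based; the last bin of each chromosome keeps its
#' reduced width.
#'
#' @param genome Genome layout.
#' @param bin_bp Bin width (default 2 Mb).
#' @return data.table (chrom, start, end, width).
#' @export
bin_genome <- function(genome, bin_bp = 2e6) {
  out <- lapply(names(genome), function(chrom) {
    L <- genome[[chrom]]
    start <- seq(0, L - 1, by = bin_bp)
    data.table::data.table(chrom = chrom, start = as.numeric(start),
                           end = pmin(start + bin_bp, L))
  })
  dt <- data.table::rbindlist(out)
  dt[, width := end - start]
  dt
}

#' Count read starts per genomic bin
#'
#' Each read is counted once, in the bin containing its (0-based) start
#' position.
#'
#' @param read_positions data.table (chrom, pos) of 0-based read starts, or
#'   a read-interval table as from [sample_reads()] (its `start` is used).
#' @param genome Genome layout.
#' @param bin_bp Bin width (default 2 Mb).
#' @return A `binned_coverage` data.table (chrom, start, end, width, count).
#' @export
bin_reads <- function(read_positions, genome, bin_bp = 2e6) {
  dt <- data.table::as.data.table(read_positions)
  if (!"pos" %in% names(dt) && "start" %in% names(dt))
    data.table::setnames(dt, "start", "pos")
  bins <- bin_genome(genome, bin_bp)
  bins[, count := 0]
  for (ch in unique(dt$chrom)) {
    if (!ch %in% names(genome)) stopf("read on unknown chromosome '%s'", ch)
    p <- dt$pos[dt$chrom == ch]
    if (any(p < 0 | p >= genome[[ch]]))
      stopf("read start outside chromosome '%s'", ch)
    rows <- which(bins$chrom == ch)
    tab <- tabulate(floor(p / bin_bp) + 1L, nbins = length(rows))
    data.table::set(bins, i = rows, j = "count", value = bins$count[rows] + tab)
  }
  data.table::setattr(bins, "class", c("binned_coverage", class(bins)))
  bins
}

#' Reference-normalized per-bin log ratios
#'
#' Relative coverage r_b = sample_b / reference_b per bin; the log ratio is
#' log2(r_b / mean(r)), so a flat sample against its reference sits at 0 and
#' the profile is invariant to total sequencing depth. Bins with zero
#' reference counts are masked (log ratio NA).
#'
#' @param sample,reference `binned_coverage` tables on the same bin grid.
#' @return data.table (chrom, start, end, ratio, log_ratio); masked bins NA.
#' @export
log_ratio <- function(sample, reference) {
  if (nrow(sample) != nrow(reference) ||
      !all(sample$chrom == reference$chrom & sample$start == reference$start))
    stopf("sample and reference must share the same bin grid")
  if (all(reference$count == 0)) stopf("all reference bins are zero")
  r <- ifelse(reference$count > 0, sample$count / reference$count, NA_real_)
  m <- mean(r, na.rm = TRUE)
  lr <- log2(r / m)
  data.table::data.table(chrom = sample$chrom, start = sample$start,
                         end = sample$end, ratio = r, log_ratio = lr)
}

# Most significant mean-shift split of x, honouring min_bins on both sides.
# The split position is the least-squares optimum (argmax of the scaled
# between-segment mean difference); significance uses a noise scale
# estimated robustly from successive differences, so a level shift inside
# one side does not inflate it. Returns list(pos, stat, p) or NULL.
best_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2L * min_bins) return(NULL)
  cand <- seq(min_bins, n - min_bins)
  cs <- cumsum(x); tot <- cs[n]
  na <- cand; nb <- n - cand
  dmean <- abs(cs[cand] / na - (tot - cs[cand]) / nb)
  score <- sqrt(na * nb / n) * dmean
  i <- which.max(score)  # first max: deterministic tie-break
  sigma <- stats::median(abs(diff(x))) / (sqrt(2) * 0.6744898)
  eps <- 1e-8 * (max(abs(x)) + 1e-12)  # constant inputs are never split
  z <- if (sigma == 0) { if (score[i] > eps) Inf else 0 } else score[i] / sigma
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-z)
  list(pos = cand[i], stat = z, p = min(p * length(cand), 1))  # Bonferroni
}

#' Segment per-bin log ratios into mean-shift segments
#'
#' A simplified, deterministic changepoint routine standing in for circular
#' binary segmentation: the most significant mean-shift split (Welch
#' statistic, Bonferroni-corrected over candidate positions) is applied
#' recursively while p < alpha, within each chromosome independently.
#' Externally computed segments can be substituted wherever segments are
#' consumed.
#'
#' @param lr A [log_ratio()] table (masked bins are dropped first), or a
#'   bare numeric vector (treated as one chromosome).
#' @param min_bins Minimum bins per segment (default 3).
#' @param alpha Significance threshold for accepting a split (default 0.01).
#' @return data.table (chrom, start_bin, end_bin, n_bins, mean_lr); the
#'   segments partition the retained bins.
#' @export
segment_log_ratios <- function(lr, min_bins = 3L, alpha = 0.01) {
  if (is.numeric(lr) && is.null(dim(lr)))
    lr <- data.table::data.table(chrom = "chr", start = seq_along(lr) - 1,
                                 end = seq_along(lr), log_ratio = lr)
  dt <- data.table::as.data.table(lr)[!is.na(log_ratio)]
  if (!nrow(dt)) stopf("no retained bins to segment")
  segments_of <- function(x) {
    recurse <- function(lo, hi) {
      sp <- best_split(x[lo:hi], min_bins)
      if (is.null(sp) || sp$p >= alpha) return(list(c(lo, hi)))
      cut <- lo + sp$pos - 1L
      c(recurse(lo, cut), recurse(cut + 1L, hi))
    }
    recurse(1L, length(x))
  }
  out <- list()
  for (chrom in unique(dt$chrom)) {
    x <- dt$log_ratio[dt$chrom == chrom]
    offs <- which(dt$chrom == chrom)
    for (seg in segments_of(x)) {
      rows <- offs[seg[1L]:seg[2L]]
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = chrom, start_bin = seg[1L], end_bin = seg[2L],
        n_bins = seg[2L] - seg[1L] + 1L, mean_lr = mean(dt$log_ratio[rows]))
    }
  }
  data.table::rbindlist(out)
}

#' End-to-end sparse CNV profile
#'
#' @param read_positions,genome,bin_bp As in [bin_reads()].
#' @param reference A `binned_coverage` reference track on the same grid.
#' @param min_bins,alpha Segmentation parameters.
#' @return List: `bins` (log-ratio table), `segments`.
#' @export
cnv_profile <- function(read_positions, reference, genome, bin_bp = 2e6,
                        min_bins = 3L, alpha = 0.01) {
  smp <- bin_reads(read_positions, genome, bin_bp)
  lr <- log_ratio(smp, reference)
  list(bins = lr, segments = segment_log_ratios(lr, min_bins, alpha))
}
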