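# Conversion of per-read per-site methylation probability calls into a
# binary array-probe profile, and adaptive-sampling target-region design.

#' Threshold a methylation probability
#'
#' p < 0.3 -> unmethylated, p > 0.7 -> methylated, the dead zone in between
#' (boundaries included) is discarded.
#'
#' @param p Methylation probabilities in \[0,1\].
#' @param lower,upper Cut-offs (strict inequalities).
#' @return Integer vector: 0 (unmethylated), 1 (methylated), NA (discarded).
#' @export
threshold_probability <- function(p, lower = 0.3, upper = 0.7) {
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0,1]")
  out <- rep(NA_integer_, length(p))
  out[p < lower] <- 0L
  out[p > upper] <- 1L
  out
}

#' Read a per-read per-site call table
#'
#' Native format: TSV with header (read_id, chrom, pos, strand, prob),
#' positions 1-based. A bedMethyl-like file (no header; chrom, start, end,
#' read_id, prob in the first five columns; start 0-based) is also accepted.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"bedmethyl"`.
#' @return data.table (read_id, chrom, pos, prob), pos 1-based.
#' @export
read_call_table <- function(path, format = c("tsv", "bedmethyl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, header = TRUE)
    need <- c("read_id", "chrom", "pos", "prob")
    if (!all(need %in% names(dt)))
      stopf("call table must have columns: %s", paste(need, collapse = ", "))
    dt <- dt[, .(read_id = as.character(read_id), chrom = as.character(chrom),
                 pos = as.integer(pos), prob = as.numeric(prob))]
  } else {
    dt <- data.table::fread(path, header = FALSE)
    if (ncol(dt) < 5L) stopf("bedMethyl-like input needs >= 5 columns")
    dt <- data.table::data.table(read_id = as.character(dt[[4L]]),
                                 chrom = as.character(dt[[1L]]),
                                 pos = as.integer(dt[[2L]]) + 1L,
                                 prob = as.numeric(dt[[5L]]))
  }
  if (any(dt$prob < 0 | dt$prob > 1)) stopf("probabilities must lie in [0,1]")
  dt
}

#' Map per-read methylation calls onto array probes
#'
#' Calls are first thresholded (dead-zone calls discarded), then assigned to
#' every probe whose centred window they fall into (a call at distance d
#' from the probe cytosine is in-window iff d <= window_bp / 2). Within each
#' (read, probe) pair the retained calls are majority-voted into one
#' per-read call; across reads a second majority vote gives the final probe
#' state. A tie at either level discards that unit. Calls on both strands
#' are pooled (CpG methylation is symmetric).
#'
#' @param calls data.table (read_id, chrom, pos, prob), pos 1-based — as
#'   from [read_call_table()].
#' @param manifest A `probe_manifest`.
#' @param window_bp Window width centred on the probe cytosine (default
#'   100 bp).
#' @param lower,upper Probability cut-offs for [threshold_probability()].
#' @return Named binary profile over the probes with a surviving call.
#' @export
map_calls_to_probes <- function(calls, manifest, window_bp = 100,
                                lower = 0.3, upper = 0.7) {
  half <- window_bp / 2
  dt <- data.table::as.data.table(calls)
  dt[, call := threshold_probability(prob, lower, upper)]
  dt <- dt[!is.na(call)]
  if (!nrow(dt)) return(stats::setNames(integer(0), character(0)))
  idx <- probe_index(manifest)
  hits <- list()
  sp <- split(seq_len(nrow(dt)), dt$chrom)
  for (chrom in names(sp)) {
    ix <- idx[[chrom]]
    if (is.null(ix)) next
    rows <- sp[[chrom]]
    pos0 <- dt$pos[rows] - 1L
    # probes with |probe_pos0 - call_pos0| <= half
    i1 <- findInterval(pos0 - half - 1e-9, ix$pos0) + 1L
    i2 <- findInterval(pos0 + half + 1e-9, ix$pos0)
    keep <- i2 >= i1
    if (!any(keep)) next
    n_hit <- i2[keep] - i1[keep] + 1L
    hits[[chrom]] <- data.table::data.table(
      read_id = rep(dt$read_id[rows[keep]], n_hit),
      probe = ix$gidx[sequence(n_hit, from = i1[keep])],
      call = rep(dt$call[rows[keep]], n_hit))
  }
  if (!length(hits)) return(stats::setNames(integer(0), character(0)))
  hits <- data.table::rbindlist(hits)
  # read-level vote per (read, probe), ties drop the read's contribution
  per_read <- hits[, .(m = sum(call == 1L), u = sum(call == 0L)),
                   by = .(read_id, probe)][m != u]
  if (!nrow(per_read)) return(stats::setNames(integer(0), character(0)))
  per_read[, call := as.integer(m > u)]
  # probe-level vote across reads, ties discard the probe
  per_probe <- per_read[, .(m = sum(call == 1L), u = sum(call == 0L)),
                        by = probe][m != u]
  per_probe <- per_probe[order(probe)]
  stats::setNames(as.integer(per_probe$m > per_probe$u),
                  manifest$probe_id[per_probe$probe])
}

#' Design adaptive-sampling target regions
#'
#' Every probe contributes the interval probe position +/- flank (clipped to
#' the chromosome); intervals separated by at most `merge_within_bp` are
#' merged. Output is sorted and disjoint, and every probe lies inside
#' exactly one region.
#'
#' @param manifest A `probe_manifest`.
#' @param genome Genome layout for end clipping.
#' @param flank_bp Flank ("buffer") size around each probe (default 5 kb).
#' @param merge_within_bp Maximum gap that still merges two regions
#'   (default 25 kb).
#' @return data.table (chrom, start, end), 0-based half-open, sorted.
#' @export
build_target_regions <- function(manifest, genome, flank_bp = 5000,
                                 merge_within_bp = 25000) {
  stopifnot(flank_bp >= 0, merge_within_bp >= 0)
  pos0 <- manifest$pos - 1L
  gr <- GenomicRanges::GRanges(
    manifest$chrom,
    IRanges::IRanges(start = pmax(pos0 - flank_bp, 0L) + 1L,
                     end = pos0 + flank_bp + 1L))  # 1-based closed, end clipped below
  lens <- as.numeric(genome[as.character(GenomicRanges::seqnames(gr))])
  if (anyNA(lens)) stopf("manifest chromosome missing from genome layout")
  IRanges::end(gr) <- pmin(IRanges::end(gr), lens)
  # gap <= merge_within_bp merges; reduce() merges gaps < min.gapwidth
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                               min.gapwidth = merge_within_bp + 1L)
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                         start = IRanges::start(red) - 1L,
                         end = IRanges::end(red))
}

#' Write regions as 3-column BED (0-based half-open, sorted)
#'
#' @param regions data.table (chrom, start, end).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  data.table::fwrite(regions[order(chrom, start)], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
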