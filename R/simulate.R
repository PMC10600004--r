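# Simulation of sparse nanopore-like methylation runs from binarized array
# profiles: read placement, probe coverage, call noise, depth series, purity
# mixtures, and a strict seed-role policy.

#' Default sparsity (depth) levels
#'
#' Twelve geometrically spaced probe-coverage fractions spanning 0.6% to 14%
#' of the probe universe. The fine-tuning curriculum uses the sub-range up to
#' 6.3% (the more difficult, sparser runs).
#'
#' @return Numeric vector of 12 strictly increasing fractions.
#' @export
default_depth_levels <- function() {
  exp(seq(log(0.006), log(0.14), length.out = 12L))
}

#' Seed-role policy
#'
#' Disjoint integer seed ranges per role, so that simulations for test,
#' validation and training folds can never share a pseudo-random stream:
#' test \[0, 499\], validation \[500, 999\], training \[1000, 1000999\].
#'
#' @return Named list of `c(lo, hi)` integer ranges.
#' @export
seed_policy <- function() {
  list(test = c(0L, 499L), validation = c(500L, 999L),
       training = c(1000L, 1000999L))
}

#' Assert that a seed belongs to a role's range
#'
#' @param seed Integer seed.
#' @param role One of `"test"`, `"validation"`, `"training"`.
#' @export
assert_seed_role <- function(seed, role = c("training", "validation", "test")) {
  role <- match.arg(role)
  rng <- seed_policy()[[role]]
  if (seed < rng[1L] || seed > rng[2L])
    stopf("seed %d outside the %s range [%d, %d]", seed, role, rng[1L], rng[2L])
  invisible(seed)
}

#' Read-length model
#'
#' Either a parametric log-normal surrogate (median-parameterized, truncated
#' below) or an empirical sample of read lengths. Intraoperative rapid-prep
#' nanopore reads are approximately 5 kb, which fixes the default median.
#'
#' @param type `"lognormal"` or `"empirical"`.
#' @param median_bp Median read length in bp (log-normal only).
#' @param sdlog Dispersion on the log scale (log-normal only).
#' @param min_bp Lower truncation in bp; drawn lengths are at least this.
#' @param lengths Integer vector of observed lengths (empirical only).
#' @return A `read_length_model` list with a `mean_bp` field used by the
#'   depth solver.
#' @export
read_length_model <- function(type = c("lognormal", "empirical"),
                              median_bp = 5000, sdlog = 0.35, min_bp = 100,
                              lengths = NULL) {
  type <- match.arg(type)
  if (type == "empirical") {
    if (is.null(lengths) || !length(lengths) || any(lengths < 1))
      stopf("empirical model needs lengths >= 1")
    m <- list(type = type, lengths = as.numeric(lengths),
              mean_bp = mean(lengths))
  } else {
    m <- list(type = type, meanlog = log(median_bp), sdlog = sdlog,
              min_bp = min_bp,
              mean_bp = exp(log(median_bp) + sdlog^2 / 2))
  }
  structure(m, class = "read_length_model")
}

# Draw n read lengths with the current RNG state.
draw_lengths <- function(model, n) {
  if (n == 0L) return(numeric(0))
  if (model$type == "empirical")  # index draw: immune to sample()'s scalar rule
    return(model$lengths[sample.int(length(model$lengths), n, replace = TRUE)])
  pmax(stats::rlnorm(n, model$meanlog, model$sdlog), model$min_bp)
}

#' Simulation configuration
#'
#' @param n_reads Number of reads per run, or `NULL` to solve it from
#'   `depth_level`.
#' @param depth_level Target probe-coverage fraction (one of the depth
#'   levels), used when `n_reads` is `NULL`.
#' @param noise_rate Probability that a covered site's call is flipped;
#'   default 0.10, matching the discrepancy observed between nanopore calls
#'   and binarized arrays.
#' @param depth_levels Ordered vector of target coverage fractions.
#' @param length_model A [read_length_model()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = NULL, depth_level = NULL, noise_rate = 0.10,
                       depth_levels = default_depth_levels(),
                       length_model = read_length_model()) {
  assert_scalar_number(noise_rate, "noise_rate", 0, 1)
  if (is.unsorted(depth_levels, strictly = TRUE))
    stopf("depth levels must be strictly increasing")
  structure(list(n_reads = n_reads, depth_level = depth_level,
                 noise_rate = noise_rate, depth_levels = depth_levels,
                 length_model = length_model),
            class = "sim_config")
}

#' Number of reads needed for a target coverage fraction
#'
#' Solved from the expected per-read probe yield: with mean read length L on
#' a genome of size G, a uniformly placed read covers a given probe with
#' probability ~ L/G, so the expected covered fraction after n reads is
#' 1 - (1 - L/G)^n. Realized coverage is recorded in run provenance.
#'
#' @param fraction Target covered fraction of the probe universe, in (0,1).
#' @param genome A genome layout.
#' @param length_model A [read_length_model()].
#' @return Integer number of reads.
#' @export
reads_for_depth <- function(fraction, genome, length_model = read_length_model()) {
  assert_scalar_number(fraction, "fraction", 1e-9, 1 - 1e-9)
  G <- sum(genome)
  p <- min(length_model$mean_bp / G, 0.999999)
  max(1L, as.integer(ceiling(log(1 - fraction) / log(1 - p))))
}

#' Sample read intervals uniformly over a genome
#'
#' Chromosomes are chosen with probability proportional to their length; the
#' start base is uniform; orientation is 50/50 and the read extends one read
#' length in that direction, clipped at the chromosome ends. Uses the current
#' RNG state unless `seed` is given.
#'
#' @param genome Genome layout (named chromosome lengths).
#' @param length_model A [read_length_model()].
#' @param n_reads Number of reads (>= 0).
#' @param seed Optional seed for a self-contained draw.
#' @return data.table (chrom, start, end, strand), 0-based half-open.
#' @export
sample_reads <- function(genome, length_model, n_reads, seed = NULL) {
  if (length(genome) == 0L) stopf("empty genome")
  if (n_reads < 0) stopf("n_reads must be >= 0")
  draw <- function() {
    if (n_reads == 0L)
      return(data.table::data.table(chrom = character(0), start = integer(0),
                                    end = integer(0), strand = character(0)))
    ci <- sample.int(length(genome), n_reads, replace = TRUE,
                     prob = as.numeric(genome))
    chrom <- names(genome)[ci]
    len_chr <- as.numeric(genome)[ci]
    anchor <- floor(stats::runif(n_reads) * len_chr)        # 0-based start base
    rlen <- floor(draw_lengths(length_model, n_reads))
    fwd <- stats::runif(n_reads) < 0.5
    start <- ifelse(fwd, anchor, anchor - rlen + 1)
    end <- ifelse(fwd, anchor + rlen, anchor + 1)
    start <- pmax(start, 0)
    end <- pmin(end, len_chr)
    data.table::data.table(chrom = chrom, start = as.integer(start),
                           end = as.integer(end),
                           strand = ifelse(fwd, "+", "-"))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Global manifest row indices of probes covered by >= 1 interval.
covered_idx <- function(intervals, manifest) {
  idx <- probe_index(manifest)
  if (nrow(intervals) == 0L) return(integer(0))
  out <- vector("list", length(idx))
  sp <- split(seq_len(nrow(intervals)), intervals$chrom)
  k <- 0L
  for (chrom in names(sp)) {
    ix <- idx[[chrom]]
    if (is.null(ix)) next
    rows <- sp[[chrom]]
    s <- intervals$start[rows]; e <- intervals$end[rows]
    i1 <- findInterval(s - 1L, ix$pos0) + 1L   # first probe with pos0 >= start
    i2 <- findInterval(e - 1L, ix$pos0)        # last probe with pos0 < end
    keep <- i2 >= i1
    if (!any(keep)) next
    hits <- sequence(i2[keep] - i1[keep] + 1L, from = i1[keep])
    k <- k + 1L
    out[[k]] <- ix$gidx[unique(hits)]
  }
  if (k == 0L) return(integer(0))
  sort(unique(unlist(out[seq_len(k)])))
}

#' Probes covered by a set of read intervals
#'
#' A probe is covered iff its cytosine position falls within at least one
#' half-open interval.
#'
#' @param intervals data.table (chrom, start, end), 0-based half-open.
#' @param manifest A `probe_manifest`.
#' @return Character vector of covered probe ids (sorted in manifest order).
#' @export
covered_probes <- function(intervals, manifest) {
  manifest$probe_id[covered_idx(intervals, manifest)]
}

#' Flip calls at random
#'
#' Each covered site's binary call is flipped independently with probability
#' `rate`; the covered set itself is unchanged.
#'
#' @param calls Named integer vector in \{0,1\}.
#' @param rate Flip probability in \[0,1\].
#' @param seed Optional seed for a self-contained draw.
#' @return Calls with the same names, flipped where the coin came up.
#' @export
apply_noise <- function(calls, rate, seed = NULL) {
  assert_scalar_number(rate, "rate", 0, 1)
  if (!length(calls) || rate == 0) return(calls)
  draw <- function() stats::runif(length(calls)) < rate
  flip <- if (is.null(seed)) draw() else with_seed(seed, draw())
  calls[flip] <- 1L - calls[flip]
  calls
}

# Align a named binary profile to manifest row order; NA where absent.
align_profile <- function(profile, manifest) {
  st <- profile[match(manifest$probe_id, names(profile))]
  as.integer(st)
}

# Core sampler shared by simulate_run / simulate_mixture / training.
# `states` is a list of manifest-aligned state vectors, `src` assigns each
# read to one of them. Per probe, the call comes from one covering read
# chosen uniformly at random (reduces to a plain lookup when all reads share
# a source). Returns list(idx = manifest rows, calls = 0/1).
.sim_calls <- function(states, manifest, genome, length_model, n_reads,
                       src_prob = NULL) {
  intervals <- sample_reads(genome, length_model, n_reads)
  if (length(states) == 1L) {
    gi <- covered_idx(intervals, manifest)
    st <- states[[1L]][gi]
    keep <- !is.na(st)
    return(list(idx = gi[keep], calls = st[keep], intervals = intervals))
  }
  src <- sample.int(length(states), n_reads, replace = TRUE, prob = src_prob)
  idx <- probe_index(manifest)
  probe <- integer(0); source <- integer(0)
  sp <- split(seq_len(nrow(intervals)), intervals$chrom)
  for (chrom in names(sp)) {
    ix <- idx[[chrom]]
    if (is.null(ix)) next
    rows <- sp[[chrom]]
    s <- intervals$start[rows]; e <- intervals$end[rows]
    i1 <- findInterval(s - 1L, ix$pos0) + 1L
    i2 <- findInterval(e - 1L, ix$pos0)
    keep <- i2 >= i1
    if (!any(keep)) next
    n_hit <- i2[keep] - i1[keep] + 1L
    hits <- sequence(n_hit, from = i1[keep])
    probe <- c(probe, ix$gidx[hits])
    source <- c(source, rep(src[rows[keep]], n_hit))
  }
  if (!length(probe)) return(list(idx = integer(0), calls = integer(0),
                                  intervals = intervals))
  # one covering read per probe, chosen uniformly at random
  ord <- sample.int(length(probe))
  probe <- probe[ord]; source <- source[ord]
  first <- !duplicated(probe)
  gi <- probe[first]; so <- source[first]
  st <- vapply(seq_along(gi), function(i) states[[so[i]]][gi[i]], integer(1))
  keep <- !is.na(st)
  o <- order(gi[keep])
  list(idx = gi[keep][o], calls = st[keep][o], intervals = intervals)
}

#' Simulate one sparse nanopore-like run from a binary profile
#'
#' Composition of read placement, probe-coverage determination, state lookup
#' in the source profile, and random call flipping. The single seed drives
#' two independent substreams (placement and noise), so the whole run,
#' including the noise realization, is reproducible.
#'
#' @param profile Named binary profile (source sample).
#' @param manifest A `probe_manifest`.
#' @param genome Genome layout.
#' @param config A [sim_config()].
#' @param seed Integer seed, drawn from the role-appropriate range.
#' @param role Seed role: `"training"`, `"validation"` or `"test"`.
#' @return A `simulated_run`: list with `calls` (named 0/1 vector) and
#'   `provenance` (seed, role, n_reads, depth level, realized coverage).
#' @export
simulate_run <- function(profile, manifest, genome, config = sim_config(),
                         seed, role = "training") {
  assert_seed_role(seed, role)
  if (!any(names(profile) %in% manifest$probe_id))
    stopf("profile and manifest share no probes")
  n_reads <- resolve_n_reads(config, genome)
  st <- align_profile(profile, manifest)
  res <- with_seed(derive_seed(seed, 1L),
                   .sim_calls(list(st), manifest, genome, config$length_model,
                              n_reads))
  calls <- stats::setNames(res$calls, manifest$probe_id[res$idx])
  calls <- apply_noise(calls, config$noise_rate, seed = derive_seed(seed, 2L))
  structure(list(calls = calls,
                 provenance = list(seed = seed, role = role, n_reads = n_reads,
                                   depth_level = config$depth_level,
                                   noise_rate = config$noise_rate,
                                   in_silico_purity = NULL,
                                   realized_coverage = length(calls) / nrow(manifest))),
            class = "simulated_run")
}

resolve_n_reads <- function(config, genome) {
  if (!is.null(config$n_reads)) return(as.integer(config$n_reads))
  if (is.null(config$depth_level))
    stopf("sim_config needs n_reads or depth_level")
  reads_for_depth(config$depth_level, genome, config$length_model)
}

#' Simulate a tumour/control read mixture
#'
#' A fraction of reads (in expectation `control_read_fraction`) is drawn
#' against the control profile and the rest against the tumour profile; at
#' probes covered by both, the reported call comes from one covering read
#' chosen at random. The in-silico purity is the original tumour fraction
#' multiplied by the tumour read fraction.
#'
#' @param tumor,control Named binary profiles over the same probe universe.
#' @param control_read_fraction Fraction of reads from the control profile.
#' @param original_tumor_fraction Purity of the source tumour sample.
#' @inheritParams simulate_run
#' @return A `simulated_run` with `in_silico_purity` set in provenance.
#' @export
simulate_mixture <- function(tumor, control, control_read_fraction,
                             original_tumor_fraction = 1, manifest, genome,
                             config = sim_config(), seed, role = "training") {
  assert_seed_role(seed, role)
  assert_scalar_number(control_read_fraction, "control_read_fraction", 0, 1)
  assert_scalar_number(original_tumor_fraction, "original_tumor_fraction", 0, 1)
  shared <- intersect(names(tumor), names(control))
  if (!length(shared))
    stopf("tumour and control profiles share no probes (different universes)")
  n_reads <- resolve_n_reads(config, genome)
  states <- list(align_profile(tumor, manifest), align_profile(control, manifest))
  res <- with_seed(derive_seed(seed, 1L),
                   .sim_calls(states, manifest, genome, config$length_model,
                              n_reads,
                              src_prob = c(1 - control_read_fraction,
                                           control_read_fraction)))
  calls <- stats::setNames(res$calls, manifest$probe_id[res$idx])
  calls <- apply_noise(calls, config$noise_rate, seed = derive_seed(seed, 2L))
  structure(list(calls = calls,
                 provenance = list(seed = seed, role = role, n_reads = n_reads,
                                   depth_level = config$depth_level,
                                   noise_rate = config$noise_rate,
                                   control_read_fraction = control_read_fraction,
                                   in_silico_purity = original_tumor_fraction *
                                     (1 - control_read_fraction),
                                   realized_coverage = length(calls) / nrow(manifest))),
            class = "simulated_run")
}

#' Simulate one run per depth level
#'
#' @param profile Named binary profile.
#' @param manifest,genome,config As in [simulate_run()].
#' @param seeds Integer vector, one seed per depth level.
#' @param role Seed role for every run.
#' @return List of `simulated_run`, one per level of `config$depth_levels`.
#' @export
depth_series <- function(profile, manifest, genome, config = sim_config(),
                         seeds, role = "training") {
  levels <- config$depth_levels
  if (length(seeds) != length(levels))
    stopf("need one seed per depth level (%d)", length(levels))
  lapply(seq_along(levels), function(i) {
    cfg <- config
    cfg$depth_level <- levels[i]
    cfg$n_reads <- NULL
    simulate_run(profile, manifest, genome, cfg, seeds[i], role)
  })
}

#' Write a simulated run (TSV calls + JSON provenance sidecar)
#'
#' @param run A `simulated_run`.
#' @param path Output TSV path; provenance goes to `<path>.json`.
#' @export
write_run <- function(run, path) {
  write_binary_profile(run$calls, path)
  jsonlite::write_json(run$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  calls <- read_binary_profile(path)
  prov <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(calls = calls, provenance = prov), class = "simulated_run")
}
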