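# Class-structured synthetic cohorts, manifests, genomes, per-read call
# tables and coverage tracks, so every stage of the pipeline is testable
# without any external download. The generator emulates class-specific
# methylation signatures on a shared background; it does not model
# genome-wide methylation autocorrelation or real tumour biology.

#' Synthetic genome layout
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Length of each chromosome (recycled).
#' @return A `genome_layout`.
#' @export
make_genome <- function(n_chrom = 2L, chrom_bp = 1e7) {
  genome_layout(stats::setNames(rep_len(as.numeric(chrom_bp), n_chrom),
                                paste0("chr", seq_len(n_chrom))))
}

#' Synthetic probe manifest
#'
#' Probes are placed uniformly at unique positions, proportionally to
#' chromosome length; deterministic per seed.
#'
#' @param n_probes Number of probes (>= 1).
#' @param genome Genome layout.
#' @param seed Seed.
#' @return A `probe_manifest`.
#' @export
make_manifest <- function(n_probes, genome, seed = 1L) {
  stopifnot(n_probes >= 1)
  if (n_probes > sum(genome)) stopf("more probes than available positions")
  with_seed(seed, {
    per <- largest_remainder(as.numeric(genome), n_probes)
    rows <- lapply(seq_along(genome), function(i) {
      if (per[i] == 0L) return(NULL)
      pos <- sort(sample.int(as.integer(genome[i]), per[i]))
      data.table::data.table(chrom = names(genome)[i], pos = pos)
    })
    dt <- data.table::rbindlist(rows)
    dt[, probe_id := sprintf("cg%06d", seq_len(.N))]
    dt[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    probe_manifest(dt, genome = genome)
  })
}

#' Specification of a synthetic reference cohort
#'
#' @param n_classes Number of classes (controls included).
#' @param samples_per_class Samples per class.
#' @param n_probes Probe-universe size.
#' @param signature_size Probes with class-specific methylation per class;
#'   signature sets are drawn disjointly. 0 produces indistinguishable
#'   classes (the negative control).
#' @param background_meth_prob Probability that a background probe's shared
#'   baseline state is methylated.
#' @param beta_sd Within-class beta noise (clipped Gaussian around class
#'   means 0.1 / 0.9).
#' @param n_control Number of classes flagged as control (non-tumour)
#'   tissue.
#' @param purity_range Range the per-sample tumour fraction is drawn from
#'   (training-cohort purities run roughly 40-85%).
#' @param genome Genome layout the manifest is placed on.
#' @param seed Seed for the whole construction.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_classes = 6L, samples_per_class = 24L,
                        n_probes = 5000L, signature_size = 400L,
                        background_meth_prob = 0.5, beta_sd = 0.08,
                        n_control = 1L, purity_range = c(0.4, 0.85),
                        genome = make_genome(), seed = 1L) {
  stopifnot(n_classes >= 1, samples_per_class >= 1, n_probes >= 1,
            signature_size >= 0, n_control >= 0, n_control <= n_classes,
            signature_size * n_classes <= n_probes)
  assert_scalar_number(background_meth_prob, "background_meth_prob", 0, 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a class-structured synthetic reference cohort
#'
#' All probes share a baseline methylation state; each class deviates from
#' it on its own disjoint signature probe set (class mean beta 0.9 where
#' the deviation is towards methylated, 0.1 towards unmethylated). Sample
#' betas are the class means plus clipped Gaussian noise.
#'
#' @param spec A [cohort_spec()].
#' @return A `reference_cohort` list: `manifest`, `genome`, `betas`,
#'   `profiles` (binarized at 0.6), `labels`, `taxonomy`, `signatures`
#'   (ground-truth probe sets per class), `purity`, `spec`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  manifest <- make_manifest(spec$n_probes, spec$genome,
                            seed = floor(derive_seed(spec$seed, 21L)) %% 2147483647)
  classes <- c(if (spec$n_classes > spec$n_control)
    sprintf("tumour_%02d", seq_len(spec$n_classes - spec$n_control)),
    if (spec$n_control > 0L) sprintf("control_%02d", seq_len(spec$n_control)))
  with_seed(floor(derive_seed(spec$seed, 22L)) %% 2147483647, {
    baseline <- stats::rbinom(spec$n_probes, 1L, spec$background_meth_prob)
    pool <- sample.int(spec$n_probes)  # disjoint signature draw
    signatures <- lapply(seq_along(classes), function(i) {
      if (spec$signature_size == 0L) return(character(0))
      manifest$probe_id[pool[(i - 1L) * spec$signature_size + seq_len(spec$signature_size)]]
    })
    names(signatures) <- classes
    base_beta <- ifelse(baseline == 1L, 0.9, 0.1)
    betas <- list(); labels <- character(0); purity <- numeric(0)
    for (ci in seq_along(classes)) {
      mean_beta <- base_beta
      sig_idx <- match(signatures[[ci]], manifest$probe_id)
      mean_beta[sig_idx] <- ifelse(baseline[sig_idx] == 1L, 0.1, 0.9)
      for (s in seq_len(spec$samples_per_class)) {
        id <- sprintf("%s_s%02d", classes[ci], s)
        b <- pmin(pmax(mean_beta + stats::rnorm(spec$n_probes, 0, spec$beta_sd), 0), 1)
        betas[[id]] <- stats::setNames(b, manifest$probe_id)
        labels[id] <- classes[ci]
        purity[id] <- stats::runif(1, spec$purity_range[1L], spec$purity_range[2L])
      }
    }
  })
  taxonomy <- class_taxonomy(
    classes = classes,
    families = paste0("family_", ceiling(seq_along(classes) / 2)),
    control = grepl("^control", classes))
  structure(list(manifest = manifest, genome = spec$genome, betas = betas,
                 profiles = lapply(betas, binarize_profile),
                 labels = labels, taxonomy = taxonomy,
                 signatures = signatures, purity = purity, spec = spec),
            class = "reference_cohort")
}

#' Simulate a per-read per-site call table from a binary profile
#'
#' Reads are placed exactly as in the run simulator; each covered probe
#' emits one probability call per covering read, drawn near 1 for a
#' methylated call and near 0 for an unmethylated one. Calls are flipped
#' with probability `prob_noise` before the probability is drawn, and a
#' configurable fraction lands in the 0.3-0.7 discard zone. Emulates the
#' 85-90% array/nanopore concordance regime.
#'
#' @param profile Named binary profile.
#' @param manifest,genome Simulation context.
#' @param n_reads Number of reads.
#' @param prob_noise Per-call flip rate.
#' @param discard_frac Fraction of calls drawn inside the dead zone.
#' @param length_model A [read_length_model()].
#' @param seed Seed; deterministic per seed.
#' @return data.table (read_id, chrom, pos, strand, prob), pos 1-based.
#' @export
make_read_calls <- function(profile, manifest, genome, n_reads,
                            prob_noise = 0, discard_frac = 0,
                            length_model = read_length_model(), seed = 1L) {
  assert_scalar_number(prob_noise, "prob_noise", 0, 1)
  assert_scalar_number(discard_frac, "discard_frac", 0, 1)
  st <- align_profile(profile, manifest)
  idx <- probe_index(manifest)
  with_seed(seed, {
    intervals <- sample_reads(genome, length_model, n_reads)
    rows <- list()
    sp <- split(seq_len(nrow(intervals)), intervals$chrom)
    for (chrom in names(sp)) {
      ix <- idx[[chrom]]
      if (is.null(ix)) next
      r <- sp[[chrom]]
      i1 <- findInterval(intervals$start[r] - 1L, ix$pos0) + 1L
      i2 <- findInterval(intervals$end[r] - 1L, ix$pos0)
      keep <- i2 >= i1
      if (!any(keep)) next
      n_hit <- i2[keep] - i1[keep] + 1L
      gi <- ix$gidx[sequence(n_hit, from = i1[keep])]
      rows[[chrom]] <- data.table::data.table(
        read = rep(r[keep], n_hit), probe = gi)
    }
    if (!length(rows))
      return(data.table::data.table(read_id = character(0), chrom = character(0),
                                    pos = integer(0), strand = character(0),
                                    prob = numeric(0)))
    hits <- data.table::rbindlist(rows)
    hits[, state := st[probe]]
    hits <- hits[!is.na(state)]
    flip <- stats::runif(nrow(hits)) < prob_noise
    hits[flip, state := 1L - state]
    in_zone <- stats::runif(nrow(hits)) < discard_frac
    p <- numeric(nrow(hits))
    p[in_zone] <- stats::runif(sum(in_zone), 0.35, 0.65)
    hi <- !in_zone & hits$state == 1L
    lo <- !in_zone & hits$state == 0L
    p[hi] <- stats::runif(sum(hi), 0.75, 1)
    p[lo] <- stats::runif(sum(lo), 0, 0.25)
    data.table::data.table(read_id = sprintf("read_%06d", hits$read),
                           chrom = manifest$chrom[hits$probe],
                           pos = manifest$pos[hits$probe],
                           strand = intervals$strand[hits$read],
                           prob = p)
  })
}

#' Synthetic binned reference coverage track
#'
#' Uniformly placed read starts binned on the CNV grid; stands in for a
#' deeply sequenced reference genome run.
#'
#' @param genome Genome layout.
#' @param n_reads Number of reads.
#' @param bin_bp Bin width.
#' @param seed Seed.
#' @return A `binned_coverage`.
#' @export
make_reference_coverage <- function(genome, n_reads = 5e4, bin_bp = 2e6,
                                    seed = 1L) {
  with_seed(seed, {
    ci <- sample.int(length(genome), n_reads, replace = TRUE,
                     prob = as.numeric(genome))
    pos <- floor(stats::runif(n_reads) * as.numeric(genome)[ci])
    bin_reads(data.table::data.table(chrom = names(genome)[ci], pos = pos),
              genome, bin_bp)
  })
}

#' Write a cohort in the package's exchange formats
#'
#' Beta matrix TSV, manifest TSV, chromosome sizes TSV and a labels TSV,
#' exactly as the readers consume them.
#'
#' @param cohort A `reference_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bm <- data.table::data.table(probe_id = cohort$manifest$probe_id)
  for (s in names(cohort$betas))
    bm[[s]] <- unname(cohort$betas[[s]][bm$probe_id])
  data.table::fwrite(bm, file.path(dir, "betas.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(probe_id = cohort$manifest$probe_id,
                           chromosome = cohort$manifest$chrom,
                           position = cohort$manifest$pos,
                           strand = cohort$manifest$strand),
    file.path(dir, "manifest.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(chrom = names(cohort$genome),
                           length = as.numeric(cohort$genome)),
    file.path(dir, "chrom_sizes.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(
    data.table::data.table(sample = names(cohort$labels),
                           label = unname(cohort$labels),
                           purity = unname(cohort$purity[names(cohort$labels)])),
    file.path(dir, "labels.tsv"), sep = "\t")
  invisible(dir)
}
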