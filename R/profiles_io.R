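# Reading, validating, binarizing and platform-restricting methylation array
# profiles and probe manifests.
#
# Coordinate conventions: manifest positions are 1-based coordinates of the
# targeted CpG cytosine. All internal interval arithmetic is half-open
# 0-based; converters sit at the I/O boundary.

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (chromosome, length), no header required.
#' @return Named numeric vector of chromosome lengths (a genome layout).
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:2,
                          col.names = c("chrom", "length"))
  genome_layout(stats::setNames(as.numeric(dt$length), dt$chrom))
}

#' Construct a genome layout from named chromosome lengths
#'
#' @param lengths Named numeric vector, chromosome -> length in bp.
#' @return Validated named numeric vector of class `genome_layout`.
#' @export
genome_layout <- function(lengths) {
  if (length(lengths) == 0L || is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stopf("genome layout needs named chromosome lengths")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stopf("chromosome lengths must be positive")
  if (anyDuplicated(names(lengths)))
    stopf("duplicate chromosome names in genome layout")
  structure(lengths, class = "genome_layout")
}

#' Read a probe manifest
#'
#' Native format is a TSV with columns `probe_id`, `chromosome`, `position`
#' (1-based cytosine coordinate) and `strand`. BED input (0-based half-open,
#' probe id in the name field) is converted on read.
#'
#' @param path Path to the manifest file.
#' @param format `"tsv"` or `"bed"`.
#' @param genome Optional genome layout; when given, positions are checked
#'   against chromosome bounds.
#' @return A `probe_manifest` (data.table: probe_id, chrom, pos, strand),
#'   sorted by (chrom, pos).
#' @export
read_manifest <- function(path, format = c("tsv", "bed"), genome = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- data.table::fread(path, header = TRUE)
    need <- c("probe_id", "chromosome", "position", "strand")
    if (!all(need %in% names(dt)))
      stopf("manifest must have columns: %s", paste(need, collapse = ", "))
    dt <- dt[, .(probe_id = as.character(probe_id), chrom = as.character(chromosome),
                 pos = as.integer(position), strand = as.character(strand))]
  } else {
    dt <- data.table::fread(path, header = FALSE)
    if (ncol(dt) < 4L) stopf("BED manifest needs at least 4 columns (name = probe id)")
    strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else rep("+", nrow(dt))
    # BED start is 0-based; the cytosine is the first base of the feature
    dt <- data.table::data.table(probe_id = as.character(dt[[4L]]),
                                 chrom = as.character(dt[[1L]]),
                                 pos = as.integer(dt[[2L]]) + 1L,
                                 strand = strand)
  }
  probe_manifest(dt, genome = genome)
}

#' Construct / validate a probe manifest
#'
#' @param dt data.frame with columns probe_id, chrom, pos (1-based), strand.
#' @param genome Optional genome layout for bounds checking.
#' @return Sorted `probe_manifest` data.table.
#' @export
probe_manifest <- function(dt, genome = NULL) {
  dt <- data.table::as.data.table(dt)[, .(probe_id = as.character(probe_id),
                                          chrom = as.character(chrom),
                                          pos = as.integer(pos),
                                          strand = as.character(strand))]
  if (anyDuplicated(dt$probe_id)) stopf("duplicate probe_id in manifest")
  if (any(dt$pos < 1L)) stopf("manifest positions must be >= 1 (1-based)")
  if (!all(dt$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (!is.null(genome)) {
    bad <- !(dt$chrom %in% names(genome)) | dt$pos > genome[dt$chrom]
    if (any(bad))
      stopf("%d manifest probes outside genome bounds (first: %s)",
            sum(bad), dt$probe_id[which(bad)[1L]])
  }
  data.table::setorder(dt, chrom, pos)
  data.table::setattr(dt, "class", c("probe_manifest", class(dt)))
  dt
}

# Per-chromosome lookup index: sorted 0-based cytosine coordinates plus the
# row index into the manifest ordering. Built once and cached by callers.
probe_index <- function(manifest) {
  idx <- attr(manifest, "probe_index", exact = TRUE)
  if (!is.null(idx)) return(idx)
  gidx <- seq_len(nrow(manifest))
  sp <- split(gidx, manifest$chrom)
  idx <- lapply(sp, function(i) list(pos0 = manifest$pos[i] - 1L, gidx = i))
  data.table::setattr(manifest, "probe_index", idx)
  idx
}

#' Load a beta-value matrix as per-sample profiles
#'
#' Delimited text with a header of sample ids; column 1 is `probe_id`. Probes
#' absent from the manifest are dropped (a message reports the count).
#'
#' @param path Path to a TSV/CSV beta matrix.
#' @param manifest A `probe_manifest`; defines the probe universe.
#' @return Named list of beta profiles (named numeric vectors in \[0,1\],
#'   `NA` allowed for missing cells).
#' @export
load_beta_matrix <- function(path, manifest) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L),
                          na.strings = c("NA", ""))
  probe_id <- dt[[1L]]
  if (anyDuplicated(probe_id))
    stopf("duplicate probe_id '%s' in beta matrix", probe_id[anyDuplicated(probe_id)])
  samples <- names(dt)[-1L]
  for (j in samples) {
    v <- dt[[j]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1L]
      stopf("malformed numeric value in column '%s', row '%s'", j, probe_id[bad])
    }
    out <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(out))
      stopf("beta value out of [0,1] in column '%s', row '%s' (value %s)",
            j, probe_id[out[1L]], format(v[out[1L]]))
  }
  keep <- probe_id %in% manifest$probe_id
  if (!all(keep))
    message(sprintf("dropping %d probes absent from the manifest", sum(!keep)))
  if (!any(keep)) stopf("no probes in common with the manifest")
  lapply(stats::setNames(samples, samples), function(j)
    stats::setNames(as.numeric(dt[[j]][keep]), probe_id[keep]))
}

#' Binarize a beta profile
#'
#' Methylated (1) iff beta >= cutoff (cut-off inclusive); missing betas are
#' dropped from the output and behave downstream as never-covered probes.
#'
#' @param beta Named numeric beta profile in \[0,1\] (NA = missing).
#' @param cutoff Binarization cut-off in (0,1); default 0.6.
#' @return Named integer vector of methylation states in \{0,1\}.
#' @export
binarize_profile <- function(beta, cutoff = 0.6) {
  assert_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff >= 1) stopf("'cutoff' must be in (0,1)")
  keep <- !is.na(beta)
  b <- beta[keep]
  if (any(b < 0 | b > 1)) stopf("beta values must lie in [0,1]")
  stats::setNames(as.integer(b >= cutoff), names(beta)[keep])
}

#' Restrict a profile to a probe set
#'
#' @param profile Named vector keyed by probe_id (beta or binary).
#' @param probe_set Character vector of probe ids (e.g. the 450K subset of an
#'   EPIC profile).
#' @return The profile restricted to `names(profile) %in% probe_set`, values
#'   unchanged.
#' @export
restrict_to_platform <- function(profile, probe_set) {
  keep <- names(profile) %in% probe_set
  if (!any(keep)) stopf("profile and probe set share no probes")
  profile[keep]
}

#' Write / read a binary profile as two-column TSV (probe_id, call)
#'
#' @param profile Named integer vector in \{0,1\}.
#' @param path Output path.
#' @export
write_binary_profile <- function(profile, path) {
  data.table::fwrite(data.table::data.table(probe_id = names(profile),
                                            call = as.integer(profile)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_binary_profile
#' @export
read_binary_profile <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(dt$call %in% c(0L, 1L))) stopf("calls must be 0/1")
  stats::setNames(as.integer(dt$call), as.character(dt$probe_id))
}

#' Construct a class taxonomy
#'
#' Maps tumour subclasses to families, flags control (non-tumour) classes,
#' and records merge groups: sets of near-identical subclasses whose scores
#' are summed at prediction time.
#'
#' @param classes Character vector of subclass labels (the model's output
#'   label order).
#' @param families Character vector, same length: family per subclass.
#' @param control Logical vector, same length: TRUE for control classes.
#' @param merge_groups Named list of character vectors; each element is a set
#'   of subclasses merged into one score named after the element.
#' @param relevant Optional logical vector for location-specific collapsing;
#'   classes with FALSE are merged into a single "other" class by
#'   [collapse_taxonomy()].
#' @return A `class_taxonomy` list.
#' @export
class_taxonomy <- function(classes, families, control = rep(FALSE, length(classes)),
                           merge_groups = list(), relevant = rep(TRUE, length(classes))) {
  stopifnot(length(families) == length(classes), length(control) == length(classes),
            length(relevant) == length(classes))
  if (anyDuplicated(classes)) stopf("duplicate class labels")
  members <- unlist(merge_groups, use.names = FALSE)
  if (anyDuplicated(members)) stopf("merge groups must be disjoint")
  if (!all(members %in% classes)) stopf("merge group member not among classes")
  structure(list(classes = as.character(classes), families = as.character(families),
                 control = as.logical(control), merge_groups = merge_groups,
                 relevant = as.logical(relevant)),
            class = "class_taxonomy")
}

#' Collapse a taxonomy for a location-specific model
#'
#' All classes flagged not-relevant are merged into a single `other_label`
#' class (flagged control so it never yields a confident tumour call).
#'
#' @param taxonomy A `class_taxonomy`.
#' @param other_label Label for the collapsed class.
#' @return A new, smaller `class_taxonomy`.
#' @export
collapse_taxonomy <- function(taxonomy, other_label = "other") {
  keep <- taxonomy$relevant
  if (all(keep)) return(taxonomy)
  class_taxonomy(classes = c(taxonomy$classes[keep], other_label),
                 families = c(taxonomy$families[keep], other_label),
                 control = c(taxonomy$control[keep], TRUE),
                 merge_groups = lapply(taxonomy$merge_groups,
                                       function(g) intersect(g, taxonomy$classes[keep])))
}

#' Class labels after merge-group summation
#'
#' @param taxonomy A `class_taxonomy`.
#' @return Character vector of post-merge labels, in stable order.
#' @export
merged_labels <- function(taxonomy) {
  members <- unlist(taxonomy$merge_groups, use.names = FALSE)
  labs <- taxonomy$classes
  out <- character(0)
  done <- character(0)
  for (lab in labs) {
    if (lab %in% members) {
      g <- names(taxonomy$merge_groups)[vapply(taxonomy$merge_groups,
                                               function(x) lab %in% x, logical(1))]
      if (!(g %in% done)) { out <- c(out, g); done <- c(done, g) }
    } else out <- c(out, lab)
  }
  out
}
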