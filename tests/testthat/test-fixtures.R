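test_that("synthetic manifests are unique, in-bounds and seed-deterministic", {
  g <- make_genome(2, 1e6)
  m <- make_manifest(100, g, seed = 3)
  expect_equal(nrow(m), 100L)
  expect_false(anyDuplicated(m$probe_id) > 0)
  expect_true(all(m$pos >= 1 & m$pos <= g[m$chrom]))
  expect_identical(m, make_manifest(100, g, seed = 3))
  expect_false(identical(m$pos, make_manifest(100, g, seed = 4)$pos))
  expect_error(make_manifest(3e6, g), "more probes")
})

test_that("cohorts carry class signatures exactly where constructed", {
  spec <- cohort_spec(n_classes = 3L, samples_per_class = 4L, n_probes = 500L,
                      signature_size = 50L, beta_sd = 0, seed = 9)
  coh <- make_cohort(spec)
  expect_length(coh$profiles, 12L)
  # zero noise: all samples of a class identical
  cls <- coh$taxonomy$classes[1]
  ids <- names(coh$labels)[coh$labels == cls]
  for (id in ids[-1]) expect_identical(coh$betas[[id]], coh$betas[[ids[1]]])
  # binarized centroids differ exactly on the signature probes
  c1 <- binarize_profile(coh$betas[[ids[1]]])
  other <- names(coh$labels)[coh$labels == coh$taxonomy$classes[2]][1]
  c2 <- binarize_profile(coh$betas[[other]])
  diff_probes <- names(c1)[c1 != c2]
  expect_setequal(diff_probes,
                  c(coh$signatures[[1]], coh$signatures[[2]]))
  # signature sets are disjoint
  expect_length(intersect(coh$signatures[[1]], coh$signatures[[2]]), 0)
  # control classes flagged
  expect_true(any(coh$taxonomy$control))
  # zero-signature cohorts are indistinguishable by construction
  neg <- make_cohort(cohort_spec(n_classes = 3L, samples_per_class = 2L,
                                 n_probes = 200L, signature_size = 0L,
                                 beta_sd = 0, seed = 10))
  b1 <- binarize_profile(neg$betas[[1]])
  b2 <- binarize_profile(neg$betas[[5]])
  expect_identical(b1, b2)
})

test_that("written cohorts round-trip through the package readers", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 120L, signature_size = 20L, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"),
                       genome = read_chrom_sizes(file.path(dir, "chrom_sizes.tsv")))
  expect_equal(man$probe_id, coh$manifest$probe_id)
  betas <- load_beta_matrix(file.path(dir, "betas.tsv"), man)
  expect_equal(names(betas), names(coh$betas))
  expect_equal(betas[[1]], coh$betas[[1]], tolerance = 1e-6)
})

test_that("read-call fixtures round-trip through probe mapping and reward voting", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 800L, signature_size = 100L, seed = 13))
  prof <- coh$profiles[[1]]
  # clean calls: probe mapping recovers the profile exactly on covered probes
  clean <- make_read_calls(prof, coh$manifest, coh$genome, n_reads = 2000,
                           prob_noise = 0, discard_frac = 0, seed = 4)
  mapped <- map_calls_to_probes(clean, coh$manifest)
  expect_gt(length(mapped), 0)
  expect_true(all(mapped == prof[names(mapped)]))
  expect_identical(clean, make_read_calls(prof, coh$manifest, coh$genome,
                                          n_reads = 2000, prob_noise = 0,
                                          discard_frac = 0, seed = 4))
  # noisy calls: majority voting lifts probe-level concordance above read level
  noisy <- make_read_calls(prof, coh$manifest, coh$genome, n_reads = 6000,
                           prob_noise = 0.12, discard_frac = 0, seed = 5)
  read_level <- mean(threshold_probability(noisy$prob) ==
                       prof[coh$manifest$probe_id[match(paste(noisy$chrom, noisy$pos),
                                                        paste(coh$manifest$chrom, coh$manifest$pos))]],
                     na.rm = TRUE)
  voted <- map_calls_to_probes(noisy, coh$manifest)
  probe_level <- mean(voted == prof[names(voted)])
  expect_gte(probe_level, read_level)
})

test_that("reference coverage tracks tile the genome and count every read", {
  g <- make_genome(2, 6e6)
  rc <- make_reference_coverage(g, n_reads = 5000, seed = 2)
  expect_equal(sum(rc$count), 5000)
  expect_equal(sum(rc$width), sum(g))
})
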