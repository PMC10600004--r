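test_that("read sampling respects bounds, clips at chromosome ends and is deterministic", {
  g <- tiny_genome()
  lm <- read_length_model()
  expect_equal(nrow(sample_reads(g, lm, 0L, seed = 1)), 0L)
  expect_error(sample_reads(genome_layout(numeric(0)), lm, 1L), "named")

  # fixed 5 kb reads on a 1 kb chromosome: every interval is clipped into
  # [0, 1000) and truncated at the chromosome edge it runs over
  g1 <- genome_layout(c(chrX = 1000))
  lmf <- read_length_model(type = "empirical", lengths = 5000L)
  reads <- sample_reads(g1, lmf, 200L, seed = 3)
  expect_true(all(reads$start >= 0L & reads$end <= 1000L & reads$start < reads$end))
  expect_true(all(reads$start == 0L | reads$end == 1000L))
  expect_true(all((reads$end - reads$start) <= 1000L))

  r1 <- sample_reads(g, lm, 100L, seed = 9)
  r2 <- sample_reads(g, lm, 100L, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$start >= 0 & r1$end <= g[r1$chrom] & r1$start < r1$end))
})

test_that("probe coverage matches a brute-force all-pairs oracle", {
  m <- probe_manifest(data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                                 pos = c(100L, 150L, 151L), strand = "+"))
  iv <- data.table::data.table(chrom = "chr1", start = 50L, end = 150L)
  # 1-based 100 is inside [50,150); 1-based 150 (0-based 149) too; 151 is not
  expect_setequal(covered_probes(iv, m), c("a", "b"))

  set.seed(11)
  man <- tiny_manifest(40, seed = 2)
  for (i in 1:50) {
    n_iv <- sample(0:6, 1)
    iv <- data.table::data.table(
      chrom = sample(names(tiny_genome()), n_iv, replace = TRUE),
      start = sample.int(9e5, n_iv))
    iv[, end := start + sample.int(5e4, n_iv)]
    expect_setequal(covered_probes(iv, man), bf_covered(iv, man))
  }
})

test_that("noise flips are rate-0/rate-1 exact and domain-preserving", {
  calls <- setNames(rep(c(0L, 1L), 50), paste0("p", 1:100))
  expect_identical(apply_noise(calls, 0, seed = 1), calls)
  expect_identical(apply_noise(calls, 1, seed = 1), setNames(1L - calls, names(calls)))
  noisy <- apply_noise(calls, 0.5, seed = 2)
  expect_identical(names(noisy), names(calls))
  expect_true(all(noisy %in% 0:1))
})

test_that("simulated runs are seed-deterministic, faithful at zero noise and differ across seeds", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 400L, signature_size = 50L, seed = 3))
  prof <- coh$profiles[[1]]
  cfg <- sim_config(depth_level = 0.05, noise_rate = 0)
  r1 <- simulate_run(prof, coh$manifest, coh$genome, cfg, seed = 1200)
  r2 <- simulate_run(prof, coh$manifest, coh$genome, cfg, seed = 1200)
  expect_identical(r1, r2)
  expect_true(all(r1$calls == prof[names(r1$calls)]))
  r3 <- simulate_run(prof, coh$manifest, coh$genome, cfg, seed = 1201)
  expect_false(identical(names(r1$calls), names(r3$calls)))
})

test_that("seed roles are disjoint and enforced", {
  pol <- seed_policy()
  expect_length(intersect(pol$test[1]:pol$test[2], pol$validation[1]:pol$validation[2]), 0)
  expect_length(intersect(pol$validation[1]:pol$validation[2], 1000:1999), 0)
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 200L, signature_size = 20L, seed = 4))
  cfg <- sim_config(n_reads = 10L)
  expect_error(simulate_run(coh$profiles[[1]], coh$manifest, coh$genome, cfg,
                            seed = 1200, role = "test"), "outside the test range")
  expect_error(simulate_run(coh$profiles[[1]], coh$manifest, coh$genome, cfg,
                            seed = 300, role = "training"), "outside the training range")
  expect_silent(invisible(simulate_run(coh$profiles[[1]], coh$manifest,
                                       coh$genome, cfg, seed = 300, role = "test")))
})

test_that("mixtures report the purity product and obey the mixture law", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 2000L, signature_size = 600L,
                                 beta_sd = 0, seed = 5))
  tum <- coh$profiles[[1]]
  ctl <- coh$profiles[[length(coh$profiles)]]
  cfg <- sim_config(n_reads = 4000L, noise_rate = 0)
  mix <- simulate_mixture(tum, ctl, control_read_fraction = 0.5,
                          original_tumor_fraction = 0.8, manifest = coh$manifest,
                          genome = coh$genome, config = cfg, seed = 2000)
  expect_equal(mix$provenance$in_silico_purity, 0.4)

  # degenerate mixtures reduce to the pure profiles
  m0 <- simulate_mixture(tum, ctl, 0, 1, manifest = coh$manifest,
                         genome = coh$genome, config = cfg, seed = 2001)
  expect_true(all(m0$calls == tum[names(m0$calls)]))
  m1 <- simulate_mixture(tum, ctl, 1, 1, manifest = coh$manifest,
                         genome = coh$genome, config = cfg, seed = 2002)
  expect_true(all(m1$calls == ctl[names(m1$calls)]))

  # at probes where the two profiles disagree, the fraction of calls that
  # match the control converges to the control read fraction
  dis <- names(tum)[tum != ctl[names(tum)]]
  for (frac in c(0.25, 0.75)) {
    got <- unlist(lapply(1:8, function(i) {
      mm <- simulate_mixture(tum, ctl, frac, 1, manifest = coh$manifest,
                             genome = coh$genome, config = cfg, seed = 2100 + i)
      d <- intersect(names(mm$calls), dis)
      mm$calls[d] == ctl[d]
    }))
    expect_lt(abs(mean(got) - frac), 0.05)
  }
})

test_that("depth series realize their target coverage fractions across all 12 levels", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 5000L, signature_size = 100L, seed = 6))
  cfg <- sim_config()
  runs <- depth_series(coh$profiles[[1]], coh$manifest, coh$genome, cfg,
                       seeds = 1000 + 1:12)
  expect_length(runs, 12L)
  realized <- vapply(runs, function(r) r$provenance$realized_coverage, numeric(1))
  expect_true(all(abs(realized / cfg$depth_levels - 1) < 0.20))
  expect_true(all(diff(vapply(runs, function(r) length(r$calls), numeric(1))) > -50))
})

test_that("runs round-trip through the TSV + JSON sidecar format", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 1L,
                                 n_probes = 300L, signature_size = 30L, seed = 7))
  cfg <- sim_config(depth_level = 0.1)
  run <- simulate_run(coh$profiles[[1]], coh$manifest, coh$genome, cfg, seed = 1010)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_run(run, f)
  back <- read_run(f)
  expect_identical(back$calls, run$calls)
  expect_equal(back$provenance$seed, 1010)
  expect_equal(back$provenance$realized_coverage, run$provenance$realized_coverage)
})
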