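test_that("probability thresholding uses strict 0.3/0.7 cut-offs", {
  expect_equal(threshold_probability(c(0.2, 0.29, 0.3, 0.5, 0.7, 0.71, 1)),
               c(0L, 0L, NA, NA, NA, 1L, 1L))
  expect_error(threshold_probability(1.1), "0,1")
})

test_that("call tables read in native and bedMethyl-like form", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\tchrom\tpos\tstrand\tprob",
               "r1\tchr1\t100\t+\t0.9", "r2\tchr1\t105\t-\t0.1"), f)
  dt <- read_call_table(f)
  expect_equal(dt$pos, c(100L, 105L))
  b <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tr1\t0.9"), b)
  db <- read_call_table(b, format = "bedmethyl")
  expect_equal(db$pos, 100L)  # 0-based BED start converts to 1-based
  expect_equal(db$read_id, "r1")
})

test_that("windowed majority voting follows the read-first tie-discard rules", {
  man <- probe_manifest(data.frame(probe_id = "pA", chrom = "chr1",
                                   pos = 1000L, strand = "+"))
  mk <- function(read, pos, prob)
    data.table::data.table(read_id = read, chrom = "chr1", pos = pos, prob = prob)
  # single in-window methylated call
  expect_equal(map_calls_to_probes(mk("r1", 1000L, 0.9), man), c(pA = 1L))
  # read-level tie -> that read contributes nothing -> probe absent
  expect_length(map_calls_to_probes(mk(c("r1", "r1"), c(990L, 1010L), c(0.9, 0.1)), man), 0)
  # three reads voting M, M, U -> methylated
  expect_equal(map_calls_to_probes(mk(c("r1", "r2", "r3"), rep(1000L, 3),
                                      c(0.9, 0.8, 0.1)), man), c(pA = 1L))
  # probe-level tie discards the probe
  expect_length(map_calls_to_probes(mk(c("r1", "r2"), rep(1000L, 2), c(0.9, 0.1)), man), 0)
  # window boundary: distance 50 is in, 51 is out (100-bp centred window)
  expect_equal(map_calls_to_probes(mk("r1", 1050L, 0.9), man), c(pA = 1L))
  expect_length(map_calls_to_probes(mk("r1", 1051L, 0.9), man), 0)
  # dead-zone calls are discarded before any voting
  expect_length(map_calls_to_probes(mk("r1", 1000L, 0.5), man), 0)
})

test_that("probe mapping equals the brute-force enumeration oracle on random small cases", {
  set.seed(23)
  g <- genome_layout(c(chr1 = 10000))
  for (i in 1:200) {
    n_probes <- sample(1:5, 1)
    man <- probe_manifest(data.frame(
      probe_id = paste0("p", 1:n_probes), chrom = "chr1",
      pos = sort(sample(seq(500L, 2000L, by = 20L), n_probes)), strand = "+"),
      genome = g)
    n_calls <- sample(1:12, 1)
    calls <- data.table::data.table(
      read_id = sample(paste0("r", 1:5), n_calls, replace = TRUE),
      chrom = "chr1",
      pos = sample(seq(450L, 2050L, by = 10L), n_calls, replace = TRUE),
      prob = sample(c(0.05, 0.25, 0.45, 0.65, 0.85, 0.95), n_calls, replace = TRUE))
    got <- map_calls_to_probes(calls, man)
    want <- bf_map_calls(calls, man)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("mapped profiles feed the encoder unchanged", {
  coh <- make_cohort(cohort_spec(n_classes = 2L, samples_per_class = 2L,
                                 n_probes = 300L, signature_size = 40L, seed = 31))
  calls <- make_read_calls(coh$profiles[[1]], coh$manifest, coh$genome,
                           n_reads = 500, prob_noise = 0.05, discard_frac = 0.05,
                           seed = 3)
  prof <- map_calls_to_probes(calls, coh$manifest)
  x <- encode_run(prof, coh$manifest)
  expect_length(x, 300)
  expect_equal(sum(x != 0), length(prof))
})

test_that("target regions merge by gap, clip at ends, cover all probes and are idempotent", {
  g <- genome_layout(c(chr1 = 1e6))
  # 30 kb apart with 5 kb flanks: 20 kb gap <= 25 kb, merged into one region
  m1 <- probe_manifest(data.frame(probe_id = c("a", "b"), chrom = "chr1",
                                  pos = c(100000L, 130000L), strand = "+"), g)
  expect_equal(nrow(build_target_regions(m1, g)), 1L)
  # 40 kb apart: 30 kb gap > 25 kb, two regions
  m2 <- probe_manifest(data.frame(probe_id = c("a", "b"), chrom = "chr1",
                                  pos = c(100000L, 140000L), strand = "+"), g)
  expect_equal(nrow(build_target_regions(m2, g)), 2L)
  # clipping at the chromosome start
  m3 <- probe_manifest(data.frame(probe_id = "a", chrom = "chr1",
                                  pos = 2000L, strand = "+"), g)
  r3 <- build_target_regions(m3, g)
  expect_equal(r3$start, 0)
  expect_equal(r3$end, 7000)

  set.seed(4)
  man <- tiny_manifest(60, seed = 5)
  got <- build_target_regions(man, tiny_genome())
  want <- bf_regions(man, tiny_genome(), 5000, 25000)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # disjoint, sorted, every probe in exactly one region
  expect_true(all(got[, diff(start) > 0, by = chrom]$V1))
  for (i in seq_len(nrow(man))) {
    p0 <- man$pos[i] - 1
    hits <- sum(got$chrom == man$chrom[i] & got$start <= p0 & p0 < got$end)
    expect_equal(hits, 1L)
  }
  # idempotence: merging the merged regions changes nothing
  again <- GenomicRanges::reduce(GenomicRanges::GRanges(
    got$chrom, IRanges::IRanges(got$start + 1, got$end)), min.gapwidth = 25001)
  expect_equal(length(again), nrow(got))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(got, f)
  expect_equal(nrow(data.table::fread(f)), nrow(got))
})
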