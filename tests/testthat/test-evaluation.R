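test_that("stratified folds balance every class and rotate roles completely", {
  labels <- setNames(rep(c("a", "b"), c(8, 7)), paste0("s", 1:15))
  f <- stratified_folds(labels, k = 4, seed = 3)
  counts_a <- table(f$fold[names(labels)[labels == "a"]])
  expect_true(all(counts_a == 2))
  counts_b <- table(factor(f$fold[names(labels)[labels == "b"]], levels = 0:3))
  expect_equal(sort(as.integer(counts_b)), c(1L, 2L, 2L, 2L))
  expect_identical(f$fold, stratified_folds(labels, k = 4, seed = 3)$fold)
  expect_false(identical(f$fold, stratified_folds(labels, k = 4, seed = 4)$fold))
  # each fold is the test fold exactly once across rotations
  test_folds <- vapply(0:3, function(r) fold_roles(f, r)$test, integer(1))
  expect_setequal(test_folds, 0:3)
  for (r in 0:3) {
    roles <- fold_roles(f, r)
    expect_setequal(c(roles$test, roles$validation, roles$train), 0:3)
  }
  expect_error(stratified_folds(labels, k = 1), "k must be")
})

test_that("F1 and TPR follow their closed forms with zero-denominator guards", {
  expect_equal(f1_score(1, 0, 0), 1)
  expect_equal(f1_score(2, 1, 1), 2 / 3)
  expect_equal(f1_score(0, 0, 0), 0)
  expect_equal(tpr(0, 5), 0)
  expect_equal(tpr(3, 1), 0.75)
  expect_equal(tpr(0, 0), 0)
})

test_that("top-k confusion equals exhaustive enumeration on random score sets", {
  set.seed(14)
  for (i in 1:40) {
    K <- sample(3:6, 1); n <- sample(5:25, 1)
    sc <- matrix(runif(n * K), n, K, dimnames = list(NULL, paste0("c", 1:K)))
    labs <- sample(colnames(sc), n, replace = TRUE)
    for (k in c(1, 3)) {
      got <- topk_confusion(sc, labs, k)
      exp <- bf_topk(sc, labs, k)
      expect_equal(got$TP, exp$TP)
      expect_equal(got$FP, exp$FP)
      expect_equal(got$FN, exp$FN)
    }
  }
  # rank rules
  sc <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(topk_confusion(sc, "z", 1)$FN[3], 1L)
  expect_equal(topk_confusion(sc, "z", 3)$TP[3], 1L)
})

test_that("family aggregation sums members and conserves the total", {
  tax <- class_taxonomy(c("a", "b", "c"), c("f1", "f1", "f2"))
  fam <- family_aggregate(c(a = 0.4, b = 0.3, c = 0.3), tax)
  expect_equal(fam, c(f1 = 0.7, f2 = 0.3))
  expect_equal(sum(fam), 1)
  solo <- class_taxonomy(c("a", "b"), c("f1", "f2"))
  expect_equal(unname(family_aggregate(c(a = 0.6, b = 0.4), solo)), c(0.6, 0.4))
})

test_that("pseudotime is a right-continuous step function over the printed thresholds", {
  tab <- pseudotime_table()
  cum <- tab$cumulative
  expect_equal(pseudotime(0), 0)
  expect_equal(pseudotime(cum[1] - 1), 0)
  expect_equal(pseudotime(cum[1]), 5)
  for (i in seq_along(cum)) {
    expect_equal(as.numeric(pseudotime(cum[i] - 1)), (i - 1) * 5)
    expect_equal(as.numeric(pseudotime(cum[i])), i * 5)
    expect_equal(as.numeric(pseudotime(cum[i] + 1)), i * 5)
  }
  # monotone, idempotent on its own thresholds, extrapolation flagged
  grid <- sort(sample.int(max(cum) + 1e5, 500))
  expect_true(all(diff(pseudotime(grid)) >= 0))
  over <- pseudotime(max(cum) + 2.5 * tab$counts[12])
  expect_equal(as.numeric(over), 70)
  expect_true(attr(over, "extrapolated"))
})

test_that("score evaluation tallies partition the samples and match the confusion", {
  tax <- class_taxonomy(c("a", "b", "ctrl"), c("f1", "f2", "f3"),
                        control = c(FALSE, FALSE, TRUE))
  sc <- rbind(c(0.97, 0.02, 0.01),
              c(0.50, 0.45, 0.05),
              c(0.02, 0.96, 0.02),
              c(0.01, 0.02, 0.97))
  colnames(sc) <- tax$classes
  rep <- evaluate_scores(sc, c("a", "a", "a", "b"), tax)
  expect_equal(sum(rep$outcomes), 4L)
  expect_equal(rep$outcomes[["correct_confident"]], 1L)
  expect_equal(rep$outcomes[["wrong_confident"]], 1L)   # row 3: confident 'b', truth 'a'
  expect_equal(rep$outcomes[["unclear"]], 2L)           # below threshold + control-confident
  pc <- rep$per_class
  expect_equal(pc$TP1[pc$class == "a"], 2L)
  expect_equal(pc$FN1[pc$class == "a"], 1L)
  f <- withr::local_tempfile()
  write_eval_report(rep, f)
  expect_true(file.exists(paste0(f, ".tsv")))
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$n, 4)
})

test_that("read-order robustness outcomes partition permutations and reproduce per seed", {
  coh <- make_cohort(cohort_spec(n_classes = 3L, samples_per_class = 4L,
                                 n_probes = 400L, signature_size = 60L, seed = 17))
  calls <- make_read_calls(coh$profiles[[1]], coh$manifest, coh$genome,
                           n_reads = 400, prob_noise = 0, seed = 6)
  thr <- threshold_probability(calls$prob)
  recs <- data.table::data.table(read_id = calls$read_id,
                                 probe_id = coh$manifest$probe_id[
                                   match(paste(calls$chrom, calls$pos),
                                         paste(coh$manifest$chrom, coh$manifest$pos))],
                                 call = thr)[!is.na(call)]
  model <- init_model(model_spec(400, 3), seed = 2,
                      labels = coh$taxonomy$classes, taxonomy = coh$taxonomy)
  n_calls <- nrow(recs)
  tab <- pseudotime_table(counts = rep(ceiling(n_calls / 4), 4))
  out <- robustness_resample(recs, list(model), coh$manifest, coh$taxonomy,
                             true_label = coh$labels[[1]], table = tab,
                             n_perm = 5, seed = 42)
  expect_equal(dim(out), c(5L, 4L))
  expect_true(all(out %in% c("correct_confident", "wrong_confident",
                             "below_threshold")))
  out2 <- robustness_resample(recs, list(model), coh$manifest, coh$taxonomy,
                              true_label = coh$labels[[1]], table = tab,
                              n_perm = 5, seed = 42)
  expect_identical(out, out2)
})
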