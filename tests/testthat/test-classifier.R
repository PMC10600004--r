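test_that("run encoding is +1/-1/0, invertible and rejects unknown probes", {
  man <- probe_manifest(data.frame(probe_id = paste0("p", 1:5), chrom = "chr1",
                                   pos = c(10L, 20L, 30L, 40L, 50L), strand = "+"))
  expect_equal(encode_run(setNames(integer(0), character(0)), man), rep(0, 5))
  x <- encode_run(c(p2 = 1L, p4 = 0L), man)
  expect_equal(x, c(0, 1, 0, -1, 0))
  expect_equal(sum(x != 0), 2)
  expect_error(encode_run(c(zz = 1L), man), "not in the manifest")
  # round trip over all runs covering <= 2 of 5 probes
  for (n_cov in 0:2) for (i in 1:10) {
    probes <- sample(man$probe_id, n_cov)
    calls <- setNames(sample(0:1, n_cov, replace = TRUE), probes)
    calls <- calls[order(match(names(calls), man$probe_id))]
    expect_identical(decode_run(encode_run(calls, man), man), calls)
  }
  # masked encoding doubles the input and separates call from coverage
  xm <- encode_run(c(p2 = 1L, p4 = 0L), man, encoding = "masked")
  expect_length(xm, 10)
  expect_equal(xm[6:10], c(0, 1, 0, 1, 0))
})

test_that("epoch size is max class count times number of classes", {
  expect_equal(epoch_size(rep(c("a", "b", "c"), c(2, 5, 3))), 15L)
  expect_equal(epoch_size("a"), 1L)
  expect_equal(epoch_size(rep(paste0("c", 1:91), c(rep(1, 90), 143)), 91L), 13013L)
})

test_that("balance updates conserve the epoch total, keep a floor and track error order", {
  bs <- balance_state(3, 4, 120)
  expect_equal(sum(bs$alloc), 120L)
  # symmetric errors give a uniform allocation
  b1 <- update_balance(bs, matrix(0.5, 3, 4))
  expect_true(all(b1$alloc == 10L))
  b0 <- update_balance(bs, matrix(0, 3, 4))
  expect_true(all(b0$alloc == 10L))  # the 0.3 floor keeps zero-error cells alive
  # printed-formula example: errors {0.7, .1, .1, .1}, total 100
  b2 <- update_balance(balance_state(2, 2, 100), matrix(c(0.7, 0.1, 0.1, 0.1), 2, 2))
  expect_equal(sum(b2$alloc), 100L)
  expect_true(all(abs(as.vector(b2$alloc) - c(45, 18, 18, 18)) <= 1))
  # allocation is monotone in error and never starves a cell
  set.seed(8)
  for (i in 1:20) {
    err <- matrix(runif(12), 3, 4)
    b <- update_balance(bs, err)
    expect_equal(sum(b$alloc), 120L)
    expect_true(all(b$alloc >= 1L))
    ord <- order(err)
    expect_true(all(diff(b$alloc[ord]) >= -1L))  # up to rounding
  }
})

test_that("checkpoint selection minimizes loss with sensitivity then recency tie-breaks", {
  hist <- list(list(val_loss = 0.9, sensitivity = 0.5, step = 1),
               list(val_loss = 0.5, sensitivity = 0.5, step = 2),
               list(val_loss = 0.7, sensitivity = 0.9, step = 3))
  expect_equal(select_best_checkpoint(hist)$step, 2)
  tie <- list(list(val_loss = 0.5, sensitivity = 0.8, step = 1),
              list(val_loss = 0.5, sensitivity = 0.9, step = 2))
  expect_equal(select_best_checkpoint(tie)$step, 2)
  late <- list(list(val_loss = 0.5, sensitivity = 0.9, step = 1),
               list(val_loss = 0.5, sensitivity = 0.9, step = 7))
  expect_equal(select_best_checkpoint(late)$step, 7)
  expect_equal(select_best_checkpoint(hist[2])$step, 2)
  expect_error(select_best_checkpoint(list()), "empty")
})

test_that("merge groups sum scores and conserve the total", {
  tax <- class_taxonomy(c("a", "b", "c"), c("f", "f", "g"),
                        merge_groups = list(ab = c("a", "b")))
  s <- c(a = 0.3, b = 0.2, c = 0.5)
  m <- merge_scores(s, tax)
  expect_equal(m, c(ab = 0.5, c = 0.5))
  expect_equal(sum(m), 1)
  none <- class_taxonomy(c("a", "b"), c("f", "g"))
  expect_equal(merge_scores(c(a = 0.4, b = 0.6), none), c(a = 0.4, b = 0.6))
})

test_that("the most confident submodel supplies the ensemble prediction", {
  spec <- model_spec(10, 3)
  models <- lapply(1:3, function(i) init_model(spec, seed = i))
  # sharpen model 2 so its maximum dominates
  models[[2]]$temperature <- 0.05
  x <- rnorm(10)
  out <- ensemble_predict(models, x)
  maxima <- vapply(models, function(m) max(predict_scores(m, x)), numeric(1))
  expect_equal(out$model_id, which.max(maxima))
  expect_equal(sum(out$scores), 1, tolerance = 1e-9)
  # identical models tie to the first; a single model is the identity
  same <- list(models[[1]], models[[1]])
  expect_equal(ensemble_predict(same, x)$model_id, 1)
  single <- ensemble_predict(models[1], x)
  expect_equal(single$scores, predict_scores(models[[1]], x)[1, ])
  bad <- init_model(model_spec(11, 3), seed = 1)
  expect_error(ensemble_predict(list(models[[1]], bad), x), "heterogeneous")
})

test_that("location-specific transfer copies hidden layers and re-draws the head", {
  m <- init_model(model_spec(50, 8), seed = 3)
  tax30 <- class_taxonomy(paste0("k", 1:5), rep("f", 5),
                          control = c(rep(FALSE, 4), TRUE))
  s1 <- specialize_model(m, tax30, seed = 10)
  expect_identical(s1$W[[1]], m$W[[1]])
  expect_identical(s1$W[[2]], m$W[[2]])
  expect_equal(ncol(s1$W[[3]]), 5L)
  expect_equal(s1$temperature, 1)
  s2 <- specialize_model(m, tax30, seed = 11)
  expect_false(identical(s1$W[[3]], s2$W[[3]]))
})

test_that("a short curriculum learns a tiny cohort, conserves epoch totals and reproduces", {
  coh <- make_cohort(cohort_spec(n_classes = 4L, samples_per_class = 8L,
                                 n_probes = 600L, signature_size = 80L, seed = 21))
  folds <- stratified_folds(coh$labels, k = 4, seed = 2)
  sch <- training_schedule(batch_size = 8L, epochs = 5L, lr_peak = 1e-2,
                           lr_floor = 2e-3, warmup_batches = 10L, decay_epochs = 5L,
                           checkpoint_every = 10L, val_batches = 2L)
  fit <- train_submodel(coh, folds, 0, sch, stage = "pretrain", seed = 31)
  expect_lt(tail(fit$loss_by_epoch, 1), fit$loss_by_epoch[1])
  # per-epoch simulated-sample conservation across the balance trace
  total <- epoch_size(coh$labels[names(folds$fold)[folds$fold %in% c(2, 3)]],
                      4L)
  for (alloc in fit$balance_trace) expect_equal(sum(alloc), total)
  # determinism end to end
  fit2 <- train_submodel(coh, folds, 0, sch, stage = "pretrain", seed = 31)
  expect_identical(fit$model$W, fit2$model$W)
  # fine-tuning restricts the level grid but still trains
  fine <- training_schedule(batch_size = 8L, epochs = 2L, lr_floor = 2e-3,
                            checkpoint_every = 10L, val_batches = 2L,
                            constant_lr = TRUE)
  fit3 <- train_submodel(coh, folds, 0, fine, stage = "finetune",
                         model = fit$model, seed = 32)
  expect_lte(nrow(fit3$balance_trace[[1]]),
             length(sim_config()$depth_levels))
  expect_error(train_submodel(coh, folds, 0, fine, stage = "finetune"),
               "pretrained")
})

test_that("model archives round-trip with a provenance sidecar", {
  m <- init_model(model_spec(20, 3), seed = 5,
                  taxonomy = class_taxonomy(paste0("c", 1:3), rep("f", 3)))
  m$temperature <- 1.7
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$W, m$W)
  expect_equal(back$temperature, 1.7)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$temperature, 1.7)
  expect_equal(side$input_size, 20)
})
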