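test_that("confusion counts partition the examples", {
  c1 <- confusion(rep(c("I", "O"), c(5L, 5L)), rep(c("I", "O"), c(5L, 5L)))
  expect_equal(unlist(c1[c("TP", "FP", "TN", "FN")]),
               c(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  c2 <- confusion(rep("I", 10L), rep(c("I", "O"), c(2L, 8L)))
  expect_equal(unlist(c2[c("TP", "FP", "TN", "FN")]),
               c(TP = 2L, FP = 8L, TN = 0L, FN = 0L))
  # brute-force recount on a random 200-example case
  prombench:::with_seed(5L, {
    pred <- sample(c("I", "O"), 200L, replace = TRUE)
    truth <- sample(c("I", "O"), 200L, replace = TRUE)
  })
  cc <- confusion(pred, truth)
  expect_equal(cc$TP, sum(pred == "I" & truth == "I"))
  expect_equal(cc$TN, sum(pred == "O" & truth == "O"))
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 200L)
  expect_error(confusion("I", c("I", "O")), "length")
})

test_that("metric formulas match a direct evaluation and flag degeneracies", {
  m1 <- metrics(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(c(m1$Sn, m1$Sp, m1$PPV, m1$MCC), c(1, 1, 1, 1))
  expect_length(m1$undefined, 0L)

  m2 <- metrics(list(TP = 3, FP = 1, TN = 90, FN = 2))
  expect_equal(m2$Sn, 3 / 5)
  expect_equal(m2$Sp, 90 / 91)
  expect_equal(m2$PPV, 3 / 4)
  expect_equal(m2$MCC, (3 * 90 - 1 * 2) / sqrt(4 * 5 * 91 * 92))

  m3 <- metrics(list(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_equal(m3$PPV, 0)
  expect_true("PPV" %in% m3$undefined)

  # predict-all-I on a balanced set: MCC denominator vanishes -> flagged 0
  m4 <- metrics(confusion(rep("I", 20L), rep(c("I", "O"), 10L)))
  expect_equal(m4$MCC, 0)
  expect_true("MCC" %in% m4$undefined)

  # MCC is symmetric under a simultaneous class swap
  cc <- list(TP = 13, FP = 7, TN = 55, FN = 25)
  swapped <- list(TP = cc$TN, FP = cc$FN, TN = cc$TP, FN = cc$FP)
  expect_equal(metrics(cc)$MCC, metrics(swapped)$MCC)
})

test_that("sampling strategies hit the requested ratios", {
  ds <- promoter_dataset(data.frame(
    sequence = c(rand_seqs(100L, 25L, 1L), rand_seqs(10000L, 25L, 2L)),
    tag = rep(c("I", "O"), c(100L, 10000L)), stringsAsFactors = FALSE))
  un <- apply_sampling(ds, "undersample", 10, seed = 3L)
  st <- dataset_stats(un)
  expect_equal(st$n_promoter, 100L)
  expect_equal(st$n_nonpromoter, 1000L)
  # undersampling never touches promoter content
  expect_setequal(subset(un$windows, tag == "I")$sequence,
                  subset(ds$windows, tag == "I")$sequence)

  ov <- apply_sampling(ds, "oversample", 10, seed = 3L)
  sto <- dataset_stats(ov)
  expect_equal(sto$n_promoter, 1000L)
  expect_equal(sto$n_nonpromoter, 10000L)
  # duplicated promoters are copies of originals; negatives untouched
  expect_true(all(subset(ov$windows, tag == "I")$sequence %in%
                    subset(ds$windows, tag == "I")$sequence))
  expect_setequal(subset(ov$windows, tag == "O")$sequence,
                  subset(ds$windows, tag == "O")$sequence)

  expect_identical(apply_sampling(ds, "normal")$windows, ds$windows)
  only_o <- promoter_dataset(data.frame(sequence = rand_seqs(5L, 25L, 4L),
                                        tag = rep("O", 5L),
                                        stringsAsFactors = FALSE))
  expect_error(apply_sampling(only_o, "undersample"), "no promoter")
})

test_that("stratified batch order preserves class proportions per batch", {
  tags <- rep(c("I", "O"), c(30L, 70L))
  prombench:::with_seed(2L, ord <- prombench:::stratified_order(tags))
  expect_setequal(ord, seq_along(tags))
  for (b in seq(1L, 100L, by = 10L)) {
    n_i <- sum(tags[ord[b:(b + 9L)]] == "I")
    expect_true(abs(n_i - 3L) <= 1L)
  }
})

test_that("training improves a separable problem and is reproducible", {
  ds <- tiny_planted_dataset(60L, 60L, 7L)
  cfg <- training_config(max_epochs = 12L, patience = 12L, seed = 3L,
                         batch_size = 16L)
  m1 <- train(build_model(tiny_cnn_spec(), seed = 3L), ds, cfg)
  expect_true(m1$trained)
  expect_gte(max(m1$history$val_mcc), 0.5)
  # early-stop bookkeeping: training never runs more than patience epochs
  # past the best epoch
  expect_lte(nrow(m1$history), m1$best_epoch + cfg$patience)
  # determinism: identical config + seed => identical run log and weights
  m2 <- train(build_model(tiny_cnn_spec(), seed = 3L), ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  empty <- promoter_dataset(data.frame(sequence = character(0),
                                       tag = character(0)))
  expect_error(train(build_model(tiny_cnn_spec(), seed = 1L), empty, cfg),
               "empty")
  one_class <- promoter_dataset(data.frame(
    sequence = rand_seqs(12L, 60L, 1L), tag = rep("O", 12L),
    stringsAsFactors = FALSE))
  expect_error(train(build_model(tiny_cnn_spec(), seed = 1L), one_class,
                     cfg), "both classes|no promoter")
})

test_that("training writes loadable best checkpoints", {
  ds <- tiny_planted_dataset(40L, 40L, 9L)
  dir <- file.path(tempdir(), "ckpt_test")
  unlink(dir, recursive = TRUE)
  cfg <- training_config(max_epochs = 4L, patience = 4L, seed = 5L,
                         checkpoint_dir = dir)
  m <- train(build_model(tiny_cnn_spec(), seed = 5L), ds, cfg)
  files <- list.files(dir, full.names = TRUE)
  expect_gte(length(files), 1L)
  best <- load_checkpoint(sort(files)[length(files)])
  expect_identical(best$params, m$params)
})

test_that("stratified k-fold CV partitions the data and reports t-intervals", {
  ds <- tiny_planted_dataset(30L, 30L, 11L)
  cfg <- training_config(max_epochs = 4L, patience = 4L, seed = 2L,
                         batch_size = 16L)
  cv <- kfold_cv(tiny_cnn_spec(), ds, k = 3L, config = cfg)
  expect_equal(nrow(cv$folds), 3L)
  # fold assignment partitions the dataset, stratified by class
  expect_equal(sort(unique(cv$fold_assignment)), 1:3)
  expect_equal(length(cv$fold_assignment), 60L)
  for (f in 1:3) {
    expect_equal(sum(cv$fold_assignment == f &
                       ds$windows$tag == "I"), 10L)
  }
  # the confidence interval equals an independent Student-t computation
  for (met in c("Sn", "Sp", "PPV", "MCC")) {
    x <- cv$folds[[met]]
    half <- stats::qt(0.995, df = 2L) * stats::sd(x) / sqrt(3L)
    row <- cv$ci[cv$ci$metric == met, ]
    expect_equal(row$lower, mean(x) - half, tolerance = 1e-12)
    expect_equal(row$upper, mean(x) + half, tolerance = 1e-12)
    expect_true(mean(x) >= row$lower && mean(x) <= row$upper)
  }
  expect_error(kfold_cv(tiny_cnn_spec(), ds, k = 1L), "k >= 2")
  small <- promoter_dataset(ds$windows[c(1:2, 31:32), ])
  expect_error(kfold_cv(tiny_cnn_spec(), small, k = 3L), "at least")
})

test_that("zero-variance fold scores give a degenerate interval", {
  # interval arithmetic on constant scores: CI collapses onto the mean
  x <- rep(0.9, 5L)
  half <- stats::qt(0.995, df = 4L) * stats::sd(x) / sqrt(5L)
  expect_equal(mean(x) - half, 0.9)
  expect_equal(mean(x) + half, 0.9)
})

test_that("cross-testing evaluates every compatible cell like a direct run", {
  m60 <- build_model(tiny_cnn_spec(), seed = 1L)
  m60b <- build_model(tiny_dprom_spec(), seed = 2L)
  d1 <- tiny_planted_dataset(15L, 15L, 1L)
  d2 <- tiny_planted_dataset(10L, 20L, 2L)
  d300 <- make_planted_dataset(5L, 5L, 3L)
  ct <- cross_test(list(a = m60, b = m60b),
                   list(x = d1, y = d2, z = d300))
  expect_equal(nrow(ct), 6L)
  expect_equal(sum(!ct$compatible), 2L)  # both models reject 300-base data
  for (r in which(ct$compatible)) {
    mod <- list(a = m60, b = m60b)[[ct$model[r]]]
    ds <- list(x = d1, y = d2, z = d300)[[ct$dataset[r]]]
    pred <- predict(mod, ds$windows$sequence)
    met <- metrics(confusion(pred$tag, ds$windows$tag))
    expect_equal(ct$MCC[r], met$MCC)
    expect_equal(ct$PPV[r], met$PPV)
  }
  expect_true(all(is.na(ct$MCC[!ct$compatible])))
})
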