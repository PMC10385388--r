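test_that("accuracy is the proportion of exact matches", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(1:5, c(2, 3, 4, 5, 1)), 0)
  expect_equal(accuracy(c(1, 1, 2, 2, 3), c(1, 2, 2, 2, 3)), 0.8)
  expect_error(accuracy(1:3, 1:4), "mismatch")
  expect_error(accuracy(integer(0), integer(0)), "empty")
})

test_that("confusion matrix counts and identities hold", {
  cm <- confusion_matrix(c(1, 2, 3, 1), c(1, 2, 3, 1), n_classes = 3)
  expect_equal(diag(cm), c(2L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(cm), 4L)
  expect_error(confusion_matrix(c(1, 8), c(1, 1)), "out of range")
  # brute-force one-vs-rest identities on a random 200-sample prediction
  set.seed(99)
  yt <- sample(1:7, 200, replace = TRUE)
  yp <- ifelse(runif(200) < 0.7, yt, sample(1:7, 200, replace = TRUE))
  cm <- confusion_matrix(yt, yp)
  ovr <- one_vs_rest(cm)
  for (k in 1:7) {
    expect_equal(ovr$TP[k], sum(yt == k & yp == k))
    expect_equal(ovr$FN[k], sum(yt == k & yp != k))
    expect_equal(ovr$FP[k], sum(yt != k & yp == k))
    expect_equal(ovr$TN[k], sum(yt != k & yp != k))
    expect_equal(ovr$TP[k] + ovr$FN[k], sum(cm[k, ]))
    expect_equal(ovr$TP[k] + ovr$FP[k], sum(cm[, k]))
  }
  # accuracy == trace(confusion)/N
  expect_equal(accuracy(yt, yp), sum(diag(cm)) / sum(cm))
})

test_that("per-phase report mirrors the study's table layout", {
  ds <- tiny_dataset(3L, seed = 91L)
  split <- list(test = seq_len(n_samples(ds)))
  y <- as.integer(ds$labels)
  # perfect classifier: every cell and mean is 1
  rep1 <- per_phase_report(NULL, ds, split, predictions = y)
  expect_true(all(rep1$table == 1))
  expect_true(all(rep1$row_means == 1))
  expect_true(all(rep1$phase_accuracy == 1))
  expect_equal(rep1$overall_accuracy, 1)
  # wrong only on 2020-June Medicago sativa: only that cell drops
  ph <- mhcgt:::dataset_phases(ds)
  bad <- y == 1 & ph == "2020-June"
  preds <- y; preds[bad] <- 2L
  rep2 <- per_phase_report(NULL, ds, split, predictions = preds)
  expect_equal(rep2$table["Medicago sativa", "2020-June"], 0)
  expect_true(all(rep2$table[-1, ] == 1))
  expect_true(all(rep2$table[1, -1] == 1))
  expect_equal(rep2$row_means[["Medicago sativa"]], 0.75)
  # row mean is the arithmetic mean of that row's cells
  expect_equal(unname(rep2$row_means), unname(rowMeans(rep2$table)))
  # per-phase accuracies aggregate to the overall accuracy by test counts
  counts <- table(ph)[names(rep2$phase_accuracy)]
  expect_equal(sum(rep2$phase_accuracy * as.numeric(counts)) / sum(counts),
               rep2$overall_accuracy)
})

test_that("a phase absent from the test set is undefined, not zero", {
  ds <- tiny_dataset(2L, seed = 92L)
  ph <- mhcgt:::dataset_phases(ds)
  y <- as.integer(ds$labels)
  keep <- !(y == 3 & ph == "2021-August")
  split <- list(test = which(keep))
  rep <- per_phase_report(NULL, ds, split, predictions = y[keep])
  expect_true(is.na(rep$table["Elymus canadensis", "2021-August"]))
  expect_false(anyNA(rep$table[-3, ]))
})

test_that("ablation table is reproducible with correct sizes", {
  ds <- tiny_dataset(5L, seed = 93L, smooth = TRUE)
  tc <- train_config(epochs = 2L, seed = 94L)
  t1 <- ablation_study(ds, model_config(), tc, fractions = c(0.3, 0.7), reps = 1L,
                       seed = 95L)
  t2 <- ablation_study(ds, model_config(), tc, fractions = c(0.3, 0.7), reps = 1L,
                       seed = 95L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(t1$fraction, c(0.3, 0.7))
  expect_equal(t1$n_train, round(c(0.3, 0.7) * n_samples(ds)))
  expect_equal(t1$n_train + t1$n_test, rep(n_samples(ds), 2L))
  expect_true(all(t1$mean_accuracy >= 0 & t1$mean_accuracy <= 1))
  expect_error(ablation_study(ds, fractions = c(0, 0.5)), "strictly between")
})

test_that("compare_methods validates methods and is deterministic", {
  ds <- tiny_dataset(5L, seed = 96L, smooth = TRUE)
  plan <- stratified_shuffle_split(ds$labels, 0.7, n_iterations = 2, seed = 97)
  expect_error(compare_methods(ds, plan, methods = c("MHCgT", "XGBoost")),
               "XGBoost.*valid methods")
  tc <- train_config(epochs = 2L, seed = 98L)
  t1 <- compare_methods(ds, plan, methods = c("MHCgT", "DT"), train_cfg = tc)
  expect_equal(nrow(t1), 2L)
  expect_equal(t1$method, c("MHCgT", "DT"))
  t2 <- compare_methods(ds, plan, methods = c("MHCgT", "DT"), train_cfg = tc)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "per_iteration"), attr(t2, "per_iteration"))
  # single-method call gives a one-row table
  t3 <- compare_methods(ds, plan, methods = "DT", train_cfg = tc)
  expect_equal(nrow(t3), 1L)
})
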