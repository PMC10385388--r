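test_that("stratified splits have exact sizes and per-class balance", {
  labels <- rep(1:7, each = 2400)       # the balanced 16,800-record design
  sp <- stratified_shuffle_split(labels, 0.1, n_iterations = 2, seed = 3)
  it <- sp$iterations[[1]]
  expect_length(it$train, 1680L)
  expect_length(it$test, 15120L)
  expect_true(all(table(labels[it$train]) == 240L))
  expect_length(intersect(it$train, it$test), 0L)
  # deterministic given the seed
  sp2 <- stratified_shuffle_split(labels, 0.1, n_iterations = 2, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp$iterations[[1]]$train, sp$iterations[[2]]$train))
})

test_that("stratification holds within one sample on unbalanced labels", {
  set.seed(17)
  labels <- factor(rep(c("a", "b", "c"), times = c(23, 41, 36)))
  for (f in c(0.2, 0.5, 0.77)) {
    sp <- stratified_shuffle_split(labels, f, n_iterations = 3, seed = 5)
    for (it in sp$iterations) {
      expect_length(it$train, round(f * length(labels)))
      got <- table(labels[it$train])
      expect_true(all(abs(got - f * table(labels)) <= 1))
      expect_length(intersect(it$train, it$test), 0L)
      expect_setequal(c(it$train, it$test), seq_along(labels))
    }
  }
})

test_that("split validation rejects impossible requests", {
  expect_error(stratified_shuffle_split(integer(0), 0.5), "non-empty")
  expect_error(stratified_shuffle_split(c(1, 1, 2), 0.5), "at least 2")
  expect_error(stratified_shuffle_split(rep(1:2, c(100, 2)), 0.004), "without train")
  expect_error(stratified_shuffle_split(rep(1:2, 5), 0), "strictly between")
  expect_error(stratified_shuffle_split(rep(1:2, 5), 1), "strictly between")
})

test_that("train_config enforces its invariants", {
  expect_error(train_config(learning_rate = 0), "positive")
  expect_error(train_config(beta1 = 1), "beta")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(early_stop_patience = 0), "patience")
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$beta2, 0.98)
  expect_equal(cfg$batch_size, 125L)
})

test_that("checkpoint selection maximizes accuracy with loss tie-break", {
  h <- data.frame(val_acc = c(0.5, 0.8, 0.8, 0.7),
                  val_loss = c(1.0, 0.6, 0.4, 0.9))
  expect_equal(select_checkpoint(h), 3L)      # tie on acc -> smaller loss
  h2 <- data.frame(val_acc = c(0.9, 0.9), val_loss = c(0.5, 0.5))
  expect_equal(select_checkpoint(h2), 1L)     # full tie -> earliest
  h3 <- data.frame(val_acc = c(0.2, 0.9, 0.6), val_loss = c(1, 2, 0.1))
  expect_equal(select_checkpoint(h3), 2L)     # accuracy dominates loss
})

test_that("engine gradients agree with finite differences", {
  cfg <- model_config(num_heads = 2, key_dim = 3, ff_dim = 3, num_blocks = 2,
                      mlp_units = 5, num_classes = 4, seq_len = 7, num_vars = 1,
                      dropout = 0, mlp_dropout = 0)
  m <- build_model(cfg, seed = 14)
  set.seed(15)
  for (b in seq_along(m$blocks)) {
    m$blocks[[b]]$ln1$beta[1] <- rnorm(1)
    m$blocks[[b]]$ln2$beta[1] <- rnorm(1)
    m$blocks[[b]]$ff$b1 <- rnorm(cfg$ff_dim)
  }
  ep <- mhcgt:::engine_params(m)
  pe <- as.numeric(m$pe[, 1])
  X <- matrix(runif(4 * 7), 4, 7)
  y <- c(1, 2, 3, 4)
  g <- mhcgt:::engine_grad(ep, X, y, pe, 0, 0)
  lossfun <- function(e) mhcgt:::engine_grad(e, X, y, pe, 0, 0)$loss
  fd <- function(get, set) {
    eps <- 1e-6
    (lossfun(set(ep, get(ep) + eps)) - lossfun(set(ep, get(ep) - eps))) / (2 * eps)
  }
  expect_equal(fd(function(e) e$head$W1[3, 2],
                  function(e, v) { e$head$W1[3, 2] <- v; e }),
               g$grads$head$W1[3, 2], tolerance = 1e-5)
  expect_equal(fd(function(e) e$head$b2[2],
                  function(e, v) { e$head$b2[2] <- v; e }),
               g$grads$head$b2[2], tolerance = 1e-5)
  expect_equal(fd(function(e) e$blocks[[1]]$beta1,
                  function(e, v) { e$blocks[[1]]$beta1 <- v; e }),
               g$grads$blocks[[1]]$beta1, tolerance = 1e-5)
  expect_equal(fd(function(e) e$blocks[[2]]$Vw[2, 3],
                  function(e, v) { e$blocks[[2]]$Vw[2, 3] <- v; e }),
               g$grads$blocks[[2]]$Vw[2, 3], tolerance = 1e-5)
  expect_equal(fd(function(e) e$blocks[[1]]$beta2,
                  function(e, v) { e$blocks[[1]]$beta2 <- v; e }),
               g$grads$blocks[[1]]$beta2, tolerance = 1e-5)
  expect_equal(fd(function(e) e$blocks[[2]]$Ow[1, 2],
                  function(e, v) { e$blocks[[2]]$Ow[1, 2] <- v; e }),
               g$grads$blocks[[2]]$Ow[1, 2], tolerance = 1e-5)
})

test_that("training is reproducible and improves the loss", {
  ds <- tiny_dataset(10L, seed = 51L, smooth = TRUE)
  sp <- stratified_shuffle_split(ds$labels, 0.8, 1, seed = 52)$iterations[[1]]
  cfg <- train_config(epochs = 10L, seed = 53L)
  f1 <- train_model(build_model(model_config(), seed = 54), ds, sp, cfg)
  f2 <- train_model(build_model(model_config(), seed = 54), ds, sp, cfg)
  expect_identical(f1$history, f2$history)
  h <- f1$history
  expect_gt(median(h$loss[1:3]), median(h$loss[(nrow(h) - 2):nrow(h)]))
  # the retained checkpoint is never dominated by an earlier epoch
  expect_equal(h$val_acc[attr(h, "selected_epoch")], max(h$val_acc))
  expect_error(train_model(build_model(model_config(), seed = 1), ds,
                           list(train = integer(0), test = sp$test), cfg),
               "empty train")
})

test_that("early stopping truncates the history under a tight patience", {
  ds <- tiny_dataset(4L, seed = 61L, smooth = TRUE)
  sp <- stratified_shuffle_split(ds$labels, 0.8, 1, seed = 62)$iterations[[1]]
  fit <- train_model(build_model(model_config(), seed = 63), ds, sp,
                     train_config(epochs = 50L, early_stop_patience = 2L, seed = 63))
  h <- fit$history
  expect_lte(nrow(h), 50L)
  if (nrow(h) < 50L) {
    k <- nrow(h)   # last two epochs did not improve on the running best
    expect_lte(h$val_acc[k], max(h$val_acc[1:(k - 1)]))
  }
})

test_that("run_repeated is reproducible and aggregates correctly", {
  ds <- tiny_dataset(6L, seed = 71L, smooth = TRUE)
  plan <- stratified_shuffle_split(ds$labels, 0.7, n_iterations = 2, seed = 72)
  cfg <- train_config(epochs = 3L, seed = 73L)
  r1 <- run_repeated(ds, model_config(), cfg, plan)
  r2 <- run_repeated(ds, model_config(), cfg, plan)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_equal(r1$mean_accuracy, mean(r1$accuracies))
  expect_equal(r1$sd_accuracy, sd(r1$accuracies))
  expect_length(r1$runs, 2L)
  expect_s3_class(r1$runs[[1]]$confusion, "confusion_counts")
})

test_that("the mhcgt() front door fits, predicts and exposes methods", {
  ds <- tiny_dataset(8L, seed = 81L)
  fit <- mhcgt(ds, train_fraction = 0.75,
               control = train_config(epochs = 4L, seed = 82L))
  expect_s3_class(fit, "mhcgt")
  expect_true(fit$accuracy >= 0 && fit$accuracy <= 1)
  pred <- predict(fit, ds[1:5])
  expect_s3_class(pred, "factor")
  expect_length(pred, 5L)
  probs <- predict(fit, ds[1:5], type = "prob")
  expect_equal(dim(probs), c(5L, 7L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
  expect_output(print(fit), "held-out accuracy")
  expect_output(print(summary(fit)), "Confusion matrix")
  expect_type(coef(fit), "list")
  r <- residuals(fit)
  expect_true(all(r %in% c(0L, 1L)))
  expect_equal(mean(r), 1 - fit$accuracy, tolerance = 1e-12)
})
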