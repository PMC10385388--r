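#' Training configuration
#'
#' Optimizer and schedule settings.  Defaults are the tuned values of the
#' study design: Adam with learning rate 1e-3, beta1 0.9, beta2 0.98,
#' epsilon 1e-9, batch size 125, 20 epochs, early stopping with patience 10.
#'
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param batch_size minibatch size (last partial batch is kept).
#' @param epochs maximum number of epochs.
#' @param early_stop_patience epochs without validation-accuracy improvement
#'   before stopping.
#' @param seed integer seed for batch order, dropout masks, and splits
#'   derived from it.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.98,
                         epsilon = 1e-9, batch_size = 125L, epochs = 20L,
                         early_stop_patience = 10L, seed = 1L) {
  if (learning_rate <= 0 || epsilon <= 0) stop("rates must be positive")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in (0, 1)")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (early_stop_patience < 1L) stop("early_stop_patience must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Select the checkpoint epoch from a training history
#'
#' The retained model is the epoch with the highest validation accuracy;
#' ties are broken by the smallest validation loss (earliest such epoch if
#' still tied).
#'
#' @param history data frame with `val_acc` and `val_loss` columns.
#' @return integer row index of the selected epoch.
#' @export
select_checkpoint <- function(history) {
  order(-history$val_acc, history$val_loss, seq_len(nrow(history)))[1L]
}

#' Train the transformer on one train/validation split
#'
#' Minimizes categorical cross-entropy with Adam, reshuffling batches every
#' epoch, evaluating the held-out set after each epoch, stopping early when
#' validation accuracy has not improved for `early_stop_patience` epochs, and
#' returning the checkpoint chosen by [select_checkpoint()].  Fully
#' reproducible from `cfg$seed` (single-threaded).
#'
#' @param model an `mhcgt_model` (univariate input, `M = 1`).
#' @param ds a [spectral_dataset()], normally already smoothed.
#' @param split list with integer `train` and `test` index vectors (e.g. one
#'   iteration of a [stratified_shuffle_split()] plan); the held-out set also
#'   serves as the validation set.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (the fitted `mhcgt_model` at the selected
#'   checkpoint) and `history` (per-epoch `loss`, `acc`, `val_loss`,
#'   `val_acc`, with attribute `selected_epoch`).
#' @export
train_model <- function(model, ds, split, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "mhcgt_model"), inherits(ds, "spectral_dataset"))
  if (model$config$num_vars != 1L)
    stop("the training engine supports univariate (M = 1) models")
  if (length(split$train) == 0L) stop("empty train set")
  x <- spectra_matrix(ds)
  y <- as.integer(ds$labels)
  if (max(y) > model$config$num_classes)
    stop("dataset has more classes than the model's num_classes")
  xtr <- x[split$train, , drop = FALSE]; ytr <- y[split$train]
  xva <- x[split$test, , drop = FALSE]; yva <- y[split$test]
  pe <- as.numeric(model$pe[, 1L])
  p_drop <- model$config$dropout
  p_mlp <- model$config$mlp_dropout

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  ep <- engine_params(model)
  st <- adam_init(ep)
  n_tr <- nrow(xtr)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, loss = Inf, ep = ep, epoch = 0L)
  monitor_best <- -Inf
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = cfg$batch_size)
    tot_loss <- 0; tot_correct <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n_tr)]
      g <- engine_grad(ep, xtr[idx, , drop = FALSE], ytr[idx], pe, p_drop, p_mlp)
      if (!is.finite(g$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      upd <- adam_step(ep, g$grads, st, cfg$learning_rate, cfg$beta1,
                       cfg$beta2, cfg$epsilon)
      ep <- upd$theta; st <- upd$state
      tot_loss <- tot_loss + g$loss * length(idx)
      tot_correct <- tot_correct + g$acc * length(idx)
    }
    pv <- engine_forward(ep, xva, pe)
    val_loss <- -mean(log(pmax(pv[cbind(seq_along(yva), yva)], 1e-12)))
    val_acc <- mean(max.col(pv, ties.method = "first") == yva)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = tot_loss / n_tr,
                                   acc = tot_correct / n_tr,
                                   val_loss = val_loss, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f",
                      epoch, tot_loss / n_tr, tot_correct / n_tr, val_loss, val_acc))
    if (val_acc > best$acc || (val_acc == best$acc && val_loss < best$loss)) {
      best <- list(acc = val_acc, loss = val_loss, ep = ep, epoch = epoch)
    }
    if (val_acc > monitor_best) {
      monitor_best <- val_acc
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  attr(hist, "selected_epoch") <- best$epoch
  class(hist) <- c("mhcgt_history", "data.frame")
  list(model = set_engine_params(model, best$ep), history = hist)
}

#' @export
print.mhcgt_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs, checkpoint at epoch %d (val_acc %.4f)\n",
              nrow(x), attr(x, "selected_epoch"),
              x$val_acc[attr(x, "selected_epoch")]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Repeated training over a split plan
#'
#' Trains one independently initialized model per split iteration (model
#' seeds derived from `train_cfg$seed` plus the iteration index), retains
#' per-iteration test metrics and reports their mean and SD.
#'
#' @param ds a [spectral_dataset()] (normally smoothed).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param split_plan a [stratified_shuffle_split()] plan.
#' @param verbose print per-epoch lines.
#' @return object of class `"mhcgt_repeat"`: list of per-iteration `runs`
#'   (model, history, test_accuracy, test_loss, confusion) plus
#'   `mean_accuracy` and `sd_accuracy`.
#' @export
run_repeated <- function(ds, model_cfg = model_config(),
                         train_cfg = train_config(), split_plan,
                         verbose = FALSE) {
  stopifnot(inherits(split_plan, "split_plan"))
  x <- spectra_matrix(ds)
  y <- as.integer(ds$labels)
  runs <- vector("list", split_plan$n_iterations)
  for (it in seq_len(split_plan$n_iterations)) {
    sp <- split_plan$iterations[[it]]
    seed_it <- derive_seed(train_cfg$seed, it)
    model <- build_model(model_cfg, seed = seed_it)
    cfg_it <- train_cfg; cfg_it$seed <- seed_it
    fit <- tryCatch(train_model(model, ds, sp, cfg_it, verbose = verbose),
                    error = function(e)
                      stop(sprintf("iteration %d failed: %s", it, conditionMessage(e))))
    pv <- engine_forward(engine_params(fit$model), x[sp$test, , drop = FALSE],
                         as.numeric(fit$model$pe[, 1L]))
    pred <- max.col(pv, ties.method = "first")
    runs[[it]] <- list(model = fit$model, history = fit$history,
                       test_accuracy = accuracy(y[sp$test], pred),
                       test_loss = -mean(log(pmax(pv[cbind(seq_along(sp$test), y[sp$test])], 1e-12))),
                       confusion = confusion_matrix(y[sp$test], pred,
                                                    n_classes = model_cfg$num_classes))
  }
  accs <- vapply(runs, `[[`, 0, "test_accuracy")
  structure(list(runs = runs, accuracies = accs,
                 mean_accuracy = mean(accs),
                 sd_accuracy = if (length(accs) > 1L) sd(accs) else 0),
            class = "mhcgt_repeat")
}

#' @export
print.mhcgt_repeat <- function(x, ...) {
  cat(sprintf("Repeated evaluation: %d runs, mean test accuracy %.4f (SD %.4f)\n",
              length(x$runs), x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}
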