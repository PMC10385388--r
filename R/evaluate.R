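#' Classification accuracy
#'
#' Proportion of exact label matches — the micro-averaged accuracy
#' `(TP + TN) / (TP + TN + FP + FN)` of the one-vs-rest counts, equal to
#' `trace(confusion) / N`.
#'
#' @param y_true,y_pred equal-length, non-empty label vectors.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("accuracy: empty label vectors")
  if (length(y_true) != length(y_pred))
    stop(sprintf("accuracy: length mismatch (%d vs %d)", length(y_true), length(y_pred)))
  mean(as.character(y_true) == as.character(y_pred))
}

#' Confusion matrix
#'
#' Rows are actual classes, columns predicted classes; entry `(r, c)` counts
#' samples of class `r` predicted as `c`.
#'
#' @param y_true,y_pred integer labels in `1..n_classes` (factors are taken
#'   by their level index).
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix of class
#'   `"confusion_counts"`.
#' @seealso [one_vs_rest()]
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 7L) {
  to_int <- function(y) if (is.factor(y)) as.integer(y) else as.integer(y)
  y_true <- to_int(y_true); y_pred <- to_int(y_pred)
  if (length(y_true) != length(y_pred))
    stop("confusion_matrix: length mismatch")
  bad <- c(y_true, y_pred)
  if (any(bad < 1L | bad > n_classes))
    stop("confusion_matrix: labels out of range 1..", n_classes)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(actual = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  structure(cm, class = c("confusion_counts", "matrix"))
}

#' One-vs-rest counts per class
#'
#' Derives per-class TP, FP, FN, TN from a confusion matrix.
#'
#' @param cm a [confusion_matrix()].
#' @return data frame with one row per class.
#' @export
one_vs_rest <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  data.frame(class = seq_len(nrow(cm)), TP = tp, FP = fp, FN = fn,
             TN = n - tp - fp - fn, row.names = NULL)
}

#' Per-species, per-phase accuracy report
#'
#' Evaluates a fitted model on the test indices of a split and tabulates
#' accuracy by species (rows) and acquisition phase (columns), with the
#' per-species row mean ("average accuracy") and the per-phase overall
#' accuracy, mirroring the standard multi-temporal report layout.  A
#' (species, phase) cell with no test samples is `NA`, not zero.
#'
#' @param model a fitted `mhcgt_model` (or `NULL` when `predictions` given).
#' @param ds the evaluated [spectral_dataset()].
#' @param split list with a `test` integer index vector.
#' @param predictions optional integer predictions for `ds` (full length or
#'   one per test index), bypassing the model.
#' @return object of class `"mhcgt_phase_report"`: list with `table` (species
#'   x phase accuracies), `row_means`, `phase_accuracy`, `overall_accuracy`,
#'   `confusion`, and per-phase confusion matrices.
#' @export
per_phase_report <- function(model, ds, split, predictions = NULL) {
  idx <- split$test
  y <- as.integer(ds$labels)[idx]
  if (is.null(predictions)) {
    stopifnot(inherits(model, "mhcgt_model"))
    pv <- engine_forward(engine_params(model),
                         spectra_matrix(ds)[idx, , drop = FALSE],
                         as.numeric(model$pe[, 1L]))
    pred <- max.col(pv, ties.method = "first")
  } else {
    pred <- as.integer(predictions)
    if (length(pred) == n_samples(ds)) pred <- pred[idx]
    if (length(pred) != length(idx))
      stop("predictions must cover the dataset or exactly the test indices")
  }
  phases <- phase_keys()
  ph <- dataset_phases(ds)[idx]
  n_cls <- nlevels(ds$labels)
  tab <- matrix(NA_real_, n_cls, length(phases),
                dimnames = list(levels(ds$labels), phases))
  for (k in seq_len(n_cls)) for (j in seq_along(phases)) {
    sel <- y == k & ph == phases[j]
    if (any(sel)) tab[k, j] <- mean(pred[sel] == y[sel])
  }
  phase_acc <- vapply(phases, function(p) {
    sel <- ph == p
    if (any(sel)) mean(pred[sel] == y[sel]) else NA_real_
  }, 0)
  per_phase_cm <- lapply(phases, function(p) {
    sel <- ph == p
    if (any(sel)) confusion_matrix(y[sel], pred[sel], n_cls) else NULL
  })
  names(per_phase_cm) <- phases
  structure(list(table = tab,
                 row_means = rowMeans(tab, na.rm = TRUE),
                 phase_accuracy = phase_acc,
                 overall_accuracy = mean(pred == y),
                 confusion = confusion_matrix(y, pred, n_cls),
                 per_phase_confusion = per_phase_cm),
            class = "mhcgt_phase_report")
}

#' @export
print.mhcgt_phase_report <- function(x, ...) {
  cat("Per-species / per-phase accuracy (%):\n")
  out <- cbind(x$table, `Average` = x$row_means) * 100
  print(round(out, 2))
  cat("Per-phase overall accuracy (%): ",
      paste(sprintf("%s %.2f", names(x$phase_accuracy), 100 * x$phase_accuracy),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("Overall accuracy: %.2f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' Training-fraction ablation study
#'
#' Sweeps the training fraction, at each fraction drawing `reps` stratified
#' splits, training one independently initialized model per split, and
#' averaging test loss and accuracy — the standard check that a
#' transformer-style model needs a large training share.
#'
#' @param ds a smoothed [spectral_dataset()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param fractions training fractions in (0, 1).
#' @param reps runs per fraction (default 5).
#' @param seed base seed; per-fraction seeds are derived deterministically.
#' @return data frame of class `"mhcgt_ablation"`: fraction, train/test
#'   sizes, mean loss, mean and SD of accuracy.
#' @export
ablation_study <- function(ds, model_cfg = model_config(),
                           train_cfg = train_config(),
                           fractions = seq(0.1, 0.9, by = 0.1), reps = 5L,
                           seed = train_cfg$seed) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly between 0 and 1")
  rows <- lapply(fractions, function(f) {
    sp <- stratified_shuffle_split(ds$labels, f, n_iterations = reps,
                                   seed = derive_seed(seed, round(1000 * f)))
    cfg_f <- train_cfg; cfg_f$seed <- derive_seed(seed, round(1000 * f) + 1L)
    rr <- tryCatch(run_repeated(ds, model_cfg, cfg_f, sp),
                   error = function(e)
                     stop(sprintf("ablation at fraction %.2f failed: %s",
                                  f, conditionMessage(e))))
    data.frame(fraction = f,
               n_train = length(sp$iterations[[1L]]$train),
               n_test = sp$n - length(sp$iterations[[1L]]$train),
               mean_loss = mean(vapply(rr$runs, `[[`, 0, "test_loss")),
               mean_accuracy = rr$mean_accuracy,
               sd_accuracy = rr$sd_accuracy)
  })
  structure(do.call(rbind, rows), class = c("mhcgt_ablation", "data.frame"))
}

#' Compare the transformer against baseline classifiers
#'
#' Runs each requested method on every iteration of a split plan and reports
#' the mean and SD of test accuracy.  Baselines use the fixed settings of the
#' comparison protocol: SVM cost `C = 1.0`; decision tree and random forest
#' maximum depth 10; the neural methods 20 epochs with batch size 125.
#'
#' @param ds a smoothed [spectral_dataset()].
#' @param split a [stratified_shuffle_split()] plan (the comparison protocol
#'   uses a 10% test share and 5 iterations).
#' @param methods subset of `"MHCgT"`, `"CNN-1D"`, `"LSTM-RNN"`, `"SVM"`,
#'   `"RF"`, `"DT"`.
#' @param model_cfg transformer [model_config()].
#' @param train_cfg transformer [train_config()].
#' @param seed base seed for the baselines.
#' @return data frame of class `"mhcgt_comparison"`: method, mean and SD of
#'   accuracy, plus per-iteration accuracies as an attribute.
#' @export
compare_methods <- function(ds, split,
                            methods = c("MHCgT", "CNN-1D", "LSTM-RNN", "SVM", "RF", "DT"),
                            model_cfg = model_config(),
                            train_cfg = train_config(),
                            seed = train_cfg$seed) {
  valid <- c("MHCgT", "CNN-1D", "LSTM-RNN", "SVM", "RF", "DT")
  bad <- setdiff(methods, valid)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid methods are: ", paste(valid, collapse = ", "))
  x <- spectra_matrix(ds)
  y <- as.integer(ds$labels)
  n_cls <- nlevels(ds$labels)
  per_method <- lapply(methods, function(m) {
    accs <- vapply(seq_len(split$n_iterations), function(it) {
      sp <- split$iterations[[it]]
      seed_it <- derive_seed(seed, 100L * it + match(m, valid))
      if (m == "MHCgT") {
        cfg_it <- train_cfg; cfg_it$seed <- seed_it
        fit <- train_model(build_model(model_cfg, seed = seed_it), ds, sp, cfg_it)
        pv <- engine_forward(engine_params(fit$model), x[sp$test, , drop = FALSE],
                             as.numeric(fit$model$pe[, 1L]))
        pred <- max.col(pv, ties.method = "first")
      } else {
        fit <- fit_baseline(m, x[sp$train, , drop = FALSE], y[sp$train],
                            n_classes = n_cls, seed = seed_it,
                            epochs = 20L, batch_size = 125L)
        pred <- predict(fit, x[sp$test, , drop = FALSE])
      }
      accuracy(y[sp$test], pred)
    }, 0)
    c(mean = mean(accs), sd = if (length(accs) > 1L) sd(accs) else 0, accs)
  })
  out <- data.frame(method = methods,
                    mean_accuracy = vapply(per_method, `[[`, 0, "mean"),
                    sd_accuracy = vapply(per_method, `[[`, 0, "sd"))
  attr(out, "per_iteration") <- lapply(per_method, function(p) unname(p[-(1:2)]))
  structure(out, class = c("mhcgt_comparison", "data.frame"))
}

#' @export
print.mhcgt_comparison <- function(x, ...) {
  cat("Method comparison (mean accuracy over split iterations):\n")
  df <- data.frame(method = x$method,
                   `accuracy %` = sprintf("%.2f", 100 * x$mean_accuracy),
                   `SD %` = sprintf("%.2f", 100 * x$sd_accuracy),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.mhcgt_ablation <- function(x, ...) {
  cat("Training-fraction ablation (mean over repetitions):\n")
  df <- data.frame(fraction = sprintf("%.0f%%", 100 * x$fraction),
                   train = x$n_train, test = x$n_test,
                   loss = sprintf("%.4f", x$mean_loss),
                   `accuracy %` = sprintf("%.2f", 100 * x$mean_accuracy),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
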