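#' Fit the transformer spectral classifier
#'
#' One-call front door for the full protocol: Savitzky-Golay smoothing, a
#' stratified train/test split, model construction, Adam training with early
#' stopping and best-checkpoint selection, and held-out evaluation.
#'
#' @param ds a [spectral_dataset()] of raw reflectance spectra.
#' @param train_fraction training share in (0, 1) (default 0.9, the
#'   protocol's 10% test share).
#' @param model a [model_config()].
#' @param control a [train_config()].
#' @param smoothing a [smoothing_config()], or `NULL` to skip smoothing.
#' @param seed integer seed governing split, initialization and training.
#' @param verbose print per-epoch lines.
#' @return object of class `"mhcgt"`: the fitted model, training history,
#'   held-out accuracy, confusion matrix and per-phase report.
#' @examples
#' \donttest{
#' ds <- generate_dataset(generator_config(samples_per_class_phase = 30, seed = 1))
#' fit <- mhcgt(ds, train_fraction = 0.8,
#'              control = train_config(epochs = 5, seed = 1))
#' fit
#' }
#' @export
mhcgt <- function(ds, train_fraction = 0.9, model = model_config(),
                  control = train_config(), smoothing = smoothing_config(),
                  seed = control$seed, verbose = FALSE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  dss <- if (is.null(smoothing)) ds else smooth_dataset(ds, smoothing)
  plan <- stratified_shuffle_split(dss$labels, train_fraction,
                                   n_iterations = 1L,
                                   seed = derive_seed(seed, 17L))
  split <- plan$iterations[[1L]]
  net <- build_model(model, seed = derive_seed(seed, 29L))
  control$seed <- derive_seed(seed, 43L)
  fit <- train_model(net, dss, split, control, verbose = verbose)
  pv <- engine_forward(engine_params(fit$model),
                       spectra_matrix(dss)[split$test, , drop = FALSE],
                       as.numeric(fit$model$pe[, 1L]))
  pred <- max.col(pv, ties.method = "first")
  report <- per_phase_report(fit$model, dss, split, predictions = pred)
  structure(list(model = fit$model, history = fit$history,
                 test_predicted = pred,
                 test_actual = as.integer(dss$labels)[split$test],
                 split = split, train_fraction = train_fraction,
                 accuracy = report$overall_accuracy,
                 confusion = report$confusion,
                 phase_report = report,
                 smoothing = smoothing,
                 levels = levels(dss$labels),
                 seed = seed,
                 call = match.call()),
            class = "mhcgt")
}

#' @export
print.mhcgt <- function(x, ...) {
  cat("Transformer spectral classifier fit\n")
  print(x$model)
  h <- x$history
  cat(sprintf("Trained %d epochs (checkpoint at epoch %d); held-out accuracy %.2f%% on %d spectra\n",
              nrow(h), attr(h, "selected_epoch"), 100 * x$accuracy,
              length(x$split$test)))
  invisible(x)
}

#' @export
summary.mhcgt <- function(object, ...) {
  structure(list(fit = object), class = "summary.mhcgt")
}

#' @export
print.summary.mhcgt <- function(x, ...) {
  print(x$fit)
  cat("\nConfusion matrix (rows = actual, columns = predicted):\n")
  print(unclass(x$fit$confusion))
  cat("\n")
  print(x$fit$phase_report)
  invisible(x)
}

#' @export
coef.mhcgt <- function(object, ...) {
  list(head = object$model$head,
       blocks = lapply(object$model$blocks, function(b)
         list(ln1 = b$ln1, attention = b$attn, ln2 = b$ln2, ff = b$ff)))
}

#' Predict species from spectra
#'
#' Applies the fit's smoothing configuration to the new spectra (unless
#' `smooth = FALSE`) and runs the fitted network.
#'
#' @param object an [mhcgt()] fit.
#' @param newdata a [spectral_dataset()] or numeric `N x S` reflectance
#'   matrix.
#' @param type `"class"` for species labels, `"prob"` for the softmax matrix.
#' @param smooth apply the training-time smoothing to `newdata`.
#' @param ... unused.
#' @return factor of predicted species, or an `N x num_classes` probability
#'   matrix.
#' @export
predict.mhcgt <- function(object, newdata, type = c("class", "prob"),
                          smooth = TRUE, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "spectral_dataset")) spectra_matrix(newdata)
       else as.matrix(newdata)
  if (smooth && !is.null(object$smoothing))
    x <- t(apply(x, 1L, savgol_smooth, cfg = object$smoothing))
  p <- engine_forward(engine_params(object$model), x,
                      as.numeric(object$model$pe[, 1L]))
  if (type == "prob") {
    colnames(p) <- object$levels
    return(p)
  }
  factor(object$levels[max.col(p, ties.method = "first")], levels = object$levels)
}

#' Plot training curves
#'
#' Loss and accuracy per epoch for the training and validation sets, with
#' the selected checkpoint marked.
#'
#' @param x an [mhcgt()] fit.
#' @param ... unused.
#' @export
plot.mhcgt <- function(x, ...) {
  h <- x$history
  sel <- attr(h, "selected_epoch")
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$loss, h$val_loss)), main = "loss")
  lines(h$epoch, h$val_loss, lty = 2)
  abline(v = sel, col = "grey60")
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n", cex = 0.8)
  plot(h$epoch, h$acc, type = "l", xlab = "epoch", ylab = "accuracy",
       ylim = range(c(h$acc, h$val_acc)), main = "accuracy")
  lines(h$epoch, h$val_acc, lty = 2)
  abline(v = sel, col = "grey60")
  invisible(x)
}

#' Residuals of a classifier fit
#'
#' For a classifier the natural residual is the misclassification indicator
#' on the held-out set (0 = correct, 1 = wrong).
#'
#' @param object an [mhcgt()] fit.
#' @param ... unused.
#' @export
residuals.mhcgt <- function(object, ...) {
  as.integer(object$test_predicted != object$test_actual)
}
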