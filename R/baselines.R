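# Baseline classifiers for the method-comparison harness.  None of the usual
# implementations (rpart, randomForest, e1071, a deep-learning framework) are
# available as dependencies here, so minimal conventional versions are
# implemented natively: a gini CART (compiled), bagged CART with per-node
# feature subsampling, a linear one-vs-rest squared-hinge SVM, a small 1-D
# CNN and an LSTM trained with the package's Adam.  Their architectures are
# repo choices pinned for reproducibility, not claims about any external
# reference implementation.

#' Fit a baseline classifier
#'
#' Dispatches to one of the comparison-harness baselines with the protocol's
#' fixed settings (SVM `C = 1.0`, trees depth 10, neural baselines trained
#' `epochs` x `batch_size`).
#'
#' @param method one of `"CNN-1D"`, `"LSTM-RNN"`, `"SVM"`, `"RF"`, `"DT"`.
#' @param x numeric `N x S` feature (spectra) matrix.
#' @param y integer labels `1..n_classes`.
#' @param n_classes number of classes.
#' @param seed integer seed.
#' @param epochs,batch_size schedule for the neural baselines.
#' @return fitted baseline of class `"mhcgt_baseline"`, with a
#'   [predict.mhcgt_baseline()] method returning integer labels.
#' @export
fit_baseline <- function(method, x, y, n_classes, seed = 1L,
                         epochs = 20L, batch_size = 125L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  fit <- switch(method,
    "DT" = fit_cart(x, y, n_classes, max_depth = 10L),
    "RF" = fit_forest(x, y, n_classes, max_depth = 10L, n_trees = 100L),
    "SVM" = fit_linear_svm(x, y, n_classes, C = 1.0),
    "CNN-1D" = fit_cnn1d(x, y, n_classes, epochs = epochs, batch_size = batch_size),
    "LSTM-RNN" = fit_lstm(x, y, n_classes, epochs = epochs, batch_size = batch_size),
    stop("unknown baseline method: ", method))
  structure(list(method = method, fit = fit), class = "mhcgt_baseline")
}

#' @export
print.mhcgt_baseline <- function(x, ...) {
  cat("Baseline classifier: ", x$method, "\n", sep = "")
  invisible(x)
}

#' Predict with a fitted baseline
#' @param object a [fit_baseline()] result.
#' @param newdata numeric `N x S` matrix.
#' @param ... unused.
#' @return integer predicted labels.
#' @export
predict.mhcgt_baseline <- function(object, newdata, ...) {
  switch(object$method,
    "DT" = predict_cart(object$fit, newdata),
    "RF" = predict_forest(object$fit, newdata),
    "SVM" = predict_linear_svm(object$fit, newdata),
    "CNN-1D" = predict_cnn1d(object$fit, newdata),
    "LSTM-RNN" = predict_lstm(object$fit, newdata))
}

# --- decision tree / random forest ------------------------------------------

fit_cart <- function(x, y, n_classes, max_depth = 10L, mtry = 0L) {
  cart_fit(as.matrix(x), as.integer(y) - 1L, n_classes,
           max_depth = as.integer(max_depth), min_samples_split = 2L,
           mtry = as.integer(mtry))
}

predict_cart <- function(tree, x) cart_predict(tree, as.matrix(x)) + 1L

fit_forest <- function(x, y, n_classes, max_depth = 10L, n_trees = 100L,
                       mtry = max(1L, floor(sqrt(ncol(x))))) {
  n <- nrow(x)
  trees <- lapply(seq_len(n_trees), function(b) {
    boot <- sample.int(n, n, replace = TRUE)
    cart_fit(as.matrix(x)[boot, , drop = FALSE], as.integer(y)[boot] - 1L,
             n_classes, max_depth = as.integer(max_depth),
             min_samples_split = 2L, mtry = as.integer(mtry))
  })
  list(trees = trees, n_classes = n_classes)
}

predict_forest <- function(fit, x) {
  votes <- matrix(0L, nrow(x), fit$n_classes)
  for (tr in fit$trees) {
    p <- cart_predict(tr, as.matrix(x)) + 1L
    votes[cbind(seq_len(nrow(x)), p)] <- votes[cbind(seq_len(nrow(x)), p)] + 1L
  }
  max.col(votes, ties.method = "first")
}

# --- linear SVM (one-vs-rest, squared hinge, BFGS) --------------------------

fit_linear_svm <- function(x, y, n_classes, C = 1.0) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl < 1e-8] <- 1
  xs <- scale(x, ctr, scl)
  n <- nrow(xs)
  w_list <- lapply(seq_len(n_classes), function(k) {
    yy <- ifelse(as.integer(y) == k, 1, -1)
    obj <- function(wb) {
      w <- wb[-length(wb)]; b <- wb[length(wb)]
      m <- pmax(0, 1 - yy * (xs %*% w + b))
      0.5 * sum(w^2) + C * sum(m^2)
    }
    grad <- function(wb) {
      w <- wb[-length(wb)]; b <- wb[length(wb)]
      m <- pmax(0, 1 - yy * (as.numeric(xs %*% w) + b))
      gw <- w - 2 * C * as.numeric(crossprod(xs, yy * m))
      gb <- -2 * C * sum(yy * m)
      c(gw, gb)
    }
    optim(numeric(ncol(xs) + 1L), obj, grad, method = "BFGS",
          control = list(maxit = 200))$par
  })
  list(W = do.call(cbind, lapply(w_list, function(w) w[-length(w)])),
       b = vapply(w_list, function(w) w[length(w)], 0),
       center = ctr, scale = scl)
}

predict_linear_svm <- function(fit, x) {
  xs <- scale(as.matrix(x), fit$center, fit$scale)
  scores <- sweep(xs %*% fit$W, 2L, fit$b, `+`)
  max.col(scores, ties.method = "first")
}

# --- shared pieces for the neural baselines ---------------------------------

onehot <- function(y, n_classes) {
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y)] <- 1
  m
}

ce_loss_grad <- function(logits, y) {
  p <- softmax_rows(logits)
  iy <- cbind(seq_len(nrow(p)), y)
  list(loss = -mean(log(pmax(p[iy], 1e-12))),
       dlogits = (p - onehot(y, ncol(p))) / nrow(p))
}

# im2col for 1-D convolution: (B, S, Cin) array -> (B*(S-k+1), k*Cin) matrix,
# rows ordered sample-major within each output position (column-filled).
im2col1d <- function(a, k) {
  B <- dim(a)[1L]; S <- dim(a)[2L]; cin <- dim(a)[3L]
  P <- S - k + 1L
  out <- matrix(0, B * P, k * cin)
  col <- 0L
  for (c in seq_len(cin)) for (j in seq_len(k)) {
    col <- col + 1L
    out[, col] <- as.numeric(a[, j:(j + P - 1L), c])
  }
  out
}

# scatter-add the im2col gradient back to the input array
col2im1d <- function(dcol, B, S, cin, k) {
  P <- S - k + 1L
  da <- array(0, c(B, S, cin))
  col <- 0L
  for (c in seq_len(cin)) for (j in seq_len(k)) {
    col <- col + 1L
    da[, j:(j + P - 1L), c] <- da[, j:(j + P - 1L), c] +
      matrix(dcol[, col], B, P)
  }
  da
}

maxpool2 <- function(a) {
  B <- dim(a)[1L]; S <- dim(a)[2L]; cc <- dim(a)[3L]
  P <- S %/% 2L
  a1 <- a[, seq(1L, 2L * P, by = 2L), , drop = FALSE]
  a2 <- a[, seq(2L, 2L * P, by = 2L), , drop = FALSE]
  list(out = pmax(a1, a2), first = a1 >= a2, P = P)
}

maxpool2_back <- function(dout, pool, S) {
  B <- dim(dout)[1L]; cc <- dim(dout)[3L]
  da <- array(0, c(B, S, cc))
  da[, seq(1L, 2L * pool$P, by = 2L), ] <- dout * pool$first
  da[, seq(2L, 2L * pool$P, by = 2L), ] <- dout * (!pool$first)
  da
}

# --- 1-D CNN: conv5x32 - pool2 - conv5x64 - pool2 - GAP - dense -------------

cnn_forward <- function(th, x, y = NULL) {
  B <- nrow(x); S <- ncol(x)
  a0 <- array(x, c(B, S, 1L))
  c1 <- im2col1d(a0, 5L)
  z1 <- sweep(c1 %*% th$W1, 2L, th$b1, `+`)
  r1 <- array(pmax(z1, 0), c(B, S - 4L, ncol(th$W1)))
  p1 <- maxpool2(r1)
  c2 <- im2col1d(p1$out, 5L)
  z2 <- sweep(c2 %*% th$W2, 2L, th$b2, `+`)
  r2 <- array(pmax(z2, 0), c(B, p1$P - 4L, ncol(th$W2)))
  p2 <- maxpool2(r2)
  g <- apply(p2$out, c(1L, 3L), mean)
  logits <- sweep(g %*% th$W3, 2L, th$b3, `+`)
  if (is.null(y)) return(list(logits = logits))
  lg <- ce_loss_grad(logits, y)
  gr <- list(W3 = crossprod(g, lg$dlogits), b3 = colSums(lg$dlogits))
  dg <- tcrossprod(lg$dlogits, th$W3)
  P2 <- p2$P
  dp2 <- array(0, dim(p2$out))
  for (cc in seq_len(dim(dp2)[3L])) dp2[, , cc] <- dg[, cc] / P2
  dr2 <- maxpool2_back(dp2, p2, dim(r2)[2L])
  dz2 <- matrix(dr2, B * dim(r2)[2L], dim(r2)[3L]) * (z2 > 0)
  gr$W2 <- crossprod(c2, dz2); gr$b2 <- colSums(dz2)
  dc2 <- tcrossprod(dz2, th$W2)
  dp1 <- col2im1d(dc2, B, p1$P, dim(r1)[3L], 5L)
  dr1 <- maxpool2_back(dp1, p1, dim(r1)[2L])
  dz1 <- matrix(dr1, B * dim(r1)[2L], dim(r1)[3L]) * (z1 > 0)
  gr$W1 <- crossprod(c1, dz1); gr$b1 <- colSums(dz1)
  list(loss = lg$loss, grads = gr)
}

fit_cnn1d <- function(x, y, n_classes, epochs = 20L, batch_size = 125L,
                      filters = c(32L, 64L), lr = 1e-3) {
  th <- list(W1 = he_uniform(5, 5L, filters[1L]), b1 = numeric(filters[1L]),
             W2 = he_uniform(5 * filters[1L], 5L * filters[1L], filters[2L]),
             b2 = numeric(filters[2L]),
             W3 = he_uniform(filters[2L], filters[2L], n_classes),
             b3 = numeric(n_classes))
  st <- adam_init(th)
  n <- nrow(x)
  for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      fb <- cnn_forward(th, x[idx, , drop = FALSE], y[idx])
      upd <- adam_step(th, fb$grads, st, lr, 0.9, 0.98, 1e-9)
      th <- upd$theta; st <- upd$state
    }
  }
  th
}

predict_cnn1d <- function(th, x)
  max.col(cnn_forward(th, as.matrix(x))$logits, ties.method = "first")

# --- LSTM: 64 recurrent units over the band sequence, final state - dense ---

sigm <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(th, x, y = NULL) {
  B <- nrow(x); S <- ncol(x); H <- nrow(th$U)
  hs <- array(0, c(B, H, S + 1L))
  cs <- array(0, c(B, H, S + 1L))
  gates <- vector("list", S)
  for (t in seq_len(S)) {
    g <- matrix(x[, t]) %*% th$W + hs[, , t] %*% th$U
    g <- sweep(g, 2L, th$b, `+`)
    i <- sigm(g[, 1:H]); f <- sigm(g[, H + 1:H])
    o <- sigm(g[, 2 * H + 1:H]); a <- tanh(g[, 3 * H + 1:H])
    cs[, , t + 1L] <- f * cs[, , t] + i * a
    hs[, , t + 1L] <- o * tanh(cs[, , t + 1L])
    gates[[t]] <- list(i = i, f = f, o = o, a = a)
  }
  hT <- hs[, , S + 1L, drop = FALSE]
  dim(hT) <- c(B, H)
  logits <- sweep(hT %*% th$V, 2L, th$bv, `+`)
  if (is.null(y)) return(list(logits = logits))
  lg <- ce_loss_grad(logits, y)
  gr <- list(W = matrix(0, 1L, 4L * H), U = matrix(0, H, 4L * H),
             b = numeric(4L * H), V = crossprod(hT, lg$dlogits),
             bv = colSums(lg$dlogits))
  dh <- tcrossprod(lg$dlogits, th$V)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(S))) {
    gt <- gates[[t]]
    ct <- cs[, , t + 1L]; dim(ct) <- c(B, H)
    cprev <- cs[, , t]; dim(cprev) <- c(B, H)
    hprev <- hs[, , t]; dim(hprev) <- c(B, H)
    tc <- tanh(ct)
    do_ <- dh * tc
    dc <- dc + dh * gt$o * (1 - tc^2)
    di <- dc * gt$a; da <- dc * gt$i; df <- dc * cprev
    dgi <- di * gt$i * (1 - gt$i)
    dgf <- df * gt$f * (1 - gt$f)
    dgo <- do_ * gt$o * (1 - gt$o)
    dga <- da * (1 - gt$a^2)
    dg <- cbind(dgi, dgf, dgo, dga)
    gr$W <- gr$W + x[, t] %*% dg
    gr$U <- gr$U + crossprod(hprev, dg)
    gr$b <- gr$b + colSums(dg)
    dh <- tcrossprod(dg, th$U)
    dc <- dc * gt$f
  }
  list(loss = lg$loss, grads = gr)
}

fit_lstm <- function(x, y, n_classes, units = 64L, epochs = 20L,
                     batch_size = 125L, lr = 1e-3) {
  H <- as.integer(units)
  th <- list(W = he_uniform(1, 1L, 4L * H),
             U = he_uniform(H, H, 4L * H),
             b = c(numeric(H), rep(1, H), numeric(2L * H)),  # forget bias 1
             V = he_uniform(H, H, n_classes),
             bv = numeric(n_classes))
  st <- adam_init(th)
  n <- nrow(x)
  for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      fb <- lstm_forward(th, x[idx, , drop = FALSE], y[idx])
      # global-norm gradient clipping keeps long-sequence BPTT stable
      gn <- sqrt(tree_sum(tree_map(fb$grads, function(g) sum(g^2))))
      if (is.finite(gn) && gn > 5)
        fb$grads <- tree_map(fb$grads, function(g) g * (5 / gn))
      upd <- adam_step(th, fb$grads, st, lr, 0.9, 0.98, 1e-9)
      th <- upd$theta; st <- upd$state
    }
  }
  th
}

predict_lstm <- function(th, x)
  max.col(lstm_forward(th, as.matrix(x))$logits, ties.method = "first")
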