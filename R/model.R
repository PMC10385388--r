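#' Model configuration
#'
#' Hyperparameters of the transformer classifier.  Defaults are the tuned
#' settings of the study design: 8 attention heads with per-head dimension
#' 256, feed-forward width 64, 4 directly connected encoder blocks, a
#' 125-unit MLP head with dropout 0.4, dropout 0.25 inside the blocks,
#' 125-band univariate input and 7 species classes.  This configuration has
#' exactly 74,768 trainable parameters.
#'
#' @param num_heads number of attention heads `n`.
#' @param key_dim per-head query/key/value dimension `D_k`.
#' @param ff_dim hidden width of the convolutional feed-forward part.
#' @param num_blocks number of encoder blocks.
#' @param mlp_units hidden width of the classification head.
#' @param mlp_dropout dropout rate in the head.
#' @param dropout dropout rate after attention and inside the feed-forward.
#' @param num_classes number of output classes.
#' @param seq_len sequence length `S` (spectral bands).
#' @param num_vars variables per step `M`.
#' @return object of class `"model_config"`.
#' @export
model_config <- function(num_heads = 8L, key_dim = 256L, ff_dim = 64L,
                         num_blocks = 4L, mlp_units = 125L,
                         mlp_dropout = 0.4, dropout = 0.25,
                         num_classes = 7L, seq_len = 125L, num_vars = 1L) {
  cfg <- list(num_heads = as.integer(num_heads), key_dim = as.integer(key_dim),
              ff_dim = as.integer(ff_dim), num_blocks = as.integer(num_blocks),
              mlp_units = as.integer(mlp_units), mlp_dropout = mlp_dropout,
              dropout = dropout, num_classes = as.integer(num_classes),
              seq_len = as.integer(seq_len), num_vars = as.integer(num_vars))
  counts <- c("num_heads", "key_dim", "ff_dim", "mlp_units", "seq_len", "num_vars")
  for (f in counts)
    if (cfg[[f]] < 1L) stop("model_config: ", f, " must be positive")
  if (cfg$num_blocks < 0L) stop("model_config: num_blocks must be >= 0")
  if (cfg$num_classes < 2L) stop("model_config: num_classes must be >= 2")
  for (f in c("mlp_dropout", "dropout"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) stop("model_config: ", f, " must lie in [0, 1)")
  structure(cfg, class = "model_config")
}

# Layer normalization over the feature (M) axis, one position at a time.
layer_norm <- function(X, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  sweep(sweep((X - mu) / sqrt(v + eps), 2L, gamma, `*`), 2L, beta, `+`)
}

#' One transformer encoder block
#'
#' Pre-norm residual block: (1) layer normalization over the feature axis,
#' multi-head self-attention, dropout, residual add; (2) layer normalization,
#' width-1 convolution to `ff_dim` with ReLU, dropout, width-1 convolution
#' back to `M`, residual add.  A width-1 convolution acts independently per
#' position, i.e. it is a position-shared dense layer.
#'
#' @param X numeric `S x M` sequence (finite).
#' @param params a block parameter list as produced by [build_model()]
#'   (fields `ln1`, `attn`, `ln2`, `ff`).
#' @param dropout_active apply dropout (training mode); draws from the
#'   current RNG state.
#' @param dropout dropout rate when active.
#' @return `S x M` matrix.
#' @export
encoder_block <- function(X, params, dropout_active = FALSE, dropout = 0.25) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("encoder_block: input contains non-finite values")
  drop_mask <- function(d) {
    if (!dropout_active || dropout == 0) return(1)
    matrix(rbinom(prod(d), 1L, 1 - dropout), d[1L], d[2L]) / (1 - dropout)
  }
  u <- layer_norm(X, params$ln1$gamma, params$ln1$beta)
  a <- multi_head_self_attention(u, params$attn)
  X <- X + a * drop_mask(dim(a))
  u <- layer_norm(X, params$ln2$gamma, params$ln2$beta)
  h <- pmax(sweep(u %*% params$ff$W1, 2L, params$ff$b1, `+`), 0)
  h <- h * drop_mask(dim(h))
  X + sweep(h %*% params$ff$W2, 2L, params$ff$b2, `+`)
}

#' Build the transformer classifier
#'
#' Assembles the full network: fixed sinusoidal positional encoding added to
#' the input, `num_blocks` directly connected encoder blocks, global average
#' pooling over the feature axis (yielding a length-`S` vector), a dense
#' layer of `mlp_units` with ReLU, dropout, and a dense softmax output over
#' the classes.  Dense and convolution weights are He-uniform, biases zero,
#' layer-norm gain 1 and bias 0; pass `seed` for a reproducible
#' initialization.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer seed for the initializer.
#' @return object of class `"mhcgt_model"` (untrained).
#' @examples
#' m <- build_model(model_config())
#' count_parameters(m)  # 74768
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  M <- cfg$num_vars
  blocks <- lapply(seq_len(cfg$num_blocks), function(b) {
    list(ln1 = list(gamma = rep(1, M), beta = rep(0, M)),
         attn = attention_parameters(cfg$num_heads, M, cfg$key_dim),
         ln2 = list(gamma = rep(1, M), beta = rep(0, M)),
         ff = list(W1 = he_uniform(M, M, cfg$ff_dim), b1 = numeric(cfg$ff_dim),
                   W2 = he_uniform(cfg$ff_dim, cfg$ff_dim, M), b2 = numeric(M)))
  })
  head_par <- list(W1 = he_uniform(cfg$seq_len, cfg$seq_len, cfg$mlp_units),
                   b1 = numeric(cfg$mlp_units),
                   W2 = he_uniform(cfg$mlp_units, cfg$mlp_units, cfg$num_classes),
                   b2 = numeric(cfg$num_classes))
  structure(list(config = cfg,
                 pe = positional_encoding(cfg$seq_len, M),
                 blocks = blocks,
                 head = head_par),
            class = "mhcgt_model")
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable array of the model (the positional
#' encoding is fixed and contributes nothing).  For the default
#' configuration the count is exactly 74,768.
#'
#' @param model an `mhcgt_model`.
#' @return integer parameter count.
#' @seealso [count_parameters_closed_form()]
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mhcgt_model"))
  n <- 0L
  count_rec <- function(x) {
    if (is.numeric(x)) length(x)
    else if (is.list(x)) sum(vapply(x, count_rec, 0L))
    else 0L
  }
  nb <- sum(vapply(model$blocks, function(b) {
    count_rec(list(b$ln1, unclass(b$attn)[c("heads", "Wo", "bo")], b$ln2, b$ff))
  }, 0L))
  as.integer(nb + count_rec(model$head))
}

#' Closed-form trainable parameter count
#'
#' Independent of any built model:
#' per block `3 n D_k (M+1)` for the Q/K/V projections and biases,
#' `n D_k M + M` for the output projection, `(2M+1) ff_dim + M` for the two
#' width-1 convolutions, and `4M` for the two layer norms; plus the head
#' `S mlp_units + mlp_units + mlp_units C + C`.  With `M = 1` the per-block
#' attention term is the familiar `7 n D_k + 1`.
#'
#' @param cfg a [model_config()].
#' @return integer parameter count.
#' @export
count_parameters_closed_form <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  M <- cfg$num_vars; n <- cfg$num_heads; Dk <- cfg$key_dim
  per_block <- 3 * n * Dk * (M + 1) + n * Dk * M + M +
    (2 * M + 1) * cfg$ff_dim + M + 4 * M
  head <- cfg$seq_len * cfg$mlp_units + cfg$mlp_units +
    cfg$mlp_units * cfg$num_classes + cfg$num_classes
  as.integer(cfg$num_blocks * per_block + head)
}

#' Reference forward pass (single sample)
#'
#' Straightforward evaluation of the full network on one `S x M` sequence:
#' add the positional encoding, run every encoder block, pool over the
#' feature axis, and apply the MLP head with softmax.  This is the readable
#' reference path used for validation and small inputs; batch prediction on
#' univariate spectra uses an algebraically equivalent fast path
#' (see [predict.mhcgt()]).
#'
#' @param model an `mhcgt_model`.
#' @param x numeric `S x M` matrix (or length-`S` vector when `M = 1`).
#' @param dropout_active apply dropout (training mode).
#' @return numeric vector of `num_classes` probabilities summing to 1.
#' @export
forward_reference <- function(model, x, dropout_active = FALSE) {
  cfg <- model$config
  if (is.null(dim(x))) x <- matrix(x, ncol = cfg$num_vars)
  stopifnot(nrow(x) == cfg$seq_len, ncol(x) == cfg$num_vars)
  z <- x + model$pe
  for (b in model$blocks)
    z <- encoder_block(z, b, dropout_active = dropout_active, dropout = cfg$dropout)
  pooled <- rowMeans(z)                     # GAP over the feature axis -> length S
  h <- pmax(as.numeric(pooled %*% model$head$W1) + model$head$b1, 0)
  if (dropout_active && cfg$mlp_dropout > 0)
    h <- h * rbinom(length(h), 1L, 1 - cfg$mlp_dropout) / (1 - cfg$mlp_dropout)
  logits <- as.numeric(h %*% model$head$W2) + model$head$b2
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' @export
print.mhcgt_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Transformer spectral classifier: %d encoder blocks, %d heads ",
                     "(D_k = %d), ff %d, MLP %d; S = %d, M = %d, %d classes\n"),
              cfg$num_blocks, cfg$num_heads, cfg$key_dim, cfg$ff_dim,
              cfg$mlp_units, cfg$seq_len, cfg$num_vars, cfg$num_classes))
  cat(sprintf("Trainable parameters: %s\n", format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS of the model object; a sidecar JSON
#' (`<path>.json`) records the configuration, the seed and the package
#' version for reproducibility.
#'
#' @param model an `mhcgt_model`.
#' @param path checkpoint file path.
#' @param seed seed recorded in the sidecar.
#' @export
save_model <- function(model, path, seed = NA) {
  saveRDS(model, path)
  jsonlite::write_json(list(config = unclass(model$config), seed = seed,
                            package_version = as.character(utils::packageVersion("mhcgt"))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
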