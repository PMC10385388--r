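# He-uniform initialization: U(-L, L) with L = sqrt(6 / fan_in).
he_uniform <- function(fan_in, nrow, ncol = NULL) {
  l <- sqrt(6 / fan_in)
  if (is.null(ncol)) runif(nrow, -l, l) else matrix(runif(nrow * ncol, -l, l), nrow, ncol)
}

#' Scaled dot-product attention
#'
#' Computes the attention weight matrix `A = softmax(Q K' / sqrt(D_k))`
#' (row-wise softmax, so every row of `A` is a probability vector over the
#' `S` keys) and the attended output `A V`.
#'
#' @param Q,K,V numeric `S x D_k` matrices sharing both dimensions.
#' @return list with `output` (`S x D_k`) and `weights` (`S x S` row-stochastic
#'   attention score matrix).
#' @examples
#' r <- scaled_dot_product_attention(matrix(c(1, 0)), matrix(c(1, 0)), matrix(c(2, 4)))
#' r$weights  # softmax([1,0]) in row 1
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (!all(dim(K) == dim(Q)))
    stop(sprintf("K: expected %d x %d to match Q, got %d x %d",
                 nrow(Q), ncol(Q), nrow(K), ncol(K)))
  if (!all(dim(V) == dim(Q)))
    stop(sprintf("V: expected %d x %d to match Q, got %d x %d",
                 nrow(Q), ncol(Q), nrow(V), ncol(V)))
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention parameters
#'
#' Per-head query/key/value projections (`M x D_k` weights plus `D_k` biases)
#' and the output projection `W_o` (`n D_k x M` plus `M` bias) recombining the
#' concatenated heads.  Weights are He-uniform, biases zero; draws from the
#' current RNG state.
#'
#' @param num_heads number of heads `n`.
#' @param num_vars input feature width `M`.
#' @param key_dim per-head dimension `D_k`.
#' @param zero if `TRUE` all weights are zero (useful for tests).
#' @return object of class `"attention_parameters"`.
#' @export
attention_parameters <- function(num_heads, num_vars, key_dim, zero = FALSE) {
  mk <- function(fan_in, nr, nc) if (zero) matrix(0, nr, nc) else he_uniform(fan_in, nr, nc)
  heads <- lapply(seq_len(num_heads), function(i) {
    list(Wq = mk(num_vars, num_vars, key_dim), bq = numeric(key_dim),
         Wk = mk(num_vars, num_vars, key_dim), bk = numeric(key_dim),
         Wv = mk(num_vars, num_vars, key_dim), bv = numeric(key_dim))
  })
  structure(list(heads = heads,
                 Wo = mk(num_heads * key_dim, num_heads * key_dim, num_vars),
                 bo = numeric(num_vars),
                 num_heads = num_heads, num_vars = num_vars, key_dim = key_dim),
            class = "attention_parameters")
}

#' Multi-head self-attention on a sequence
#'
#' Each head `i` applies [scaled_dot_product_attention()] to the projected
#' sequence `(X W_i^Q, X W_i^K, X W_i^V)`; head outputs are concatenated and
#' mapped back to the input width by `W_o`:
#' `MultiHeadSelfAttn(X) = Concat(head_1, ..., head_n) W_o + b_o`.
#'
#' @param X numeric `S x M` sequence.
#' @param params an [attention_parameters()] object.
#' @param return_weights also return the per-head attention matrices.
#' @return `S x M` matrix; if `return_weights`, a list `output`, `weights`
#'   (list of `n` row-stochastic `S x S` matrices).
#' @export
multi_head_self_attention <- function(X, params, return_weights = FALSE) {
  stopifnot(inherits(params, "attention_parameters"))
  X <- as.matrix(X)
  if (ncol(X) != params$num_vars)
    stop(sprintf("X: expected %d columns (M), got %d", params$num_vars, ncol(X)))
  outs <- vector("list", params$num_heads)
  wts <- vector("list", params$num_heads)
  for (i in seq_along(params$heads)) {
    h <- params$heads[[i]]
    r <- scaled_dot_product_attention(
      sweep(X %*% h$Wq, 2L, h$bq, `+`),
      sweep(X %*% h$Wk, 2L, h$bk, `+`),
      sweep(X %*% h$Wv, 2L, h$bv, `+`))
    outs[[i]] <- r$output
    wts[[i]] <- r$weights
  }
  out <- sweep(do.call(cbind, outs) %*% params$Wo, 2L, params$bo, `+`)
  if (return_weights) list(output = out, weights = wts) else out
}
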