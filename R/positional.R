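#' Sinusoidal positional encoding
#'
#' Fixed (untrainable) sinusoidal encoding added to the input sequence so the
#' otherwise permutation-equivariant encoder can see band order:
#' `PE(pos, 2i) = sin(pos / 10000^(2i/M))`,
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/M))`, positions `0..S-1`, channels
#' 0-based.  For a univariate sequence (`M = 1`) this reduces to `sin(pos)`.
#'
#' @param S sequence length (number of spectral bands).
#' @param M number of variables per step.
#' @return `S x M` numeric matrix with entries in `[-1, 1]`.
#' @examples
#' positional_encoding(4, 2)
#' @export
positional_encoding <- function(S, M) {
  S <- as.integer(S); M <- as.integer(M)
  if (S < 1L || M < 1L) stop("positional_encoding: S and M must be positive")
  pos <- 0:(S - 1L)
  pe <- matrix(0, S, M)
  for (j in seq_len(M)) {
    i <- (j - 1L) %/% 2L
    angle <- pos / 10000^(2 * i / M)
    pe[, j] <- if (j %% 2L == 1L) sin(angle) else cos(angle)
  }
  pe
}
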