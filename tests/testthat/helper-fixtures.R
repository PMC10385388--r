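# Shared fixtures: everything is generated in code at test time.

# Small multi-temporal dataset (7 species x 4 phases x n_per_cell).
tiny_dataset <- function(n_per_cell = 3L, seed = 101L, smooth = FALSE, ...) {
  ds <- generate_dataset(generator_config(samples_per_class_phase = n_per_cell,
                                          seed = seed, ...))
  if (smooth) smooth_dataset(ds) else ds
}

# Small model configuration that still exercises every component.
tiny_model_config <- function(...) {
  model_config(num_heads = 2L, key_dim = 4L, ff_dim = 3L, num_blocks = 2L,
               mlp_units = 8L, num_classes = 7L, seq_len = 125L, num_vars = 1L,
               ...)
}

# A degenerate archetype whose noise-free spectrum is flat at the continuum:
# zero-depth wells, zero green peak, plateau equal to the continuum, and all
# per-sample variability switched off.
flat_archetype <- function(level = 0.3) {
  species_archetype("flat", baseline_continuum = level,
                    absorption_features = list(c(490, 25, 0), c(670, 22, 0)),
                    green_peak = c(550, 18, 0),
                    red_edge = c(718, 10),
                    nir_plateau = level,
                    water_band = c(960, 28, 0),
                    noise_sigma = 0, amplitude_sd = 0, chlorophyll_sd = 0,
                    water_sd = 0, offset_sd = 0, tilt_sd = 0, outlier_rate = 0)
}

# Independent per-head loop oracle for multi-head self-attention: explicit
# per-element formulas, no matrix shortcuts shared with the implementation.
mhsa_loop_oracle <- function(X, params) {
  S <- nrow(X)
  n <- params$num_heads
  Dk <- params$key_dim
  heads_out <- matrix(0, S, n * Dk)
  for (i in seq_len(n)) {
    h <- params$heads[[i]]
    Q <- matrix(0, S, Dk); K <- matrix(0, S, Dk); V <- matrix(0, S, Dk)
    for (s in 1:S) for (d in 1:Dk) {
      Q[s, d] <- sum(X[s, ] * h$Wq[, d]) + h$bq[d]
      K[s, d] <- sum(X[s, ] * h$Wk[, d]) + h$bk[d]
      V[s, d] <- sum(X[s, ] * h$Wv[, d]) + h$bv[d]
    }
    for (s in 1:S) {
      scores <- numeric(S)
      for (t in 1:S) scores[t] <- sum(Q[s, ] * K[t, ]) / sqrt(Dk)
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      for (d in 1:Dk)
        heads_out[s, (i - 1) * Dk + d] <- sum(w * V[, d])
    }
  }
  out <- matrix(0, S, params$num_vars)
  for (s in 1:S) for (m in seq_len(params$num_vars))
    out[s, m] <- sum(heads_out[s, ] * params$Wo[, m]) + params$bo[m]
  out
}

# Run only the encoder stack of a model (positional encoding NOT added).
encoder_stack <- function(model, X) {
  z <- X
  for (b in model$blocks) z <- encoder_block(z, b)
  z
}
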