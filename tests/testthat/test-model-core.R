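test_that("positional encoding follows the sinusoidal scheme", {
  pe <- positional_encoding(4, 4)
  expect_equal(pe[1, ], c(0, 1, 0, 1))                 # sin(0), cos(0) pairs
  pe1 <- positional_encoding(125, 1)
  expect_equal(pe1[2, 1], sin(1), tolerance = 1e-6)    # position 1, M = 1
  expect_equal(pe1[, 1], sin(0:124))
  big <- positional_encoding(50, 8)
  expect_true(all(big >= -1 & big <= 1))
  expect_error(positional_encoding(0, 1), "positive")
  expect_error(positional_encoding(5, 0), "positive")
})

test_that("scaled dot-product attention matches hand-computed cases", {
  # S = 2, D_k = 1 worked example: softmax([1, 0]) = (e, 1)/(e + 1)
  r <- scaled_dot_product_attention(matrix(c(1, 0)), matrix(c(1, 0)),
                                    matrix(c(2, 4)))
  w1 <- exp(1) / (exp(1) + 1)
  expect_equal(r$weights[1, ], c(w1, 1 - w1), tolerance = 1e-6)
  expect_equal(r$output[1, 1], w1 * 2 + (1 - w1) * 4, tolerance = 1e-6)
  expect_equal(r$output[1, 1], 2.53788, tolerance = 1e-4)
  expect_equal(r$weights[2, ], c(0.5, 0.5))            # equal scores
  # zero queries: uniform weights, output = column means of V
  set.seed(1)
  V <- matrix(rnorm(12), 4, 3)
  rz <- scaled_dot_product_attention(matrix(0, 4, 3), matrix(rnorm(12), 4, 3), V)
  expect_equal(rz$weights, matrix(0.25, 4, 4), ignore_attr = TRUE)
  expect_equal(rz$output[1, ], colMeans(V))
  # single key
  r1 <- scaled_dot_product_attention(matrix(5, 1, 1), matrix(2, 1, 1), matrix(9, 1, 1))
  expect_equal(r1$weights, matrix(1), ignore_attr = TRUE)
  expect_equal(r1$output, matrix(9), ignore_attr = TRUE)
  expect_error(scaled_dot_product_attention(matrix(0, 3, 2), matrix(0, 2, 2),
                                            matrix(0, 3, 2)), "^K")
  expect_error(scaled_dot_product_attention(matrix(0, 3, 2), matrix(0, 3, 2),
                                            matrix(0, 3, 1)), "^V")
})

test_that("attention weight rows are probability vectors", {
  set.seed(7)
  for (i in 1:20) {
    S <- sample(2:8, 1); Dk <- sample(1:8, 1)
    r <- scaled_dot_product_attention(matrix(rnorm(S * Dk, sd = 2), S, Dk),
                                      matrix(rnorm(S * Dk, sd = 2), S, Dk),
                                      matrix(rnorm(S * Dk), S, Dk))
    expect_true(all(r$weights >= 0))
    expect_equal(rowSums(r$weights), rep(1, S), tolerance = 1e-6)
  }
})

test_that("multi-head attention equals the per-head loop oracle", {
  set.seed(11)
  for (i in 1:10) {
    S <- sample(3:8, 1); M <- sample(1:3, 1); n <- sample(1:4, 1)
    Dk <- sample(2:8, 1)
    params <- attention_parameters(n, M, Dk)
    for (h in seq_len(n)) {
      params$heads[[h]]$bq <- rnorm(Dk, sd = 0.2)
      params$heads[[h]]$bk <- rnorm(Dk, sd = 0.2)
      params$heads[[h]]$bv <- rnorm(Dk, sd = 0.2)
    }
    params$bo <- rnorm(M, sd = 0.2)
    X <- matrix(rnorm(S * M), S, M)
    expect_equal(multi_head_self_attention(X, params), mhsa_loop_oracle(X, params),
                 tolerance = 1e-5)
  }
})

test_that("multi-head attention degenerate cases", {
  set.seed(3)
  # one head: equals a single scaled-dot-product head mapped by Wo
  p1 <- attention_parameters(1, 2, 3)
  X <- matrix(rnorm(10), 5, 2)
  h <- p1$heads[[1]]
  ref <- scaled_dot_product_attention(X %*% h$Wq, X %*% h$Wk, X %*% h$Wv)$output
  expect_equal(multi_head_self_attention(X, p1),
               ref %*% p1$Wo, ignore_attr = TRUE, tolerance = 1e-10)
  # all-zero parameters give zero output
  pz <- attention_parameters(3, 2, 4, zero = TRUE)
  expect_equal(multi_head_self_attention(X, pz), matrix(0, 5, 2),
               ignore_attr = TRUE)
  expect_error(multi_head_self_attention(matrix(0, 4, 3), p1), "columns")
})

test_that("encoder block is the identity when sub-layer weights are zero", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 2)
  b <- m$blocks[[1]]
  b$attn <- attention_parameters(cfg$num_heads, 1, cfg$key_dim, zero = TRUE)
  b$ff$W1[] <- 0; b$ff$W2[] <- 0
  X <- matrix(runif(125), 125, 1)
  expect_equal(encoder_block(X, b), X, tolerance = 1e-12)
})

test_that("encoder block matches an independent scalar-loop evaluation", {
  set.seed(5)
  cfg <- model_config(num_heads = 2, key_dim = 3, ff_dim = 2, num_blocks = 1,
                      mlp_units = 4, num_classes = 3, seq_len = 4, num_vars = 2)
  m <- build_model(cfg, seed = 9)
  b <- m$blocks[[1]]
  b$ln1$beta <- rnorm(2, sd = 0.3); b$ln1$gamma <- runif(2, 0.5, 1.5)
  b$ln2$beta <- rnorm(2, sd = 0.3); b$ln2$gamma <- runif(2, 0.5, 1.5)
  X <- matrix(rnorm(8), 4, 2)
  # step-by-step scalar oracle
  ln <- function(x, g, be) {
    out <- x
    for (s in 1:nrow(x)) {
      mu <- mean(x[s, ]); v <- mean((x[s, ] - mu)^2)
      out[s, ] <- g * (x[s, ] - mu) / sqrt(v + 1e-6) + be
    }
    out
  }
  u <- ln(X, b$ln1$gamma, b$ln1$beta)
  z <- X + mhsa_loop_oracle(u, b$attn)
  u2 <- ln(z, b$ln2$gamma, b$ln2$beta)
  ff <- z
  for (s in 1:4) {
    h <- pmax(as.numeric(u2[s, ] %*% b$ff$W1) + b$ff$b1, 0)
    ff[s, ] <- z[s, ] + as.numeric(h %*% b$ff$W2) + b$ff$b2
  }
  expect_equal(encoder_block(X, b), ff, tolerance = 1e-5)
  expect_error(encoder_block(matrix(c(NA, 1), 1, 2), b), "finite")
})

test_that("parameter count is exact: 74,768 for the default configuration", {
  cfg <- model_config()
  m <- build_model(cfg, seed = 1)
  expect_identical(count_parameters(m), 74768L)
  expect_identical(count_parameters_closed_form(cfg), 74768L)
  # head only
  cfg0 <- model_config(num_blocks = 0)
  expect_identical(count_parameters(build_model(cfg0)), 16632L)
  expect_identical(count_parameters_closed_form(cfg0), 16632L)
  # the fixed positional encoding never contributes
  m2 <- m; m2$pe <- m2$pe * 0
  expect_identical(count_parameters(m2), count_parameters(m))
})

test_that("closed-form count matches the built model for random configurations", {
  set.seed(13)
  for (i in 1:5) {
    cfg <- model_config(num_heads = sample(1:4, 1), key_dim = sample(2:16, 1),
                        ff_dim = sample(2:16, 1), num_blocks = sample(0:3, 1),
                        mlp_units = sample(3:20, 1), num_classes = sample(2:7, 1),
                        seq_len = sample(5:30, 1), num_vars = sample(1:3, 1))
    expect_identical(count_parameters(build_model(cfg)),
                     count_parameters_closed_form(cfg))
  }
})

test_that("forward pass yields a probability simplex and is deterministic", {
  m <- build_model(tiny_model_config(), seed = 4)
  x <- runif(125)
  p1 <- forward_reference(m, x)
  p2 <- forward_reference(m, x)
  expect_identical(p1, p2)
  expect_length(p1, 7L)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  # batch path agrees and has shape (B, C)
  xb <- matrix(runif(3 * 125), 3, 125)
  pb <- mhcgt:::engine_forward(mhcgt:::engine_params(m), xb, as.numeric(m$pe[, 1]))
  expect_equal(dim(pb), c(3L, 7L))
  expect_equal(rowSums(pb), rep(1, 3), tolerance = 1e-6)
})

test_that("fast univariate engine matches the reference forward exactly", {
  cfg <- model_config(num_heads = 3, key_dim = 5, ff_dim = 4, num_blocks = 2,
                      mlp_units = 6, num_classes = 4, seq_len = 9, num_vars = 1,
                      dropout = 0, mlp_dropout = 0)
  m <- build_model(cfg, seed = 21)
  set.seed(22)
  for (b in seq_along(m$blocks)) {    # nonzero offsets so blocks matter
    m$blocks[[b]]$ln1$beta[1] <- rnorm(1)
    m$blocks[[b]]$ln2$beta[1] <- rnorm(1)
    m$blocks[[b]]$ff$b1 <- rnorm(cfg$ff_dim)
    m$blocks[[b]]$attn$bo[1] <- rnorm(1)
    for (i in seq_along(m$blocks[[b]]$attn$heads))
      m$blocks[[b]]$attn$heads[[i]]$bv <- rnorm(cfg$key_dim)
  }
  X <- matrix(runif(5 * 9), 5, 9)
  ref <- t(apply(X, 1, function(r) forward_reference(m, r)))
  eng <- mhcgt:::engine_forward(mhcgt:::engine_params(m), X, as.numeric(m$pe[, 1]))
  expect_equal(eng, ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("encoder stack is permutation-equivariant only without the positional encoding", {
  set.seed(31)
  cfg <- model_config(num_heads = 2, key_dim = 4, ff_dim = 3, num_blocks = 2,
                      mlp_units = 5, num_classes = 3, seq_len = 10, num_vars = 3)
  m <- build_model(cfg, seed = 32)
  for (b in seq_along(m$blocks)) {
    m$blocks[[b]]$ln1$beta <- rnorm(3, sd = 0.2)
    m$blocks[[b]]$ln2$beta <- rnorm(3, sd = 0.2)
  }
  X <- matrix(rnorm(30), 10, 3)
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  # without the encoding: f(PX) = P f(X)
  expect_equal(encoder_stack(m, X[perm, ]), encoder_stack(m, X)[perm, ],
               tolerance = 1e-8)
  # with the encoding added first, equivariance breaks
  pe <- positional_encoding(10, 3)
  with_pe_perm <- encoder_stack(m, X[perm, ] + pe)
  with_pe <- encoder_stack(m, X + pe)
  expect_gt(max(abs(with_pe_perm - with_pe[perm, ])), 1e-3)
})

test_that("model checkpoints round-trip through disk", {
  m <- build_model(tiny_model_config(), seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path, seed = 8)
  m2 <- load_model(path)
  expect_equal(m2, m)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$seed, 8)
  expect_equal(sidecar$config$num_heads, 2)
})
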