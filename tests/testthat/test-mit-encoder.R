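tiny_config <- function() {
  encoder_config(NULL, stage_channels = c(8, 8, 16, 16),
                 stage_depths = c(1, 1, 1, 1), stage_heads = c(1, 1, 2, 2),
                 stage_reduction = c(8, 4, 2, 1), mlp_ratio = 2)
}

test_that("overlapped patch merging follows the output-size formula", {
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  out <- overlapped_patch_merge(x, K = 3, S = 2, P = 1, C_out = 5)
  expect_equal(dim(out), c(32, 32, 5)) # floor((64+2-3)/2)+1
  out2 <- overlapped_patch_merge(array(rnorm(512 * 512 * 3),
                                       c(512, 512, 3)),
                                 K = 7, S = 4, P = 3, C_out = 4)
  expect_equal(dim(out2)[1:2], c(128, 128))
  expect_error(overlapped_patch_merge(x, K = 3, S = 2, P = 2, C_out = 4),
               "padding")
  expect_error(overlapped_patch_merge(x, K = 0, S = 1, P = 0, C_out = 4))
})

test_that("1x1/stride-1 patch merge with identity weights is the identity", {
  set.seed(2)
  x <- array(rnorm(5 * 7 * 4), c(5, 7, 4))
  out <- overlapped_patch_merge(x, K = 1, S = 1, P = 0, C_out = 4,
                                weights = diag(4))
  expect_equal(out, x)
})

test_that("sequence-reduced attention matches the dense oracle at R = 1", {
  set.seed(3)
  for (case in 1:20) {
    L <- sample(2:64, 1); heads <- sample(c(1, 2, 4), 1)
    C <- heads * sample(2:8, 1)
    tokens <- matrix(rnorm(L * C), L, C)
    w <- rand_attn_weights(C, 1)
    got <- efficient_self_attention(tokens, heads, R = 1, weights = w)
    want <- oracle_attention(tokens, heads, 1, w)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("reduced attention matches the literal reshape+linear oracle", {
  set.seed(4)
  for (case in 1:5) {
    L <- 8; heads <- 2; C <- 8; R <- 2
    tokens <- matrix(rnorm(L * C), L, C)
    w <- rand_attn_weights(C, R)
    got <- efficient_self_attention(tokens, heads, R = R, weights = w)
    want <- oracle_attention(tokens, heads, R, w)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("attention rows are stochastic and degenerate inputs error", {
  set.seed(5)
  tokens <- matrix(rnorm(12 * 8), 12, 8)
  out <- efficient_self_attention(tokens, heads = 2, R = 2)
  for (A in attr(out, "attention")) {
    expect_true(all(A >= 0))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  }
  # single token: softmax over one key is 1
  one <- matrix(rnorm(4), 1, 4)
  w <- rand_attn_weights(4, 1)
  got <- efficient_self_attention(one, heads = 1, R = 1, weights = w)
  v <- one %*% w$Wv + w$bv
  expect_equal(got, v %*% w$Wo + rep(w$bo, each = 1),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(efficient_self_attention(matrix(0, 0, 4)), "zero-length")
})

test_that("attention is permutation-equivariant; Mix-FFN is not", {
  set.seed(6)
  L <- 16; C <- 8
  tokens <- matrix(rnorm(L * C), L, C)
  w <- rand_attn_weights(C, 1)
  perm <- sample(L)
  a1 <- efficient_self_attention(tokens, 2, 1, w)[perm, ]
  a2 <- efficient_self_attention(tokens[perm, ], 2, 1, w)
  expect_lt(max(abs(a1 - a2)), 1e-10)
  # the depthwise conv in Mix-FFN injects positional information
  set.seed(7)
  wf <- list(W1 = matrix(rnorm(C * 2 * C, sd = 0.3), C, 2 * C),
             b1 = rnorm(2 * C), Wd = matrix(rnorm(9 * 2 * C, sd = 0.3),
                                            9, 2 * C),
             bd = rnorm(2 * C), W2 = matrix(rnorm(2 * C * C, sd = 0.3),
                                            2 * C, C),
             b2 = rnorm(C))
  f1 <- mix_ffn(tokens, 4, 4, mlp_ratio = 2, weights = wf)[perm, ]
  f2 <- mix_ffn(tokens[perm, ], 4, 4, mlp_ratio = 2, weights = wf)
  expect_gt(max(abs(f1 - f2)), 1e-4)
})

test_that("Mix-FFN is a residual transform with verifiable scalar case", {
  set.seed(8)
  x <- matrix(rnorm(16 * 4), 16, 4)
  zero <- list(W1 = matrix(0, 4, 8), b1 = numeric(8),
               Wd = matrix(0, 9, 8), bd = numeric(8),
               W2 = matrix(0, 8, 4), b2 = numeric(4))
  expect_equal(mix_ffn(x, 4, 4, 2, zero), x)
  expect_error(mix_ffn(x, 3, 4, 2), "H\\*W")
  # 1x1 grid, one channel, mlp_ratio 1: value computable by hand
  wh <- list(W1 = matrix(2), b1 = 0.5, Wd = matrix(c(0, 0, 0, 0, 3, 0,
                                                     0, 0, 0), 9, 1),
             bd = -0.25, W2 = matrix(-1), b2 = 0.1)
  xs <- matrix(0.7)
  h <- 2 * 0.7 + 0.5
  hd <- 3 * h - 0.25
  g <- hd * pnorm(hd)
  expect_equal(mix_ffn(xs, 1, 1, 1, wh), matrix(-g + 0.1 + 0.7),
               tolerance = 1e-12)
  # shape contract
  expect_equal(dim(mix_ffn(matrix(rnorm(12 * 6), 12, 6), 3, 4, 2)),
               c(12, 6))
})

test_that("the encoder emits the halving pyramid and is deterministic", {
  enc <- mit_encoder(tiny_config())
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  pyr <- encode(enc, img)
  expect_equal(lapply(pyr, function(a) dim(a)[1]), list(8L, 4L, 2L, 1L))
  expect_equal(sapply(pyr, function(a) dim(a)[3]), c(8, 8, 16, 16))
  img64 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pyr64 <- encode(enc, img64)
  expect_equal(sapply(pyr64, function(a) dim(a)[1]), c(16, 8, 4, 2))
  expect_identical(encode(enc, img64), pyr64) # bitwise determinism
  expect_error(encode(enc, array(0, c(48, 48, 3))), "multiples of 32")
})

test_that("encoder configs enforce their invariants", {
  expect_error(encoder_config("huge"), "size_tag")
  expect_error(encoder_config(NULL, stage_channels = c(33, 64, 160, 256),
                              stage_depths = c(2, 2, 2, 2),
                              stage_heads = c(2, 2, 5, 8)),
               "divisible")
  small <- encoder_config("small"); large <- encoder_config("large")
  expect_gt(sum(large$stage_depths), sum(small$stage_depths))
  expect_equal(small$patch_params[[1]], list(K = 7L, S = 4L, P = 3L))
  for (i in 2:4)
    expect_equal(small$patch_params[[i]], list(K = 3L, S = 2L, P = 1L))
})

test_that("checkpoints round-trip weights and configuration", {
  m <- build_model("UN", "small", 2, seed = 9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_logits(m, img)
  path <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(predict_logits(m2, img), p1, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".yaml")))
})
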