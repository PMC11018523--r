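# Independent oracles and small fixture builders used across tests.
# The oracles implement the reference equations in plain R, separate
# from the package's layer machinery.

rand_attn_weights <- function(C, R, sd = 0.2) {
  w <- list(Wq = matrix(rnorm(C * C, sd = sd), C, C), bq = rnorm(C, sd = sd),
            Wk = matrix(rnorm(C * C, sd = sd), C, C), bk = rnorm(C, sd = sd),
            Wv = matrix(rnorm(C * C, sd = sd), C, C), bv = rnorm(C, sd = sd),
            Wo = matrix(rnorm(C * C, sd = sd), C, C), bo = rnorm(C, sd = sd))
  if (R > 1) {
    w$Wkr <- matrix(rnorm(C * R * C, sd = sd), C * R, C)
    w$bkr <- rnorm(C, sd = sd)
    w$Wvr <- matrix(rnorm(C * R * C, sd = sd), C * R, C)
    w$bvr <- rnorm(C, sd = sd)
  }
  w
}

softmax_rows_oracle <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# literal dense / sequence-reduced scaled-dot-product attention:
# K and V are reshaped to (L/R) x (C*R) and linearly mapped back to C,
# then ordinary dense attention runs against the shortened sequence
oracle_attention <- function(tokens, heads, R, w) {
  L <- nrow(tokens); C <- ncol(tokens); d <- C / heads
  q <- tokens %*% w$Wq + rep(w$bq, each = L)
  k <- tokens %*% w$Wk + rep(w$bk, each = L)
  v <- tokens %*% w$Wv + rep(w$bv, each = L)
  if (R > 1) {
    resh <- function(m) matrix(t(m), ncol = C * R, byrow = TRUE)
    k <- resh(k) %*% w$Wkr + rep(w$bkr, each = L / R)
    v <- resh(v) %*% w$Wvr + rep(w$bvr, each = L / R)
  }
  out <- matrix(0, L, C)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * d + 1):(h * d)
    A <- softmax_rows_oracle(q[, idx, drop = FALSE] %*%
                               t(k[, idx, drop = FALSE]) / sqrt(d))
    out[, idx] <- A %*% v[, idx, drop = FALSE]
  }
  out %*% w$Wo + rep(w$bo, each = L)
}

# brute-force per-segment modal vote (classes 1..3; soil untouched;
# ties to the lower class index)
oracle_majority <- function(labels, seg) {
  out <- labels
  for (s in unique(as.vector(seg))) {
    px <- which(seg == s & labels > 0)
    if (!length(px)) next
    cnt <- tabulate(labels[px], 3)
    out[px] <- which.max(cnt)
  }
  out
}

# random contiguous-ish partition for majority-vote tests: nearest of
# k random seed points (a Voronoi partition is connected)
random_partition <- function(h, w, k) {
  sy <- runif(k, 1, h); sx <- runif(k, 1, w)
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  d <- outer(g$y, sy, "-")^2 + outer(g$x, sx, "-")^2
  structure(list(labels = matrix(max.col(-d), h, w), n_segments = k),
            class = "superpixel_partition")
}

toy_tiles <- function(n, canvas = 64, seed0 = 100) {
  lapply(seq_len(n), function(i) {
    sc <- generate_scene(scene_spec(canvas = canvas, seed = seed0 + i,
                                    senescent_frac = 0))
    list(image = sc$image, mask = sc$binary)
  })
}
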