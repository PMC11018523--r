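# Minimal neural-network core: layer objects with explicit forward/backward
# passes over BLAS matrix products. Activations travel as "token matrices"
# of shape (B*H*W) x C, spatial row-major per sample; convolutions go
# through im2col/col2im so that a convolution weight is a (K*K*Cin) x Cout
# matrix and the heavy lifting is a single matrix product.

.rs_env <- new.env(parent = emptyenv())
.rs_env$flops_active <- FALSE
.rs_env$flops <- 0

rs_count_macs <- function(macs) {
  if (.rs_env$flops_active)
    .rs_env$flops <- .rs_env$flops + 2 * macs # 1 multiply-accumulate = 2 FLOPs
  invisible(NULL)
}

#' @keywords internal
rs_flop_meter <- function(expr) {
  .rs_env$flops_active <- TRUE
  .rs_env$flops <- 0
  on.exit(.rs_env$flops_active <- FALSE)
  force(expr)
  .rs_env$flops
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

new_layer <- function(name, params, decay, fwd, bwd, extra = list()) {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$decay <- decay
  e$training <- TRUE
  for (n in names(extra)) assign(n, extra[[n]], envir = e)
  e$fwd <- fwd
  e$bwd <- bwd
  environment(e$fwd) <- list2env(list(self = e), parent = environment(fwd))
  environment(e$bwd) <- list2env(list(self = e), parent = environment(bwd))
  class(e) <- "rs_layer"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect all layer objects of a model component
#' @keywords internal
rs_layers <- function(m) {
  if (inherits(m, "rs_layer")) return(list(m))
  if (is.list(m)) return(unlist(lapply(m, rs_layers), recursive = FALSE))
  list()
}

rs_set_training <- function(m, training) {
  for (l in rs_layers(m)) l$training <- training
  invisible(m)
}

rs_zero_grads <- function(m) {
  for (l in rs_layers(m))
    l$grads <- lapply(l$params, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(m)
}

rs_n_params <- function(m) sum(vapply(rs_layers(m),
                                      function(l) sum(lengths(l$params)), 0))

# Parameter initialisers: truncated-normal-like draws for projections,
# He-scaled for convolutions, zeros for the classifier head (small-step
# optimisers then see noise-free logits from step one).
init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

layer_linear <- function(cin, cout, name = "linear", sd = 0.02,
                         zero_init = FALSE) {
  W <- if (zero_init) matrix(0, cin, cout) else init_mat(cin, cout, sd)
  new_layer(
    name,
    params = list(W = W, b = numeric(cout)),
    decay = c(W = TRUE, b = FALSE),
    fwd = function(x) {
      self$x <- x
      rs_count_macs(as.double(nrow(x)) * ncol(x) * ncol(self$params$W))
      add_bias(x %*% self$params$W, self$params$b)
    },
    bwd = function(dout) {
      self$grads$W <- self$grads$W + crossprod(self$x, dout)
      self$grads$b <- self$grads$b + colSums(dout)
      dx <- dout %*% t(self$params$W)
      self$x <- NULL
      dx
    })
}

layer_conv <- function(K, S, P, cin, cout, name = "conv", zero_init = FALSE) {
  if (K < 2 * P + 1)
    stop("conv kernel ", K, " with padding ", P,
         " allows windows entirely inside padding (need K >= 2P+1)")
  fan_in <- K * K * cin
  W <- if (zero_init) matrix(0, fan_in, cout)
       else init_mat(fan_in, cout, sqrt(2 / fan_in))
  new_layer(
    name,
    params = list(W = W, b = numeric(cout)),
    decay = c(W = TRUE, b = FALSE),
    extra = list(K = K, S = S, P = P, cin = cin, cout = cout),
    fwd = function(x, B, H, W_) {
      if (H + 2 * self$P < self$K || W_ + 2 * self$P < self$K)
        stop("input ", H, "x", W_, " smaller than kernel")
      self$x <- x; self$B <- B; self$H <- H; self$W_ <- W_
      cols <- im2col_cpp(x, B, H, W_, self$K, self$S, self$P)
      rs_count_macs(as.double(nrow(cols)) * ncol(cols) * self$cout)
      add_bias(cols %*% self$params$W, self$params$b)
    },
    bwd = function(dout) {
      cols <- im2col_cpp(self$x, self$B, self$H, self$W_,
                         self$K, self$S, self$P)
      self$grads$W <- self$grads$W + crossprod(cols, dout)
      self$grads$b <- self$grads$b + colSums(dout)
      dx <- col2im_cpp(dout %*% t(self$params$W), self$B, self$H, self$W_,
                       self$cin, self$K, self$S, self$P)
      self$x <- NULL
      dx
    })
}

conv_out_dim <- function(n, K, S, P) (n + 2 * P - K) %/% S + 1

# Depthwise 3x3 convolution (stride 1, padding 1): one 3x3 kernel per channel.
layer_dwconv3 <- function(C, name = "dwconv3") {
  new_layer(
    name,
    params = list(W = init_mat(9, C, sqrt(2 / 9)), b = numeric(C)),
    decay = c(W = TRUE, b = FALSE),
    extra = list(C = C),
    fwd = function(x, B, H, W_) {
      C <- self$C
      cols <- im2col_cpp(x, B, H, W_, 3L, 1L, 1L)
      self$cols <- cols; self$B <- B; self$H <- H; self$W_ <- W_
      out <- matrix(0, nrow(cols), C)
      for (k in 1:9)
        out <- out + cols[, ((k - 1) * C + 1):(k * C), drop = FALSE] *
          rep(self$params$W[k, ], each = nrow(cols))
      rs_count_macs(as.double(nrow(cols)) * 9 * C)
      add_bias(out, self$params$b)
    },
    bwd = function(dout) {
      C <- self$C
      n <- nrow(dout)
      dcols <- matrix(0, n, 9 * C)
      for (k in 1:9) {
        idx <- ((k - 1) * C + 1):(k * C)
        dcols[, idx] <- dout * rep(self$params$W[k, ], each = n)
        self$grads$W[k, ] <- self$grads$W[k, ] +
          colSums(self$cols[, idx, drop = FALSE] * dout)
      }
      self$grads$b <- self$grads$b + colSums(dout)
      dx <- col2im_cpp(dcols, self$B, self$H, self$W_, C, 3L, 1L, 1L)
      self$cols <- NULL
      dx
    })
}

layer_layernorm <- function(C, name = "ln", eps = 1e-6) {
  new_layer(
    name,
    params = list(g = rep(1, C), b = numeric(C)),
    decay = c(g = FALSE, b = FALSE),
    extra = list(eps = eps),
    fwd = function(x) {
      mu <- rowMeans(x)
      xc <- x - mu
      inv <- 1 / sqrt(rowMeans(xc * xc) + self$eps)
      xhat <- xc * inv
      self$xhat <- xhat; self$inv <- inv
      add_bias(xhat * rep(self$params$g, each = nrow(x)), self$params$b)
    },
    bwd = function(dout) {
      xhat <- self$xhat
      self$grads$g <- self$grads$g + colSums(dout * xhat)
      self$grads$b <- self$grads$b + colSums(dout)
      dxh <- dout * rep(self$params$g, each = nrow(dout))
      dx <- self$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
      self$xhat <- NULL; self$inv <- NULL
      dx
    })
}

layer_batchnorm <- function(C, name = "bn", eps = 1e-5, momentum = 0.1) {
  new_layer(
    name,
    params = list(g = rep(1, C), b = numeric(C)),
    decay = c(g = FALSE, b = FALSE),
    extra = list(eps = eps, momentum = momentum,
                 run_mean = numeric(C), run_var = rep(1, C)),
    fwd = function(x) {
      n <- nrow(x)
      if (self$training) {
        mu <- colMeans(x)
        xc <- x - rep(mu, each = n)
        v <- colMeans(xc * xc)
        self$run_mean <- (1 - self$momentum) * self$run_mean + self$momentum * mu
        self$run_var <- (1 - self$momentum) * self$run_var + self$momentum * v
      } else {
        mu <- self$run_mean
        v <- self$run_var
        xc <- x - rep(mu, each = n)
      }
      inv <- 1 / sqrt(v + self$eps)
      xhat <- xc * rep(inv, each = n)
      self$xhat <- xhat; self$inv <- inv
      add_bias(xhat * rep(self$params$g, each = n), self$params$b)
    },
    bwd = function(dout) {
      n <- nrow(dout)
      xhat <- self$xhat
      self$grads$g <- self$grads$g + colSums(dout * xhat)
      self$grads$b <- self$grads$b + colSums(dout)
      gi <- rep(self$params$g * self$inv, each = n)
      if (self$training) {
        dx <- gi * (dout - rep(colMeans(dout), each = n) -
                      xhat * rep(colMeans(dout * xhat), each = n))
      } else {
        dx <- gi * dout
      }
      self$xhat <- NULL; self$inv <- NULL
      dx
    })
}

layer_gelu <- function(name = "gelu") {
  new_layer(
    name, params = list(), decay = logical(0),
    fwd = function(x) {
      self$x <- x
      x * stats::pnorm(x)
    },
    bwd = function(dout) {
      x <- self$x
      self$x <- NULL
      dout * (stats::pnorm(x) + x * stats::dnorm(x))
    })
}

layer_relu <- function(name = "relu") {
  new_layer(
    name, params = list(), decay = logical(0),
    fwd = function(x) {
      self$pos <- x > 0
      x * self$pos
    },
    bwd = function(dout) {
      dx <- dout * self$pos
      self$pos <- NULL
      dx
    })
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# Reshape an L x C token matrix into (L/R) x (C*R) by concatenating the
# channels of R consecutive tokens per row (zero-padding the tail).
reduce_reshape <- function(m, R) {
  L <- nrow(m); C <- ncol(m)
  Lp <- ceiling(L / R) * R
  if (Lp != L) m <- rbind(m, matrix(0, Lp - L, C))
  matrix(t(m), ncol = C * R, byrow = TRUE)
}

reduce_unreshape <- function(dm, R, L, C) {
  full <- matrix(t(dm), ncol = C, byrow = TRUE)
  full[seq_len(L), , drop = FALSE]
}

#' Efficient self-attention layer with sequence reduction
#'
#' Keys and values are shortened by the reduction ratio \code{R}: the
#' projected sequence is reshaped to (L/R) x (C*R) and mapped back to C
#' channels by a learned linear layer, so queries attend to L/R positions.
#' The scaled-dot-product uses the per-head key dimension.
#' @keywords internal
layer_attention <- function(C, heads, R, name = "attn") {
  stopifnot(C %% heads == 0)
  p <- list(Wq = init_mat(C, C, 0.02), bq = numeric(C),
            Wk = init_mat(C, C, 0.02), bk = numeric(C),
            Wv = init_mat(C, C, 0.02), bv = numeric(C),
            Wo = init_mat(C, C, 0.02), bo = numeric(C))
  d <- c(Wq = TRUE, bq = FALSE, Wk = TRUE, bk = FALSE,
         Wv = TRUE, bv = FALSE, Wo = TRUE, bo = FALSE)
  if (R > 1) {
    p$Wkr <- init_mat(C * R, C, 0.02); p$bkr <- numeric(C)
    p$Wvr <- init_mat(C * R, C, 0.02); p$bvr <- numeric(C)
    d <- c(d, Wkr = TRUE, bkr = FALSE, Wvr = TRUE, bvr = FALSE)
  }
  new_layer(
    name, params = p, decay = d,
    extra = list(C = C, heads = heads, R = R),
    fwd = function(x, B, L) {
      if (L < 1) stop("zero-length token sequence")
      C <- self$C; h <- self$heads; R <- self$R; dh <- C / h
      P <- self$params
      out <- matrix(0, nrow(x), C)
      self$cache <- vector("list", B)
      for (b in seq_len(B)) {
        rows <- ((b - 1) * L + 1):(b * L)
        xb <- x[rows, , drop = FALSE]
        q <- add_bias(xb %*% P$Wq, P$bq)
        k <- add_bias(xb %*% P$Wk, P$bk)
        v <- add_bias(xb %*% P$Wv, P$bv)
        rs_count_macs(3 * L * C * C)
        if (R > 1) {
          krm <- reduce_reshape(k, R)
          vrm <- reduce_reshape(v, R)
          kh <- add_bias(krm %*% P$Wkr, P$bkr)
          vh <- add_bias(vrm %*% P$Wvr, P$bvr)
          rs_count_macs(2 * nrow(krm) * ncol(krm) * C)
        } else {
          krm <- NULL; vrm <- NULL; kh <- k; vh <- v
        }
        Lr <- nrow(kh)
        A <- vector("list", h)
        O <- matrix(0, L, C)
        for (hh in seq_len(h)) {
          idx <- ((hh - 1) * dh + 1):(hh * dh)
          s <- q[, idx, drop = FALSE] %*% t(kh[, idx, drop = FALSE]) / sqrt(dh)
          A[[hh]] <- softmax_rows(s)
          O[, idx] <- A[[hh]] %*% vh[, idx, drop = FALSE]
          rs_count_macs(2 * L * Lr * dh)
        }
        out[rows, ] <- add_bias(O %*% P$Wo, P$bo)
        rs_count_macs(L * C * C)
        self$cache[[b]] <- list(xb = xb, q = q, k = k, v = v, krm = krm,
                                vrm = vrm, kh = kh, vh = vh, A = A, O = O)
      }
      self$B <- B; self$L <- L
      out
    },
    bwd = function(dout) {
      C <- self$C; h <- self$heads; R <- self$R; dh <- C / h
      P <- self$params; G <- self$grads
      B <- self$B; L <- self$L
      dx <- matrix(0, nrow(dout), C)
      for (b in seq_len(B)) {
        rows <- ((b - 1) * L + 1):(b * L)
        cb <- self$cache[[b]]
        dob <- dout[rows, , drop = FALSE]
        G$Wo <- G$Wo + crossprod(cb$O, dob)
        G$bo <- G$bo + colSums(dob)
        dO <- dob %*% t(P$Wo)
        Lr <- nrow(cb$kh)
        dq <- matrix(0, L, C)
        dkh <- matrix(0, Lr, C)
        dvh <- matrix(0, Lr, C)
        for (hh in seq_len(h)) {
          idx <- ((hh - 1) * dh + 1):(hh * dh)
          A <- cb$A[[hh]]
          dOh <- dO[, idx, drop = FALSE]
          dA <- dOh %*% t(cb$vh[, idx, drop = FALSE])
          dvh[, idx] <- crossprod(A, dOh)
          dS <- A * (dA - rowSums(A * dA))
          dq[, idx] <- dS %*% cb$kh[, idx, drop = FALSE] / sqrt(dh)
          dkh[, idx] <- crossprod(dS, cb$q[, idx, drop = FALSE]) / sqrt(dh)
        }
        if (R > 1) {
          G$Wkr <- G$Wkr + crossprod(cb$krm, dkh)
          G$bkr <- G$bkr + colSums(dkh)
          G$Wvr <- G$Wvr + crossprod(cb$vrm, dvh)
          G$bvr <- G$bvr + colSums(dvh)
          dk <- reduce_unreshape(dkh %*% t(P$Wkr), R, L, C)
          dv <- reduce_unreshape(dvh %*% t(P$Wvr), R, L, C)
        } else {
          dk <- dkh; dv <- dvh
        }
        G$Wq <- G$Wq + crossprod(cb$xb, dq)
        G$bq <- G$bq + colSums(dq)
        G$Wk <- G$Wk + crossprod(cb$xb, dk)
        G$bk <- G$bk + colSums(dk)
        G$Wv <- G$Wv + crossprod(cb$xb, dv)
        G$bv <- G$bv + colSums(dv)
        dx[rows, ] <- dq %*% t(P$Wq) + dk %*% t(P$Wk) + dv %*% t(P$Wv)
      }
      self$grads <- G
      self$cache <- NULL
      dx
    })
}

# Parameter-free bilinear resize wrapped as a layer so FLOP metering and
# backward plumbing stay uniform (4 MACs per output element).
layer_bilinear <- function(name = "bilinear") {
  new_layer(
    name, params = list(), decay = logical(0),
    fwd = function(x, B, H, W_, Ho, Wo) {
      self$B <- B; self$H <- H; self$W_ <- W_; self$Ho <- Ho; self$Wo <- Wo
      rs_count_macs(4 * B * Ho * Wo * ncol(x))
      bilinear_fwd_cpp(x, B, H, W_, Ho, Wo)
    },
    bwd = function(dout) {
      bilinear_bwd_cpp(dout, self$B, self$H, self$W_, self$Ho, self$Wo)
    })
}

#' AdamW optimiser step over a set of layers
#'
#' Decoupled weight decay is applied to weight matrices only (never biases
#' or normalisation parameters). Gradients are zeroed after the step.
#' @keywords internal
rs_adamw_step <- function(layers, lr, betas = c(0.9, 0.999), eps = 1e-8,
                          weight_decay = 0.01) {
  for (l in layers) {
    if (!length(l$params)) next
    if (is.null(l$opt)) {
      l$opt <- list(
        m = lapply(l$params, function(p) array(0, dim = dim(p) %||% length(p))),
        v = lapply(l$params, function(p) array(0, dim = dim(p) %||% length(p))),
        t = 0)
    }
    l$opt$t <- l$opt$t + 1
    bc1 <- 1 - betas[1]^l$opt$t
    bc2 <- 1 - betas[2]^l$opt$t
    for (n in names(l$params)) {
      g <- l$grads[[n]]
      l$opt$m[[n]] <- betas[1] * l$opt$m[[n]] + (1 - betas[1]) * g
      l$opt$v[[n]] <- betas[2] * l$opt$v[[n]] + (1 - betas[2]) * g * g
      upd <- (l$opt$m[[n]] / bc1) / (sqrt(l$opt$v[[n]] / bc2) + eps)
      p <- l$params[[n]] - lr * upd
      if (isTRUE(l$decay[[n]])) p <- p - lr * weight_decay * l$params[[n]]
      l$params[[n]] <- p
      l$grads[[n]][] <- 0
    }
  }
  invisible(NULL)
}
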