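# Decoder family and model assembly. Decoder widths for the UN and
# MLP_base variants are calibrated (jointly with the encoder presets)
# against the published trainable-parameter budgets; see the methods
# vignette for the calibration procedure.

.rs_un_widths <- list(small = c(298L, 135L, 64L), large = c(441L, 240L, 128L))
.rs_mlp_embed <- c(small = 792L, large = 768L)

rs_variants <- c("UN", "DU", "DP", "MLP_base", "TransConv", "SubPixel")

# pixel shuffle: (B,H,W,C) tokens -> (B,rH,rW,C/r^2); channel co at offset
# (dy,dx) comes from input channel co*r^2 + dy*r + dx.
pixel_shuffle_fwd <- function(x, B, H, W, r) {
  C <- ncol(x)
  stopifnot(C %% (r * r) == 0)
  Cout <- C %/% (r * r)
  out <- matrix(0, B * H * r * W * r, Cout)
  base_b <- rep((seq_len(B) - 1) * H * W, each = H * W)
  ys <- rep(rep(0:(H - 1), each = W), times = B)
  xs <- rep(rep(0:(W - 1), times = H), times = B)
  for (dy in 0:(r - 1)) for (dx in 0:(r - 1)) {
    orow <- base_b * r * r + (ys * r + dy) * (W * r) + (xs * r + dx) + 1
    cols <- (0:(Cout - 1)) * r * r + dy * r + dx + 1
    out[orow, ] <- x[, cols, drop = FALSE]
  }
  out
}

pixel_shuffle_bwd <- function(dout, B, H, W, r, C) {
  dx_ <- matrix(0, B * H * W, C)
  Cout <- C %/% (r * r)
  base_b <- rep((seq_len(B) - 1) * H * W, each = H * W)
  ys <- rep(rep(0:(H - 1), each = W), times = B)
  xs <- rep(rep(0:(W - 1), times = H), times = B)
  for (dy in 0:(r - 1)) for (dx in 0:(r - 1)) {
    orow <- base_b * r * r + (ys * r + dy) * (W * r) + (xs * r + dx) + 1
    cols <- (0:(Cout - 1)) * r * r + dy * r + dx + 1
    dx_[, cols] <- dout[orow, , drop = FALSE]
  }
  dx_
}

# 2x2/stride-2 transposed convolution as linear map + pixel shuffle.
layer_tconv2 <- function(cin, cout, name = "tconv2") {
  new_layer(
    name,
    params = list(W = init_mat(cin, 4 * cout, sqrt(2 / cin)),
                  b = numeric(cout)),
    decay = c(W = TRUE, b = FALSE),
    extra = list(cin = cin, cout = cout),
    fwd = function(x, B, H, W_) {
      self$x <- x; self$B <- B; self$H <- H; self$W_ <- W_
      rs_count_macs(as.double(nrow(x)) * self$cin * 4 * self$cout)
      y <- x %*% self$params$W
      add_bias(pixel_shuffle_fwd(y, B, H, W_, 2L), self$params$b)
    },
    bwd = function(dout) {
      dy <- pixel_shuffle_bwd(dout, self$B, self$H, self$W_, 2L,
                              4 * self$cout)
      self$grads$W <- self$grads$W + crossprod(self$x, dy)
      self$grads$b <- self$grads$b + colSums(dout)
      dx <- dy %*% t(self$params$W)
      self$x <- NULL
      dx
    })
}

# conv/bn/relu x2 fusion block; convs optionally depthwise-separable.
make_fuse_block <- function(cin, cout, separable = FALSE, tag = "blk") {
  mk <- function(ci, co, nm) {
    if (separable) list(dw = layer_dwconv3(ci, paste0(nm, ".dw")),
                        pw = layer_conv(1L, 1L, 0L, ci, co, paste0(nm, ".pw")))
    else list(conv = layer_conv(3L, 1L, 1L, ci, co, nm))
  }
  list(up = layer_bilinear(paste0(tag, ".up")),
       c1 = mk(cin, cout, paste0(tag, ".c1")), bn1 = layer_batchnorm(cout),
       r1 = layer_relu(),
       c2 = mk(cout, cout, paste0(tag, ".c2")), bn2 = layer_batchnorm(cout),
       r2 = layer_relu())
}

conv_unit_fwd <- function(u, x, B, H, W) {
  if (!is.null(u$conv)) return(u$conv$fwd(x, B, H, W))
  u$pw$fwd(u$dw$fwd(x, B, H, W), B, H, W)
}

conv_unit_bwd <- function(u, d) {
  if (!is.null(u$conv)) return(u$conv$bwd(d))
  u$dw$bwd(u$pw$bwd(d))
}

#' Build a decoder for a given variant
#' @keywords internal
rs_decoder <- function(variant, enc_channels, n_classes, size_tag = "small") {
  variant <- match.arg(variant, rs_variants)
  ch <- enc_channels
  dec <- list(variant = variant, n_classes = n_classes,
              enc_channels = ch)
  if (variant %in% c("UN", "DU")) {
    w <- .rs_un_widths[[size_tag]] %||% .rs_un_widths$small
    sep <- variant == "DU"
    dec$widths <- w
    dec$blocks <- list(
      make_fuse_block(ch[4] + ch[3], w[1], sep, "d1"),
      make_fuse_block(w[1] + ch[2], w[2], sep, "d2"),
      make_fuse_block(w[2] + ch[1], w[3], sep, "d3"))
    dec$head <- layer_conv(1L, 1L, 0L, w[3], n_classes, "head",
                           zero_init = TRUE)
  } else if (variant %in% c("MLP_base", "TransConv", "SubPixel")) {
    E <- .rs_mlp_embed[[size_tag]] %||% .rs_mlp_embed[["small"]]
    dec$E <- E
    dec$proj <- lapply(1:4, function(i)
      layer_linear(ch[i], E, sprintf("proj%d", i)))
    if (variant == "TransConv") {
      dec$ups <- lapply(2:4, function(i)
        lapply(seq_len(i - 1), function(k) layer_tconv2(E, E)))
    } else if (variant == "SubPixel") {
      dec$ups <- lapply(2:4, function(i)
        lapply(seq_len(i - 1), function(k)
          list(expand = layer_linear(E, 4L * E))))
    } else {
      dec$ups <- lapply(2:4, function(i) layer_bilinear())
    }
    dec$fuse <- layer_conv(1L, 1L, 0L, 4L * E, E, "fuse")
    dec$bn <- layer_batchnorm(E)
    dec$relu <- layer_relu()
    dec$head <- layer_conv(1L, 1L, 0L, E, n_classes, "head",
                           zero_init = TRUE)
  } else { # DP: ASPP-style context on stride 32 + one stride-4 skip
    A <- 256L
    dec$A <- A
    dec$aspp <- list(
      b1 = layer_conv(1L, 1L, 0L, ch[4], A, "aspp.1x1"),
      b2 = layer_conv(3L, 1L, 1L, ch[4], A, "aspp.3x3"),
      pool_proj = layer_linear(ch[4], A, "aspp.pool"),
      fuse = layer_conv(1L, 1L, 0L, 3L * A, A, "aspp.fuse"),
      bn = layer_batchnorm(A), relu = layer_relu(),
      up = layer_bilinear())
    dec$low <- layer_conv(1L, 1L, 0L, ch[1], 48L, "low")
    dec$ref1 <- make_fuse_block(A + 48L, A, FALSE, "ref")
    dec$head <- layer_conv(1L, 1L, 0L, A, n_classes, "head",
                           zero_init = TRUE)
  }
  dec$final_up <- layer_bilinear("final_up")
  dec
}

check_pyramid <- function(dec, pyr) {
  for (i in 1:4) {
    got <- ncol(pyr[[i]]$x)
    want <- dec$enc_channels[i]
    if (got != want)
      stop("pyramid level ", i, " has ", got, " channels, expected ", want)
  }
}

decoder_forward <- function(dec, pyr) {
  check_pyramid(dec, pyr)
  B <- pyr[[1]]$B
  H0 <- pyr[[1]]$H * 4L; W0 <- pyr[[1]]$W * 4L
  if (dec$variant %in% c("UN", "DU")) {
    x <- pyr[[4]]$x; H <- pyr[[4]]$H; W <- pyr[[4]]$W
    for (k in 1:3) {
      blk <- dec$blocks[[k]]
      skip <- pyr[[4 - k]]
      x <- blk$up$fwd(x, B, H, W, skip$H, skip$W)
      H <- skip$H; W <- skip$W
      x <- cbind(x, skip$x)
      x <- blk$r1$fwd(blk$bn1$fwd(conv_unit_fwd(blk$c1, x, B, H, W)))
      x <- blk$r2$fwd(blk$bn2$fwd(conv_unit_fwd(blk$c2, x, B, H, W)))
    }
    x <- dec$head$fwd(x, B, H, W)
    x <- dec$final_up$fwd(x, B, H, W, H0, W0)
  } else if (dec$variant %in% c("MLP_base", "TransConv", "SubPixel")) {
    H <- pyr[[1]]$H; W <- pyr[[1]]$W
    feats <- vector("list", 4)
    for (i in 1:4) {
      f <- dec$proj[[i]]$fwd(pyr[[i]]$x)
      if (i > 1) {
        u <- dec$ups[[i - 1]]
        hi <- pyr[[i]]$H; wi <- pyr[[i]]$W
        if (dec$variant == "MLP_base") {
          f <- u$fwd(f, B, hi, wi, H, W)
        } else {
          for (step in u) {
            if (dec$variant == "TransConv") {
              f <- step$fwd(f, B, hi, wi)
            } else {
              f <- pixel_shuffle_fwd(step$expand$fwd(f), B, hi, wi, 2L)
            }
            hi <- hi * 2L; wi <- wi * 2L
          }
        }
      }
      feats[[i]] <- f
    }
    x <- do.call(cbind, feats)
    x <- dec$relu$fwd(dec$bn$fwd(dec$fuse$fwd(x, B, H, W)))
    x <- dec$head$fwd(x, B, H, W)
    x <- dec$final_up$fwd(x, B, H, W, H0, W0)
  } else { # DP
    p4 <- pyr[[4]]; p1 <- pyr[[1]]
    H <- p4$H; W <- p4$W
    a1 <- dec$aspp$b1$fwd(p4$x, B, H, W)
    a2 <- dec$aspp$b2$fwd(p4$x, B, H, W)
    # image-level pooling branch: per-sample spatial mean, projected,
    # broadcast back over the grid
    L <- H * W
    means <- t(vapply(seq_len(B), function(b)
      colMeans(p4$x[((b - 1) * L + 1):(b * L), , drop = FALSE]),
      numeric(ncol(p4$x))))
    a3 <- dec$aspp$pool_proj$fwd(means)[rep(seq_len(B), each = L), ,
                                        drop = FALSE]
    x <- cbind(a1, a2, a3)
    x <- dec$aspp$fuse$fwd(x, B, H, W)
    x <- dec$aspp$relu$fwd(dec$aspp$bn$fwd(x))
    x <- dec$aspp$up$fwd(x, B, H, W, p1$H, p1$W)
    low <- dec$low$fwd(p1$x, B, p1$H, p1$W)
    x <- cbind(x, low)
    blk <- dec$ref1
    x <- blk$r1$fwd(blk$bn1$fwd(conv_unit_fwd(blk$c1, x, B, p1$H, p1$W)))
    x <- blk$r2$fwd(blk$bn2$fwd(conv_unit_fwd(blk$c2, x, B, p1$H, p1$W)))
    x <- dec$head$fwd(x, B, p1$H, p1$W)
    x <- dec$final_up$fwd(x, B, p1$H, p1$W, H0, W0)
  }
  list(x = x, B = B, H = H0, W = W0, dec = dec)
}

decoder_backward <- function(dec, dlogits, pyr) {
  B <- pyr[[1]]$B
  dpyr <- vector("list", 4)
  d <- dec$final_up$bwd(dlogits)
  if (dec$variant %in% c("UN", "DU")) {
    d <- dec$head$bwd(d)
    for (k in 3:1) {
      blk <- dec$blocks[[k]]
      d <- conv_unit_bwd(blk$c1, blk$bn1$bwd(blk$r1$bwd(
        conv_unit_bwd(blk$c2, blk$bn2$bwd(blk$r2$bwd(d))))))
      nup <- if (k == 1) dec$enc_channels[4] else dec$widths[k - 1]
      dpyr[[4 - k]] <- d[, (nup + 1):ncol(d), drop = FALSE]
      d <- blk$up$bwd(d[, seq_len(nup), drop = FALSE])
    }
    dpyr[[4]] <- d
  } else if (dec$variant %in% c("MLP_base", "TransConv", "SubPixel")) {
    d <- dec$head$bwd(d)
    d <- dec$fuse$bwd(dec$bn$bwd(dec$relu$bwd(d)))
    E <- dec$E
    for (i in 4:1) {
      df <- d[, ((i - 1) * E + 1):(i * E), drop = FALSE]
      if (i > 1) {
        u <- dec$ups[[i - 1]]
        if (dec$variant == "MLP_base") {
          df <- u$bwd(df)
        } else {
          hi <- pyr[[i]]$H * 2L^(i - 1); wi <- pyr[[i]]$W * 2L^(i - 1)
          for (step in rev(u)) {
            hi <- hi %/% 2L; wi <- wi %/% 2L
            if (dec$variant == "TransConv") {
              df <- step$bwd(df)
            } else {
              df <- step$expand$bwd(
                pixel_shuffle_bwd(df, B, hi, wi, 2L, 4L * E))
            }
          }
        }
      }
      dpyr[[i]] <- dec$proj[[i]]$bwd(df)
    }
  } else { # DP
    d <- dec$head$bwd(d)
    blk <- dec$ref1
    d <- conv_unit_bwd(blk$c1, blk$bn1$bwd(blk$r1$bwd(
      conv_unit_bwd(blk$c2, blk$bn2$bwd(blk$r2$bwd(d))))))
    ns <- dec$A
    dlow <- d[, (ns + 1):ncol(d), drop = FALSE]
    dpyr[[1]] <- dec$low$bwd(dlow)
    d <- dec$aspp$up$bwd(d[, seq_len(ns), drop = FALSE])
    d <- dec$aspp$bn$bwd(dec$aspp$relu$bwd(d))
    d <- dec$aspp$fuse$bwd(d)
    A <- dec$A
    d1 <- dec$aspp$b1$bwd(d[, 1:A, drop = FALSE])
    d2 <- dec$aspp$b2$bwd(d[, (A + 1):(2 * A), drop = FALSE])
    L <- pyr[[4]]$H * pyr[[4]]$W
    dm <- rowsum(d[, (2 * A + 1):(3 * A), drop = FALSE],
                 rep(seq_len(B), each = L))
    dmean <- dec$aspp$pool_proj$bwd(dm)
    d3 <- dmean[rep(seq_len(B), each = L), , drop = FALSE] / L
    dpyr[[4]] <- d1 + d2 + d3
  }
  dpyr
}

#' Assemble a segmentation model
#'
#' Builds the encoder and one of the decoder variants into a full
#' segmentation model with reproducible initialisation.
#'
#' Variants: \code{"UN"} (UNet-style skip-fusion decoder), \code{"DU"}
#' (same with depthwise-separable convolutions), \code{"MLP_base"} (the
#' original lightweight all-MLP decoder), \code{"TransConv"} /
#' \code{"SubPixel"} (all-MLP decoder with transposed-convolution /
#' pixel-shuffle upsampling), \code{"DP"} (ASPP-style context decoder).
#'
#' @param variant decoder variant name (see Details).
#' @param size_tag encoder size, "small" or "large".
#' @param n_classes output classes (2 binary, 4 senescence).
#' @param seed integer seed for weight initialisation.
#' @return Object of class \code{rs_model}.
#' @examples
#' m <- build_model("UN", "small", 2)
#' count_params(m) # 5.81
#' @export
build_model <- function(variant = "UN", size_tag = "small", n_classes = 2,
                        seed = 0) {
  if (!variant %in% rs_variants)
    stop("unknown variant '", variant, "'; supported: ",
         paste(rs_variants, collapse = ", "))
  set.seed(seed)
  cfg <- encoder_config(size_tag)
  enc <- mit_encoder(cfg)
  dec <- rs_decoder(variant, cfg$stage_channels, as.integer(n_classes),
                    size_tag)
  structure(list(encoder = enc, decoder = dec, variant = variant,
                 size_tag = size_tag, n_classes = as.integer(n_classes),
                 seed = seed),
            class = "rs_model")
}

#' @export
print.rs_model <- function(x, ...) {
  cat("rootseg segmentation model: variant", x$variant,
      "| encoder", x$size_tag, "|", x$n_classes, "classes\n")
  cat("  trainable parameters:", format(count_params(x), nsmall = 2),
      "M\n")
  invisible(x)
}

#' Count trainable parameters (in millions)
#'
#' @param model an \code{rs_model} (or any nested structure of layers).
#' @param digits decimal places for the reported value (default 2).
#' @return Parameter count in millions.
#' @export
count_params <- function(model, digits = 2) {
  round(rs_n_params(model) / 1e6, digits)
}

#' Count forward-pass FLOPs (in millions) at a given input size
#'
#' Convention: one multiply-accumulate = 2 FLOPs, counted over all matrix
#' products (convolutions via im2col, linear projections, attention score
#' and value products) plus 4 MACs per bilinear-interpolated output
#' element; elementwise activations and normalisations are not counted.
#' The count is obtained by metering an actual forward pass, so no layer
#' can be silently skipped.
#'
#' @param model an \code{rs_model}.
#' @param input_size spatial side of the square RGB input (default 512).
#' @return FLOPs in millions at the stated input size.
#' @export
count_flops <- function(model, input_size = 512) {
  stopifnot(input_size %% 32 == 0)
  rs_set_training(model, FALSE)
  on.exit(rs_set_training(model, TRUE))
  x <- matrix(0, input_size * input_size, 3)
  fl <- rs_flop_meter({
    pyr <- encoder_forward(model$encoder, x, 1L, input_size, input_size)
    decoder_forward(model$decoder, pyr)
  })
  fl / 1e6
}

#' Run a full forward pass to per-pixel class scores
#'
#' @param model an \code{rs_model}.
#' @param image H x W x 3 array (dims multiples of 32).
#' @param probs return softmax probabilities instead of raw logits.
#' @return H x W x n_classes array.
#' @export
predict_logits <- function(model, image, probs = FALSE) {
  stopifnot(length(dim(image)) == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H %% 32 || W %% 32) stop("input dims must be multiples of 32")
  rs_set_training(model, FALSE)
  on.exit(rs_set_training(model, TRUE))
  pyr <- encoder_forward(model$encoder, spatial_to_tokens(image), 1L, H, W)
  out <- decoder_forward(model$decoder, pyr)
  z <- out$x
  if (probs) z <- softmax_rows(z)
  tokens_to_spatial(z, out$H, out$W)
}

#' Decode a feature pyramid with a UNet-style decoder
#'
#' Fuses the four pyramid levels stride 32 -> 16 -> 8 -> 4 through
#' upsample + skip-concatenation + double-convolution blocks, then a
#' segmentation head and a final x4 upsample restore input resolution.
#'
#' @param model an \code{rs_model} with variant "UN" or "DU".
#' @param pyramid an \code{rs_pyramid} from [encode()].
#' @param probs return per-pixel softmax probabilities.
#' @return H x W x n_classes array at the original input resolution.
#' @export
unet_decode <- function(model, pyramid, probs = FALSE) {
  stopifnot(inherits(model, "rs_model"),
            model$variant %in% c("UN", "DU"))
  rs_set_training(model, FALSE)
  on.exit(rs_set_training(model, TRUE))
  pyr <- lapply(pyramid, function(a)
    list(x = spatial_to_tokens(a), B = 1L, H = dim(a)[1], W = dim(a)[2]))
  out <- decoder_forward(model$decoder, pyr)
  z <- out$x
  if (probs) z <- softmax_rows(z)
  tokens_to_spatial(z, out$H, out$W)
}

#' Double a feature map's resolution by one of three upsampling methods
#'
#' @param feature H x W x C array.
#' @param mode "transposed_conv" (2x2/stride-2 deconvolution, random
#'   weights), "subpixel" (parameter-free pixel shuffle, C must be
#'   divisible by 4) or "bilinear".
#' @param C_out output channels for transposed_conv (default C).
#' @return Upsampled array at 2x resolution.
#' @export
ablation_upsample <- function(feature,
                              mode = c("transposed_conv", "subpixel",
                                       "bilinear"),
                              C_out = NULL) {
  mode <- match.arg(mode)
  H <- dim(feature)[1]; W <- dim(feature)[2]; C <- dim(feature)[3]
  x <- spatial_to_tokens(feature)
  out <- switch(mode,
    transposed_conv = {
      co <- as.integer(C_out %||% C)
      layer_tconv2(C, co)$fwd(x, 1L, H, W)
    },
    subpixel = {
      if (C %% 4 != 0)
        stop("subpixel upsampling needs channels divisible by 4, got ", C)
      pixel_shuffle_fwd(x, 1L, H, W, 2L)
    },
    bilinear = bilinear_fwd_cpp(x, 1L, H, W, 2L * H, 2L * W))
  tokens_to_spatial(out, 2L * H, 2L * W)
}

#' Depthwise-separable convolution block
#'
#' Factorises a dense 3x3 convolution into a per-channel 3x3 spatial
#' convolution followed by a 1x1 pointwise channel fusion, costing
#' C_in*9 + C_in*C_out weights (plus biases) instead of C_in*9*C_out.
#'
#' @param feature H x W x C array.
#' @param C_out output channel count.
#' @param weights optional named list (Wd, bd, Wp, bp).
#' @return List with \code{out} (H x W x C_out array) and \code{n_params}.
#' @export
depthwise_separable_block <- function(feature, C_out, weights = NULL) {
  H <- dim(feature)[1]; W <- dim(feature)[2]; C <- dim(feature)[3]
  dw <- layer_dwconv3(C)
  pw <- layer_conv(1L, 1L, 0L, C, as.integer(C_out))
  if (!is.null(weights)) {
    dw$params <- list(W = weights$Wd, b = weights$bd)
    pw$params <- list(W = weights$Wp, b = weights$bp)
  }
  x <- pw$fwd(dw$fwd(spatial_to_tokens(feature), 1L, H, W), 1L, H, W)
  list(out = tokens_to_spatial(x, H, W),
       n_params = rs_n_params(list(dw, pw)))
}
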