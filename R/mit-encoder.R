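#' Encoder configuration for the hierarchical mix-transformer
#'
#' Describes the four-stage pyramid encoder: per-stage channel widths,
#' block counts, attention head counts and key/value reduction ratios,
#' plus the overlapped patch-merging geometry. Stage 1 embeds the RGB
#' input with a 7x7/stride-4 window; stages 2-4 halve resolution with
#' 3x3/stride-2 windows, so an H x W input yields feature maps at
#' H/2^(i+1) x W/2^(i+1) for stages i = 1..4.
#'
#' Two named configurations are provided. \code{"small"} uses channels
#' (32, 64, 160, 256) with two transformer blocks per stage;
#' \code{"large"} widens to (64, 128, 320, 512) and deepens stage 3,
#' with the decoder widths of [build_model()] calibrated jointly against
#' the published parameter budgets.
#'
#' @param size_tag "small" or "large", or NULL when passing fields directly.
#' @param stage_channels,stage_depths,stage_heads,stage_reduction integer
#'   vectors of length 4.
#' @param mlp_ratio Mix-FFN expansion factor.
#' @return An object of class \code{encoder_config}.
#' @export
encoder_config <- function(size_tag = "small", stage_channels = NULL,
                           stage_depths = NULL, stage_heads = NULL,
                           stage_reduction = NULL, mlp_ratio = 4) {
  presets <- list(
    small = list(channels = c(32, 64, 160, 256), depths = c(2, 2, 2, 2)),
    large = list(channels = c(64, 128, 320, 512), depths = c(2, 2, 4, 2)))
  if (!is.null(size_tag)) {
    if (!size_tag %in% names(presets))
      stop("unknown size_tag '", size_tag, "'; use 'small' or 'large'")
    pre <- presets[[size_tag]]
    if (is.null(stage_channels)) stage_channels <- pre$channels
    if (is.null(stage_depths)) stage_depths <- pre$depths
  }
  if (is.null(stage_heads)) stage_heads <- c(1, 2, 5, 8)
  if (is.null(stage_reduction)) stage_reduction <- c(8, 4, 2, 1)
  stopifnot(length(stage_channels) == 4, length(stage_depths) == 4,
            length(stage_heads) == 4, length(stage_reduction) == 4,
            all(stage_reduction >= 1))
  if (any(stage_channels %% stage_heads != 0))
    stop("stage channels must be divisible by stage head counts")
  cfg <- structure(list(
    stage_channels = as.integer(stage_channels),
    stage_depths = as.integer(stage_depths),
    stage_heads = as.integer(stage_heads),
    stage_reduction = as.integer(stage_reduction),
    patch_params = list(list(K = 7L, S = 4L, P = 3L),
                        list(K = 3L, S = 2L, P = 1L),
                        list(K = 3L, S = 2L, P = 1L),
                        list(K = 3L, S = 2L, P = 1L)),
    mlp_ratio = mlp_ratio,
    size_tag = size_tag %||% "custom"), class = "encoder_config")
  cfg
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("mix-transformer encoder config [", x$size_tag, "]\n", sep = "")
  cat("  channels:", x$stage_channels, "\n  depths:  ", x$stage_depths,
      "\n  heads:   ", x$stage_heads, "\n  reduction:", x$stage_reduction,
      "\n  mlp ratio:", x$mlp_ratio, "\n")
  invisible(x)
}

#' Overlapped patch merging (strided convolution token downsampling)
#'
#' Downsamples a feature map with an overlapping window (K > S preserves
#' local continuity between adjacent patches). Output spatial size is
#' floor((n + 2P - K)/S) + 1 per axis.
#'
#' @param feature H x W x C numeric array.
#' @param K,S,P window size, stride and padding (stage 1 of the encoder
#'   uses 7/4/3; later stages 3/2/1).
#' @param C_out output channel count.
#' @param weights optional (K*K*C) x C_out weight matrix; random
#'   He-initialised when omitted.
#' @param bias optional length-C_out bias (default zeros).
#' @return H' x W' x C_out array.
#' @export
overlapped_patch_merge <- function(feature, K, S, P, C_out,
                                   weights = NULL, bias = NULL) {
  stopifnot(length(dim(feature)) == 3)
  if (K <= 0 || S <= 0 || P < 0) stop("need K > 0, S > 0, P >= 0")
  if (K < 2 * P + 1)
    stop("K < 2P + 1: some windows would lie entirely in padding")
  H <- dim(feature)[1]; W <- dim(feature)[2]; C <- dim(feature)[3]
  if (H + 2 * P < K || W + 2 * P < K) stop("input smaller than window")
  Ho <- conv_out_dim(H, K, S, P); Wo <- conv_out_dim(W, K, S, P)
  if (Ho < 1 || Wo < 1) stop("non-positive output dims")
  x <- spatial_to_tokens(feature)
  cols <- im2col_cpp(x, 1L, H, W, as.integer(K), as.integer(S), as.integer(P))
  if (is.null(weights)) weights <- init_mat(K * K * C, C_out, sqrt(2 / (K * K * C)))
  if (is.null(bias)) bias <- numeric(C_out)
  stopifnot(nrow(weights) == K * K * C, ncol(weights) == C_out)
  tokens_to_spatial(add_bias(cols %*% weights, bias), Ho, Wo)
}

# H x W x C array <-> (H*W) x C row-major token matrix
spatial_to_tokens <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

tokens_to_spatial <- function(x, H, W) {
  aperm(array(x, dim = c(W, H, ncol(x))), c(2, 1, 3))
}

#' Efficient self-attention over a token sequence
#'
#' Scaled dot-product self-attention in which the key and value sequences
#' are shortened by the reduction ratio \code{R}: K and V are reshaped to
#' (L/R) x (C*R) and projected back to C channels by a learned linear map,
#' so the score matrix is L x (L/R) instead of L x L. With R = 1 this is
#' ordinary dense multi-head self-attention. Sequences whose length is not
#' divisible by R are zero-padded to the next multiple before the reshape.
#'
#' @param tokens L x C numeric matrix.
#' @param heads number of attention heads (must divide C).
#' @param R reduction ratio (>= 1).
#' @param weights optional named list (Wq, bq, Wk, bk, Wv, bv, Wo, bo and,
#'   for R > 1, Wkr, bkr, Wvr, bvr); randomly initialised when omitted.
#' @return L x C matrix with attribute \code{"attention"}: a list of
#'   per-head row-stochastic attention matrices.
#' @export
efficient_self_attention <- function(tokens, heads = 1, R = 1,
                                     weights = NULL) {
  stopifnot(is.matrix(tokens))
  if (nrow(tokens) < 1) stop("zero-length token sequence")
  C <- ncol(tokens)
  att <- layer_attention(C, heads, R)
  if (!is.null(weights)) {
    stopifnot(all(names(att$params) %in% names(weights)))
    att$params <- weights[names(att$params)]
  }
  out <- att$fwd(tokens, 1L, nrow(tokens))
  attr(out, "attention") <- att$cache[[1]]$A
  out
}

#' Mix-FFN feed-forward block
#'
#' Residual feed-forward transform: pointwise expansion, 3x3 depthwise
#' convolution over the spatial grid (the encoder's only source of
#' positional information), GELU, pointwise projection, plus the input.
#'
#' @param tokens L x C matrix with L = H * W.
#' @param H,W spatial grid dims of the token sequence.
#' @param mlp_ratio expansion factor for the hidden width.
#' @param weights optional named list (W1, b1, Wd, bd, W2, b2).
#' @return L x C matrix.
#' @export
mix_ffn <- function(tokens, H, W, mlp_ratio = 4, weights = NULL) {
  stopifnot(is.matrix(tokens))
  C <- ncol(tokens)
  if (nrow(tokens) != H * W) stop("token count ", nrow(tokens),
                                  " != H*W = ", H * W)
  hidden <- C * mlp_ratio
  fc1 <- layer_linear(C, hidden)
  dw <- layer_dwconv3(hidden)
  fc2 <- layer_linear(hidden, C)
  if (!is.null(weights)) {
    fc1$params <- list(W = weights$W1, b = weights$b1)
    dw$params <- list(W = weights$Wd, b = weights$bd)
    fc2$params <- list(W = weights$W2, b = weights$b2)
  }
  h <- fc1$fwd(tokens)
  h <- dw$fwd(h, 1L, as.integer(H), as.integer(W))
  h <- h * stats::pnorm(h)
  fc2$fwd(h) + tokens
}

#' Build the hierarchical mix-transformer encoder
#'
#' @param config an [encoder_config()].
#' @return An object of class \code{rs_encoder} holding all layer weights.
#' @export
mit_encoder <- function(config = encoder_config("small")) {
  stopifnot(inherits(config, "encoder_config"))
  cin <- 3L
  stages <- vector("list", 4)
  for (i in 1:4) {
    C <- config$stage_channels[i]
    pp <- config$patch_params[[i]]
    blocks <- vector("list", config$stage_depths[i])
    for (j in seq_along(blocks)) {
      blocks[[j]] <- list(
        ln1 = layer_layernorm(C, sprintf("s%d.b%d.ln1", i, j)),
        attn = layer_attention(C, config$stage_heads[i],
                               config$stage_reduction[i],
                               sprintf("s%d.b%d.attn", i, j)),
        ln2 = layer_layernorm(C, sprintf("s%d.b%d.ln2", i, j)),
        fc1 = layer_linear(C, C * config$mlp_ratio,
                           sprintf("s%d.b%d.fc1", i, j)),
        dw = layer_dwconv3(C * config$mlp_ratio,
                           sprintf("s%d.b%d.dw", i, j)),
        gelu = layer_gelu(),
        fc2 = layer_linear(C * config$mlp_ratio, C,
                           sprintf("s%d.b%d.fc2", i, j)))
    }
    stages[[i]] <- list(
      patch = layer_conv(pp$K, pp$S, pp$P, cin, C, sprintf("s%d.patch", i)),
      embed_ln = layer_layernorm(C, sprintf("s%d.embed_ln", i)),
      blocks = blocks,
      out_ln = layer_layernorm(C, sprintf("s%d.out_ln", i)))
    cin <- C
  }
  structure(list(config = config, stages = stages), class = "rs_encoder")
}

# Forward through the encoder on token input x ((B*H*W) x 3).
# Returns list(pyramid = 4 x list(x, B, H, W)).
encoder_forward <- function(enc, x, B, H, W) {
  pyramid <- vector("list", 4)
  for (i in 1:4) {
    st <- enc$stages[[i]]
    x <- st$patch$fwd(x, B, H, W)
    H <- conv_out_dim(H, st$patch$K, st$patch$S, st$patch$P)
    W <- conv_out_dim(W, st$patch$K, st$patch$S, st$patch$P)
    x <- st$embed_ln$fwd(x)
    L <- H * W
    for (bl in st$blocks) {
      x <- x + bl$attn$fwd(bl$ln1$fwd(x), B, L)
      h <- bl$fc1$fwd(bl$ln2$fwd(x))
      h <- bl$dw$fwd(h, B, H, W)
      h <- bl$gelu$fwd(h)
      x <- x + bl$fc2$fwd(h)
    }
    x <- st$out_ln$fwd(x)
    pyramid[[i]] <- list(x = x, B = B, H = H, W = W)
  }
  pyramid
}

# Backward: dpyr is a list of 4 gradients matching encoder_forward output
# (NULL entries allowed). Returns nothing useful (input gradient dropped).
encoder_backward <- function(enc, dpyr) {
  d <- NULL
  for (i in 4:1) {
    st <- enc$stages[[i]]
    di <- dpyr[[i]]
    if (is.null(d)) d <- di else if (!is.null(di)) d <- d + di
    d <- st$out_ln$bwd(d)
    for (bl in rev(st$blocks)) {
      dh <- bl$fc2$bwd(d)
      dh <- bl$gelu$bwd(dh)
      dh <- bl$dw$bwd(dh)
      d <- d + bl$ln2$bwd(bl$fc1$bwd(dh))
      d <- d + bl$ln1$bwd(bl$attn$bwd(d))
    }
    d <- st$embed_ln$bwd(d)
    d <- st$patch$bwd(d)
  }
  invisible(d)
}

#' Encode an image into a four-level feature pyramid
#'
#' Runs the encoder: each stage halves the resolution, producing maps at
#' 1/4, 1/8, 1/16 and 1/32 of the input with the configured channel
#' widths. Height and width must be multiples of 32 (resize upstream with
#' [resize_pair()] otherwise).
#'
#' @param encoder an [mit_encoder()].
#' @param image H x W x 3 numeric array.
#' @return List of 4 feature arrays (class \code{rs_pyramid}).
#' @export
encode <- function(encoder, image) {
  stopifnot(inherits(encoder, "rs_encoder"), length(dim(image)) == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H %% 32 != 0 || W %% 32 != 0)
    stop("input dims ", H, "x", W, " are not multiples of 32; ",
         "resize upstream (see resize_pair) before encoding")
  pyr <- encoder_forward(encoder, spatial_to_tokens(image), 1L, H, W)
  out <- lapply(pyr, function(p) tokens_to_spatial(p$x, p$H, p$W))
  class(out) <- "rs_pyramid"
  out
}
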