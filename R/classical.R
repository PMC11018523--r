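# Classical (non-learning) senescent-root extraction: morphological
# taproot removal, reference-block mean/variance classification, and
# sliding-window 2-norm pixel enhancement. Morphology, blur and Otsu
# thresholding go through EBImage.

#' Split a binary root prediction into taproot and lateral roots
#'
#' The dominant vertical structure is isolated by a morphological opening
#' with a tall vertical structuring element; its edge (Sobel gradient
#' magnitude, Gaussian-blurred and Otsu-thresholded) is united with the
#' opening to capture the taproot boundary halo. Lateral roots are the
#' remaining foreground. Both outputs are subsets of the input
#' foreground.
#'
#' @param binary H x W 0/1 root mask.
#' @param open_height height (px) of the vertical structuring element;
#'   default one fifth of the image height (odd).
#' @param blur_sigma Gaussian blur applied to the gradient (default 2).
#' @return List with 0/1 matrices \code{taproot} and \code{lateral}.
#' @export
remove_taproot <- function(binary, open_height = NULL, blur_sigma = 2) {
  stopifnot(is.matrix(binary))
  binary <- (binary != 0) * 1
  if (sum(binary) == 0) {
    warning("empty root mask: returning empty taproot and lateral masks")
    return(list(taproot = binary * 0, lateral = binary * 0))
  }
  H <- nrow(binary)
  if (is.null(open_height)) open_height <- max(15L, round(H / 5))
  if (open_height %% 2 == 0) open_height <- open_height + 1
  kern <- matrix(1, open_height, 1)
  opened <- EBImage::opening(binary, kern)
  sobel_y <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(opened, sobel_y)
  gy <- EBImage::filter2(opened, t(sobel_y))
  grad <- sqrt(gx^2 + gy^2)
  if (max(grad) > 0) grad <- grad / max(grad)
  grad <- EBImage::gblur(grad, sigma = blur_sigma)
  edge <- if (max(grad) > min(grad)) {
    thr <- EBImage::otsu(EBImage::Image(grad), range = range(grad))
    (grad > thr) * 1
  } else grad * 0
  taproot <- pmin(1, (opened + edge)) * binary
  lateral <- binary * (1 - taproot)
  list(taproot = taproot, lateral = lateral)
}

#' Per-channel mean/variance statistics of reference pixel blocks
#'
#' The operator supplies one normal-root block and two senescent-root
#' blocks picked from the original RGB image; their channel statistics
#' drive [classify_by_stats()].
#'
#' @param image H x W x 3 array in [0, 1].
#' @param normal,senescent1,senescent2 blocks c(y, x, h, w) in 1-based
#'   matrix coordinates.
#' @return Object of class \code{ref_block_stats}.
#' @export
ref_block_stats <- function(image, normal, senescent1, senescent2) {
  grab <- function(b, nm) {
    px <- matrix(image[b[1]:(b[1] + b[3] - 1), b[2]:(b[2] + b[4] - 1), ],
                 ncol = 3)
    v <- apply(px, 2, stats::var)
    if (any(v == 0))
      stop("reference block '", nm, "' has zero variance in a channel; ",
           "choose a larger or more textured block")
    list(mean = colMeans(px), sd = sqrt(v))
  }
  structure(list(normal = grab(normal, "normal"),
                 senescent = list(grab(senescent1, "senescent1"),
                                  grab(senescent2, "senescent2"))),
            class = "ref_block_stats")
}

within_envelope <- function(px, st, k) {
  lo <- st$mean - k * st$sd; hi <- st$mean + k * st$sd
  (px[, 1] >= lo[1] & px[, 1] <= hi[1]) &
    (px[, 2] >= lo[2] & px[, 2] <= hi[2]) &
    (px[, 3] >= lo[3] & px[, 3] <= hi[3])
}

#' Mean/variance classification of root pixels into normal root
#'
#' Root pixels whose RGB values fall inside the normal block's
#' mean +- k*sd envelope and outside both senescent envelopes are kept.
#' The pass is applied twice: the intermediate mask is despeckled
#' (Gaussian-smoothed and re-thresholded) before the envelopes filter
#' the surviving pixels once more.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param root_mask H x W 0/1 mask restricting classification to roots.
#' @param stats a [ref_block_stats()].
#' @param k envelope half-width in standard deviations (default 2).
#' @return H x W 0/1 mask of retained normal-root pixels.
#' @export
classify_by_stats <- function(image, root_mask, stats, k = 2) {
  stopifnot(inherits(stats, "ref_block_stats"),
            all(dim(image)[1:2] == dim(root_mask)))
  H <- dim(image)[1]; W <- dim(image)[2]
  px <- matrix(image, H * W, 3)
  keep <- within_envelope(px, stats$normal, k) &
    !within_envelope(px, stats$senescent[[1]], k) &
    !within_envelope(px, stats$senescent[[2]], k)
  m1 <- matrix(as.numeric(keep), H, W) * (root_mask != 0)
  # despeckle, then filter by mean/variance once again
  sm <- EBImage::gblur(m1, sigma = 1) > 0.4
  m2 <- sm & matrix(keep, H, W) & (root_mask != 0)
  m2 * 1
}

#' Sliding-window 2-norm pixel enhancement
#'
#' Scans both images row-major with a 2 px core window (stride 1). Any
#' window where the 2-norm of original - filtered is positive copies the
#' original block into the filtered image; where the 2 px core is
#' identical but its 4 px surround differs, the window grows to 4 px and
#' the larger block is restored. Idempotent on its own output.
#'
#' @param original,filtered H x W x C arrays of identical shape.
#' @return Enhanced H x W x C array.
#' @export
pixel_enhance <- function(original, filtered) {
  if (!all(dim(original) == dim(filtered)))
    stop("shape mismatch: ", paste(dim(original), collapse = "x"),
         " vs ", paste(dim(filtered), collapse = "x"))
  d <- dim(original)
  if (length(d) == 2) {
    original <- array(original, c(d, 1))
    filtered <- array(filtered, c(d, 1))
  }
  out <- pixel_enhance_cpp(spatial_to_tokens(original),
                           spatial_to_tokens(filtered),
                           dim(original)[1], dim(original)[2])
  res <- tokens_to_spatial(out, dim(original)[1], dim(original)[2])
  if (length(d) == 2) res <- res[, , 1]
  res
}

#' Classical end-to-end senescent/normal root separation
#'
#' Chains the traditional pipeline: taproot removal from the binary
#' prediction, mean/variance classification of the lateral roots using
#' the reference blocks, and pixel enhancement of the filtered result
#' against the original image.
#'
#' @param image H x W x 3 RGB array.
#' @param binary H x W 0/1 root prediction.
#' @param stats a [ref_block_stats()].
#' @param k envelope half-width (default 2).
#' @return List: \code{taproot}, \code{lateral}, \code{normal} (0/1
#'   masks), \code{enhanced} (RGB array of the enhanced filtered image).
#' @export
classical_baseline <- function(image, binary, stats, k = 2) {
  tp <- remove_taproot(binary)
  normal <- classify_by_stats(image, tp$lateral, stats, k)
  filtered <- image * as.vector(normal)
  enhanced <- pixel_enhance(image, filtered)
  list(taproot = tp$taproot, lateral = tp$lateral, normal = normal,
       enhanced = enhanced)
}
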