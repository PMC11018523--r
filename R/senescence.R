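# Four-class senescence post-processing: binary-mask protection, SLIC
# superpixel majority correction, time-series pixel statistics, cubic
# trajectory fitting and time-interval clustering.

# sRGB [0,1] -> CIELAB (D65), vectorised over an n x 3 matrix
rgb_to_lab <- function(px) {
  lin <- ifelse(px <= 0.04045, px / 12.92, ((px + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1, 1.08883)
  xyz <- sweep(xyz, 2, wp, "/")
  f <- ifelse(xyz > (6 / 29)^3, xyz^(1 / 3),
              xyz / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' SLIC superpixel partition of an RGB image
#'
#' Localised k-means in combined CIELAB + spatial (l, a, b, x, y) space:
#' cluster centres start on a regular grid of spacing S = sqrt(HW/n) and
#' pixels within a 2S window of each centre compete by the distance
#' D = sqrt(d_lab^2 + (d_xy/S)^2 * m^2), where m is the compactness.
#' A final pass enforces 4-connectivity, absorbing fragments smaller
#' than S^2/4 into their neighbour.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param n_segments target segment count (default one per 25 x 25 px).
#' @param compactness spatial weight m (default 10).
#' @param iterations assignment/update sweeps (default 10).
#' @return Object of class \code{superpixel_partition}: \code{labels}
#'   (H x W, 1-based), \code{n_segments}.
#' @export
slic_partition <- function(image, n_segments = NULL, compactness = 10,
                           iterations = 10) {
  stopifnot(length(dim(image)) == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(n_segments)) n_segments <- max(1, round(H * W / 625))
  if (n_segments > H * W)
    stop("n_segments (", n_segments, ") exceeds pixel count ", H * W)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments == 1) {
    return(structure(list(labels = matrix(1L, H, W), n_segments = 1L),
                     class = "superpixel_partition"))
  }
  lab <- rgb_to_lab(matrix(image, H * W, 3))
  Lm <- matrix(lab[, 1], H, W); am <- matrix(lab[, 2], H, W)
  bm <- matrix(lab[, 3], H, W)
  S <- sqrt(H * W / n_segments)
  cy <- seq(S / 2, H, by = S); cx <- seq(S / 2, W, by = S)
  centers <- expand.grid(y = cy, x = cx)
  yi <- pmin(H, pmax(1, round(centers$y)))
  xi <- pmin(W, pmax(1, round(centers$x)))
  ctr <- cbind(L = Lm[cbind(yi, xi)], a = am[cbind(yi, xi)],
               b = bm[cbind(yi, xi)], y = centers$y, x = centers$x)
  nC <- nrow(ctr)
  m2S2 <- (compactness / S)^2
  ygrid <- matrix(seq_len(H), H, W); xgrid <- matrix(seq_len(W), H, W,
                                                    byrow = TRUE)
  labels <- matrix(0L, H, W)
  for (it in seq_len(iterations)) {
    best <- matrix(Inf, H, W)
    for (k in seq_len(nC)) {
      ys <- max(1, floor(ctr[k, "y"] - S)):min(H, ceiling(ctr[k, "y"] + S))
      xs <- max(1, floor(ctr[k, "x"] - S)):min(W, ceiling(ctr[k, "x"] + S))
      dlab <- (Lm[ys, xs] - ctr[k, "L"])^2 + (am[ys, xs] - ctr[k, "a"])^2 +
        (bm[ys, xs] - ctr[k, "b"])^2
      dxy <- (ygrid[ys, xs] - ctr[k, "y"])^2 + (xgrid[ys, xs] - ctr[k, "x"])^2
      D <- dlab + dxy * m2S2
      upd <- D < best[ys, xs]
      if (any(upd)) {
        bb <- best[ys, xs]; ll <- labels[ys, xs]
        bb[upd] <- D[upd]; ll[upd] <- k
        best[ys, xs] <- bb; labels[ys, xs] <- ll
      }
    }
    # pixels outside every window (possible on ragged grids): nearest centre
    if (any(labels == 0L)) {
      miss <- which(labels == 0L, arr.ind = TRUE)
      for (i in seq_len(nrow(miss))) {
        d <- (ctr[, "y"] - miss[i, 1])^2 + (ctr[, "x"] - miss[i, 2])^2
        labels[miss[i, 1], miss[i, 2]] <- which.min(d)
      }
    }
    idx <- as.vector(labels)
    u <- sort(unique(idx))
    cnt <- tabulate(idx, nC)
    for (nm in c("L", "a", "b", "y", "x")) {
      v <- switch(nm, L = Lm, a = am, b = bm, y = ygrid, x = xgrid)
      ctr[u, nm] <- as.vector(rowsum(as.vector(v), idx)) / cnt[u]
    }
  }
  labels <- enforce_connectivity_cpp(labels, as.integer(max(1, S * S / 4)))
  structure(list(labels = labels, n_segments = max(labels)),
            class = "superpixel_partition")
}

#' @export
print.superpixel_partition <- function(x, ...) {
  cat("superpixel partition:", x$n_segments, "segments over",
      paste(dim(x$labels), collapse = " x "), "px\n")
  invisible(x)
}

#' Protect senescence labels with a binary root mask
#'
#' The binary prediction is the authority on root extent: every pixel
#' outside its foreground becomes soil (class 0), every foreground pixel
#' keeps its senescence class, and foreground pixels the senescence pass
#' called soil are reassigned to normal root (class 1) so that all root
#' pixels carry a root class.
#'
#' @param senescence H x W matrix with classes 0 soil / 1 normal /
#'   2 senescent / 3 taproot.
#' @param binary H x W 0/1 root mask.
#' @return Corrected H x W senescence label matrix.
#' @export
protect_with_binary <- function(senescence, binary) {
  if (!all(dim(senescence) == dim(binary)))
    stop("shape mismatch: senescence ",
         paste(dim(senescence), collapse = "x"), " vs binary ",
         paste(dim(binary), collapse = "x"))
  out <- senescence
  out[binary == 0] <- 0L
  out[binary != 0 & senescence == 0] <- 1L
  out
}

#' Majority-vote superpixel correction of senescence labels
#'
#' Within each superpixel, all root pixels (classes 1-3) are reassigned
#' to the modal root class of that segment (the colour with the highest
#' weight, weight = pixel count); ties go to the lower class index
#' (normal before senescent). Soil pixels are never touched, and
#' segments containing no root pixels are left unchanged. The operation
#' is idempotent and preserves the total root pixel count.
#'
#' @param labels H x W senescence label matrix.
#' @param partition a [slic_partition()] over the same image.
#' @return Corrected H x W label matrix.
#' @export
majority_correct <- function(labels, partition) {
  stopifnot(inherits(partition, "superpixel_partition"))
  seg <- partition$labels
  if (!all(dim(labels) == dim(seg)))
    stop("labels and partition shapes differ")
  ns <- max(seg)
  counts <- vapply(1:3, function(k) tabulate(seg[labels == k], ns),
                   numeric(ns))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = ns)
  modal <- max.col(counts, ties.method = "first") # lowest class wins ties
  root <- labels > 0
  out <- labels
  out[root] <- modal[seg[root]]
  out
}

#' Per-timepoint root pixel statistics of a senescence series
#'
#' Counts normal / senescent / taproot pixels per image and derives two
#' normalisations: proportions over root pixels (classes 1+2+3) and
#' ratios over the whole image. Images without root pixels yield missing
#' (NA) proportions rather than zeros.
#'
#' @param images list of H x W senescence label matrices.
#' @param timepoints numeric days, strictly increasing, one per image.
#' @return data.frame of class \code{senescence_series}.
#' @export
count_series <- function(images, timepoints) {
  if (!length(images)) stop("empty series")
  stopifnot(length(images) == length(timepoints))
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  rows <- lapply(seq_along(images), function(i) {
    m <- images[[i]]
    n1 <- sum(m == 1); n2 <- sum(m == 2); n3 <- sum(m == 3)
    tot <- n1 + n2 + n3
    data.frame(day = timepoints[i], normal = n1, senescent = n2,
               taproot = n3,
               prop_normal = if (tot > 0) n1 / tot else NA_real_,
               prop_senescent = if (tot > 0) n2 / tot else NA_real_,
               ratio_normal = n1 / length(m),
               ratio_senescent = n2 / length(m))
  })
  structure(do.call(rbind, rows),
            class = c("senescence_series", "data.frame"))
}

#' Least-squares cubic fit of a senescence trajectory
#'
#' Fits y = c0 + c1 t + c2 t^2 + c3 t^3 by ordinary least squares and
#' reports R^2 = 1 - SS_res/SS_tot and MSE = SS_res/n. Missing values
#' are dropped. Constant responses have undefined R^2 (reported NA).
#'
#' @param timepoints numeric predictor (days).
#' @param proportions numeric response.
#' @return List of class \code{cubic_fit}: coefficients (c0..c3),
#'   r_squared, mse, fitted, model (the underlying \code{lm}).
#' @export
fit_cubic <- function(timepoints, proportions) {
  ok <- is.finite(timepoints) & is.finite(proportions)
  t_ <- timepoints[ok]; y <- proportions[ok]
  if (length(unique(t_)) < 4)
    stop("cubic fit needs at least 4 distinct timepoints, got ",
         length(unique(t_)))
  fit <- stats::lm(y ~ t_ + I(t_^2) + I(t_^3))
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    coefficients = stats::setNames(stats::coef(fit),
                                   c("c0", "c1", "c2", "c3")),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    mse = ss_res / length(y),
    fitted = stats::fitted(fit),
    model = fit), class = "cubic_fit")
}

#' @export
print.cubic_fit <- function(x, ...) {
  cat("cubic trajectory fit: y =",
      paste(sprintf("%.3g", x$coefficients), c("", "t", "t^2", "t^3"),
            collapse = " + "), "\n")
  cat(sprintf("  R^2 = %.4f, MSE = %.3g\n", x$r_squared, x$mse))
  invisible(x)
}

#' Cluster a time series into k intervals
#'
#' Reduces per-timepoint features (by default normal, senescent and total
#' root pixel counts of a [count_series()] result) to two principal
#' components and k-means-clusters them; reports whether each cluster's
#' timepoints are contiguous in time.
#'
#' @param x a \code{senescence_series}, or a numeric matrix/vector of
#'   per-timepoint features.
#' @param k number of clusters (default 10 time intervals).
#' @param seed RNG seed for k-means restarts.
#' @return List: \code{assignment} (one cluster id per timepoint),
#'   \code{contiguous} (logical per cluster), \code{scores} (PC scores).
#' @export
cluster_timepoints <- function(x, k = 10, seed = 0) {
  if (inherits(x, "senescence_series"))
    feats <- cbind(x$normal, x$senescent, x$normal + x$senescent + x$taproot)
  else feats <- as.matrix(x)
  n <- nrow(feats)
  if (k > n) stop("k = ", k, " exceeds number of timepoints ", n)
  keep <- apply(feats, 2, stats::sd) > 0
  scores <- if (any(keep) && n > 1) {
    pc <- stats::prcomp(feats[, keep, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  } else feats
  set.seed(seed)
  assign_ <- if (k == n) seq_len(n) # one cluster per point: exact optimum
  else stats::kmeans(scores, centers = k, nstart = 10)$cluster
  contiguous <- vapply(seq_len(k), function(cl) {
    w <- which(assign_ == cl)
    length(w) == 0 || all(diff(w) == 1)
  }, logical(1))
  list(assignment = assign_, contiguous = contiguous, scores = scores)
}

#' Nearest-reference-colour senescence classification
#'
#' Simple per-pixel classifier assigning each pixel to the class of the
#' nearest reference colour in CIELAB space; serves as the inference
#' stand-in ahead of binary-mask protection and superpixel correction in
#' the post-processing pipeline.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param centers n_classes x 3 matrix of reference RGB colours in
#'   [0, 1], one row per class (row 1 = class 0).
#' @return H x W integer label matrix.
#' @export
classify_by_colors <- function(image, centers) {
  stopifnot(length(dim(image)) == 3, ncol(centers) == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  lab <- rgb_to_lab(matrix(image, H * W, 3))
  clab <- rgb_to_lab(centers)
  d <- sapply(seq_len(nrow(clab)), function(k)
    colSums((t(lab) - clab[k, ])^2))
  matrix(max.col(-d) - 1L, H, W)
}
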