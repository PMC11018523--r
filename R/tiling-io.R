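# Annotation colour schemes, giant-scan tiling with exact stitching,
# mask encoding/decoding, and dataset splitting.

#' Annotation label schemes
#'
#' \code{"binary"} maps 0 = soil (black) and 1 = root (white);
#' \code{"senescence"} maps 0 = soil (black), 1 = normal root (green),
#' 2 = senescent root (red), 3 = taproot (white). Palettes are bijections
#' between class indices and RGB triples.
#'
#' @param name "binary" or "senescence".
#' @return Object of class \code{label_scheme} with a palette matrix
#'   (one class per row, RGB in 0..255).
#' @export
label_scheme <- function(name = c("binary", "senescence")) {
  name <- match.arg(name)
  pal <- if (name == "binary") {
    rbind(soil = c(0, 0, 0), root = c(255, 255, 255))
  } else {
    rbind(soil = c(0, 0, 0), normal = c(0, 255, 0),
          senescent = c(255, 0, 0), taproot = c(255, 255, 255))
  }
  structure(list(name = name, palette = pal, n_classes = nrow(pal)),
            class = "label_scheme")
}

#' Plan a tile grid for an image of given size
#'
#' rows = ceiling(H/window), cols = ceiling(W/window); the padded canvas
#' (rows*window x cols*window) is partitioned exactly, padding filled
#' with black. Offsets are 0-based, origin top-left, row-major.
#'
#' @param h,w source image size in px.
#' @param window tile side in px (default 768).
#' @return Object of class \code{tile_grid}.
#' @export
plan_tile_grid <- function(h, w, window = 768) {
  stopifnot(window > 0, h >= 1, w >= 1)
  rows <- ceiling(h / window); cols <- ceiling(w / window)
  structure(list(h = as.integer(h), w = as.integer(w),
                 window = as.integer(window),
                 rows = as.integer(rows), cols = as.integer(cols),
                 padded_h = as.integer(rows * window),
                 padded_w = as.integer(cols * window)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %d x %d px, window %d -> %d x %d = %d tiles\n",
              x$h, x$w, x$window, x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

#' Cut an image (or mask) into fixed-size tiles with black padding
#'
#' Non-overlapping windows; bottom/right tiles are padded with black
#' pixels (value 0). Every source pixel lands in exactly one tile. Each
#' tile carries its 0-based grid position as attributes \code{row} /
#' \code{col}, so a shuffled tile list still stitches correctly.
#'
#' @param image H x W x C array or H x W matrix.
#' @param window tile side (default 768).
#' @return List with \code{tiles} (row-major list) and \code{grid}.
#' @export
tile_image <- function(image, window = 768) {
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1) || length(image) == 0)
    stop("empty image")
  grid <- plan_tile_grid(d[1], d[2], window)
  is_mat <- length(d) == 2
  tiles <- vector("list", grid$rows * grid$cols)
  k <- 0
  for (r in seq_len(grid$rows)) {
    for (cc in seq_len(grid$cols)) {
      k <- k + 1
      y0 <- (r - 1) * grid$window; x0 <- (cc - 1) * grid$window
      ys <- (y0 + 1):min(y0 + grid$window, d[1])
      xs <- (x0 + 1):min(x0 + grid$window, d[2])
      tile <- if (is_mat) {
        t_ <- matrix(vector(typeof(image), 1), grid$window, grid$window)
        t_[seq_along(ys), seq_along(xs)] <- image[ys, xs]
        t_
      } else {
        t_ <- array(vector(typeof(image), 1),
                    c(grid$window, grid$window, d[3]))
        t_[seq_along(ys), seq_along(xs), ] <- image[ys, xs, ]
        t_
      }
      attr(tile, "row") <- r - 1L
      attr(tile, "col") <- cc - 1L
      tiles[[k]] <- tile
    }
  }
  list(tiles = tiles, grid = grid)
}

#' Reassemble tiles into the original image
#'
#' Exact inverse of [tile_image()]: places each tile at the offset given
#' by its \code{row}/\code{col} attributes and crops the padded canvas
#' back to the source size. Order-independent.
#'
#' @param tiles list of tiles from [tile_image()].
#' @param grid the matching \code{tile_grid}.
#' @return The restored image/mask at the original H x W.
#' @export
stitch <- function(tiles, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  seen <- matrix(FALSE, grid$rows, grid$cols)
  first <- tiles[[1]]
  is_mat <- length(dim(first)) == 2
  canvas <- if (is_mat)
    matrix(vector(typeof(first), 1), grid$padded_h, grid$padded_w)
  else array(vector(typeof(first), 1),
             c(grid$padded_h, grid$padded_w, dim(first)[3]))
  for (tile in tiles) {
    r <- attr(tile, "row"); cc <- attr(tile, "col")
    if (is.null(r) || is.null(cc))
      stop("tile without row/col position attributes")
    ys <- (r * grid$window + 1):((r + 1) * grid$window)
    xs <- (cc * grid$window + 1):((cc + 1) * grid$window)
    if (is_mat) canvas[ys, xs] <- tile else canvas[ys, xs, ] <- tile
    seen[r + 1, cc + 1] <- TRUE
  }
  if (!all(seen)) {
    miss <- which(!seen, arr.ind = TRUE)[1, ]
    stop("missing tile at grid row ", miss[1] - 1, ", col ", miss[2] - 1)
  }
  if (is_mat) canvas[seq_len(grid$h), seq_len(grid$w)]
  else canvas[seq_len(grid$h), seq_len(grid$w), , drop = FALSE]
}

#' Nearest-neighbour resize of a label matrix
#' @param mask H x W matrix.
#' @param ho,wo target size.
#' @return Resized matrix (label set preserved).
#' @export
nearest_resize <- function(mask, ho, wo) {
  d <- dim(mask)
  yi <- pmin(d[1], pmax(1, floor((seq_len(ho) - 0.5) * d[1] / ho) + 1))
  xi <- pmin(d[2], pmax(1, floor((seq_len(wo) - 0.5) * d[2] / wo) + 1))
  mask[yi, xi, drop = FALSE]
}

#' Resize an image/mask pair for model input
#'
#' The image is interpolated bilinearly; the mask by nearest neighbour so
#' its label set is preserved exactly.
#'
#' @param image H x W x C array.
#' @param mask H x W label matrix (same spatial size).
#' @param side target side length (default 512).
#' @return List with resized \code{image} and \code{mask}.
#' @export
resize_pair <- function(image, mask, side = 512) {
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  d <- dim(image)
  img <- tokens_to_spatial(
    bilinear_fwd_cpp(spatial_to_tokens(image), 1L, d[1], d[2],
                     as.integer(side), as.integer(side)),
    side, side)
  list(image = img, mask = nearest_resize(mask, side, side))
}

#' Encode a label matrix as an RGB mask image
#'
#' @param labels H x W integer matrix of class indices.
#' @param scheme a [label_scheme()].
#' @return H x W x 3 array in [0, 1] (write with [write_image()]).
#' @export
encode_mask <- function(labels, scheme = label_scheme("binary")) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (any(labels < 0 | labels >= scheme$n_classes))
    stop("labels outside scheme range 0..", scheme$n_classes - 1)
  pal <- scheme$palette / 255
  d <- dim(labels)
  array(pal[labels + 1L, ], c(d[1], d[2], 3))
}

#' Decode an RGB mask image into a label matrix
#'
#' In strict mode every pixel must match a palette colour exactly
#' (error reports the first offending location and colour); in lenient
#' mode off-palette pixels snap to the nearest palette colour in RGB
#' distance and the count is reported via attribute \code{n_snapped}.
#'
#' @param rgb H x W x 3 array in [0, 1] (or 0..255).
#' @param scheme a [label_scheme()].
#' @param strict error on off-palette pixels (default TRUE).
#' @return H x W integer label matrix.
#' @export
decode_mask <- function(rgb, scheme = label_scheme("binary"),
                        strict = TRUE) {
  stopifnot(inherits(scheme, "label_scheme"), length(dim(rgb)) == 3)
  if (max(rgb) <= 1) rgb <- rgb * 255
  d <- dim(rgb)
  px <- matrix(round(rgb), d[1] * d[2], 3)
  pal <- scheme$palette
  d2 <- sapply(seq_len(nrow(pal)), function(k)
    colSums((t(px) - pal[k, ])^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  lab <- max.col(-d2)
  mind <- d2[cbind(seq_len(nrow(d2)), lab)]
  off <- mind > 0
  if (any(off)) {
    if (strict) {
      i <- which(off)[1]
      y <- (i - 1) %% d[1] + 1; x <- (i - 1) %/% d[1] + 1
      stop("off-palette pixel at (", y, ",", x, "): [",
           paste(px[i, ], collapse = ","), "] not in '", scheme$name,
           "' palette (use strict = FALSE to snap)")
    }
  }
  out <- matrix(lab - 1L, d[1], d[2])
  attr(out, "n_snapped") <- sum(off)
  out
}

#' Read an RGB image (JPEG or PNG)
#' @param path file path; format chosen by extension.
#' @return H x W x 3 array in [0, 1].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    jpg = , jpeg = jpeg::readJPEG(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB image (JPEG or PNG)
#' @param image H x W x 3 array in [0, 1].
#' @param path destination; format chosen by extension.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- pmin(pmax(image, 0), 1)
  switch(ext,
    jpg = , jpeg = jpeg::writeJPEG(image, path, quality = 0.95),
    png = png::writePNG(image, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Write/read tile-grid metadata as a JSON sidecar
#' @param grid a \code{tile_grid}.
#' @param path JSON file path.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(unclass(grid), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(g, as.integer), class = "tile_grid")
}

#' Split items into train/validation/test sets
#'
#' Reproducible shuffled split with largest-remainder rounding of the
#' fraction sizes (so sizes always sum to the item count).
#'
#' @param items vector or list to split.
#' @param fractions length-3 fractions summing to 1 (default 0.7/0.2/0.1).
#' @param seed RNG seed.
#' @return List with elements \code{train}, \code{val}, \code{test}.
#' @export
split_dataset <- function(items, fractions = c(0.7, 0.2, 0.1), seed = 0) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  n <- length(items)
  if (n < sum(fractions > 0))
    stop("fewer items (", n, ") than non-empty splits")
  sizes <- floor(n * fractions)
  rem <- n * fractions - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[give] <- sizes[give] + 1
  }
  set.seed(seed)
  ord <- sample(n)
  take <- function(from, len)
    if (len == 0) items[integer(0)] else items[ord[from:(from + len - 1)]]
  list(train = take(1, sizes[1]),
       val = take(sizes[1] + 1, sizes[2]),
       test = take(sizes[1] + sizes[2] + 1, sizes[3]))
}
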