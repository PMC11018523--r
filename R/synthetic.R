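# Deterministic generator of synthetic root-scan scenes and time series
# with paired ground-truth masks: curvilinear branching laterals on
# multi-octave noise soil, a thick vertical taproot, low-contrast and
# occluded segments, and nested growth/senescence over time.

#' Specification of a synthetic root scene
#'
#' @param canvas square canvas side in px (default 256).
#' @param n_lateral_roots number of lateral roots branching off the
#'   taproot.
#' @param taproot_width taproot width in px (0 disables the taproot).
#' @param root_width_range min/max lateral root width in px.
#' @param senescent_frac target senescent fraction of root pixels
#'   (classes 2 / (1+2+3)); the rendered fraction is within 0.05.
#' @param soil_base base soil RGB colour.
#' @param soil_noise amplitude of the multi-octave soil value noise.
#' @param occlusion_density fraction of the canvas covered by occluding
#'   soil particles drawn over the roots (image only, never the masks).
#' @param low_contrast_frac fraction of laterals rendered low-contrast
#'   (blended towards the soil colour).
#' @param seed RNG seed; identical specs render bitwise-identical scenes.
#' @return Object of class \code{scene_spec}.
#' @export
scene_spec <- function(canvas = 256, n_lateral_roots = 8,
                       taproot_width = 10, root_width_range = c(3, 6),
                       senescent_frac = 0.25,
                       soil_base = c(0.30, 0.21, 0.13), soil_noise = 0.5,
                       occlusion_density = 0.01, low_contrast_frac = 0.15,
                       seed = 1) {
  stopifnot(canvas >= 32, senescent_frac >= 0, senescent_frac <= 1,
            length(root_width_range) == 2,
            root_width_range[1] <= root_width_range[2])
  structure(as.list(environment()), class = "scene_spec")
}

#' Specification of a synthetic senescence time series
#'
#' @param n_timepoints number of scans (default 10).
#' @param day_step days between scans (default 10, as in decade-interval
#'   minirhizotron campaigns).
#' @param trajectory function day -> target senescent fraction, monotone
#'   non-decreasing; default linear 0 -> 0.3 over the series.
#' @param scene a [scene_spec()] describing the final-day scene.
#' @return Object of class \code{series_spec}.
#' @export
series_spec <- function(n_timepoints = 10, day_step = 10,
                        trajectory = NULL, scene = scene_spec()) {
  stopifnot(n_timepoints >= 1, day_step > 0,
            inherits(scene, "scene_spec"))
  if (is.null(trajectory)) {
    dmax <- n_timepoints * day_step
    trajectory <- function(day) 0.3 * day / dmax
  }
  structure(list(n_timepoints = as.integer(n_timepoints),
                 day_step = day_step, trajectory = trajectory,
                 scene = scene), class = "series_spec")
}

# multi-octave value noise in [-0.5, 0.5]
value_noise <- function(n, octaves = c(8, 16, 32, 64)) {
  acc <- matrix(0, n, n)
  amp <- 1
  tot <- 0
  for (g in octaves) {
    coarse <- matrix(stats::runif(g * g), g, g)
    fine <- tokens_to_spatial(
      bilinear_fwd_cpp(matrix(as.vector(t(coarse)), g * g, 1),
                       1L, g, g, n, n), n, n)[, , 1]
    acc <- acc + amp * fine
    tot <- tot + amp
    amp <- amp / 2
  }
  acc / tot - 0.5
}

# smoothed random-walk polyline from (y0, x0); returns dense 1 px samples
walk_path <- function(y0, x0, dir0, len, n, wobble = 0.25) {
  ys <- numeric(len); xs <- numeric(len)
  y <- y0; x <- x0; th <- dir0
  for (i in seq_len(len)) {
    th <- th + stats::rnorm(1, 0, wobble) * 0.5
    y <- y + sin(th); x <- x + cos(th)
    if (y < 2 || y > n - 1) th <- -th
    if (x < 2 || x > n - 1) th <- pi - th
    y <- min(max(y, 2), n - 1); x <- min(max(x, 2), n - 1)
    ys[i] <- y; xs[i] <- x
  }
  cbind(y = ys, x = xs)
}

disk_offsets <- function(r) {
  s <- ceiling(r)
  g <- expand.grid(dy = -s:s, dx = -s:s)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# stamp path samples [i1, i2] with tapering width; returns pixel indices
stamp_samples <- function(path, widths, i1, i2, n) {
  idx <- integer(0)
  for (i in i1:i2) {
    off <- disk_offsets(widths[i] / 2)
    yy <- round(path[i, 1]) + off$dy
    xx <- round(path[i, 2]) + off$dx
    ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= n
    idx <- c(idx, (xx[ok] - 1L) * n + yy[ok])
  }
  unique(idx)
}

# deterministic geometry shared by scene and series generation
build_geometry <- function(spec) {
  set.seed(spec$seed)
  n <- spec$canvas
  geom <- list(n = n)
  if (spec$taproot_width > 0) {
    tap <- walk_path(2, n / 2 + stats::rnorm(1, 0, n / 30), pi / 2,
                     n - 4, n, wobble = 0.08)
    geom$taproot <- list(path = tap,
                         widths = spec$taproot_width *
                           seq(1, 0.6, length.out = nrow(tap)))
  }
  nl <- spec$n_lateral_roots
  lats <- vector("list", nl)
  if (nl > 0) {
    for (i in seq_len(nl)) {
      t0 <- stats::runif(1, 0.05, 0.9)
      if (!is.null(geom$taproot)) {
        a <- geom$taproot$path[max(1, round(t0 * nrow(geom$taproot$path))), ]
      } else {
        a <- c(stats::runif(1, 2, n - 1), stats::runif(1, 2, n - 1))
      }
      side <- sample(c(-1, 1), 1)
      dir0 <- side * stats::runif(1, 0.2, 1.2)
      len <- round(stats::runif(1, 0.35, 0.8) * n)
      w0 <- stats::runif(1, spec$root_width_range[1],
                         spec$root_width_range[2])
      path <- walk_path(a[1], a[2], dir0, len, n)
      lats[[i]] <- list(path = path,
                        widths = w0 * seq(1, 0.35, length.out = len),
                        appear = stats::runif(1, 0, 0.55),
                        low_contrast =
                          stats::runif(1) < spec$low_contrast_frac)
    }
  }
  geom$laterals <- lats
  # senescence chunks: 20 per lateral; proximal (oldest) chunks senesce
  # first while growing tips stay normal; root order shuffled once
  chunks <- list()
  nchunk <- 20
  if (nl > 0) {
    ord <- sample(nl)
    for (rank in seq_len(nchunk)) {
      for (i in ord) {
        len <- nrow(lats[[i]]$path)
        i1 <- floor((rank - 1) * len / nchunk) + 1
        i2 <- floor(rank * len / nchunk)
        if (i2 >= i1)
          chunks[[length(chunks) + 1]] <- list(root = i, i1 = i1, i2 = i2)
      }
    }
  }
  geom$chunks <- chunks
  # occlusion particles and soil are frozen here too
  geom$soil <- value_noise(n)
  npart <- round(spec$occlusion_density * n * n / 6)
  geom$particles <- if (npart > 0)
    cbind(y = stats::runif(npart, 1, n), x = stats::runif(npart, 1, n),
          r = stats::runif(npart, 0.8, 1.8))
  else NULL
  geom$pixel_jitter <- matrix(stats::rnorm(n * n, 0, 0.05), n, n)
  geom
}

# render a scene at growth fraction `grow` with senescent chunk set
# `sen_chunks` (indices into geom$chunks); returns image + masks
render_scene <- function(geom, spec, grow = 1, sen_chunks = integer(0)) {
  n <- geom$n
  cls <- matrix(0L, n, n)
  # taproot grows from the top
  if (!is.null(geom$taproot)) {
    nt <- nrow(geom$taproot$path)
    up_to <- max(1, round(nt * min(1, 0.5 + 0.5 * grow)))
    idx <- stamp_samples(geom$taproot$path, geom$taproot$widths, 1, up_to, n)
    cls[idx] <- 3L
  }
  lat_px <- vector("list", length(geom$laterals))
  for (i in seq_along(geom$laterals)) {
    lt <- geom$laterals[[i]]
    gf <- min(1, max(0, (grow - lt$appear) / (1 - lt$appear)))
    if (gf <= 0) { lat_px[[i]] <- integer(0); next }
    up_to <- max(1, round(nrow(lt$path) * gf))
    idx <- stamp_samples(lt$path, lt$widths, 1, up_to, n)
    cls[idx] <- 1L
    lat_px[[i]] <- idx
    lt$drawn <- up_to
    geom$laterals[[i]] <- lt
  }
  for (ci in sen_chunks) {
    ch <- geom$chunks[[ci]]
    lt <- geom$laterals[[ch$root]]
    if (is.null(lt$drawn)) next
    i2 <- min(ch$i2, lt$drawn)
    if (i2 < ch$i1) next
    idx <- stamp_samples(lt$path, lt$widths, ch$i1, i2, n)
    idx <- idx[cls[idx] == 1L] # never recolour taproot/soil
    cls[idx] <- 2L
  }
  # render: soil, then classes, then occluding particles (image only)
  img <- array(0, c(n, n, 3))
  tone <- 1 + spec$soil_noise * geom$soil + geom$pixel_jitter
  for (ch in 1:3) img[, , ch] <- spec$soil_base[ch] * tone
  col_of <- rbind(c(0, 0, 0), c(0.82, 0.72, 0.55), c(0.45, 0.20, 0.12),
                  c(0.90, 0.85, 0.70))
  shade <- 1 + geom$pixel_jitter
  for (k in 1:3) {
    sel <- cls == k
    if (!any(sel)) next
    for (ch in 1:3)
      img[, , ch][sel] <- col_of[k + 1, ch] * shade[sel]
  }
  for (i in seq_along(geom$laterals)) { # low-contrast laterals
    lt <- geom$laterals[[i]]
    if (!isTRUE(lt$low_contrast) || !length(lat_px[[i]])) next
    sel <- lat_px[[i]]
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[sel] <- 0.55 * pl[sel] + 0.45 * spec$soil_base[ch] * tone[sel]
      img[, , ch] <- pl
    }
  }
  if (!is.null(geom$particles)) {
    for (p in seq_len(nrow(geom$particles))) {
      off <- disk_offsets(geom$particles[p, "r"])
      yy <- round(geom$particles[p, "y"]) + off$dy
      xx <- round(geom$particles[p, "x"]) + off$dx
      ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= n
      sel <- (xx[ok] - 1L) * n + yy[ok]
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[sel] <- spec$soil_base[ch] * 0.55
        img[, , ch] <- pl
      }
    }
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, binary = (cls > 0) * 1L, senescence = cls)
}

sen_fraction <- function(cls) {
  tot <- sum(cls > 0)
  if (tot == 0) return(0)
  sum(cls == 2L) / tot
}

# grow the senescent chunk set until the rendered fraction reaches the
# target; only chunks whose path range is already drawn at this growth
# stage are eligible (a chunk of an unexpressed root would silently
# senesce wholesale once the root appears)
choose_chunks <- function(geom, spec, grow, target, start = integer(0)) {
  sel <- start
  sc <- render_scene(geom, spec, grow, sel)
  drawn <- vapply(geom$laterals, function(lt) {
    gf <- min(1, max(0, (grow - lt$appear) / (1 - lt$appear)))
    if (gf <= 0) 0 else max(1, round(nrow(lt$path) * gf))
  }, 0)
  cand <- setdiff(seq_along(geom$chunks), sel)
  cand <- cand[vapply(cand, function(k) {
    ch <- geom$chunks[[k]]
    drawn[ch$root] >= ch$i1
  }, logical(1))]
  for (k in cand) {
    if (sen_fraction(sc$senescence) >= target) break
    sel <- c(sel, k)
    sc <- render_scene(geom, spec, grow, sel)
  }
  list(sel = sel, scene = sc)
}

#' Generate a synthetic root scene with paired ground-truth masks
#'
#' Renders textured soil, a vertical taproot and curvilinear lateral
#' roots (some low-contrast, some occluded by soil particles), with the
#' requested senescent fraction of root pixels. The returned masks are
#' exactly consistent with the rendered geometry and survive the strict
#' palette decode of [decode_mask()].
#'
#' @param spec a [scene_spec()].
#' @return List: \code{image} (H x W x 3 in [0,1]), \code{binary}
#'   (0/1 matrix), \code{senescence} (labels 0-3), \code{spec}.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  geom <- build_geometry(spec)
  res <- choose_chunks(geom, spec, 1, spec$senescent_frac)
  got <- sen_fraction(res$scene$senescence)
  if (got < spec$senescent_frac - 0.05)
    stop("target senescent fraction ", spec$senescent_frac,
         " infeasible: laterals can only supply ", round(got, 3),
         " of the root area")
  c(res$scene, list(spec = spec))
}

#' Generate a nested synthetic time series of root scenes
#'
#' Roots only extend over time and the senescent pixel set at each day is
#' a subset of the next day's, so the measured senescent fraction is
#' non-decreasing and tracks the trajectory of the [series_spec()].
#'
#' @param spec a [series_spec()].
#' @return List of timepoints, each \code{list(image, binary, senescence,
#'   day)}.
#' @export
generate_series <- function(spec = series_spec()) {
  stopifnot(inherits(spec, "series_spec"))
  geom <- build_geometry(spec$scene)
  out <- vector("list", spec$n_timepoints)
  sel <- integer(0)
  prev_frac <- 0
  for (i in seq_len(spec$n_timepoints)) {
    day <- i * spec$day_step
    grow <- i / spec$n_timepoints
    target <- max(spec$trajectory(day), prev_frac)
    res <- choose_chunks(geom, spec$scene, grow, target, sel)
    sel <- res$sel
    prev_frac <- sen_fraction(res$scene$senescence)
    out[[i]] <- c(res$scene, list(day = day))
  }
  out
}

#' Nominal rendering palette of the synthetic generator
#'
#' Reference RGB colours (rows: soil, normal root, senescent root,
#' taproot) matching the generator's rendering tones; usable as centres
#' for [classify_by_colors()].
#'
#' @return 4 x 3 numeric matrix in [0, 1].
#' @export
synth_palette <- function() {
  rbind(soil = c(0.30, 0.21, 0.13), normal = c(0.82, 0.72, 0.55),
        senescent = c(0.45, 0.20, 0.12), taproot = c(0.90, 0.85, 0.70))
}
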