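test_that("binary-mask protection enforces the root-extent authority", {
  sen <- matrix(c(0, 1, 2,
                  2, 0, 3,
                  1, 2, 0), 3, 3, byrow = TRUE)
  bin <- matrix(c(0, 1, 0,
                  1, 1, 1,
                  0, 1, 1), 3, 3, byrow = TRUE)
  out <- protect_with_binary(sen, bin)
  expect_true(all(out[bin == 0] == 0))       # senescent outside mask -> soil
  expect_true(all(out[bin == 1] > 0))
  expect_equal(out[2, 2], 1)                 # soil-classified root -> normal
  expect_identical((out > 0) * 1, bin * 1)   # foreground equals the mask
  # all-zero mask -> all soil; consistent mask -> identity
  expect_true(all(protect_with_binary(sen, matrix(0, 3, 3)) == 0))
  expect_identical(protect_with_binary(sen, (sen > 0) * 1), sen)
  expect_error(protect_with_binary(sen, matrix(0, 2, 3)), "mismatch")
})

test_that("SLIC partitions are valid and respect colour boundaries", {
  set.seed(1)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_error(slic_partition(img, n_segments = 40 * 40 + 1), "exceeds")
  p1 <- slic_partition(img, n_segments = 1)
  expect_true(all(p1$labels == 1))
  # uniform colour: segments form an approximately regular lattice
  uni <- array(0.5, c(48, 48, 3))
  pu <- slic_partition(uni, n_segments = 16)
  sizes <- tabulate(pu$labels)
  expect_gt(min(sizes), 0.3 * mean(sizes))
  expect_lt(max(sizes), 3 * mean(sizes))
  expect_true(abs(pu$n_segments - 16) <= 8)
  # every pixel assigned exactly once, labels contiguous from 1
  expect_true(all(sort(unique(as.vector(pu$labels))) ==
                    seq_len(pu$n_segments)))
})

test_that("SLIC segments are 4-connected", {
  set.seed(2)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  p <- slic_partition(img, n_segments = 20)
  for (s in seq_len(p$n_segments)) {
    px <- which(p$labels == s, arr.ind = TRUE)
    # flood fill from the first pixel must reach all pixels of the segment
    reach <- matrix(FALSE, 40, 40)
    stack <- list(px[1, ])
    reach[px[1, 1], px[1, 2]] <- TRUE
    while (length(stack)) {
      c0 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y <- c0[1] + d[1]; x <- c0[2] + d[2]
        if (y >= 1 && y <= 40 && x >= 1 && x <= 40 &&
            !reach[y, x] && p$labels[y, x] == s) {
          reach[y, x] <- TRUE
          stack[[length(stack) + 1]] <- c(y, x)
        }
      }
    }
    expect_equal(sum(reach), nrow(px))
  }
})

test_that("SLIC matches a colour+space k-means oracle on a two-tone image", {
  img <- array(0, c(40, 40, 3))
  img[, 1:20, ] <- 0.2; img[, 21:40, ] <- 0.8
  p <- slic_partition(img, n_segments = 16, compactness = 10)
  purity <- function(labels) {
    left <- labels[, 1:20]; right <- labels[, 21:40]
    mean(vapply(seq_len(max(labels)), function(s) {
      a <- sum(left == s); b <- sum(right == s)
      if (a + b == 0) 1 else max(a, b) / (a + b)
    }, 0))
  }
  expect_gt(purity(p$labels), 0.95)
  # independent oracle: plain k-means in (l, a, b, x, y) feature space
  S <- sqrt(40 * 40 / 16)
  lab <- rootseg:::rgb_to_lab(matrix(img, 1600, 3))
  feats <- cbind(lab, y = rep(1:40, 40) * 10 / S,
                 x = rep(1:40, each = 40) * 10 / S)
  set.seed(3)
  km <- kmeans(feats, centers = 16, nstart = 5, iter.max = 30)
  expect_gt(purity(matrix(km$cluster, 40, 40)), 0.95)
})

test_that("majority correction equals the per-segment modal-vote oracle", {
  set.seed(4)
  for (i in 1:50) {
    h <- sample(8:16, 1); w <- sample(8:16, 1)
    labels <- matrix(sample(0:3, h * w, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
                     h, w)
    part <- random_partition(h, w, sample(2:6, 1))
    got <- majority_correct(labels, part)
    expect_identical(got, oracle_majority(labels, part$labels))
    # idempotence and root-count preservation
    expect_identical(majority_correct(got, part), got)
    expect_equal(sum(got > 0), sum(labels > 0))
    expect_true(all((got > 0) == (labels > 0)))
  }
})

test_that("majority correction ties resolve to the lower class and fixed points hold", {
  seg <- structure(list(labels = matrix(1L, 2, 5), n_segments = 1L),
                   class = "superpixel_partition")
  lab6040 <- matrix(c(2, 2, 2, 1, 1, 2, 2, 2, 1, 0), 2, 5)
  out <- majority_correct(lab6040, seg) # 6 senescent vs 3 normal
  expect_true(all(out[lab6040 > 0] == 2))
  tie <- matrix(c(1, 1, 2, 2, 0, 0, 0, 0, 0, 0), 2, 5)
  expect_true(all(majority_correct(tie, seg)[tie > 0] == 1)) # normal wins
  uniform <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2, 5)
  expect_identical(majority_correct(uniform, seg), uniform)
})

test_that("series counting reports counts, proportions and missing values", {
  img <- matrix(0L, 10, 10)
  img[1:3, 1:10] <- 1L   # 30 normal
  img[5, 1:10] <- 2L     # 10 senescent
  cs <- count_series(list(img), 1)
  expect_equal(cs$normal, 30)
  expect_equal(cs$senescent, 10)
  expect_equal(cs$prop_senescent, 0.25)
  empty <- matrix(0L, 4, 4)
  cs2 <- count_series(list(img, empty), c(1, 2))
  expect_true(is.na(cs2$prop_senescent[2])) # missing, not zero
  expect_equal(cs2$ratio_senescent[2], 0)
  expect_error(count_series(list(), numeric(0)), "empty")
  expect_error(count_series(list(img, img), c(2, 1)), "increasing")
})

test_that("cubic fits recover exact and noisy trajectories", {
  t_ <- seq(0, 20, length.out = 30)
  y <- 0.001 * t_^3 - 0.01 * t_^2 + 0.1
  f <- fit_cubic(t_, y)
  expect_equal(unname(f$coefficients), c(0.1, 0, -0.01, 0.001),
               tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_lt(f$mse, 1e-12 * stats::var(y)) # relative numerical zero
  # noisy recovery: sigma = 0.005, n = 100
  set.seed(5)
  tn <- seq(0, 20, length.out = 100)
  yn <- 0.001 * tn^3 - 0.01 * tn^2 + 0.1 + rnorm(100, 0, 0.005)
  fn <- fit_cubic(tn, yn)
  se <- summary(fn$model)$coefficients[, "Std. Error"]
  expect_true(all(abs(fn$coefficients - c(0.1, 0, -0.01, 0.001)) <
                    3 * se))
  expect_gte(fn$r_squared, 0.98)
  # fitting linear data: quadratic and cubic terms vanish
  yl <- 0.02 * tn + 0.05 + rnorm(100, 0, 0.002)
  fl <- fit_cubic(tn, yl)
  sel <- summary(fl$model)$coefficients[, "Std. Error"]
  expect_lt(abs(fl$coefficients[["c2"]]), 3 * sel[3])
  expect_lt(abs(fl$coefficients[["c3"]]), 3 * sel[4])
  expect_error(fit_cubic(1:3, 1:3), "4 distinct")
  expect_true(is.na(fit_cubic(1:5, rep(0.3, 5))$r_squared))
})

test_that("timepoint clustering finds gaps and degenerate cases", {
  # each timepoint its own cluster when k = n
  r <- cluster_timepoints(matrix(c(1, 5, 9, 14), 4, 1), k = 4, seed = 1)
  expect_equal(length(unique(r$assignment)), 4)
  # exhaustively-optimal 2-means split of {1,2,3,101,102,103}
  r2 <- cluster_timepoints(matrix(c(1, 2, 3, 101, 102, 103), 6, 1),
                           k = 2, seed = 1)
  expect_equal(length(unique(r2$assignment[1:3])), 1)
  expect_equal(length(unique(r2$assignment[4:6])), 1)
  expect_false(r2$assignment[1] == r2$assignment[4])
  expect_true(all(r2$contiguous))
  # determinism
  r3 <- cluster_timepoints(matrix(c(1, 2, 3, 101, 102, 103), 6, 1),
                           k = 2, seed = 1)
  expect_identical(r2$assignment, r3$assignment)
  expect_error(cluster_timepoints(matrix(1:3, 3, 1), k = 5), "exceeds")
})

test_that("colour-rule classification separates the rendering palette", {
  sc <- generate_scene(scene_spec(canvas = 96, seed = 8,
                                  occlusion_density = 0))
  pred <- classify_by_colors(sc$image, synth_palette())
  agree <- mean(pred == sc$senescence)
  expect_gt(agree, 0.8)
})
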