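test_that("tile grids follow the ceiling arithmetic of the scan protocol", {
  g <- plan_tile_grid(10200, 14039, 768)
  expect_equal(c(g$rows, g$cols), c(14, 19))
  expect_equal(g$rows * g$cols, 266)
  g2 <- plan_tile_grid(768, 768, 768)
  expect_equal(c(g2$rows, g2$cols), c(1, 1))
  g3 <- plan_tile_grid(800, 800, 768)
  expect_equal(c(g3$rows, g3$cols), c(2, 2))
})

test_that("single-window images tile to themselves and padding is black", {
  set.seed(1)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  tl <- tile_image(img, 64)
  expect_length(tl$tiles, 1)
  expect_equal(tl$tiles[[1]], img, ignore_attr = TRUE)
  # 80x80 with window 64: bottom/right tiles padded with zeros
  img2 <- array(runif(80 * 80 * 3), c(80, 80, 3))
  tl2 <- tile_image(img2, 64)
  expect_length(tl2$tiles, 4)
  expect_true(all(tl2$tiles[[4]][20:64, 20:64, ] == 0))
  expect_error(tile_image(array(0, c(0, 4, 3))), "empty")
})

test_that("tiling and stitching round-trip losslessly across random sizes", {
  set.seed(2)
  for (i in 1:12) {
    h <- sample(1:150, 1); w <- sample(1:150, 1)
    win <- sample(c(16, 33, 64), 1)
    msk <- matrix(sample(0:3, h * w, replace = TRUE), h, w)
    tl <- tile_image(msk, win)
    expect_identical(stitch(tl$tiles, tl$grid), msk)
  }
  # shuffled tile order stitches identically (offsets are authoritative)
  img <- array(runif(100 * 90 * 3), c(100, 90, 3))
  tl <- tile_image(img, 48)
  expect_equal(stitch(tl$tiles[sample(length(tl$tiles))], tl$grid),
               stitch(tl$tiles, tl$grid))
  expect_error(stitch(tl$tiles[-3], tl$grid), "missing tile")
})

test_that("grid metadata survives the JSON sidecar round trip", {
  g <- plan_tile_grid(1000, 900, 256)
  p <- file.path(tempdir(), "grid.json")
  write_grid_json(g, p)
  expect_equal(read_grid_json(p), g)
})

test_that("mask colour coding is a bijection under both schemes", {
  for (sname in c("binary", "senescence")) {
    sch <- label_scheme(sname)
    set.seed(3)
    m <- matrix(sample(0:(sch$n_classes - 1), 100, replace = TRUE), 10, 10)
    expect_identical(decode_mask(encode_mask(m, sch), sch),
                     m, ignore_attr = TRUE)
  }
  chk <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  rgb <- encode_mask(chk, label_scheme("binary"))
  expect_equal(rgb[1, 1, ], c(0, 0, 0))
  expect_equal(rgb[2, 1, ], c(1, 1, 1))
})

test_that("off-palette pixels error in strict mode and snap in lenient mode", {
  sch <- label_scheme("senescence")
  rgb <- encode_mask(matrix(0L, 3, 3), sch)
  rgb[2, 3, ] <- c(254, 0, 0) / 255
  expect_error(decode_mask(rgb, sch), "off-palette pixel at \\(2,3\\)")
  lenient <- decode_mask(rgb, sch, strict = FALSE)
  expect_equal(lenient[2, 3], 2L) # nearest palette colour is senescent red
  expect_equal(attr(lenient, "n_snapped"), 1L)
})

test_that("padding never introduces non-background classes after decode", {
  sc <- generate_scene(scene_spec(canvas = 100, seed = 5))
  rgb <- encode_mask(sc$senescence, label_scheme("senescence"))
  tl <- tile_image(rgb, 64)
  for (tile in tl$tiles) {
    lab <- decode_mask(tile, label_scheme("senescence"))
    expect_true(all(lab %in% 0:3))
    expect_true(all(lab[60:64, ] %in% 0:3))
  }
  pad <- decode_mask(tl$tiles[[4]], label_scheme("senescence"))
  expect_true(all(pad[(100 - 64 + 1):64, ] == 0))
})

test_that("pair resizing keeps masks nearest-neighbour clean", {
  set.seed(6)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  msk <- matrix(sample(0:1, 96 * 96, TRUE), 96, 96)
  rp <- resize_pair(img, msk, side = 64)
  expect_equal(dim(rp$image), c(64, 64, 3))
  expect_true(all(rp$mask %in% 0:1))
  cimg <- array(0.42, c(96, 96, 3))
  expect_lt(max(abs(resize_pair(cimg, msk, 64)$image - 0.42)), 1e-12)
  # blockwise masks survive the up/down cycle (blocks >= 2 px)
  blocks <- matrix(rep(rep(0:1, each = 8), times = 8)[1:64], 64, 64)
  up <- nearest_resize(blocks, 96, 96)
  down <- nearest_resize(up, 64, 64)
  expect_identical(down, blocks, ignore_attr = TRUE)
})

test_that("dataset splitting is exhaustive, disjoint and reproducible", {
  s <- split_dataset(seq_len(18883), seed = 1)
  expect_equal(lengths(s), c(train = 13218, val = 3777, test = 1888))
  expect_equal(sort(unname(unlist(s))), seq_len(18883))
  s10 <- split_dataset(seq_len(10), seed = 2)
  expect_equal(lengths(s10), c(train = 7, val = 2, test = 1))
  expect_identical(split_dataset(letters, seed = 3),
                   split_dataset(letters, seed = 3))
  expect_false(identical(split_dataset(letters, seed = 3),
                         split_dataset(letters, seed = 4)))
  expect_error(split_dataset(1:2), "fewer items")
})

test_that("images round-trip through PNG and JPEG files", {
  set.seed(7)
  img <- array(runif(20 * 30 * 3), c(20, 30, 3))
  p <- file.path(tempdir(), "img.png")
  write_image(img, p)
  expect_lt(max(abs(read_image(p) - img)), 1 / 255)
  j <- file.path(tempdir(), "img.jpg")
  write_image(img, j)
  expect_equal(dim(read_image(j)), c(20, 30, 3))
  expect_error(read_image("x.gif"), "unsupported")
})
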