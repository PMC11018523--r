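test_that("confusion counts agree with exhaustive pixel enumeration", {
  pred <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 1), 3, 3)
  truth <- matrix(c(0, 1, 0, 1, 1, 0, 1, 0, 0), 3, 3)
  cm <- confusion(pred, truth, 1)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:3) for (j in 1:3) {
    p <- pred[i, j] == 1; t_ <- truth[i, j] == 1
    if (p && t_) tp <- tp + 1 else if (p && !t_) fp <- fp + 1
    else if (!p && t_) fn <- fn + 1 else tn <- tn + 1
  }
  expect_equal(unclass(cm), list(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 9)
  # extremes
  all_root <- matrix(1, 10, 10); all_soil <- matrix(0, 10, 10)
  cm2 <- confusion(all_root, all_soil, 1)
  expect_equal(unclass(cm2), list(TP = 0, FP = 100, FN = 0, TN = 0))
  cm3 <- confusion(truth, truth, 1)
  expect_equal(cm3$FP + cm3$FN, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("metric formulas match hand arithmetic including degenerate cases", {
  m <- metrics(list(TP = 3, FP = 1, FN = 1))
  expect_equal(unname(m), c(75, 75, 60, 75))
  perfect <- metrics(list(TP = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  degen <- metrics(list(TP = 0, FP = 0, FN = 0))
  expect_equal(unname(degen), c(100, 100, 100, 100), ignore_attr = TRUE)
  expect_true(attr(degen, "degenerate"))
  ghost <- metrics(list(TP = 0, FP = 5, FN = 0)) # predicted but absent
  expect_equal(unname(ghost), c(0, 0, 0, 0))
})

test_that("IoU and F1 obey the Jaccard/harmonic-mean inequalities", {
  set.seed(1)
  for (i in 1:50) {
    cm <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               FN = sample(0:50, 1))
    if (cm$TP + cm$FP + cm$FN == 0) next
    m <- metrics(cm)
    expect_lte(m[["IoU"]], min(m[["Precision"]], m[["Recall"]]) + 1e-9)
    expect_gte(m[["F1"]], m[["IoU"]] - 1e-9)
    expect_true(all(m >= 0 & m <= 100))
  }
})

test_that("confusion matrices are additive over tiles", {
  set.seed(2)
  pred <- matrix(sample(0:1, 96 * 96, TRUE), 96, 96)
  truth <- matrix(sample(0:1, 96 * 96, TRUE), 96, 96)
  whole <- confusion(pred, truth, 1)
  tp_ <- tile_image(pred, 40); tt <- tile_image(truth, 40)
  acc <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                   class = "rs_confusion")
  for (k in seq_along(tp_$tiles))
    acc <- acc + confusion(tp_$tiles[[k]], tt$tiles[[k]], 1)
  # padding contributes equal TN on both sides; compare root-relevant counts
  expect_equal(acc$TP, whole$TP)
  expect_equal(acc$FP, whole$FP)
  expect_equal(acc$FN, whole$FN)
  expect_equal(metrics(acc), metrics(whole))
})

test_that("macro report averages all classes and stays within range", {
  set.seed(3)
  pred <- matrix(sample(0:3, 400, TRUE), 20, 20)
  truth <- matrix(sample(0:3, 400, TRUE), 20, 20)
  rep_ <- metric_report(pred, truth, 4)
  expect_equal(nrow(rep_), 5)
  expect_equal(rep_$IoU[5], mean(rep_$IoU[1:4]))
  expect_true(all(rep_$F1 >= 0 & rep_$F1 <= 100))
})

test_that("the cosine schedule starts at the initial rate and decays to the floor", {
  cfg <- train_config(epochs = 100, lr = 1e-4, lr_floor = 1e-6)
  lrs <- lr_schedule(cfg)
  expect_equal(lrs[1], 1e-4)
  expect_equal(lrs[100], 1e-6)
  expect_true(all(diff(lrs) <= 0)) # non-increasing over one annealing cycle
})

test_that("augmentation transforms image and mask coherently", {
  set.seed(4)
  img <- array(runif(32 * 32 * 3, 0.2, 0.8), c(32, 32, 3))
  msk <- matrix(sample(0:1, 32 * 32, TRUE), 32, 32)
  cfg <- train_config()
  # mask label set never grows, output shapes preserved
  for (s in 1:20) {
    a <- augment(img, msk, cfg, rng = s)
    expect_true(all(a$mask %in% 0:1))
    expect_equal(dim(a$image), dim(img))
    expect_equal(dim(a$mask), dim(msk))
  }
  # identical rng => identical augmentation (determinism)
  expect_identical(augment(img, msk, cfg, rng = 11),
                   augment(img, msk, cfg, rng = 11))
  # find a seed whose draws skip every geometric transform: the mask must
  # pass through bitwise unchanged while photometric ops touch the image
  geo_free <- NULL; geo_only <- NULL
  for (s in 1:200) {
    set.seed(s); d <- runif(3)
    if (all(d >= 0.5)) geo_free <- s
    if (d[1] < 0.5 && d[2] >= 0.5 && d[3] >= 0.5 && is.null(geo_only))
      geo_only <- s
    if (!is.null(geo_free) && !is.null(geo_only)) break
  }
  a <- augment(img, msk, cfg, rng = geo_free)
  expect_identical(a$mask, msk)
  expect_false(identical(a$image, img)) # photometric ops still applied
  # horizontal flip is applied to both and is an involution on the mask
  b <- augment(img, msk, cfg, rng = geo_only)
  expect_identical(b$mask, msk[, 32:1])
  expect_identical(b$mask[, 32:1], msk)
})

test_that("augment is a no-op when disabled", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  msk <- matrix(0L, 16, 16)
  a <- augment(img, msk, train_config(augment = FALSE), rng = 1)
  expect_identical(a$image, img)
  expect_identical(a$mask, msk)
})

test_that("short training runs reduce the loss and are seed-reproducible", {
  tiles <- toy_tiles(2, canvas = 64)
  m <- build_model("UN", "small", 2, seed = 5)
  cfg <- train_config(epochs = 4, batch_size = 2, augment = FALSE, seed = 1)
  r <- train(m, tiles, config = cfg)
  expect_equal(nrow(r$log), 4)
  expect_lt(r$log$loss[4], r$log$loss[1])
  expect_equal(r$log$lr[1], 1e-4)
  m2 <- build_model("UN", "small", 2, seed = 5)
  r2 <- train(m2, tiles, config = cfg)
  expect_equal(r2$log$loss, r$log$loss, tolerance = 1e-12)
  # guards
  expect_error(train(m, list(), config = cfg), "empty")
  bad <- tiles
  bad[[1]]$mask[1, 1] <- 7L
  expect_error(train(m, bad, config = cfg), "classes")
})
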