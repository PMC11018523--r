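#' Training configuration
#'
#' Defaults follow the published training recipe: AdamW with betas
#' (0.9, 0.999), initial learning rate 1e-4 decayed by cosine annealing
#' over the epoch horizon, and paired geometric/photometric augmentation
#' (flips, random crop, brightness, contrast, saturation, hue).
#'
#' @param epochs training epochs (cosine horizon).
#' @param batch_size tiles per optimisation step.
#' @param lr initial learning rate.
#' @param lr_floor final learning rate of the cosine schedule.
#' @param betas AdamW moment coefficients.
#' @param weight_decay decoupled weight decay (weight matrices only).
#' @param augment apply data augmentation during training.
#' @param class_weights \code{"balanced"} (default) weighs the pixel
#'   cross-entropy by inverse class frequency so sparse root classes are
#'   not drowned by the soil background; \code{"none"} for the unweighted
#'   loss; or an explicit numeric vector of per-class weights.
#' @param seed seed controlling shuffling and augmentation.
#' @return Object of class \code{train_config}.
#' @export
train_config <- function(epochs = 100, batch_size = 4, lr = 1e-4,
                         lr_floor = 0, betas = c(0.9, 0.999),
                         weight_decay = 0.01, augment = TRUE,
                         class_weights = "balanced", seed = 0) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, lr_floor >= 0,
            lr_floor <= lr, length(betas) == 2)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, lr_floor = lr_floor, betas = betas,
                 weight_decay = weight_decay, augment = augment,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning-rate schedule
#'
#' lr(t) = floor + (lr0 - floor)/2 * (1 + cos(pi * t / (T - 1))) for
#' epochs t = 0..T-1: starts at the initial rate, decays monotonically,
#' ends at the floor.
#'
#' @param config a [train_config()].
#' @return Numeric vector of per-epoch learning rates.
#' @export
lr_schedule <- function(config) {
  T_ <- config$epochs
  if (T_ == 1) return(config$lr)
  t <- seq_len(T_) - 1
  config$lr_floor + 0.5 * (config$lr - config$lr_floor) *
    (1 + cos(pi * t / (T_ - 1)))
}

# vectorised HSV <-> RGB on c(3, n) matrices, values in [0, 1]
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p)))
  b <- ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  rbind(r, g, b)
}

#' Paired augmentation of an image and its mask
#'
#' Geometric transforms (horizontal/vertical flip, random crop-and-zoom)
#' are applied identically to image and mask; photometric transforms
#' (brightness, contrast, saturation, hue) touch the image only, so the
#' mask's label set can never grow.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mask H x W integer label matrix.
#' @param config a [train_config()]; \code{config$augment} gates all ops.
#' @param rng optional integer seed for reproducible draws.
#' @return List with elements \code{image} and \code{mask}.
#' @export
augment <- function(image, mask, config = train_config(), rng = NULL) {
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  if (!is.null(rng)) set.seed(rng)
  if (!isTRUE(config$augment)) return(list(image = image, mask = mask))
  H <- dim(image)[1]; W <- dim(image)[2]
  if (stats::runif(1) < 0.5) {
    image <- image[, W:1, , drop = FALSE]
    mask <- mask[, W:1, drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {
    image <- image[H:1, , , drop = FALSE]
    mask <- mask[H:1, , drop = FALSE]
  }
  if (stats::runif(1) < 0.5) { # crop-and-zoom, nearest for the mask
    sc <- stats::runif(1, 0.8, 1)
    ch <- max(2L, floor(H * sc)); cw <- max(2L, floor(W * sc))
    oy <- sample.int(H - ch + 1L, 1); ox <- sample.int(W - cw + 1L, 1)
    sub <- image[oy:(oy + ch - 1L), ox:(ox + cw - 1L), , drop = FALSE]
    subm <- mask[oy:(oy + ch - 1L), ox:(ox + cw - 1L), drop = FALSE]
    image <- tokens_to_spatial(
      bilinear_fwd_cpp(spatial_to_tokens(sub), 1L, ch, cw, H, W), H, W)
    mask <- nearest_resize(subm, H, W)
  }
  image <- image * stats::runif(1, 0.8, 1.2)            # brightness
  mu <- mean(image)
  image <- (image - mu) * stats::runif(1, 0.8, 1.2) + mu # contrast
  px <- matrix(pmin(pmax(image, 0), 1), ncol = 3)
  hsvm <- grDevices::rgb2hsv(t(px), maxColorValue = 1)
  hsvm[1, ] <- hsvm[1, ] + stats::runif(1, -0.05, 0.05)  # hue
  hsvm[2, ] <- pmin(1, hsvm[2, ] * stats::runif(1, 0.8, 1.2)) # saturation
  image <- array(t(hsv_to_rgb(hsvm[1, ], hsvm[2, ], hsvm[3, ])), dim(image))
  image <- pmin(pmax(image, 0), 1)
  list(image = image, mask = mask)
}

#' One-vs-rest pixel confusion matrix for a class
#'
#' @param pred,truth integer label matrices of identical shape.
#' @param class the class index counted as positive.
#' @return Object of class \code{rs_confusion}: counts TP, FP, FN, TN.
#' @export
confusion <- function(pred, truth, class = 1) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth shapes differ: ",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  p <- pred == class; t_ <- truth == class
  structure(list(TP = sum(p & t_), FP = sum(p & !t_),
                 FN = sum(!p & t_), TN = sum(!p & !t_)),
            class = "rs_confusion")
}

#' @export
"+.rs_confusion" <- function(e1, e2) {
  structure(list(TP = e1$TP + e2$TP, FP = e1$FP + e2$FP,
                 FN = e1$FN + e2$FN, TN = e1$TN + e2$TN),
            class = "rs_confusion")
}

#' Precision, Recall, IoU and F1 from a confusion matrix
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), IoU = TP/(TP+FP+FN),
#' F1 = 2PR/(P+R), all as percentages. When the class is absent and never
#' predicted (TP = FP = FN = 0) all four are reported as 100 by convention
#' and the result carries attribute \code{degenerate = TRUE}; a 0/0 in an
#' individual formula otherwise resolves to 0 (class predicted but absent,
#' or absent but predicted).
#'
#' @param cm an [confusion()] result, or a list with TP, FP, FN.
#' @return Named numeric vector (Precision, Recall, IoU, F1) in percent.
#' @export
metrics <- function(cm) {
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP + FN == 0) {
    out <- c(Precision = 100, Recall = 100, IoU = 100, F1 = 100)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  P <- if (TP + FP == 0) 0 else 100 * TP / (TP + FP)
  R <- if (TP + FN == 0) 0 else 100 * TP / (TP + FN)
  IoU <- 100 * TP / (TP + FP + FN)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(Precision = P, Recall = R, IoU = IoU, F1 = F1)
}

#' Full per-class and macro-averaged metric report
#'
#' Emits one row per class plus a macro mean over all classes (background
#' included) with mPrecision, mRecall, mIoU, mF1.
#'
#' @param pred,truth integer label matrices.
#' @param n_classes number of classes (labels 0..n_classes-1).
#' @return data.frame with columns class, Precision, Recall, IoU, F1.
#' @export
metric_report <- function(pred, truth, n_classes = 2) {
  rows <- lapply(0:(n_classes - 1), function(k) {
    m <- metrics(confusion(pred, truth, k))
    data.frame(class = k, Precision = m["Precision"], Recall = m["Recall"],
               IoU = m["IoU"], F1 = m["F1"], row.names = NULL)
  })
  df <- do.call(rbind, rows)
  rbind(df, data.frame(class = NA, Precision = mean(df$Precision),
                       Recall = mean(df$Recall), IoU = mean(df$IoU),
                       F1 = mean(df$F1)))
}

# (optionally class-weighted) cross-entropy loss and gradient on logit
# tokens (N x K) vs 0-based labels
ce_loss_grad <- function(logits, labels, class_w = NULL) {
  pr <- softmax_rows(logits)
  n <- nrow(pr)
  idx <- cbind(seq_len(n), labels + 1L)
  eps <- 1e-12
  if (is.null(class_w)) {
    loss <- -mean(log(pr[idx] + eps))
    grad <- pr
    grad[idx] <- grad[idx] - 1
    grad <- grad / n
  } else {
    w <- class_w[labels + 1L]
    sw <- sum(w)
    loss <- -sum(w * log(pr[idx] + eps)) / sw
    grad <- pr * (w / sw)
    grad[idx] <- grad[idx] - w / sw
  }
  list(loss = loss, grad = grad, pred = max.col(pr) - 1L)
}

#' Train a segmentation model
#'
#' Minibatch AdamW with cosine-annealed learning rate and optional paired
#' augmentation; the loss is pixel-wise cross-entropy. All randomness
#' (shuffling, augmentation) derives from \code{config$seed}, so runs are
#' reproducible. Model weights are updated in place (layers are
#' environments) and the trained model is also returned.
#'
#' @param model an \code{rs_model} from [build_model()].
#' @param train_set list of samples, each \code{list(image, mask)} with an
#'   H x W x 3 array in [0,1] and an H x W integer mask (dims multiples
#'   of 32).
#' @param val_set optional validation samples (same format), evaluated
#'   each epoch.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return List with \code{model} and \code{log}, a data.frame of
#'   per-epoch learning rate, loss, and root-class IoU (train/val).
#' @export
train <- function(model, train_set, val_set = NULL,
                  config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "rs_model"), inherits(config, "train_config"))
  if (!length(train_set)) stop("empty training set")
  maxlab <- max(vapply(train_set, function(s) max(s$mask), 0))
  if (maxlab >= model$n_classes)
    stop("mask labels reach ", maxlab, " but model has ",
         model$n_classes, " classes")
  set.seed(config$seed)
  lrs <- lr_schedule(config)
  layers <- rs_layers(model)
  class_w <- NULL
  if (identical(config$class_weights, "balanced")) {
    cnt <- numeric(model$n_classes)
    for (s in train_set)
      cnt <- cnt + tabulate(s$mask + 1L, model$n_classes)
    cnt <- pmax(cnt, 1)
    class_w <- sum(cnt) / (model$n_classes * cnt)
  } else if (is.numeric(config$class_weights)) {
    stopifnot(length(config$class_weights) == model$n_classes)
    class_w <- config$class_weights
  }
  rs_set_training(model, TRUE)
  log <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(train_set))
    ep_loss <- 0; nb <- 0
    cm <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                    class = "rs_confusion")
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
      B <- length(idx)
      xs <- vector("list", B); ys <- vector("list", B)
      for (k in seq_len(B)) {
        s <- train_set[[idx[k]]]
        if (isTRUE(config$augment)) s <- augment(s$image, s$mask, config)
        xs[[k]] <- spatial_to_tokens(s$image)
        ys[[k]] <- as.integer(t(s$mask))
      }
      H <- dim(train_set[[idx[1]]]$image)[1]
      W <- dim(train_set[[idx[1]]]$image)[2]
      x <- do.call(rbind, xs)
      y <- unlist(ys)
      pyr <- encoder_forward(model$encoder, x, B, H, W)
      out <- decoder_forward(model$decoder, pyr)
      lg <- ce_loss_grad(out$x, y, class_w)
      dpyr <- decoder_backward(model$decoder, lg$grad, pyr)
      encoder_backward(model$encoder, dpyr)
      rs_adamw_step(layers, lrs[ep], config$betas,
                    weight_decay = config$weight_decay)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
      cm <- cm + confusion(matrix(lg$pred, ncol = 1),
                           matrix(y, ncol = 1), 1)
    }
    val_iou <- NA_real_
    if (!is.null(val_set) && length(val_set)) {
      vcm <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                       class = "rs_confusion")
      for (s in val_set) {
        pm <- predict_mask(model, s$image)
        vcm <- vcm + confusion(pm, s$mask, 1)
      }
      val_iou <- metrics(vcm)[["IoU"]]
      rs_set_training(model, TRUE)
    }
    log[[ep]] <- data.frame(epoch = ep, lr = lrs[ep],
                            loss = ep_loss / nb,
                            train_iou = metrics(cm)[["IoU"]] / 100,
                            val_iou = val_iou / 100)
    if (verbose)
      cat(sprintf("epoch %3d lr %.2e loss %.4f train IoU %.3f\n",
                  ep, lrs[ep], ep_loss / nb, log[[ep]]$train_iou))
  }
  list(model = model, log = do.call(rbind, log))
}

#' Predict a label mask for an image
#'
#' @param model trained \code{rs_model}.
#' @param image H x W x 3 array (dims multiples of 32).
#' @return H x W integer matrix of argmax class labels (0-based).
#' @export
predict_mask <- function(model, image) {
  z <- predict_logits(model, image)
  d <- dim(z)
  matrix(max.col(matrix(z, d[1] * d[2], d[3])) - 1L, d[1], d[2])
}

#' Evaluate a model's segmentation IoU on a dataset
#'
#' Confusion counts are accumulated over all samples before computing
#' metrics (equivalent to evaluating the stitched image).
#'
#' @param model trained \code{rs_model}.
#' @param dataset list of \code{list(image, mask)} samples.
#' @param class positive class (default 1 = root).
#' @return Named metric vector from [metrics()].
#' @export
evaluate <- function(model, dataset, class = 1) {
  cm <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                  class = "rs_confusion")
  for (s in dataset) cm <- cm + confusion(predict_mask(model, s$image),
                                          s$mask, class)
  metrics(cm)
}
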