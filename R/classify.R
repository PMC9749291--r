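#' Stratified train/test split
#'
#' Per class, `round(test_frac * n)` items go to the held-out test set and
#' the remainder to the training pool; the validation subset is drawn from
#' the training pool per class at training time (see
#' [train_classifier()]). With 878 normal and 678 distressed items and the
#' default 10% fraction this yields the 88/68 test and 790/610 training
#' partition.
#'
#' @param manifest data.frame with columns `item_id` and `label`.
#' @param test_frac held-out fraction per class (default 0.10).
#' @param seed RNG seed; the same seed always produces the same split.
#' @return list with `train`, `test` (item id vectors) and `seed`.
#' @export
stratified_split <- function(manifest, test_frac = 0.10, seed = 20210000) {
  stopifnot(all(c("item_id", "label") %in% names(manifest)))
  classes <- unique(as.character(manifest$label))
  if (any(table(manifest$label) < 2L)) {
    stop("split error: every class needs at least 2 items")
  }
  test <- character(0)
  set.seed(seed)
  for (cls in sort(classes)) {
    ids <- manifest$item_id[manifest$label == cls]
    n_test <- round_half_up(test_frac * length(ids), 0)
    test <- c(test, sample(ids, n_test))
  }
  list(train = setdiff(manifest$item_id, test), test = test, seed = seed)
}

#' Grid-pooling image backbone
#'
#' A deterministic feature extractor for scalogram images: the image is
#' divided into a `grid x grid` cell lattice and each cell is mean-pooled
#' per RGB channel, giving `grid^2 * 3` features. It plays the role of the
#' frozen convolutional trunk in transfer learning; any function mapping a
#' `H x W x 3` array to a fixed-length numeric vector can be plugged in
#' instead (e.g. an exported pretrained network).
#'
#' @param grid cells per image side (default 16, i.e. 768 features; coarser
#'   grids blur the scalogram texture that separates the classes).
#' @return a function `image -> numeric`.
#' @export
pool_backbone <- function(grid = 16) {
  force(grid)
  function(image) {
    d <- dim(image)
    cx <- ceiling(seq_len(d[1]) / d[1] * grid)
    cy <- ceiling(seq_len(d[2]) / d[2] * grid)
    feats <- vapply(1:3, function(ch) {
      as.vector(tapply(image[, , ch], list(cx[row(image[, , ch])],
                                           cy[col(image[, , ch])]), mean))
    }, numeric(grid * grid))
    as.numeric(feats) / 255
  }
}

#' Extract backbone features for every dataset item
#'
#' Renders each item's scalogram image and passes it through the backbone,
#' one item at a time so full-size images never accumulate in memory.
#'
#' @param dataset a `ctg_dataset` from [build_dataset()].
#' @param bank a [morse_filterbank()] matching the segment length; built
#'   from `params` when NULL.
#' @param params Morse parameters used when `bank` is NULL.
#' @param backbone feature extractor, e.g. [pool_backbone()].
#' @param size image size passed to [render_scalogram()].
#' @return list with `x` (items x features matrix), `y` (label factor),
#'   `item_id`.
#' @export
dataset_features <- function(dataset, bank = NULL, params = morse_params(),
                             backbone = pool_backbone(), size = c(224, 224)) {
  if (is.null(backbone)) stop("backbone unavailable: supply a feature extractor")
  n_samp <- length(dataset$items[[1]]$segment$samples)
  fs <- dataset$items[[1]]$segment$fs
  bank <- bank %||% morse_filterbank(n_samp, fs, params)
  rows <- lapply(dataset$items, function(it) {
    backbone(scalogram_image(it$segment, bank, size = size))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(dataset$items, `[[`, "", "item_id")
  list(x = x,
       y = factor(vapply(dataset$items, `[[`, "", "label"),
                  levels = c("normal", "distressed")),
       item_id = rownames(x))
}

#' Training configuration for the classifier head
#'
#' Defaults follow the fine-tuning recipe used for the FHR scalogram
#' experiments: Adam, learning rate 0.001, mini-batch 30, validation
#' monitored every 15 iterations, up to 15 epochs (the best validation
#' accuracy was observed at epoch 13).
#'
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param minibatch samples per gradient step.
#' @param max_epochs passes over the training data.
#' @param validation_frequency iterations between validation evaluations.
#' @param validation_frac per-class fraction of training data held out for
#'   validation during training.
#' @param seed RNG seed for shuffling and initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 0.001,
                         minibatch = 30, max_epochs = 15,
                         validation_frequency = 15, validation_frac = 0.10,
                         seed = 20210000) {
  stopifnot(learning_rate > 0, minibatch >= 1)
  if (!identical(optimizer, "adam")) stop("unsupported optimizer: ", optimizer)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 minibatch = as.integer(minibatch),
                 max_epochs = as.integer(max_epochs),
                 validation_frequency = as.integer(validation_frequency),
                 validation_frac = validation_frac, seed = seed),
            class = "train_config")
}

#' Train the two-class classifier head
#'
#' Transfer-learning stage: backbone features are standardized and a
#' two-class softmax head is fitted with mini-batch Adam, replacing the
#' original classification layer of the pretrained trunk. A per-class
#' validation subset (10% of the training items by default) is carved out
#' with the config seed and evaluated every `validation_frequency`
#' iterations, producing the usual learning curves.
#'
#' @param x features matrix (items x features), e.g. from
#'   [dataset_features()].
#' @param y factor of labels with levels `normal`, `distressed`.
#' @param config a [train_config()].
#' @return an object of class `ctg_classifier` with the fitted weights,
#'   feature standardization, and a `curves` data.frame of per-iteration
#'   training loss/accuracy plus validation points.
#' @export
train_classifier <- function(x, y, config = train_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(y, levels = c("normal", "distressed"))
  if (any(table(y) == 0)) stop("training error: both classes must be present")
  set.seed(config$seed)
  # per-class validation carve-out from the training pool
  val_idx <- unlist(lapply(levels(y), function(cls) {
    ids <- which(y == cls)
    sample(ids, max(1L, round_half_up(config$validation_frac * length(ids), 0)))
  }))
  tr_idx <- setdiff(seq_along(y), val_idx)
  center <- colMeans(x[tr_idx, , drop = FALSE])
  scale_ <- apply(x[tr_idx, , drop = FALSE], 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  d <- ncol(x)
  w <- matrix(rnorm(d * 2, sd = 0.01), d, 2)
  b <- c(0, 0)
  mw <- vw <- matrix(0, d, 2); mb <- vb <- c(0, 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  yi <- as.integer(y)  # 1 = normal, 2 = distressed
  curves <- list()
  softmax <- function(z) {
    z <- z - apply(z, 1, max)
    e <- exp(z); e / rowSums(e)
  }
  eval_set <- function(idx) {
    p <- softmax(xs[idx, , drop = FALSE] %*% w +
                   matrix(b, length(idx), 2, byrow = TRUE))
    loss <- -mean(log(pmax(p[cbind(seq_along(idx), yi[idx])], 1e-12)))
    acc <- mean(max.col(p) == yi[idx])
    c(loss = loss, acc = acc)
  }
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$minibatch))
    for (batch in batches) {
      t <- t + 1L
      xb <- xs[batch, , drop = FALSE]
      z <- xb %*% w + matrix(b, length(batch), 2, byrow = TRUE)
      p <- softmax(z)
      tgt <- matrix(0, length(batch), 2)
      tgt[cbind(seq_along(batch), yi[batch])] <- 1
      g <- (p - tgt) / length(batch)
      gw <- crossprod(xb, g); gb <- colSums(g)
      mw <- beta1 * mw + (1 - beta1) * gw; vw <- beta2 * vw + (1 - beta2) * gw^2
      mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
      lr_t <- config$learning_rate * sqrt(1 - beta2^t) / (1 - beta1^t)
      w <- w - lr_t * mw / (sqrt(vw) + eps)
      b <- b - lr_t * mb / (sqrt(vb) + eps)
      train_m <- eval_set(batch)
      val_m <- if (t %% config$validation_frequency == 0L) {
        eval_set(val_idx)
      } else {
        c(loss = NA_real_, acc = NA_real_)
      }
      curves[[t]] <- data.frame(
        iteration = t, epoch = epoch,
        train_loss = train_m["loss"], train_acc = train_m["acc"],
        val_loss = val_m["loss"], val_acc = val_m["acc"])
    }
  }
  structure(list(w = w, b = b, center = center, scale = scale_,
                 classes = levels(y), config = config,
                 validation_ids = rownames(x)[val_idx] %||% val_idx,
                 curves = do.call(rbind, curves)),
            class = "ctg_classifier")
}

#' @export
print.ctg_classifier <- function(x, ...) {
  last_val <- x$curves$val_acc[!is.na(x$curves$val_acc)]
  cat(sprintf(
    "<ctg_classifier> %d features, %d iterations; final validation acc %s\n",
    nrow(x$w), nrow(x$curves),
    if (length(last_val)) sprintf("%.1f%%", 100 * tail(last_val, 1)) else "n/a"))
  invisible(x)
}

#' Predict class labels
#'
#' @param object a `ctg_classifier`.
#' @param x features matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of labels, or matrix of class probabilities.
#' @export
predict.ctg_classifier <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  z <- xs %*% object$w + matrix(object$b, nrow(x), 2, byrow = TRUE)
  z <- z - apply(z, 1, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p)], levels = object$classes)
}

#' Binary confusion matrix (distressed positive)
#'
#' @param tp,fn,fp,tn non-negative counts; `tp + fn` is the number of
#'   distressed test items, `fp + tn` the number of normal ones.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fn=%d fp=%d tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Evaluate a classifier on held-out items
#'
#' @param model a `ctg_classifier`.
#' @param x test features matrix.
#' @param y test label factor.
#' @return a [confusion_matrix()] with distressed as the positive class.
#' @export
evaluate_classifier <- function(model, x, y) {
  if (length(y) == 0L) stop("evaluation error: empty test set")
  y <- factor(y, levels = c("normal", "distressed"))
  pred <- predict(model, x)
  confusion_matrix(
    tp = sum(pred == "distressed" & y == "distressed"),
    fn = sum(pred == "normal" & y == "distressed"),
    fp = sum(pred == "distressed" & y == "normal"),
    tn = sum(pred == "normal" & y == "normal"))
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `Acc = (tp+tn)/(tp+tn+fp+fn)`, `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)`,
#' with the distressed class positive. Reported as percentages rounded
#' half-up to one decimal. A zero denominator yields `NA` with an
#' `undefined` flag rather than an error.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent)
#'   and `undefined` (character vector of metrics with no denominator).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("metrics error: empty confusion matrix")
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  undefined <- character(0)
  se <- if (pos > 0) 100 * cm$tp / pos else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  sp <- if (neg > 0) 100 * cm$tn / neg else { undefined <- c(undefined, "specificity"); NA_real_ }
  list(accuracy = round_half_up(100 * (cm$tp + cm$tn) / total, 1),
       sensitivity = round_half_up(se, 1),
       specificity = round_half_up(sp, 1),
       undefined = undefined)
}
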