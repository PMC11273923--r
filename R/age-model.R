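# Expected-value (DEX) age head, training loop and evaluation metrics.
#
# Networks predict a probability distribution over K = 76 integer age labels
# (0..75 years); the age estimate is the expectation of that distribution.
# Training minimizes cross-entropy against label-smoothed targets; the
# expectation is used only at inference.

AGE_CLASSES <- 76L

#' Age distribution over the discrete label set
#'
#' @param probs Non-negative vector summing to 1.
#' @param labels Integer labels, strictly increasing from 0 (default
#'   `0:(length(probs) - 1)`).
#' @return An object of class `age_distribution`.
#' @export
age_distribution <- function(probs, labels = seq_along(probs) - 1L) {
  stopifnot(length(probs) == length(labels), all(probs >= -1e-12))
  if (abs(sum(probs) - 1) > 1e-6)
    stop("probabilities must sum to 1", call. = FALSE)
  if (labels[1] != 0L || any(diff(labels) <= 0))
    stop("labels must be strictly increasing integers starting at 0", call. = FALSE)
  structure(list(probs = as.numeric(probs), labels = as.integer(labels)),
            class = "age_distribution")
}

#' Expected age of an age distribution
#'
#' `y = sum_k p_k * l_k`, the expectation of the predicted distribution over
#' the age labels; always lies within the label range.
#'
#' @param dist An [age_distribution()].
#' @return The predicted age in years (single number).
#' @export
#' @examples
#' p <- rep(0, 76); p[31] <- 1     # one-hot at age 30
#' dex_expected_age(age_distribution(p))
dex_expected_age <- function(dist) {
  stopifnot(inherits(dist, "age_distribution"))
  sum(dist$probs * dist$labels)
}

# rows of `probmat` are per-image distributions over 0..K-1
dex_expected_age_batch <- function(probmat) {
  as.vector(probmat %*% (seq_len(ncol(probmat)) - 1))
}

#' Label-smoothed target distribution for an integer age
#'
#' Mass `1 - eps` on the true bin and `eps / (K - 1)` on every other bin.
#'
#' @param age Integer age in `0..K-1`.
#' @param K Number of age bins.
#' @param eps Smoothing mass.
#' @return An [age_distribution()].
#' @export
label_smoothing_target <- function(age, K = AGE_CLASSES, eps = 0.1) {
  age <- as.integer(age)
  if (age < 0L || age > K - 1L)
    stop("age outside 0..", K - 1L, "; clamp with clamp_ages() first", call. = FALSE)
  p <- rep(eps / (K - 1L), K)
  p[age + 1L] <- 1 - eps
  age_distribution(p)
}

#' Clamp ages to the supported label range
#'
#' The label set covers 0..75 years; older subjects are clamped to 75 with
#' a warning.
#'
#' @param ages Integer vector.
#' @param max_age Upper label.
#' @return Clamped integer vector.
#' @export
clamp_ages <- function(ages, max_age = AGE_CLASSES - 1L) {
  over <- ages > max_age
  if (any(over))
    warning(sum(over), " age(s) above ", max_age, " clamped to ", max_age,
            call. = FALSE)
  pmin(pmax(as.integer(ages), 0L), max_age)
}

#' Mean absolute error in years
#'
#' @param pred_ages,true_ages Equal-length numeric vectors.
#' @return `sum(|pred - true|) / N`.
#' @export
mae <- function(pred_ages, true_ages) {
  if (length(pred_ages) != length(true_ages))
    stop("length mismatch", call. = FALSE)
  stopifnot(length(pred_ages) >= 1L)
  mean(abs(pred_ages - true_ages))
}

#' Cumulative score at error tolerance j
#'
#' Percentage of predictions whose absolute error does not exceed `j` years.
#'
#' @param pred_ages,true_ages Numeric vectors.
#' @param j Tolerance in years (vectorized).
#' @return Percentage(s) in `[0, 100]`, non-decreasing in `j`.
#' @export
cumulative_score <- function(pred_ages, true_ages, j) {
  stopifnot(all(j >= 0), length(pred_ages) == length(true_ages))
  err <- abs(pred_ages - true_ages)
  vapply(j, function(jj) 100 * mean(err <= jj), numeric(1))
}

#' Mean absolute error per age decade
#'
#' @param pred_ages,true_ages Numeric vectors.
#' @param bin_width Bin width in years (10 = decades).
#' @return Named numeric vector, names like `"0-10"`; empty bins absent.
#' @export
per_age_group_mae <- function(pred_ages, true_ages, bin_width = 10L) {
  stopifnot(length(pred_ages) == length(true_ages))
  bin <- floor(true_ages / bin_width)
  err <- abs(pred_ages - true_ages)
  grouped <- split(err, bin)
  out <- vapply(grouped, mean, numeric(1))
  names(out) <- vapply(as.integer(names(grouped)), function(b)
    sprintf("%d-%d", b * bin_width, (b + 1L) * bin_width), character(1))
  out
}

#' Full evaluation report
#'
#' @param pred_ages,true_ages Numeric vectors.
#' @param cs_tolerances Tolerances (years) at which the cumulative score is
#'   reported.
#' @return An `eval_report`: list with `mae`, `cs_curve`, `per_bin_mae`, `n`.
#' @export
evaluate_ages <- function(pred_ages, true_ages, cs_tolerances = 0:10) {
  cs <- cumulative_score(pred_ages, true_ages, cs_tolerances)
  names(cs) <- as.character(cs_tolerances)
  structure(list(mae = mae(pred_ages, true_ages), cs_curve = cs,
                 per_bin_mae = per_age_group_mae(pred_ages, true_ages),
                 n = length(true_ages)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("age evaluation on %d images\n", x$n))
  cat(sprintf("  MAE: %.3f years\n", x$mae))
  cat("  CS(j): ", paste(sprintf("%s:%.1f%%", names(x$cs_curve), x$cs_curve),
                         collapse = " "), "\n")
  invisible(x)
}

# --- runtime networks -------------------------------------------------------

#' Build a runnable network from an architecture specification
#'
#' @param arch An [arch_spec()] (block-based or cell-based).
#' @return A runtime network usable with [predict_ages()] and
#'   [train_age_model()].
#' @export
build_network_from_spec <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  if (!is.null(arch$cells)) return(build_cell_network_from_spec(arch))
  stem <- make_stem_module(arch$stem, arch$input_channels)
  blocks <- lapply(arch$blocks, make_block)
  last_c <- arch$blocks[[length(arch$blocks)]]$cout
  head <- make_head_module(last_c, arch$head$conv_width, arch$head$num_classes)
  structure(list(stem = stem, blocks = blocks, head = head,
                 num_classes = arch$head$num_classes,
                 input_channels = arch$input_channels),
            class = "age_network")
}

net_forward <- function(net, x, train = TRUE) UseMethod("net_forward")
net_backward <- function(net, dlogits) UseMethod("net_backward")
net_params <- function(net) UseMethod("net_params")

#' @export
net_forward.age_network <- function(net, x, train = TRUE) {
  h <- nn_forward(net$stem, x, train)
  for (b in net$blocks) h <- nn_forward(b, h, train)
  nn_forward(net$head, h, train)
}

#' @export
net_backward.age_network <- function(net, dlogits) {
  dh <- nn_backward(net$head, dlogits)
  for (b in rev(net$blocks)) dh <- nn_backward(b, dh)
  nn_backward(net$stem, dh)
}

#' @export
net_params.age_network <- function(net) {
  ps <- c(nn_params(net$stem), nn_params(net$head))
  for (b in net$blocks) ps <- c(ps, nn_params(b))
  ps
}

#' Predict ages for a batch of images
#'
#' @param net A runtime network.
#' @param x Array `(H, W, N, C)` of images in `[0, 1]`.
#' @param mirror Average the prediction with that of the horizontally
#'   mirrored image.
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of predicted ages.
#' @export
predict_ages <- function(net, x, mirror = FALSE, batch_size = 64L) {
  n <- dim(x)[3]
  preds <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- x[, , idx, , drop = FALSE]
    p <- dex_expected_age_batch(softmax_rows(net_forward(net, xb, train = FALSE)))
    if (mirror) {
      xm <- xb[, rev(seq_len(dim(xb)[2])), , , drop = FALSE]
      pm <- dex_expected_age_batch(softmax_rows(net_forward(net, xm, train = FALSE)))
      p <- (p + pm) / 2
    }
    preds[idx] <- p
  }
  preds
}

#' Mirror-averaged age prediction for a single image
#'
#' Feeds the image and its horizontal mirror through the network and
#' averages the two expected ages; for a left-right symmetric image this
#' equals the plain prediction.
#'
#' @param net A runtime network.
#' @param image Matrix `(H, W)` or array `(H, W, 1, C)`.
#' @return Predicted age in years.
#' @export
predict_with_mirror <- function(net, image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L, 1L))
  predict_ages(net, image, mirror = TRUE)
}

# --- data loading and augmentation ------------------------------------------

#' Read a dataset manifest
#'
#' @param manifest_csv Path to a CSV with columns `image_path` (relative to
#'   the manifest's directory or absolute) and `age`.
#' @return Data frame with absolute `image_path` and integer `age`.
#' @export
read_manifest <- function(manifest_csv) {
  m <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  if (!all(c("image_path", "age") %in% names(m)))
    stop("manifest needs image_path and age columns", call. = FALSE)
  rel <- !grepl("^/", m$image_path)
  m$image_path[rel] <- file.path(dirname(manifest_csv), m$image_path[rel])
  m$age <- as.integer(m$age)
  m
}

#' Load manifest images into a batch array
#'
#' Reads each image (PNG/JPEG, grayscale), resizes to `image_size` and
#' stacks into an `(H, W, N, 1)` array with values in `[0, 1]`. Unreadable
#' images are skipped with a warning.
#'
#' @param manifest Data frame from [read_manifest()].
#' @param image_size Square side length in pixels.
#' @return List with `x` (the array) and `age` (integer vector).
#' @export
load_image_data <- function(manifest, image_size = 64L) {
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest", call. = FALSE)
  imgs <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    img <- tryCatch(suppressWarnings({
      im <- EBImage::readImage(manifest$image_path[i])
      if (length(dim(im)) == 3L) im <- im[, , 1]
      if (!all(dim(im) == image_size))
        im <- EBImage::resize(im, w = image_size, h = image_size)
      t(EBImage::imageData(im))  # files store (x, y); arrays are (row, col)
    }), error = function(e) {
      warning("skipping unreadable image ", manifest$image_path[i], ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(img)) {
      imgs[[i]] <- img
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("no readable images in manifest", call. = FALSE)
  x <- array(0, dim = c(image_size, image_size, sum(ok), 1L))
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    x[, , j, 1L] <- imgs[[i]]
  }
  list(x = x, age = as.integer(manifest$age[ok]))
}

# Random flip / isotropic scale / translation of one image matrix, by
# nearest-neighbour resampling about the image centre.
augment_image <- function(img, flip, scale, tx, ty) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- round((seq_len(h) - cy) / scale + cy - ty)
  xx <- round((seq_len(w) - cx) / scale + cx - tx)
  yy <- pmin(pmax(yy, 1L), h)
  xx <- pmin(pmax(xx, 1L), w)
  out <- img[yy, xx, drop = FALSE]
  if (flip) out <- out[, rev(seq_len(w)), drop = FALSE]
  out
}

augment_batch <- function(xb, scale_range = c(0.9, 1.1), shift_frac = 0.05) {
  d <- dim(xb)
  for (i in seq_len(d[3])) {
    xb[, , i, 1] <- augment_image(
      xb[, , i, 1],
      flip = stats::runif(1) < 0.5,
      scale = stats::runif(1, scale_range[1], scale_range[2]),
      tx = stats::runif(1, -shift_frac, shift_frac) * d[2],
      ty = stats::runif(1, -shift_frac, shift_frac) * d[1])
  }
  xb
}

#' Train an age-estimation network
#'
#' Minimizes cross-entropy between the predicted distribution over age bins
#' and label-smoothed targets with Adam; horizontal flip, scale and
#' translation augmentation is applied to training batches only. The DEX
#' expectation is used for validation MAE.
#'
#' @param net A runtime network from [build_network_from_spec()].
#' @param data List with `x` (array) and `age` (integers within the label
#'   range; clamp first with [clamp_ages()]).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty.
#' @param label_eps Label-smoothing mass.
#' @param augment Apply training augmentation.
#' @param val_data Optional held-out list with `x` and `age` for per-epoch
#'   validation MAE.
#' @param seed Seed for batch order and augmentation.
#' @param verbose Print per-epoch progress.
#' @return List with the trained `net` and a `log` data frame
#'   (epoch, loss, val_mae).
#' @export
train_age_model <- function(net, data, epochs = 5L, batch_size = 16L, lr = 1e-4,
                            weight_decay = 0, label_eps = 0.1, augment = TRUE,
                            val_data = NULL, seed = 1L, verbose = FALSE) {
  set.seed(seed)
  n <- dim(data$x)[3]
  if (n == 0L) stop("empty training data", call. = FALSE)
  k <- net$num_classes
  if (any(data$age < 0L | data$age > k - 1L))
    stop("ages outside 0..", k - 1L, "; clamp with clamp_ages()", call. = FALSE)
  ps <- net_params(net)
  log_rows <- data.frame(epoch = integer(), loss = numeric(), val_mae = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- data$x[, , idx, , drop = FALSE]
      if (augment) xb <- augment_batch(xb)
      targets <- t(vapply(data$age[idx], function(a)
        label_smoothing_target(a, k, label_eps)$probs, numeric(k)))
      logits <- net_forward(net, xb, train = TRUE)
      ls <- softmax_xent(logits, targets)
      for (p in ps) p$g <- NULL
      net_backward(net, ls$dlogits)
      opt_adam_step(ps, lr, weight_decay = weight_decay)
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    vm <- if (!is.null(val_data))
      mae(predict_ages(net, val_data$x), val_data$age) else NA_real_
    log_rows <- rbind(log_rows,
                      data.frame(epoch = ep, loss = ep_loss / nb, val_mae = vm))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, ep_loss / nb,
                      if (is.na(vm)) "" else sprintf(", val MAE %.2f", vm)))
  }
  list(net = net, log = log_rows)
}

#' A small reference network for desk-scale training
#'
#' A four-stage grayscale network (stem plus three inverted-residual
#' blocks) sized for 64x64 inputs; used by the end-to-end tests and the
#' worked examples.
#'
#' @param num_classes Classifier width.
#' @param width Base channel count.
#' @return An [arch_spec()].
#' @export
build_small_agenet <- function(num_classes = 76L, width = 8L) {
  arch_spec("small-age-net",
            stem = list(cout = width, kernel = 3L, stride = 2L),
            blocks = list(
              block_spec("mbconv", width, 2L * width, stride = 2L, expand = 3),
              block_spec("parallel_asym", 2L * width, 4L * width, stride = 2L,
                         expand = 3),
              block_spec("mbconv", 4L * width, 4L * width, stride = 1L, expand = 3,
                         kernel = 3L)),
            head = list(conv_width = 16L * width, num_classes = as.integer(num_classes)),
            input_channels = 1L)
}
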