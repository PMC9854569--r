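#' Training configuration
#'
#' Optimization and augmentation settings.  Defaults are the reference
#' training recipe: SGD with momentum 0.99 and weight decay 1e-8,
#' learning rate 1e-3, batch size 12, 650 epochs, an 8:2 train/test
#' split, and loss weights `alpha = 0.5` (binary cross-entropy) and
#' `beta = 1` (weighted mean absolute error).
#'
#' @param alpha weight of the probability (BCE) loss term.
#' @param beta weight of the distance (WMAE) loss term.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size images per SGD step.
#' @param epochs number of passes over the training set.
#' @param split_ratio train fraction when splitting a dataset.
#' @param seed RNG seed controlling initialization, shuffling and
#'   augmentation.
#' @param augment apply random augmentation during training.
#' @param equalize apply histogram equalization to inputs.
#' @param normalize_by `"all_pixels"` (default) divides both losses by
#'   the image pixel count; `"foreground_pixels"` divides by the number
#'   of foreground pixels.
#' @return object of class `spc_train_config`.
#' @export
spc_train_config <- function(alpha = 0.5, beta = 1, learning_rate = 1e-3,
                             momentum = 0.99, weight_decay = 1e-8,
                             batch_size = 12, epochs = 650,
                             split_ratio = 0.8, seed = 1, augment = TRUE,
                             equalize = TRUE,
                             normalize_by = c("all_pixels",
                                              "foreground_pixels")) {
  stopifnot(alpha >= 0, beta >= 0, split_ratio > 0, split_ratio < 1,
            epochs >= 0, batch_size >= 1)
  structure(list(alpha = alpha, beta = beta,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = batch_size,
                 epochs = epochs, split_ratio = split_ratio,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 equalize = isTRUE(equalize),
                 normalize_by = match.arg(normalize_by)),
            class = "spc_train_config")
}

.loss_n <- function(prob_true, normalize_by) {
  if (normalize_by == "foreground_pixels") max(1, sum(prob_true > 0))
  else length(prob_true)
}

#' Binary cross-entropy loss
#'
#' Mean two-class cross-entropy between the predicted and target object
#' probability maps, with the soft target treated as the positive-class
#' probability: `-(1/N) * sum(y*log(x) + (1-y)*log(1-x))`.  Predictions
#' are clamped to `[eps, 1-eps]`.
#'
#' @param prob_pred,prob_true numeric matrices of the same shape.
#' @param eps clamping constant.
#' @param normalize_by see [spc_train_config()].
#' @return non-negative scalar.
#' @export
bce_loss <- function(prob_pred, prob_true, eps = 1e-7,
                     normalize_by = "all_pixels") {
  if (!all(dim(prob_pred) == dim(prob_true)))
    stop("bce_loss: shape mismatch")
  x <- pmin(pmax(prob_pred, eps), 1 - eps)
  -sum(prob_true * log(x) + (1 - prob_true) * log(1 - x)) /
    .loss_n(prob_true, normalize_by)
}

#' Weighted mean absolute error loss
#'
#' Radial-distance regression loss: each pixel's absolute errors, summed
#' over the ray channels, are weighted by that pixel's ground-truth
#' object probability, so predictions near instance cores count more and
#' background pixels (weight 0) not at all:
#' `(1/N) * sum_i y_i * sum_j |t_ij - p_ij|`.
#'
#' @param dist_pred,dist_true `H x W x n_rays` arrays.
#' @param prob_true `H x W` ground-truth probability map (the weights).
#' @param normalize_by see [spc_train_config()].
#' @return non-negative scalar.
#' @export
wmae_loss <- function(dist_pred, dist_true, prob_true,
                      normalize_by = "all_pixels") {
  if (!all(dim(dist_pred) == dim(dist_true)) ||
      !all(dim(dist_pred)[1:2] == dim(prob_true)))
    stop("wmae_loss: shape mismatch")
  ae <- abs(dist_true - dist_pred)
  per_pixel <- rowSums(matrix(ae, ncol = dim(ae)[3]))
  sum(as.vector(prob_true) * per_pixel) / .loss_n(prob_true, normalize_by)
}

#' Total training loss
#'
#' `alpha * BCE + beta * WMAE`; see [bce_loss()] and [wmae_loss()].
#'
#' @inheritParams bce_loss
#' @inheritParams wmae_loss
#' @param alpha,beta loss weights.
#' @return non-negative scalar.
#' @export
total_loss <- function(prob_pred, prob_true, dist_pred, dist_true,
                       alpha = 0.5, beta = 1,
                       normalize_by = "all_pixels") {
  alpha * bce_loss(prob_pred, prob_true, normalize_by = normalize_by) +
    beta * wmae_loss(dist_pred, dist_true, prob_true,
                     normalize_by = normalize_by)
}

#' Histogram equalization
#'
#' Standard grayscale histogram equalization: intensities are mapped
#' through the empirical cumulative distribution computed on `nbins`
#' levels, yielding values in `[0, 1]`.
#'
#' @param image numeric matrix; any non-negative range.
#' @param nbins number of histogram bins.
#' @return equalized matrix in `[0, 1]`.
#' @export
equalize_histogram <- function(image, nbins = 256) {
  rng <- range(image)
  if (rng[2] <= rng[1]) return(image)
  lev <- pmin(as.integer((image - rng[1]) / (rng[2] - rng[1]) * (nbins - 1)),
              nbins - 1L)
  h <- tabulate(lev + 1L, nbins)
  cdf <- cumsum(h) / length(image)
  matrix(cdf[lev + 1L], nrow(image), ncol(image))
}

#' Random augmentation of an image/label pair
#'
#' A randomly sampled composition of horizontal/vertical flips, rotation,
#' isotropic scaling, translation, cropping (crop then resize back) and
#' elastic deformation.  Geometric transforms are applied identically to
#' the image (bilinear) and the label map (nearest neighbor), preserving
#' integer instance ids; the output size equals the input size.
#'
#' @param image numeric matrix.
#' @param labels integer label map, same shape.
#' @param p_transform probability that each individual transform is
#'   active in one draw.
#' @param max_rotate rotation range in degrees (`+/-`).
#' @param scale_range isotropic scale factor range.
#' @param max_translate translation range as a fraction of image size.
#' @param crop_range retained fraction when cropping.
#' @param elastic_alpha elastic displacement amplitude in pixels.
#' @param elastic_grid control-grid size of the elastic field.
#' @return list with transformed `image` and `labels`.
#' @export
augment_pair <- function(image, labels, p_transform = 0.5,
                         max_rotate = 90, scale_range = c(0.8, 1.2),
                         max_translate = 0.1, crop_range = c(0.8, 1),
                         elastic_alpha = 8, elastic_grid = 6) {
  stopifnot(all(dim(image) == dim(labels)))
  H <- nrow(image); W <- ncol(image)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  ang <- 0; sc <- 1; tr <- c(0, 0); flh <- FALSE; flv <- FALSE
  if (runif(1) < p_transform) ang <- runif(1, -max_rotate, max_rotate) * pi / 180
  if (runif(1) < p_transform) sc <- runif(1, scale_range[1], scale_range[2])
  if (runif(1) < p_transform)
    tr <- c(runif(1, -max_translate, max_translate) * H,
            runif(1, -max_translate, max_translate) * W)
  if (runif(1) < p_transform) {  # crop: zoom into a random window
    f <- runif(1, crop_range[1], crop_range[2])
    sc <- sc / f
    tr <- tr + c(runif(1, 0, (1 - f)) * H * 0.5, runif(1, 0, (1 - f)) * W * 0.5)
  }
  if (runif(1) < p_transform) flh <- TRUE
  if (runif(1) < p_transform) flv <- TRUE
  # inverse map: output pixel -> source coordinate
  gr <- matrix(rep(0:(H - 1), W), H, W) - cy
  gc <- matrix(rep(0:(W - 1), each = H), H, W) - cx
  if (flh) gc <- -gc
  if (flv) gr <- -gr
  ca <- cos(-ang); sa <- sin(-ang)
  rows <- (gr * ca - gc * sa) / sc + cy + tr[1]
  cols <- (gr * sa + gc * ca) / sc + cx + tr[2]
  if (runif(1) < p_transform) {  # elastic deformation
    g <- elastic_grid
    dr <- cpp_resize_bilinear(array(rnorm(g * g), c(g, g, 1)), H, W)
    dc <- cpp_resize_bilinear(array(rnorm(g * g), c(g, g, 1)), H, W)
    rows <- rows + elastic_alpha * matrix(dr, H, W)
    cols <- cols + elastic_alpha * matrix(dc, H, W)
  }
  img2 <- cpp_warp(image, rows, cols, 0L)
  lab2 <- cpp_warp(matrix(as.numeric(labels), H, W), rows, cols, 1L)
  list(image = img2, labels = matrix(as.integer(lab2), H, W))
}

.sgd_update <- function(params, grads, state, lr, mom, wd) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    if (is.null(st)) st <- list(vw = 0 * g$gw, vb = if (!is.null(g$gb)) 0 * g$gb)
    st$vw <- mom * st$vw + g$gw + wd * params[[nm]]$w
    params[[nm]]$w <- params[[nm]]$w - lr * st$vw
    if (!is.null(g$gb)) {
      st$vb <- mom * st$vb + g$gb + wd * params[[nm]]$b
      params[[nm]]$b <- params[[nm]]$b - lr * st$vb
    }
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train the segmentation network
#'
#' Encodes each label map into probability/distance targets, optionally
#' augments and equalizes inputs, and minimizes
#' `alpha * BCE + beta * WMAE` with momentum SGD.  Fully reproducible for
#' a fixed seed.
#'
#' @param dataset list of `list(image = matrix, labels = matrix)` pairs.
#' @param net_config [spc_network()] configuration.
#' @param train_config [spc_train_config()] settings.
#' @param params optional warm-start parameters.
#' @param verbose print one line per epoch.
#' @return list with trained `params` and the numeric per-epoch mean
#'   `history` of the total loss.
#' @export
spc_train <- function(dataset, net_config, train_config = spc_train_config(),
                      params = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  tc <- train_config
  set.seed(tc$seed)
  if (is.null(params)) params <- spc_init(net_config, seed = tc$seed)
  state <- list()
  history <- numeric(0)
  nr <- net_config$n_rays
  # without augmentation the targets are fixed: encode once
  enc_cache <- if (!tc$augment) lapply(dataset, function(pair) {
    img <- pair$image
    if (tc$equalize) img <- equalize_histogram(img)
    c(encode_targets(pair$labels, nr), list(image = img))
  }) else NULL
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(length(dataset))
    epoch_losses <- numeric(0)
    batch_grads <- NULL
    batch_n <- 0L
    for (ii in ord) {
      if (is.null(enc_cache)) {
        pair <- dataset[[ii]]
        aug <- augment_pair(pair$image, pair$labels)
        img <- aug$image
        if (tc$equalize) img <- equalize_histogram(img)
        enc <- encode_targets(aug$labels, nr)
      } else {
        enc <- enc_cache[[ii]]
        img <- enc$image
      }
      fw <- spc_forward(img, params, keep_cache = TRUE)
      N <- .loss_n(enc$prob, tc$normalize_by)
      loss <- tc$alpha * bce_loss(fw$prob, enc$prob,
                                  normalize_by = tc$normalize_by) +
        tc$beta * wmae_loss(fw$dist, enc$dist, enc$prob,
                            normalize_by = tc$normalize_by)
      epoch_losses <- c(epoch_losses, loss)
      # analytic head gradients (pre-activation)
      gprob <- array((fw$prob - enc$prob) * tc$alpha / N,
                     c(nrow(img), ncol(img), 1))
      gd <- sign(fw$dist - enc$dist) * as.vector(enc$prob) * tc$beta / N
      gd[fw$dist <= 0] <- 0  # ReLU subgradient
      grads <- spc_backward(params, fw$cache, gprob, gd)
      batch_grads <- if (is.null(batch_grads)) grads else
        mapply(function(a, b) list(gw = a$gw + b$gw,
                                   gb = if (is.null(a$gb)) NULL else a$gb + b$gb),
               batch_grads, grads, SIMPLIFY = FALSE)
      batch_n <- batch_n + 1L
      if (batch_n == tc$batch_size || ii == ord[length(ord)]) {
        scaled <- lapply(batch_grads, function(g)
          list(gw = g$gw / batch_n,
               gb = if (is.null(g$gb)) NULL else g$gb / batch_n))
        upd <- .sgd_update(params, scaled, state, tc$learning_rate,
                           tc$momentum, tc$weight_decay)
        params <- upd$params; state <- upd$state
        batch_grads <- NULL; batch_n <- 0L
      }
    }
    history <- c(history, mean(epoch_losses))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", epoch, tc$epochs,
                      mean(epoch_losses)))
  }
  attr(params, "config") <- net_config
  class(params) <- "spc_params"
  list(params = params, history = history)
}

#' Split a dataset into train and test parts
#'
#' @param dataset list of image/label pairs.
#' @param split_ratio train fraction.
#' @param seed shuffle seed.
#' @return list with `train` and `test` sublists.
#' @export
split_dataset <- function(dataset, split_ratio = 0.8, seed = 1) {
  set.seed(seed)
  n <- length(dataset)
  ord <- sample(n)
  ntr <- max(1, round(split_ratio * n))
  list(train = dataset[ord[seq_len(ntr)]],
       test = dataset[ord[setdiff(seq_len(n), seq_len(ntr))]])
}
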