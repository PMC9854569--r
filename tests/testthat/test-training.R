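test_that("BCE loss: closed forms and direct-summation oracle", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  x <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lte(bce_loss(x, y), 1e-6)
  # y = 1, x = 0.5 everywhere -> ln 2
  expect_equal(bce_loss(matrix(0.5, 3, 3), matrix(1, 3, 3)), log(2),
               tolerance = 1e-9)
  set.seed(12)
  yp <- matrix(runif(64), 8, 8)
  xp <- matrix(runif(64, 0.01, 0.99), 8, 8)
  direct <- -mean(yp * log(xp) + (1 - yp) * log(1 - xp))
  expect_equal(bce_loss(xp, yp), direct, tolerance = 1e-6)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("WMAE loss: annihilation, hand case, permutation invariance", {
  d <- array(runif(4 * 4 * 32), c(4, 4, 32))
  y <- matrix(runif(16), 4, 4)
  expect_equal(wmae_loss(d, d, y), 0)
  expect_equal(wmae_loss(d, d + 5, matrix(0, 4, 4)), 0)
  # 4x4 toy: weight 1 on two pixels, |t - p| = 1 on all 32 rays there
  t0 <- array(0, c(4, 4, 32))
  p0 <- t0
  p0[1, 1, ] <- 1; p0[3, 2, ] <- 1
  w <- matrix(0, 4, 4); w[1, 1] <- 1; w[3, 2] <- 1
  expect_equal(wmae_loss(p0, t0, w), (2 * 32 * 1) / 16)
  expect_equal(wmae_loss(p0, t0, w), 4.0)
  # consistent ray-channel permutation leaves the loss unchanged
  set.seed(5)
  t1 <- array(runif(4 * 4 * 8), c(4, 4, 8))
  p1 <- array(runif(4 * 4 * 8), c(4, 4, 8))
  perm <- sample(8)
  expect_equal(wmae_loss(p1, t1, y), wmae_loss(p1[, , perm], t1[, , perm], y),
               tolerance = 1e-12)
  expect_error(wmae_loss(p1, t1[, , 1:4], y), "shape")
})

test_that("total loss recomposes its terms", {
  set.seed(6)
  y <- matrix(runif(36), 6, 6)
  x <- matrix(runif(36, 0.05, 0.95), 6, 6)
  t1 <- array(runif(36 * 4), c(6, 6, 4))
  p1 <- array(runif(36 * 4), c(6, 6, 4))
  expect_equal(total_loss(x, y, p1, t1),
               0.5 * bce_loss(x, y) + 1 * wmae_loss(p1, t1, y),
               tolerance = 1e-9)
  expect_equal(total_loss(x, y, p1, t1, alpha = 0),
               wmae_loss(p1, t1, y), tolerance = 1e-12)
  expect_equal(total_loss(x, y, p1, t1, beta = 0),
               0.5 * bce_loss(x, y), tolerance = 1e-12)
  # zero loss needs hard probability targets (soft-target BCE has an
  # entropy floor)
  yb <- matrix(as.numeric(runif(36) > 0.5), 6, 6)
  expect_equal(total_loss(yb, yb, t1, t1), 0, tolerance = 1e-5)
})

test_that("histogram equalization follows the CDF", {
  const <- matrix(0.4, 5, 5)
  expect_equal(equalize_histogram(const), const)
  # two-level image: levels map to their CDF values
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  eq <- equalize_histogram(img)
  expect_equal(sort(unique(as.vector(eq))), c(0.5, 1.0))
  expect_true(all(eq[img == 10] == 0.5) && all(eq[img == 200] == 1.0))
  set.seed(3)
  r <- matrix(runif(400), 20, 20)
  er <- equalize_histogram(r)
  expect_gte(min(er), 0); expect_lte(max(er), 1)
})

test_that("augmentation preserves alignment, ids, and size", {
  set.seed(77)
  g <- generate_image(generator_config(image_size = c(48, 48),
                                       cells_per_image = c(2, 4),
                                       radius_range = c(5, 9)))
  # identity draw: nothing active
  id <- augment_pair(g$image, g$labels, p_transform = 0)
  expect_equal(id$image, g$image)
  expect_equal(id$labels, g$labels)
  # flips are involutions: all transforms on but only flips non-trivial
  flip_once <- function(img, lab) augment_pair(
    img, lab, p_transform = 1, max_rotate = 0, scale_range = c(1, 1),
    max_translate = 0, crop_range = c(1, 1), elastic_alpha = 0)
  f1 <- flip_once(g$image, g$labels)
  f2 <- flip_once(f1$image, f1$labels)
  expect_equal(f2$labels, g$labels)
  expect_equal(f2$image, g$image, tolerance = 1e-12)
  # arbitrary draw: output ids form a subset, size is preserved
  for (k in 1:5) {
    a <- augment_pair(g$image, g$labels)
    expect_equal(dim(a$image), dim(g$image))
    expect_true(all(unique(as.vector(a$labels)) %in%
                      unique(as.vector(g$labels))))
    expect_true(is.integer(a$labels))
  }
})

test_that("training contract: errors, epochs = 0, determinism, smoke", {
  expect_error(spc_train(list(), spc_network()), "empty")
  ds <- tiny_dataset(6)
  net <- spc_network(n_rays = 8, base_channels = 2, use_aspp = FALSE)
  tc0 <- spc_train_config(epochs = 0, seed = 3)
  fit0 <- spc_train(ds, net, tc0)
  expect_equal(fit0$history, numeric(0))
  expect_equal(unclass(fit0$params), unclass(spc_init(net, 3)))
  # same seed twice -> identical loss history (with augmentation on)
  tc2 <- spc_train_config(epochs = 2, batch_size = 3, seed = 11)
  h1 <- spc_train(ds, net, tc2)$history
  h2 <- spc_train(ds, net, tc2)$history
  expect_identical(h1, h2)
  expect_length(h1, 2)
  expect_true(all(is.finite(h1)))
})

test_that("short training reduces the loss on a tiny problem", {
  ds <- tiny_dataset(20)
  net <- spc_network(n_rays = 8, base_channels = 4, use_aspp = FALSE)
  tc <- spc_train_config(epochs = 5, batch_size = 4, seed = 2,
                         augment = FALSE)
  fit <- spc_train(ds, net, tc)
  expect_lt(fit$history[5], fit$history[1])
})

test_that("training configuration defaults match the reference recipe", {
  tc <- spc_train_config()
  expect_equal(tc$learning_rate, 1e-3)
  expect_equal(tc$batch_size, 12)
  expect_equal(tc$momentum, 0.99)
  expect_equal(tc$weight_decay, 1e-8)
  expect_equal(tc$epochs, 650)
  expect_equal(tc$split_ratio, 0.8)
  expect_equal(tc$alpha, 0.5)
  expect_equal(tc$beta, 1)
})
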