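tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_size = 16L, in_channels = 3L, stream_widths = c(4L, 8L, 16L),
         batch_size = 16L, epochs = 5L, lr = 0.01, seed = 1L),
    list(...))
  do.call(model_config, args)
}

test_that("measured longest-path depth is 12 in both kernel modes", {
  for (mode in c("asymmetric_1x7_7x1", "square_3x3")) {
    for (w in list(c(4L, 8L, 16L), c(8L, 8L, 8L), c(16L, 32L, 64L))) {
      m <- build_model(tiny_cfg(kernel_mode = mode, stream_widths = w))
      expect_equal(model_depth(m), 12L)
      expect_equal(model_n_streams(m), 3L)
    }
  }
})

test_that("asymmetric and square modes differ in parameters, not depth", {
  w <- c(4L, 8L, 16L)
  ma <- build_model(tiny_cfg(kernel_mode = "asymmetric_1x7_7x1",
                             stream_widths = w))
  ms <- build_model(tiny_cfg(kernel_mode = "square_3x3", stream_widths = w))
  expect_equal(model_depth(ma), model_depth(ms))
  # per block of width c: factorized pair has 2*(7c^2 + c) parameters where
  # a single 3x3 conv has 9c^2 + c; four blocks per stream
  expected_diff <- sum(4 * (2 * (7 * w^2 + w) - (9 * w^2 + w)))
  expect_equal(n_parameters(ma) - n_parameters(ms), expected_diff)
})

test_that("forward pass maps image batches to two class scores", {
  m <- build_model(tiny_cfg())
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  p <- predict_model(m, x)
  expect_equal(dim(p), c(4L, 2L))
  expect_equal(colnames(p), c("AF", "NSR"))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_error(train_model(m, x, c("AF", "NSR")), "labels length")
  bad <- array(0, c(8, 8, 3, 2))
  expect_error(train_model(m, bad, c("AF", "NSR")), "shape")
})

test_that("a trivially separable set is fitted perfectly within five epochs", {
  imgs <- lapply(1:60, function(i) {
    lev <- if (i <= 30) 0.2 else 0.8
    array(lev + runif(16 * 16 * 3, -0.1, 0.1), c(16, 16, 3))
  })
  labs <- rep(c("AF", "NSR"), each = 30)
  m <- train_model(build_model(tiny_cfg()), imgs, labs)
  expect_equal(tail(m$history$acc, 1), 1)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
})

test_that("training and prediction are seed-deterministic", {
  set.seed(99)
  imgs <- array(runif(16 * 16 * 3 * 20), c(16, 16, 3, 20))
  labs <- rep(c("AF", "NSR"), 10)
  m1 <- train_model(build_model(tiny_cfg(epochs = 2L)), imgs, labs)
  m2 <- train_model(build_model(tiny_cfg(epochs = 2L)), imgs, labs)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(predict_model(m1, imgs), predict_model(m2, imgs))
})

test_that("predictions are invariant to batch partitioning and duplication", {
  set.seed(7)
  imgs <- array(runif(16 * 16 * 3 * 10), c(16, 16, 3, 10))
  labs <- rep(c("AF", "NSR"), 5)
  m <- train_model(build_model(tiny_cfg(epochs = 2L)), imgs, labs)
  p1 <- predict_model(m, imgs, batch_size = 1L)
  p10 <- predict_model(m, imgs, batch_size = 10L)
  expect_equal(p1, p10, tolerance = 1e-12)
  dup <- array(imgs[, , , c(1, 1, 2)], c(16, 16, 3, 3))
  pd <- predict_model(m, dup)
  expect_equal(pd[1, ], pd[2, ], tolerance = 1e-12)
})

test_that("lead stacking concatenates channels", {
  im <- function() array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(dim(stack_leads(list(im(), im()))), c(16, 16, 6))
  one <- im()
  expect_equal(stack_leads(list(one)), one)
  expect_equal(dim(stack_leads(replicate(12, im(), simplify = FALSE))),
               c(16, 16, 36))
  expect_error(stack_leads(list(im(), array(0, c(8, 8, 3)))), "size")
})

test_that("checkpoints round-trip through disk", {
  set.seed(5)
  imgs <- array(runif(16 * 16 * 3 * 8), c(16, 16, 3, 8))
  labs <- rep(c("AF", "NSR"), 4)
  m <- train_model(build_model(tiny_cfg(epochs = 1L)), imgs, labs)
  td <- withr::local_tempdir()
  path <- file.path(td, "ckpt.rds")
  save_model(m, path)
  expect_true(file.exists(file.path(td, "ckpt.json")))
  m2 <- load_model(path)
  expect_equal(predict_model(m2, imgs), predict_model(m, imgs))
})

test_that("the network beats a pixel-logistic baseline on shift-variant textures", {
  # both classes share the same pixel histogram; they differ only in the
  # spatial arrangement of the bright pixels (periodic stripes vs random
  # scatter at a random phase), so a linear model on pixels has no usable
  # per-pixel signal while local convolution filters do
  set.seed(21)
  mk <- function(label) {
    base <- matrix(runif(16 * 16, 0.4, 0.6), 16, 16)
    ph <- sample(0:7, 1)
    cph <- sample(0:1, 1)
    rows <- ((seq_len(16) + ph) %/% 2) %% 2 == 0
    cols <- (seq_len(16) + cph) %% 2 == 0
    stripe <- which(outer(rows, cols, "&"))
    bright <- if (label == "AF") stripe else
      sample(length(base), length(stripe))
    base[bright] <- base[bright] + 0.35
    array(rep(base, 3), c(16, 16, 3))
  }
  labs <- rep(c("AF", "NSR"), each = 40)
  imgs <- lapply(labs, mk)
  tr <- c(1:30, 41:70)
  te <- setdiff(seq_along(labs), tr)
  cnn <- parnet_factory(tiny_cfg(epochs = 15L))(3L, seed = 2L)
  cnn$fit(imgs[tr], labs[tr])
  f1_cnn <- metrics(confusion(labs[te], cnn$predict(imgs[te])))$f1
  lgr <- logistic_pixel_factory()(3L, seed = 2L)
  lgr$fit(imgs[tr], labs[tr])
  f1_log <- metrics(confusion(labs[te], lgr$predict(imgs[te])))$f1
  expect_gt(f1_cnn, f1_log)
})
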