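# O(N^2) brute-force recurrence oracle, independent of the implementation
brute_rp <- function(pts, norm = "euclidean", epsilon = NULL) {
  n <- nrow(pts)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- pts[i, ] - pts[j, ]
      v <- switch(norm,
                  euclidean = sqrt(sum(d^2)),
                  max = max(abs(d)),
                  manhattan = sum(abs(d)))
      out[i, j] <- if (is.null(epsilon)) v else as.numeric(v <= epsilon)
    }
  }
  out
}

test_that("delay embedding pairs each sample with its lagged copy", {
  tr <- takens_embed(c(1, 2, 3, 4), tau = 1)
  expect_equal(unname(tr$points),
               rbind(c(2, 1), c(3, 2), c(4, 3)))
  const <- takens_embed(rep(2, 10))
  expect_true(all(const$points == 2))
  expect_equal(nrow(takens_embed(rnorm(3000))$points), 2999L)
  tr2 <- takens_embed(1:10, tau = 3)
  expect_equal(nrow(tr2$points), 7L)
  expect_equal(unname(tr2$points[1, ]), c(4, 1))
  expect_error(takens_embed(c(1, 2), tau = 2), "longer")
})

test_that("un-thresholded matrices match hand-checked distances", {
  tr <- structure(list(points = rbind(c(0, 0), c(3, 4)), tau = 1L),
                  class = "trajectory")
  r <- unthresholded_rp(tr)
  expect_equal(r$values, rbind(c(0, 5), c(5, 0)))
  same <- structure(list(points = matrix(1, 5, 2), tau = 1L),
                    class = "trajectory")
  expect_true(all(unthresholded_rp(same)$values == 0))
})

test_that("both recurrence modes equal the brute-force oracle exactly", {
  set.seed(11)
  for (case in 1:30) {
    n <- sample(10:120, 1)
    tr <- takens_embed(rnorm(n + 1))
    norm <- sample(c("euclidean", "max", "manhattan"), 1)
    r <- unthresholded_rp(tr, norm)
    expect_identical(dim(r$values), c(n, n))
    expect_equal(r$values, brute_rp(tr$points, norm), tolerance = 1e-14)
    eps <- stats::runif(1, 0, max(r$values))
    rt <- thresholded_rp(tr, eps, norm)
    expect_equal(rt$values, brute_rp(tr$points, norm, eps))
    # thresholding is the indicator of the un-thresholded matrix
    expect_equal(rt$values, (r$values <= eps) + 0)
  }
})

test_that("threshold boundary, extremes and errors follow the Heaviside convention", {
  tr <- structure(list(points = rbind(c(0, 0), c(3, 4)), tau = 1L),
                  class = "trajectory")
  expect_equal(thresholded_rp(tr, 5)$values, matrix(1, 2, 2))  # tie -> 1
  expect_equal(thresholded_rp(tr, 4.999)$values, diag(2))
  big <- takens_embed(rnorm(30))
  rmax <- max(unthresholded_rp(big)$values)
  expect_true(all(thresholded_rp(big, rmax)$values == 1))
  expect_equal(thresholded_rp(big, 0)$values, diag(29))
  expect_error(thresholded_rp(big, -0.1), "epsilon")
})

test_that("recurrence matrices are symmetric with the diagonal convention", {
  for (s in 1:5) {
    set.seed(s)
    tr <- takens_embed(rnorm(60))
    r <- unthresholded_rp(tr)$values
    expect_equal(r, t(r))
    expect_true(all(diag(r) == 0))
    b <- thresholded_rp(tr, 0.5)$values
    expect_equal(b, t(b))
    expect_true(all(diag(b) == 1))
    expect_true(all(b %in% c(0, 1)))
  }
})

test_that("rendering is square RGB in [0,1], scale-invariant, degenerate-safe", {
  img <- render_rp_image(matrix(0, 40, 40), size = 32)
  expect_equal(dim(img$pixels), c(32, 32, 3))
  for (ch in 1:3) expect_equal(length(unique(as.vector(img$pixels[, , ch]))), 1L)
  r <- unthresholded_rp(takens_embed(rnorm(80)))
  a <- render_rp_image(r, size = 299)
  expect_equal(dim(a$pixels), c(299, 299, 3))
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  scaled <- r
  scaled$values <- r$values * 3.7
  b <- render_rp_image(scaled, size = 299)
  expect_equal(a$pixels, b$pixels)
  expect_error(render_rp_image(r, size = 1), "size")
})

test_that("the 1D-to-image pipeline is deterministic with the documented geometry", {
  x <- as.vector(scale(rnorm(3000)))
  img1 <- ecg_to_rp(x, 300)
  img2 <- ecg_to_rp(x, 300)
  expect_identical(img1$pixels, img2$pixels)
  expect_equal(dim(img1$pixels), c(299, 299, 3))
  # 10 s at 300 Hz decimated to 300 points embeds into a 299 x 299 matrix
  dec <- pkg$decimate_uniform(zscore(x), 300L)
  expect_length(dec, 300L)
  expect_equal(nrow(unthresholded_rp(takens_embed(dec))$values), 299L)
  # full-matrix route produces the same output shape
  imgf <- ecg_to_rp(x[1:400], 300, rp_config(size = 64, full_matrix = TRUE))
  expect_equal(dim(imgf$pixels), c(64, 64, 3))
})

test_that("recurrence plots are order-sensitive", {
  set.seed(3)
  x <- rnorm(100)
  r1 <- ecg_to_rp(x, 100, rp_config(size = 32))
  r2 <- ecg_to_rp(rev(x), 100, rp_config(size = 32))
  r3 <- ecg_to_rp(sample(x), 100, rp_config(size = 32))
  expect_false(identical(r1$pixels, r3$pixels))
  expect_false(identical(r1$pixels, r2$pixels))
})

test_that("NSR recurrence texture is more periodic at the RR lag than AF", {
  cfg <- synth_config(fs = 300, noise_sd = 0.01)
  pc <- prep_config(target_fs = 300, segment_len = 10)
  lag <- round(cfg$rr_mean_nsr * 300 / 10)  # RR lag in decimated samples
  acf_at_rr <- function(label, seed) {
    rec <- generate_record(cfg, label, seed)
    seg <- lead_segment(rec, "II", pc)
    dec <- pkg$decimate_uniform(seg$samples, 300L)
    prof <- rowMeans(unthresholded_rp(takens_embed(dec))$values)
    stats::acf(prof, lag.max = lag + 2, plot = FALSE)$acf[lag + 1]
  }
  deltas <- vapply(1:25, function(s) {
    acf_at_rr("NSR", 3000 + s) - acf_at_rr("AF", 4000 + s)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.6)
})
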