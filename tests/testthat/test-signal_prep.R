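test_that("CSV and WFDB round-trips preserve signals and metadata", {
  cfg <- tiny_synth(duration = 2)
  rec <- generate_record(cfg, "AF", seed = 1L)
  td <- withr::local_tempdir()
  write_record(rec, file.path(td, "rec1"), format = "csv")
  back <- load_record(file.path(td, "rec1"))
  expect_equal(back$signals, rec$signals, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$label, "AF")
  write_record(rec, file.path(td, "rec2"), format = "wfdb")
  backw <- load_record(file.path(td, "rec2.hea"))
  # 16-bit quantization at gain 1000: half an ADC unit of tolerance
  expect_lt(max(abs(backw$signals - rec$signals)), 1e-3)
  expect_equal(backw$fs, rec$fs)
  expect_equal(backw$lead_names, rec$lead_names)
})

test_that("a CSV record without sampling-rate metadata is rejected", {
  td <- withr::local_tempdir()
  utils::write.csv(data.frame(I = 1:10, II = 1:10),
                   file.path(td, "nofs.csv"), row.names = FALSE)
  expect_error(load_record(file.path(td, "nofs")), "sidecar")
})

test_that("shuffled lead columns are restored to canonical order", {
  cfg <- tiny_synth(duration = 2)
  rec <- generate_record(cfg, "NSR", seed = 2L)
  perm <- c(7L, 1L, 12L, 3L, 5L, 2L, 4L, 6L, 9L, 8L, 11L, 10L)
  shuffled <- ecg_record(rec$signals[, perm], rec$fs,
                         rec$lead_names[perm], rec$label, "shuf")
  td <- withr::local_tempdir()
  write_record(shuffled, file.path(td, "shuf"), format = "wfdb")
  back <- load_record(file.path(td, "shuf"))
  expect_equal(back$lead_names, rec$lead_names)
  expect_lt(max(abs(back$signals - rec$signals)), 1e-3)
})

test_that("single-label filtering keeps exactly the single-labelled AF/NSR records", {
  mk <- function(lab) ecg_record(matrix(0, 4, 1), 100, "II", lab, "x")
  recs <- list(mk(c("AF", "PVC")), mk("NSR"), mk("AF"), mk("PVC"))
  kept <- select_single_label(recs)
  expect_length(kept, 2L)
  expect_equal(vapply(kept, function(r) r$label, character(1)),
               c("NSR", "AF"))
  expect_length(select_single_label(list()), 0L)
})

test_that("balancing and splitting follow the four-in-five design", {
  mk <- function(lab, i) ecg_record(matrix(0, 4, 1), 100, "II", lab,
                                    paste0(lab, i))
  recs <- c(lapply(1:30, function(i) mk("AF", i)),
            lapply(1:50, function(i) mk("NSR", i)))
  sp <- balance_and_split(recs, prep_config(seed = 1L))
  labs <- function(x) table(vapply(x, function(r) r$label, character(1)))
  expect_equal(unname(labs(sp$train_val)["AF"]), 24)
  expect_equal(unname(labs(sp$train_val)["NSR"]), 24)
  expect_equal(unname(labs(sp$test)["AF"]), 6)
  expect_equal(unname(labs(sp$test)["NSR"]), 6)
  sp2 <- balance_and_split(recs, prep_config(seed = 1L))
  ids <- function(x) vapply(x, function(r) r$record_id, character(1))
  expect_identical(ids(sp$test), ids(sp2$test))
  expect_error(balance_and_split(recs[1:30], prep_config()), "both classes")
})

test_that("train/test partitions are record-disjoint for many seeds", {
  mk <- function(lab, i) ecg_record(matrix(0, 4, 1), 100, "II", lab,
                                    paste0(lab, i))
  recs <- c(lapply(1:60, function(i) mk("AF", i)),
            lapply(1:60, function(i) mk("NSR", i)))
  for (s in 0:9) {
    sp <- balance_and_split(recs, prep_config(seed = s))
    ids <- function(x) vapply(x, function(r) r$record_id, character(1))
    expect_length(intersect(ids(sp$train_val), ids(sp$test)), 0L)
  }
})

test_that("resampling honours length arithmetic and preserves tones", {
  x <- sin(2 * pi * 5 * seq(0, 10, length.out = 5000 + 1))[-1]
  y <- resample_lead(x, 500, 300)
  expect_length(y, 3000L)
  expect_identical(resample_lead(x, 500, 500), x)
  y2 <- resample_lead(x, 500, 200)
  ref <- sin(2 * pi * 5 * (seq_len(2000) / 200))
  expect_gt(stats::cor(y2, ref), 0.999)
  expect_error(resample_lead(x, -1, 200))
})

test_that("segments are taken from the first sample with exact lengths", {
  x <- seq_len(4000)
  expect_equal(take_segment(x, 200, 5), x[1:1000])
  expect_equal(take_segment(x, 300, 10), x[1:3000])
  expect_equal(take_segment(x, 400, 10), x)
  expect_error(take_segment(x, 500, 10), "too short")
})

test_that("z-score normalization matches the direct formula and guards constants", {
  expect_equal(mean(zscore(c(1, 2, 3))), 0)
  expect_equal(sd(zscore(c(1, 2, 3))), 1)
  expect_equal(zscore(rep(4, 10)), rep(0, 10))
  x <- rnorm(100, 5, 3)
  expect_equal(zscore(x), (x - mean(x)) / sd(x), tolerance = 1e-12)
})

test_that("preparation is idempotent at the target rate", {
  cfg <- tiny_synth(duration = 10)
  rec <- generate_record(cfg, "NSR", seed = 8L)
  pc <- prep_config(target_fs = 250, segment_len = 5)
  seg <- lead_segment(rec, "II", pc)
  expect_length(seg$samples, 1250L)
  again <- zscore(take_segment(resample_lead(seg$samples, 250, 250), 250, 5))
  expect_equal(again, seg$samples, tolerance = 1e-12)
})
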