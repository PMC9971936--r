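test_that("record generation is deterministic and respects the label contract", {
  cfg <- tiny_synth()
  a <- generate_record(cfg, "AF", seed = 5L)
  b <- generate_record(cfg, "AF", seed = 5L)
  expect_identical(a$signals, b$signals)
  expect_equal(nrow(a$signals), round(cfg$fs * cfg$duration))
  expect_equal(ncol(a$signals), cfg$n_leads)
  c <- generate_record(cfg, "AF", seed = 6L)
  expect_false(identical(a$signals, c$signals))
  expect_error(generate_record(cfg, "PVC", seed = 1L), "label")
  expect_error(generate_record(cfg, c("AF", "NSR"), seed = 1L), "label")
})

test_that("config invariants are enforced", {
  expect_error(synth_config(rr_cv_af = 0.02, rr_cv_nsr = 0.03))
  expect_error(synth_config(duration = -1))
  bad_f <- rep(0.1, 12)
  bad_f[3] <- 0.5  # max not on V1
  expect_error(synth_config(f_wave_amp_by_lead = bad_f), "v1_index")
  cfg <- planted_synth_config()
  expect_equal(which.max(cfg$f_wave_amp_by_lead), cfg$v1_index)
  expect_gt(cfg$rr_cv_af, cfg$rr_cv_nsr)
})

test_that("clean NSR records have near-regular RR intervals", {
  cfg <- tiny_synth(noise_sd = 0)
  for (s in 1:5) {
    rec <- generate_record(cfg, "NSR", seed = s)
    rr <- rr_intervals(rec$signals[, "II"], rec$fs)
    expect_gte(length(rr), 8)
    expect_lte(sd(rr) / mean(rr), 2 * cfg$rr_cv_nsr)
  }
})

test_that("AF records have larger RR variability than NSR (Monte Carlo)", {
  cfg <- tiny_synth()
  cvs <- vapply(0:149, function(s) {
    lab <- if (s %% 2 == 0) "AF" else "NSR"
    rec <- generate_record(cfg, lab, seed = 1000L + s)
    rr <- rr_intervals(rec$signals[, "II"], rec$fs)
    if (length(rr) >= 2) sd(rr) / mean(rr) else NA_real_
  }, numeric(1))
  af_cv <- cvs[seq(1, 150, by = 2)]
  nsr_cv <- cvs[seq(2, 150, by = 2)]
  expect_gt(mean(af_cv, na.rm = TRUE), mean(nsr_cv, na.rm = TRUE))
  expect_gt(mean(af_cv, na.rm = TRUE), 2 * mean(nsr_cv, na.rm = TRUE))
})

test_that("datasets are balanced, uniquely labelled and reproducible", {
  cfg <- tiny_synth(duration = 4)
  ds <- generate_dataset(cfg, 5L, seed = 3L)
  expect_length(ds, 10L)
  labs <- vapply(ds, function(r) r$label, character(1))
  expect_equal(sum(labs == "AF"), 5L)
  ids <- vapply(ds, function(r) r$record_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  ds2 <- generate_dataset(cfg, 5L, seed = 3L)
  expect_identical(lapply(ds, `[[`, "signals"), lapply(ds2, `[[`, "signals"))
})

test_that("f-wave band power in AF is dominant on the V1-analog lead", {
  cfg <- tiny_synth(f_wave_amp_cv = 0)
  band_power <- function(x, fs, f0, half = 1) {
    n <- length(x)
    p <- Mod(stats::fft(x - mean(x)))^2
    freqs <- (seq_len(n) - 1) * fs / n
    sum(p[freqs >= f0 - half & freqs <= f0 + half])
  }
  ratio <- vapply(1:40, function(s) {
    rec <- generate_record(cfg, "AF", seed = 500L + s)
    band_power(rec$signals[, "V1"], cfg$fs, cfg$f_wave_freq) /
      band_power(rec$signals[, "I"], cfg$fs, cfg$f_wave_freq)
  }, numeric(1))
  expect_gt(mean(ratio), 1)
  # planted informativeness: the class band-power difference peaks on V1
  diff_by_lead <- sapply(seq_len(cfg$n_leads), function(l) {
    af <- mean(vapply(1:15, function(s) {
      band_power(generate_record(cfg, "AF", seed = 700L + s)$signals[, l],
                 cfg$fs, cfg$f_wave_freq)
    }, numeric(1)))
    nsr <- mean(vapply(1:15, function(s) {
      band_power(generate_record(cfg, "NSR", seed = 800L + s)$signals[, l],
                 cfg$fs, cfg$f_wave_freq)
    }, numeric(1)))
    af - nsr
  })
  expect_equal(which.max(diff_by_lead), cfg$v1_index)
})

test_that("a trivial RR-variability rule separates clean synthetic classes", {
  cfg <- synth_config()
  recs <- generate_dataset(cfg, 100L, seed = 9L)
  pred <- rr_cv_classifier(recs)
  truth <- vapply(recs, function(r) r$label, character(1))
  expect_gt(mean(pred == truth), 0.95)
})

test_that("AF cue dropout is mutually exclusive and changes the signal", {
  cfg <- tiny_synth(af_f_dropout = 1, af_rhythm_dropout = 0,
                    noise_sd = 0, f_wave_amp_cv = 0)
  rec <- generate_record(cfg, "AF", seed = 4L)
  # with all f-waves dropped, V1 loses nearly all of its 6 Hz band power
  band <- function(x) {
    p <- Mod(stats::fft(x - mean(x)))^2
    freqs <- (seq_along(p) - 1) * cfg$fs / length(p)
    sum(p[freqs >= 5 & freqs <= 7])
  }
  cfg_keep <- tiny_synth(af_f_dropout = 0, af_rhythm_dropout = 0,
                         noise_sd = 0, f_wave_amp_cv = 0)
  kept <- generate_record(cfg_keep, "AF", seed = 4L)
  expect_lt(band(rec$signals[, "V1"]), 0.1 * band(kept$signals[, "V1"]))
  cfg2 <- tiny_synth(af_f_dropout = 0, af_rhythm_dropout = 1, noise_sd = 0)
  rec2 <- generate_record(cfg2, "AF", seed = 4L)
  rr <- rr_intervals(rec2$signals[, "II"], cfg2$fs)
  expect_lte(sd(rr) / mean(rr), 2 * cfg2$rr_cv_nsr)
  expect_error(synth_config(af_f_dropout = 0.6, af_rhythm_dropout = 0.6))
})
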