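#' Signal-preparation configuration
#'
#' Controls the record-level preparation applied before recurrence-plot
#' imaging: class balancing, the record-disjoint ("inter-patient")
#' train+validation / test split, band-limited resampling to a target rate,
#' leading-segment extraction and per-segment z-score normalization.
#'
#' @param target_fs target sampling rate in Hz (200, 300 or 500; default
#'   300, the rate at which classification was found to work best).
#' @param segment_len segment length in seconds (5 or 10; default 10).
#' @param test_fraction fraction of records held out as the test set
#'   (default 1/5).
#' @param balance equalize class counts before splitting.
#' @param balance_cap optional maximum records per class after balancing
#'   (default 1200).
#' @param zscore apply per-lead-segment z-score normalization.
#' @param seed integer seed controlling balancing and the split.
#' @return a list of class `prep_config`.
#' @export
prep_config <- function(target_fs = 300, segment_len = 10,
                        test_fraction = 1 / 5, balance = TRUE,
                        balance_cap = 1200L, zscore = TRUE, seed = 1L) {
  stopifnot(target_fs > 0, segment_len > 0,
            test_fraction > 0, test_fraction < 1)
  structure(list(target_fs = target_fs, segment_len = segment_len,
                 test_fraction = test_fraction, balance = balance,
                 balance_cap = balance_cap, zscore = zscore,
                 seed = as.integer(seed)),
            class = "prep_config")
}

#' Keep only records with exactly one allowed rhythm label
#'
#' Multi-labelled records (e.g. AF plus another arrhythmia) are removed so
#' that the classifier is trained on single-labelled AF/NSR data only.
#'
#' @param records list of [ecg_record()]; `label` may be a character vector.
#' @param allowed admissible labels.
#' @return filtered list of records.
#' @export
select_single_label <- function(records, allowed = c("AF", "NSR")) {
  Filter(function(rec) {
    length(rec$label) == 1 && rec$label %in% allowed
  }, records)
}

#' Balance classes and split records into train+validation and test sets
#'
#' Classes are equalized by seeded subsampling to the minority count (or
#' `balance_cap` if smaller), then `test_fraction` of each class is held
#' out. The split is at record level, so the two partitions share no
#' records; with one record per subject this is an inter-patient split.
#'
#' @param records list of single-labelled [ecg_record()].
#' @param cfg a [prep_config()].
#' @return list with elements `train_val` and `test` (lists of records).
#' @export
balance_and_split <- function(records, cfg = prep_config()) {
  labels <- vapply(records, function(r) r$label[1], character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("both classes must be present; got only: ",
         paste(classes, collapse = ", "))
  }
  with_seed(cfg$seed, function() {
    per_class <- lapply(classes, function(cl) which(labels == cl))
    n_keep <- min(lengths(per_class))
    if (cfg$balance && !is.null(cfg$balance_cap)) {
      n_keep <- min(n_keep, cfg$balance_cap)
    }
    train_idx <- integer(0)
    test_idx <- integer(0)
    for (idx in per_class) {
      keep <- if (cfg$balance) sort(sample(idx, n_keep)) else idx
      n_test <- round(length(keep) * cfg$test_fraction)
      te <- sort(sample(keep, n_test))
      test_idx <- c(test_idx, te)
      train_idx <- c(train_idx, setdiff(keep, te))
    }
    list(train_val = records[sort(train_idx)], test = records[sort(test_idx)])
  })
}

#' Band-limited resampling of one lead
#'
#' Zero-phase windowed-sinc resampling: output sample `k` (at time
#' `k / fs_out`) interpolates the input with a symmetric Hann-windowed
#' sinc kernel whose cutoff is the lower of the two Nyquist frequencies,
#' so downsampling is anti-aliased and no group delay is introduced. The
#' signal is reflection-padded at the edges and the output has exactly
#' `round(length(x) * fs_out / fs_in)` samples.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return resampled numeric vector.
#' @export
resample_lead <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(x)
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  r <- fs_out / fs_in
  cutoff <- min(1, r)
  m <- ceiling(8 / cutoff)  # sinc half-width in input samples
  pad <- min(n - 1, m + 2)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  u <- seq_len(n_out) / r + pad  # fractional input positions, padded frame
  base <- floor(u)
  frac <- u - base
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  np <- length(xp)
  for (o in (-m):m) {
    t <- frac - o
    w <- cutoff * sinc(cutoff * t) * (0.5 + 0.5 * cos(pi * t / (m + 1)))
    idx <- base + o
    ok <- idx >= 1 & idx <= np
    y[ok] <- y[ok] + xp[idx[ok]] * w[ok]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  y / wsum
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Extract the leading segment of a trace
#'
#' Returns the first `round(fs * seconds)` samples, i.e. segments are
#' always taken from the first sample of the record.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seconds segment length in seconds.
#' @return numeric vector of length `round(fs * seconds)`.
#' @export
take_segment <- function(x, fs, seconds) {
  n <- round(fs * seconds)
  if (length(x) < n) {
    stop(sprintf("signal too short: %d samples, need %d", length(x), n))
  }
  x[seq_len(n)]
}

#' Z-score normalize a signal
#'
#' Centred and scaled to unit standard deviation; a constant input maps to
#' the zero vector rather than dividing by zero.
#'
#' @param x numeric vector.
#' @return normalized numeric vector.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Build a single lead segment from a record
#'
#' Applies resampling to `cfg$target_fs`, leading-segment extraction of
#' `cfg$segment_len` seconds and (optionally) z-score normalization to one
#' lead of a record.
#'
#' @param record an [ecg_record()].
#' @param lead lead name.
#' @param cfg a [prep_config()].
#' @return a list of class `lead_segment` with fields `samples`, `fs`,
#'   `lead_name`, `label`, `record_id`.
#' @export
lead_segment <- function(record, lead, cfg = prep_config()) {
  idx <- match(lead, record$lead_names)
  if (is.na(idx)) stop("lead not present in record: ", lead)
  if (cfg$target_fs > record$fs) {
    warning(sprintf("upsampling %s from %g to %g Hz adds no information",
                    record$record_id, record$fs, cfg$target_fs))
  }
  x <- resample_lead(record$signals[, idx], record$fs, cfg$target_fs)
  x <- take_segment(x, cfg$target_fs, cfg$segment_len)
  if (cfg$zscore) x <- zscore(x)
  structure(list(samples = x, fs = cfg$target_fs, lead_name = lead,
                 label = record$label[1], record_id = record$record_id),
            class = "lead_segment")
}
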