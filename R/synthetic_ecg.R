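#' Configuration for the synthetic multi-lead ECG generator
#'
#' Builds the parameter set used by [generate_record()] and
#' [generate_dataset()]. The generator emulates the two rhythm classes the
#' detector discriminates: normal sinus rhythm (NSR), with near-regular RR
#' intervals and visible P waves, and atrial fibrillation (AF), with highly
#' irregular RR intervals, absent P waves and a continuous low-amplitude
#' fibrillatory (f-wave) oscillation whose amplitude is largest on a
#' designated V1-analog channel -- the lead on which f-waves are most
#' prominent clinically.
#'
#' Beat morphology is a sum of Gaussian bumps (P, R, S, T) placed at beat
#' times drawn from a truncated log-normal RR model; this is deliberately
#' simpler than a full dynamical ECG model but reproduces the three
#' properties the downstream pipeline relies on: P-wave presence/absence,
#' RR (ir)regularity, and lead-specific f-wave amplitude.
#'
#' @param n_leads number of leads (default 12, standard clinical set).
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds.
#' @param rr_mean_nsr,rr_mean_af mean RR interval in seconds per class.
#' @param rr_cv_nsr,rr_cv_af coefficient of variation of RR intervals per
#'   class; must satisfy `rr_cv_af > rr_cv_nsr`.
#' @param f_wave_freq fibrillatory-wave frequency in Hz (physiological range
#'   4--9 Hz).
#' @param f_wave_amp_by_lead per-lead f-wave amplitude (mV-like units);
#'   its maximum must sit at `v1_index`.
#' @param f_wave_amp_cv per-record log-normal coefficient of variation of
#'   the overall f-wave amplitude, emulating the clinical spread between
#'   coarse and fine fibrillatory waves (0 disables).
#' @param p_wave_amp_by_lead per-lead P-wave amplitude; forced to zero for
#'   AF records at generation time.
#' @param p_wave_amp_cv per-record log-normal coefficient of variation of
#'   the overall P-wave amplitude (NSR records), emulating low-voltage P
#'   waves in some subjects (0 disables).
#' @param qrs_amp_by_lead per-lead R-wave amplitude.
#' @param t_wave_amp_by_lead per-lead T-wave amplitude.
#' @param af_f_dropout probability that an AF record carries no visible
#'   f-waves (fibrillatory waves too fine to see; 0 disables).
#' @param af_rhythm_dropout probability that an AF record keeps an
#'   NSR-like ventricular rhythm (rate-controlled AF; 0 disables). Drawn
#'   mutually exclusively with `af_f_dropout`, so every AF record retains
#'   at least one cue when the two probabilities sum to less than 1.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param v1_index index of the V1-analog lead in `lead_names`.
#' @param lead_names ordered lead labels.
#' @param seed default master seed used by [generate_dataset()].
#' @return a validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(fs = 250, duration = 5)
#' rec <- generate_record(cfg, "AF", seed = 7)
#' dim(rec$signals)
synth_config <- function(n_leads = 12,
                         fs = 500,
                         duration = 10,
                         rr_mean_nsr = 0.8,
                         rr_cv_nsr = 0.03,
                         rr_mean_af = 0.6,
                         rr_cv_af = 0.25,
                         f_wave_freq = 6,
                         f_wave_amp_by_lead = NULL,
                         f_wave_amp_cv = 0.5,
                         p_wave_amp_by_lead = NULL,
                         p_wave_amp_cv = 0,
                         qrs_amp_by_lead = NULL,
                         t_wave_amp_by_lead = NULL,
                         af_f_dropout = 0,
                         af_rhythm_dropout = 0,
                         noise_sd = 0.03,
                         v1_index = 7L,
                         lead_names = NULL,
                         seed = 1L) {
  if (is.null(lead_names)) {
    lead_names <- canonical_leads()[seq_len(n_leads)]
    if (n_leads > 12) {
      lead_names <- c(canonical_leads(), paste0("X", seq_len(n_leads - 12)))
    }
  }
  stopifnot(length(lead_names) == n_leads)
  # physiologically flavoured defaults: P largest on II, f-wave on V1
  if (is.null(f_wave_amp_by_lead)) {
    f_wave_amp_by_lead <- default_lead_profile(
      c(I = 0.02, II = 0.04, III = 0.03, aVR = 0.03, aVL = 0.02, aVF = 0.04,
        V1 = 0.15, V2 = 0.08, V3 = 0.06, V4 = 0.05, V5 = 0.04, V6 = 0.03),
      lead_names, fallback = 0.03)
  }
  if (is.null(p_wave_amp_by_lead)) {
    p_wave_amp_by_lead <- default_lead_profile(
      c(I = 0.05, II = 0.15, III = 0.10, aVR = 0.08, aVL = 0.04, aVF = 0.12,
        V1 = 0.05, V2 = 0.06, V3 = 0.08, V4 = 0.08, V5 = 0.07, V6 = 0.06),
      lead_names, fallback = 0.06)
  }
  if (is.null(qrs_amp_by_lead)) {
    qrs_amp_by_lead <- default_lead_profile(
      c(I = 0.6, II = 1.1, III = 0.5, aVR = 0.5, aVL = 0.3, aVF = 0.8,
        V1 = 0.4, V2 = 0.7, V3 = 1.0, V4 = 1.2, V5 = 1.0, V6 = 0.8),
      lead_names, fallback = 0.7)
  }
  if (is.null(t_wave_amp_by_lead)) t_wave_amp_by_lead <- 0.3 * qrs_amp_by_lead

  cfg <- structure(list(
    n_leads = as.integer(n_leads), fs = fs, duration = duration,
    rr_mean_nsr = rr_mean_nsr, rr_cv_nsr = rr_cv_nsr,
    rr_mean_af = rr_mean_af, rr_cv_af = rr_cv_af,
    f_wave_freq = f_wave_freq,
    f_wave_amp_by_lead = unname(f_wave_amp_by_lead),
    f_wave_amp_cv = f_wave_amp_cv,
    p_wave_amp_by_lead = unname(p_wave_amp_by_lead),
    p_wave_amp_cv = p_wave_amp_cv,
    qrs_amp_by_lead = unname(qrs_amp_by_lead),
    t_wave_amp_by_lead = unname(t_wave_amp_by_lead),
    af_f_dropout = af_f_dropout, af_rhythm_dropout = af_rhythm_dropout,
    noise_sd = noise_sd, v1_index = as.integer(v1_index),
    lead_names = lead_names, seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

canonical_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

default_lead_profile <- function(named, lead_names, fallback) {
  out <- named[lead_names]
  out[is.na(out)] <- fallback
  unname(out)
}

validate_synth_config <- function(cfg) {
  stopifnot(
    cfg$n_leads >= 1,
    cfg$fs > 0, cfg$duration > 0,
    cfg$rr_mean_nsr > 0, cfg$rr_mean_af > 0,
    cfg$rr_cv_nsr > 0, cfg$rr_cv_af > cfg$rr_cv_nsr,
    cfg$f_wave_freq > 0,
    cfg$f_wave_amp_cv >= 0, cfg$p_wave_amp_cv >= 0,
    cfg$af_f_dropout >= 0, cfg$af_rhythm_dropout >= 0,
    cfg$af_f_dropout + cfg$af_rhythm_dropout <= 1,
    cfg$noise_sd >= 0,
    cfg$v1_index >= 1, cfg$v1_index <= cfg$n_leads,
    length(cfg$f_wave_amp_by_lead) == cfg$n_leads,
    length(cfg$p_wave_amp_by_lead) == cfg$n_leads,
    length(cfg$qrs_amp_by_lead) == cfg$n_leads,
    length(cfg$t_wave_amp_by_lead) == cfg$n_leads,
    all(cfg$f_wave_amp_by_lead >= 0), all(cfg$p_wave_amp_by_lead >= 0),
    all(cfg$qrs_amp_by_lead >= 0),
    max(cfg$f_wave_amp_by_lead) > 0, max(cfg$qrs_amp_by_lead) > 0
  )
  if (which.max(cfg$f_wave_amp_by_lead) != cfg$v1_index) {
    stop("f_wave_amp_by_lead must attain its maximum at v1_index ",
         "(the V1-analog lead)")
  }
  invisible(cfg)
}

#' Construct an ECG record container
#'
#' @param signals numeric matrix, one column per lead (mV-like units).
#' @param fs sampling rate in Hz.
#' @param lead_names character vector, one name per column.
#' @param label rhythm label, `"AF"` or `"NSR"` (or a character vector of
#'   labels for multi-labelled source data).
#' @param record_id identifier string.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, lead_names, label, record_id) {
  signals <- as.matrix(signals)
  stopifnot(fs > 0, ncol(signals) == length(lead_names))
  colnames(signals) <- lead_names
  structure(list(signals = signals, fs = fs, lead_names = lead_names,
                 label = label, record_id = record_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s>  %d leads x %d samples @ %g Hz  label: %s\n",
              x$record_id, ncol(x$signals), nrow(x$signals), x$fs,
              paste(x$label, collapse = "+")))
  invisible(x)
}

# run fn with a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

# log-normal RR draws with target mean/cv, clamped to a physiological window
draw_rr <- function(n, mean_rr, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_rr) - sdlog^2 / 2
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), 0.3), 2.0)
}

#' Generate one synthetic ECG record
#'
#' Deterministic for a fixed `(cfg, label, seed)` triple. NSR records carry
#' P-QRS-T complexes at near-regular RR intervals; AF records draw RR
#' intervals with the larger coefficient of variation `rr_cv_af`, zero the
#' P-wave amplitude on every lead, and superimpose a continuous
#' amplitude-modulated oscillation at `f_wave_freq` weighted by
#' `f_wave_amp_by_lead` (maximal on the V1-analog lead).
#'
#' @param cfg a [synth_config()].
#' @param label `"AF"` or `"NSR"`.
#' @param seed integer seed for this record.
#' @return an [ecg_record()].
#' @export
generate_record <- function(cfg, label, seed) {
  validate_synth_config(cfg)
  if (!is.character(label) || length(label) != 1 ||
      !label %in% c("AF", "NSR")) {
    stop("label must be \"AF\" or \"NSR\"")
  }
  with_seed(seed, function() {
    n <- round(cfg$fs * cfg$duration)
    tt <- (seq_len(n) - 1) / cfg$fs
    af <- label == "AF"
    # mutually exclusive cue dropout for AF records: a record either loses
    # its f-waves, or keeps a normal ventricular rhythm, or (usually) both
    # cues are present
    u <- if (af) stats::runif(1) else 1
    drop_f <- af && u < cfg$af_f_dropout
    drop_rhythm <- af && !drop_f &&
      u < cfg$af_f_dropout + cfg$af_rhythm_dropout
    rr_mean <- if (af && !drop_rhythm) cfg$rr_mean_af else cfg$rr_mean_nsr
    rr_cv <- if (af && !drop_rhythm) cfg$rr_cv_af else cfg$rr_cv_nsr
    n_beats <- ceiling((cfg$duration + 2) / 0.3)
    rr <- draw_rr(n_beats, rr_mean, rr_cv)
    r_times <- stats::runif(1, 0.15, 0.15 + rr_mean) + cumsum(c(0, rr))
    r_times <- r_times[r_times < cfg$duration + 0.5]

    # unit-amplitude component shapes shared by all leads
    p_sh <- beat_shape(tt, r_times - 0.17, 0.022)
    r_sh <- beat_shape(tt, r_times, 0.012)
    s_sh <- beat_shape(tt, r_times + 0.028, 0.010)
    t_sh <- beat_shape(tt, r_times + 0.30, 0.055)

    p_scale <- if (!af && cfg$p_wave_amp_cv > 0) {
      sdl <- sqrt(log(1 + cfg$p_wave_amp_cv^2))
      stats::rlnorm(1, -sdl^2 / 2, sdl)
    } else 1
    p_amp <- if (af) rep(0, cfg$n_leads) else p_scale * cfg$p_wave_amp_by_lead
    amp <- rbind(p_amp, cfg$qrs_amp_by_lead, -0.25 * cfg$qrs_amp_by_lead,
                 cfg$t_wave_amp_by_lead)
    signals <- cbind(p_sh, r_sh, s_sh, t_sh) %*% amp

    if (af && !drop_f) {
      phi <- stats::runif(2, 0, 2 * pi)
      amp_scale <- if (cfg$f_wave_amp_cv > 0) {
        sdl <- sqrt(log(1 + cfg$f_wave_amp_cv^2))
        stats::rlnorm(1, -sdl^2 / 2, sdl)
      } else 1
      fw <- sin(2 * pi * cfg$f_wave_freq * tt + phi[1]) *
        (1 + 0.3 * sin(2 * pi * 0.33 * tt + phi[2]))
      signals <- signals + outer(fw, amp_scale * cfg$f_wave_amp_by_lead)
    }
    if (cfg$noise_sd > 0) {
      signals <- signals +
        matrix(stats::rnorm(n * cfg$n_leads, 0, cfg$noise_sd), n, cfg$n_leads)
    }
    ecg_record(signals, cfg$fs, cfg$lead_names, label,
               sprintf("%s_s%d", label, as.integer(seed %% 1e9)))
  })
}

# sum of unit Gaussians centred at each beat time (vectorized over beats)
beat_shape <- function(tt, centers, width) {
  out <- numeric(length(tt))
  for (cen in centers) {
    idx <- which(abs(tt - cen) < 5 * width)
    if (length(idx)) out[idx] <- out[idx] + exp(-(tt[idx] - cen)^2 / (2 * width^2))
  }
  out
}

# deterministic per-record seed derived from a master seed (32-bit safe)
derive_seed <- function(master, index) {
  as.integer((as.double(master %% 65536L) * 30269 +
                as.double(index) * 30307 + 11213) %% 2147483587)
}

#' Generate a balanced labelled dataset of synthetic ECG records
#'
#' Produces exactly `n_per_class` AF and `n_per_class` NSR records with
#' unique ids; per-record seeds are derived deterministically from the
#' master `seed`, so datasets of any size are reproducible.
#'
#' @param cfg a [synth_config()].
#' @param n_per_class records per rhythm class.
#' @param seed master seed (defaults to `cfg$seed`).
#' @return list of [ecg_record()] objects, AF and NSR interleaved.
#' @export
generate_dataset <- function(cfg, n_per_class, seed = cfg$seed) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("AF", "NSR"), n_per_class)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    rec <- generate_record(cfg, labels[i], derive_seed(seed, i))
    rec$record_id <- sprintf("%s_%03d", labels[i], (i + 1L) %/% 2L)
    out[[i]] <- rec
  }
  out
}

#' Detect R peaks in a single-lead ECG trace
#'
#' Simple amplitude-greedy peak picking: local maxima above
#' `threshold_frac` of the global maximum are accepted in decreasing
#' amplitude order subject to a refractory period of `min_rr` seconds.
#' Intended for clean or lightly noisy (synthetic) traces.
#'
#' @param x numeric vector, one lead.
#' @param fs sampling rate in Hz.
#' @param min_rr minimum admissible RR interval in seconds.
#' @param threshold_frac amplitude threshold as a fraction of `max(x)`.
#' @return integer vector of peak sample indices, sorted.
#' @export
detect_r_peaks <- function(x, fs, min_rr = 0.25, threshold_frac = 0.5) {
  n <- length(x)
  stopifnot(n > 2, fs > 0)
  thr <- threshold_frac * max(x)
  cand <- which(x >= thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] > x[cand + 1]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- min_rr * fs
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

#' RR intervals of a trace, in seconds
#' @inheritParams detect_r_peaks
#' @return numeric vector of successive RR intervals.
#' @export
rr_intervals <- function(x, fs, min_rr = 0.25, threshold_frac = 0.5) {
  diff(detect_r_peaks(x, fs, min_rr, threshold_frac)) / fs
}

#' Baseline AF classifier from RR-interval variability
#'
#' Labels a record AF when the coefficient of variation of its detected RR
#' intervals on one lead exceeds `threshold`. This deliberately trivial
#' rule serves as a sanity baseline: the synthetic classes must be
#' separable by RR variability alone for the imaging/CNN pipeline to have
#' anything to learn.
#'
#' @param records list of [ecg_record()].
#' @param lead lead name to analyse (default `"II"`).
#' @param threshold RR coefficient-of-variation decision threshold.
#' @return character vector of predicted labels.
#' @export
rr_cv_classifier <- function(records, lead = "II", threshold = 0.1) {
  vapply(records, function(rec) {
    idx <- match(lead, rec$lead_names)
    if (is.na(idx)) idx <- 1L
    rr <- rr_intervals(rec$signals[, idx], rec$fs)
    cv <- if (length(rr) >= 2 && mean(rr) > 0) stats::sd(rr) / mean(rr) else Inf
    if (is.finite(cv) && cv > threshold) "AF" else "NSR"
  }, character(1))
}

#' Planted-informativeness configuration for lead-selection validation
#'
#' Builds a [synth_config()] in which class information is confined to two
#' known leads, giving the stepwise lead search a recoverable ground
#' truth: fibrillatory waves appear only on the V1-analog lead (AF
#' records), QRS complexes -- and therefore all RR-rhythm information --
#' appear only on the rhythm lead (lead II analog), P waves are disabled
#' everywhere, and every other lead is measurement noise. Noise and
#' amplitude levels are set so that each informative lead alone is a good
#' but imperfect classifier and the pair is close to perfect.
#'
#' @param n_leads number of leads (default 12).
#' @param fs sampling rate in Hz (default 300).
#' @param duration seconds (default 10).
#' @param f_lead_index lead carrying f-waves (default 7, V1).
#' @param rhythm_lead_index lead carrying QRS rhythm (default 2, II).
#' @param f_amp f-wave amplitude on the f-wave lead.
#' @param qrs_amp R-wave amplitude on the rhythm lead.
#' @param noise_sd white-noise level on every lead.
#' @param ... further overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
planted_synth_config <- function(n_leads = 12, fs = 300, duration = 10,
                                 f_lead_index = 7L, rhythm_lead_index = 2L,
                                 f_amp = 0.35, qrs_amp = 2.0, p_amp = 0.3,
                                 noise_sd = 0.12, f_wave_amp_cv = 1.0,
                                 p_wave_amp_cv = 1.0,
                                 af_f_dropout = 0,
                                 af_rhythm_dropout = 0.2, ...) {
  zero <- rep(0, n_leads)
  f_wave <- zero
  f_wave[f_lead_index] <- f_amp
  qrs <- zero
  qrs[rhythm_lead_index] <- qrs_amp
  pw <- zero
  pw[rhythm_lead_index] <- p_amp
  synth_config(n_leads = n_leads, fs = fs, duration = duration,
               rr_mean_af = 0.5, f_wave_amp_by_lead = f_wave,
               f_wave_amp_cv = f_wave_amp_cv, p_wave_amp_by_lead = pw,
               p_wave_amp_cv = p_wave_amp_cv,
               qrs_amp_by_lead = qrs, t_wave_amp_by_lead = 0 * qrs,
               af_f_dropout = af_f_dropout,
               af_rhythm_dropout = af_rhythm_dropout,
               noise_sd = noise_sd, v1_index = f_lead_index, ...)
}
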