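# shared fixtures, built in code and memoised for the test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# small, fast generator config used where the clinical defaults are
# unnecessarily expensive (lower rate, shorter records)
tiny_synth <- function(duration = 10, ...) {
  synth_config(fs = 250, duration = duration, ...)
}

# a 20-record default-condition dataset at native 500 Hz
default_records <- function() {
  memo("default_records", function() {
    generate_dataset(synth_config(), n_per_class = 10L, seed = 42L)
  })
}

# deterministic pseudo-RP dataset: images whose pixels encode the label on
# chosen "informative" leads, so search mechanics can be tested with a
# cheap linear factory and no ECG simulation at all
coded_rp_dataset <- function(n_per_class = 12L, leads = c("A", "B", "C", "D"),
                             informative = "A", split_half = NULL,
                             size = 8L, noise = 0.05, seed = 7L) {
  labels <- rep(c("AF", "NSR"), n_per_class)
  rpafnet:::with_seed(seed, function() {
    images <- lapply(seq_along(labels), function(i) {
      per_lead <- lapply(leads, function(ld) {
        base <- 0.5
        if (ld %in% informative) {
          base <- if (labels[i] == "AF") 0.8 else 0.2
        }
        if (!is.null(split_half) && ld %in% names(split_half)) {
          # informative only for half of the AF/NSR record pairs, so the
          # informative half contains both labels
          grp <- split_half[[ld]]
          pair <- (i + 1L) %/% 2L
          in_grp <- (pair %% 2L == 0L) == (grp == "even")
          if (in_grp) base <- if (labels[i] == "AF") 0.8 else 0.2
        }
        array(base + stats::rnorm(size * size * 3, 0, noise),
              c(size, size, 3))
      })
      names(per_lead) <- leads
      per_lead
    })
    structure(list(images = images, labels = labels,
                   record_ids = sprintf("r%03d", seq_along(labels)),
                   leads = leads, size = size),
              class = "rp_dataset")
  })
}

# internal helper access
pkg <- asNamespace("rpafnet")
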