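#' Write an ECG record to disk
#'
#' Two dialects are supported:
#' * `"csv"`: `<path>.csv` with a header row of lead names, one column per
#'   lead, plus a JSON sidecar `<path>.json` holding `fs`, `label` and
#'   `record_id`.
#' * `"wfdb"`: a minimal WFDB pair `<path>.hea` / `<path>.dat` (format 16,
#'   16-bit little-endian interleaved samples, fixed gain), with the label
#'   stored as a `# label:` header comment.
#'
#' @param record an [ecg_record()].
#' @param path output path without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @param gain integer ADC units per signal unit for the WFDB dialect.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb"),
                         gain = 1000L) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(record$signals),
                     paste0(path, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(fs = record$fs, label = as.list(record$label),
           record_id = record$record_id),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    write_wfdb(record, path, gain)
  }
  invisible(path)
}

write_wfdb <- function(record, path, gain = 1000L) {
  sig <- record$signals
  n <- nrow(sig)
  name <- basename(path)
  adc <- round(sig * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- c(
    sprintf("%s %d %g %d", name, ncol(sig), record$fs, n),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
            name, gain, as.integer(adc[1, ]), record$lead_names),
    sprintf("# label: %s", paste(record$label, collapse = ",")),
    sprintf("# record_id: %s", record$record_id)
  )
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # format 16: sample-major interleave, 16-bit little-endian
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(path)
}

read_wfdb <- function(path) {
  hea <- readLines(paste0(path, ".hea"))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  if (is.na(fs) || fs <= 0) stop("WFDB header missing sampling rate: ", path)
  sig_lines <- hea[2:(1 + n_sig)]
  fields <- strsplit(trimws(sig_lines), "\\s+")
  fmt <- vapply(fields, `[`, character(1), 2)
  if (!all(startsWith(fmt, "16"))) {
    stop("only WFDB format 16 is supported (got ", fmt[1], ")")
  }
  gains <- vapply(fields, function(f) {
    as.numeric(sub("\\(.*$", "", sub("/.*$", "", f[3])))
  }, numeric(1))
  gains[!is.finite(gains) | gains == 0] <- 200  # WFDB default gain
  leads <- vapply(fields, function(f) f[length(f)], character(1))
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n * n_sig, size = 2L, signed = TRUE,
                 endian = "little")
  adc <- matrix(raw, nrow = n_sig)  # sample-major interleave
  signals <- sweep(t(adc), 2, gains, "/")
  comments <- hea[startsWith(trimws(hea), "#")]
  label <- parse_hea_comment(comments, "label")
  label <- if (is.na(label)) character(0) else strsplit(label, ",")[[1]]
  rid <- parse_hea_comment(comments, "record_id")
  if (is.na(rid)) rid <- basename(path)
  ecg_record(signals, fs, leads, trimws(label), rid)
}

parse_hea_comment <- function(comments, key) {
  hit <- grep(paste0("^#\\s*", key, ":"), comments, value = TRUE)
  if (!length(hit)) return(NA_character_)
  trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
}

#' Load an ECG record from disk
#'
#' Accepts either a WFDB header path (`.hea`, with its `.dat` companion) or
#' a CSV path (`.csv`, with its `.json` sidecar carrying the sampling
#' rate); the extension may be omitted, in which case WFDB is preferred if
#' both exist. Leads are reordered to the canonical clinical order
#' I, II, III, aVR, aVL, aVF, V1--V6 whenever all names are recognisable.
#'
#' @param path record path, with or without extension.
#' @return an [ecg_record()].
#' @export
load_record <- function(path) {
  stem <- sub("\\.(hea|dat|csv|json)$", "", path)
  rec <- if (file.exists(paste0(stem, ".hea"))) {
    read_wfdb(stem)
  } else if (file.exists(paste0(stem, ".csv"))) {
    sidecar <- paste0(stem, ".json")
    if (!file.exists(sidecar)) {
      stop("CSV record has no JSON sidecar with sampling-rate metadata: ",
           sidecar)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
      stop("sidecar metadata missing a positive fs: ", sidecar)
    }
    df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
    ecg_record(as.matrix(df), meta$fs, colnames(df),
               unlist(meta$label),
               if (is.null(meta$record_id)) basename(stem) else meta$record_id)
  } else {
    stop("no WFDB (.hea) or CSV record found at: ", stem)
  }
  canonicalize_leads(rec)
}

# reorder columns into clinical lead order when every name is recognised
canonicalize_leads <- function(rec) {
  ord <- match(canonical_leads(), rec$lead_names)
  ord <- ord[!is.na(ord)]
  if (length(ord) == length(rec$lead_names)) {
    rec$signals <- rec$signals[, ord, drop = FALSE]
    rec$lead_names <- rec$lead_names[ord]
  }
  rec
}
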