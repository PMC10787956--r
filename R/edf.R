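# Minimal EDF (European Data Format) reader and writer: 256-byte fixed
# header + 256 bytes per signal, then 16-bit little-endian samples grouped
# into fixed-duration data records. Physical values are mapped linearly
# onto the digital range -32768..32767.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width)
}

# render a numeric header value into <= 8 ASCII characters
.edf_fmt_num <- function(v) {
  for (digits in 7:1) {
    s <- formatC(v, digits = digits, format = "g", width = 0)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", v, " into an 8-character EDF field", call. = FALSE)
}

.edf_num <- function(raw, field) {
  x <- suppressWarnings(as.numeric(trimws(raw)))
  if (is.na(x)) {
    stop("malformed EDF header: field '", field, "' is not numeric (got \"",
         trimws(raw), "\")", call. = FALSE)
  }
  x
}

new_psg_recording <- function(subject_id, channels, fs, units) {
  structure(list(subject_id = subject_id, channels = channels, fs = fs,
                 units = units), class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", x$subject_id, ": ", length(x$channels),
      " channel(s)\n", sep = "")
  for (ch in names(x$channels)) {
    cat(sprintf("  %-8s %8d samples @ %g Hz [%s]\n", ch,
                length(x$channels[[ch]]), x$fs[[ch]], x$units[[ch]]))
  }
  invisible(x)
}

#' Write a recording to an EDF file
#'
#' All channels must span the same duration in whole seconds; channels may
#' have different sampling rates. The header timestamp is a fixed constant
#' so identically-specified cohorts produce byte-identical files.
#'
#' @param rec A `psg_recording` (named channel list + per-channel `fs` and
#'   `units`).
#' @param path Output path.
#' @param phys_range Length-2 physical range (signal units) mapped onto
#'   the full 16-bit digital range; values outside are clipped.
#' @param record_duration Data-record length in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range, record_duration = 1) {
  stopifnot(inherits(rec, "psg_recording"), length(phys_range) == 2L,
            phys_range[1] < phys_range[2])
  labels <- names(rec$channels)
  ns <- length(labels)
  spr <- vapply(labels, function(ch) {
    v <- rec$fs[[ch]] * record_duration
    if (abs(v - round(v)) > 1e-9) {
      stop("fs * record_duration must be integral for channel ", ch,
           call. = FALSE)
    }
    as.integer(round(v))
  }, integer(1))
  durations <- vapply(labels, function(ch) {
    length(rec$channels[[ch]]) / rec$fs[[ch]]
  }, numeric(1))
  if (max(durations) - min(durations) > 1e-9) {
    stop("all channels must span the same duration", call. = FALSE)
  }
  n_rec <- durations[1] / record_duration
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("signal duration must be a whole number of data records",
         call. = FALSE)
  }
  n_rec <- as.integer(round(n_rec))

  # round the physical range to what fits the 8-char header fields and
  # quantise against the rounded values so file and scaling agree
  pr_str <- vapply(phys_range, .edf_fmt_num, character(1))
  phys_range <- as.numeric(pr_str)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad(rec$subject_id, 80), .edf_pad("remband", 80),
    .edf_pad("01.01.85", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256L * (ns + 1L), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(format(record_duration), 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(labels, 16)
  field(rep("synthetic EEG", ns), 80)
  field(vapply(labels, function(ch) rec$units[[ch]], character(1)), 8)
  field(rep(pr_str[1], ns), 8)
  field(rep(pr_str[2], ns), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(spr, 8)
  field(rep("", ns), 32)

  scale <- (phys_range[2] - phys_range[1]) / 65535
  dig <- lapply(labels, function(ch) {
    d <- round((rec$channels[[ch]] - phys_range[1]) / scale) - 32768
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  names(dig) <- labels
  for (r in seq_len(n_rec)) {
    for (i in seq_along(labels)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[labels[i]]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the header, validates the field values and the file length
#' against the declared record structure, and returns every signal scaled
#' to physical units. Channels keep their own sampling rates; nothing is
#' resampled.
#'
#' @param path Path to an EDF file.
#' @param subject_id Subject identifier; defaults to the patient-id header
#'   field.
#' @return A `psg_recording`.
#' @export
read_recording <- function(path, subject_id = NULL) {
  if (!file.exists(path)) {
    stop("EDF file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256) {
    stop("malformed EDF: file shorter than the 256-byte fixed header",
         call. = FALSE)
  }
  fld <- function(from, len) substr(fixed, from, from + len - 1L)
  patient <- trimws(fld(9, 80))
  header_bytes <- .edf_num(fld(185, 8), "header bytes")
  n_rec <- .edf_num(fld(237, 8), "number of data records")
  rec_dur <- .edf_num(fld(245, 8), "record duration")
  ns <- .edf_num(fld(253, 4), "number of signals")
  if (ns < 1 || ns != round(ns)) {
    stop("malformed EDF: field 'number of signals' invalid (", ns, ")",
         call. = FALSE)
  }
  ns <- as.integer(ns)
  if (header_bytes != 256 * (ns + 1)) {
    stop("malformed EDF: field 'header bytes' (", header_bytes,
         ") inconsistent with ", ns, " signals", call. = FALSE)
  }
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256L * ns) {
    stop("malformed EDF: truncated signal header", call. = FALSE)
  }
  svec <- function(offset, width, field, numeric = TRUE) {
    vals <- vapply(seq_len(ns), function(i) {
      substr(sig_hdr, offset * ns + (i - 1L) * width + 1L,
             offset * ns + i * width)
    }, character(1))
    if (numeric) vapply(vals, .edf_num, numeric(1), field = field)
    else trimws(vals)
  }
  labels <- svec(0, 16, "label", numeric = FALSE)
  units <- svec(96, 8, "dimension", numeric = FALSE)
  phys_min <- svec(104, 8, "physical minimum")
  phys_max <- svec(112, 8, "physical maximum")
  dig_min <- svec(120, 8, "digital minimum")
  dig_max <- svec(128, 8, "digital maximum")
  spr <- svec(216, 8, "samples per record")
  if (any(phys_max <= phys_min)) {
    stop("malformed EDF: field 'physical maximum' not above 'physical ",
         "minimum'", call. = FALSE)
  }
  if (any(dig_max <= dig_min)) {
    stop("malformed EDF: field 'digital maximum' not above 'digital ",
         "minimum'", call. = FALSE)
  }
  if (any(spr < 1 | spr != round(spr))) {
    stop("malformed EDF: field 'samples per record' invalid", call. = FALSE)
  }
  spr <- as.integer(spr)
  rec_size <- sum(spr)
  expected <- header_bytes + n_rec * rec_size * 2
  actual <- file.size(path)
  if (actual != expected) {
    stop("truncated or inconsistent EDF: expected ", expected,
         " bytes for ", n_rec, " records, found ", actual, call. = FALSE)
  }
  raw <- readBin(con, "integer", n = n_rec * rec_size, size = 2L,
                 signed = TRUE, endian = "little")
  channels <- stats::setNames(vector("list", ns), labels)
  offsets <- c(0L, cumsum(spr))
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_rec) - 1L) * rec_size, `+`))
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    channels[[i]] <- phys_min[i] + (raw[idx] - dig_min[i]) * scale
  }
  new_psg_recording(
    subject_id = if (is.null(subject_id)) patient else subject_id,
    channels = channels,
    fs = stats::setNames(spr / rec_dur, labels),
    units = stats::setNames(units, labels))
}
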