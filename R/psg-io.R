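# Hypnogram parsing and REM epoch extraction / accounting.
#
# Hypnogram dialect: UTF-8 text, one annotation per line,
# whitespace-separated `STAGE ONSET_SECONDS DURATION_SECONDS`, `#` starts
# a comment. Stages: W, S1, S2, S3, S4, REM, MT. Onsets are seconds from
# recording start; intervals are half-open [onset, onset + duration).

.sleep_stages <- c("W", "S1", "S2", "S3", "S4", "REM", "MT")

#' Read a hypnogram annotation file
#'
#' @param path Path to a hypnogram text file (dialect above).
#' @return Tibble with columns `stage`, `onset`, `duration`, ordered by
#'   onset; empty files yield an empty (valid) hypnogram.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  entries <- lapply(keep, function(i) {
    parts <- strsplit(stripped[i], "\\s+")[[1]]
    if (length(parts) != 3L) {
      stop("hypnogram line ", i, ": expected 'STAGE ONSET DURATION', got \"",
           lines[i], "\"", call. = FALSE)
    }
    if (!parts[1] %in% .sleep_stages) {
      stop("hypnogram line ", i, ": unknown stage code \"", parts[1], "\"",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[2:3]))
    if (anyNA(vals)) {
      stop("hypnogram line ", i, ": non-numeric onset or duration",
           call. = FALSE)
    }
    tibble::tibble(stage = parts[1], onset = vals[1], duration = vals[2])
  })
  hyp <- if (length(entries)) dplyr::bind_rows(entries) else
    tibble::tibble(stage = character(), onset = numeric(),
                   duration = numeric())
  validate_hypnogram(hyp)
}

#' Validate a hypnogram table
#'
#' Checks stage codes, positive durations, non-decreasing onsets and
#' non-overlapping entries.
#'
#' @param hyp Tibble with `stage`, `onset`, `duration`.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_hypnogram <- function(hyp) {
  stopifnot(all(c("stage", "onset", "duration") %in% names(hyp)))
  if (nrow(hyp) == 0) return(hyp)
  if (!all(hyp$stage %in% .sleep_stages)) {
    stop("unknown stage code(s): ",
         paste(setdiff(hyp$stage, .sleep_stages), collapse = ", "),
         call. = FALSE)
  }
  if (any(hyp$duration <= 0)) {
    stop("hypnogram durations must be positive", call. = FALSE)
  }
  if (is.unsorted(hyp$onset)) {
    stop("hypnogram onsets must be non-decreasing", call. = FALSE)
  }
  ends <- hyp$onset + hyp$duration
  if (nrow(hyp) > 1 && any(hyp$onset[-1] < ends[-nrow(hyp)] - 1e-9)) {
    stop("hypnogram entries overlap", call. = FALSE)
  }
  hyp
}

#' Write a hypnogram annotation file
#'
#' @param hyp Tibble with `stage`, `onset`, `duration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  validate_hypnogram(hyp)
  writeLines(c("# stage onset_seconds duration_seconds",
               sprintf("%s %s %s", hyp$stage, format(hyp$onset, trim = TRUE),
                       format(hyp$duration, trim = TRUE))), path)
  invisible(path)
}

#' Extract 30-s REM epochs from a recording
#'
#' Merges contiguous REM annotations into maximal REM intervals, tiles
#' each interval into consecutive non-overlapping `epoch_len`-second
#' epochs starting at its onset, and discards any trailing remainder
#' shorter than one epoch. No epoch crosses an annotation boundary.
#'
#' @param rec A `psg_recording` (see [read_recording()]).
#' @param hyp A hypnogram tibble (see [read_hypnogram()]).
#' @param channel Channel label to extract.
#' @param group Group label to attach (e.g. `"healthy"`, `"bruxism"`).
#' @param epoch_len Epoch length in seconds (default 30).
#' @return Tibble of class `rem_epochs` with columns `subject_id`,
#'   `group`, `channel`, `onset`, `fs` and list-column `signal`; each
#'   signal has exactly `round(epoch_len * fs)` samples.
#' @export
extract_rem_epochs <- function(rec, hyp, channel, group,
                               epoch_len = 30) {
  stopifnot(inherits(rec, "psg_recording"))
  validate_hypnogram(hyp)
  if (!channel %in% names(rec$channels)) {
    stop("channel \"", channel, "\" not present; available: ",
         paste(names(rec$channels), collapse = ", "), call. = FALSE)
  }
  fs <- rec$fs[[channel]]
  n_per <- epoch_len * fs
  if (abs(n_per - round(n_per)) > 1e-9) {
    stop("epoch_len * fs must be integral", call. = FALSE)
  }
  n_per <- as.integer(round(n_per))
  x <- rec$channels[[channel]]

  rem <- hyp[hyp$stage == "REM", , drop = FALSE]
  empty <- tibble::tibble(subject_id = character(), group = character(),
                          channel = character(), onset = numeric(),
                          fs = numeric(), signal = list())
  if (nrow(rem) == 0) return(structure(empty, class = c("rem_epochs",
                                                        class(empty))))
  # merge contiguous REM annotations into maximal intervals
  starts <- rem$onset[1]; ends <- rem$onset[1] + rem$duration[1]
  if (nrow(rem) > 1) {
    for (i in 2:nrow(rem)) {
      if (abs(rem$onset[i] - ends[length(ends)]) < 1e-9) {
        ends[length(ends)] <- rem$onset[i] + rem$duration[i]
      } else {
        starts <- c(starts, rem$onset[i])
        ends <- c(ends, rem$onset[i] + rem$duration[i])
      }
    }
  }
  rows <- list()
  for (i in seq_along(starts)) {
    k <- floor((ends[i] - starts[i]) / epoch_len + 1e-9)
    for (e in seq_len(k)) {
      onset <- starts[i] + (e - 1) * epoch_len
      first <- round(onset * fs) + 1
      if (first + n_per - 1 > length(x)) {
        stop("REM annotation at ", onset, " s extends past the end of the ",
             "recording", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = rec$subject_id, group = group, channel = channel,
        onset = onset, fs = fs,
        signal = list(x[first:(first + n_per - 1L)]))
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("rem_epochs", class(out)))
}

#' REM epoch accounting
#'
#' Per-subject epoch counts and total REM seconds, with per-group
#' subtotals and a grand total appended. Accepts either an epoch table
#' from [extract_rem_epochs()] or a pre-tabulated count table with
#' columns `subject_id`, `group`, `epoch_count`.
#'
#' @param x Epoch tibble or count tibble.
#' @param epoch_len Epoch length in seconds (default 30).
#' @return Tibble with columns `subject_id`, `group`, `epoch_count`,
#'   `total_seconds`. Subtotal rows have `subject_id = "total"` and the
#'   group label; the grand-total row has both set to `"total"`.
#' @examples
#' counts <- tibble::tibble(
#'   subject_id = c("brux1", "brux2", "n3"),
#'   group = c("bruxism", "bruxism", "healthy"),
#'   epoch_count = c(67, 209, 188))
#' rem_accounting(counts)
#' @export
rem_accounting <- function(x, epoch_len = 30) {
  if (!"epoch_count" %in% names(x)) {
    stopifnot(all(c("subject_id", "group") %in% names(x)))
    x <- dplyr::count(x, .data$subject_id, .data$group,
                      name = "epoch_count")
  }
  per <- dplyr::mutate(
    dplyr::select(x, "subject_id", "group", "epoch_count"),
    total_seconds = .data$epoch_count * epoch_len)
  sub <- dplyr::summarise(
    dplyr::group_by(per, .data$group),
    subject_id = "total",
    epoch_count = sum(.data$epoch_count),
    total_seconds = sum(.data$total_seconds), .groups = "drop")
  grand <- tibble::tibble(
    subject_id = "total", group = "total",
    epoch_count = sum(per$epoch_count),
    total_seconds = sum(per$total_seconds))
  dplyr::bind_rows(per, dplyr::select(sub, names(per)), grand)
}
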