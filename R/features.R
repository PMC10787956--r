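# The 28-feature vector per REM epoch: 12 time-domain (mean / SD / RMS per
# band), 12 frequency-domain (relative power per band + 4 spectral ratios +
# absolute power per band) and 4 nonlinear (sample entropy per band).

.bands4 <- c("delta", "theta", "alpha", "beta")

#' Canonical feature names
#'
#' The fixed ordering of the 28 per-epoch features: mean, SD and RMS per
#' band (mV), relative band power (percent), the four spectral ratios
#' (theta+alpha)/beta, alpha/delta, alpha/theta, alpha/beta, absolute band
#' power, and sample entropy per band.
#'
#' @return Character vector of length 28.
#' @export
feature_names <- function() {
  c(paste0("mean_", .bands4), paste0("sd_", .bands4), paste0("rms_", .bands4),
    paste0("rpsd_", .bands4),
    "ratio_thetaalpha_beta", "ratio_alpha_delta", "ratio_alpha_theta",
    "ratio_alpha_beta",
    paste0("apsd_", .bands4), paste0("sampen_", .bands4))
}

#' Feature domain lookup
#'
#' @return Tibble mapping each canonical feature name to its domain
#'   (`time`, `frequency`, `nonlinear`) and display label.
#' @export
feature_catalogue <- function() {
  nm <- feature_names()
  sym <- c(delta = "δ", theta = "θ", alpha = "α",
           beta = "β")
  lab <- nm
  for (b in .bands4) {
    lab <- sub(paste0("^mean_", b), paste0("Mean(", sym[b], ")"), lab)
    lab <- sub(paste0("^sd_", b), paste0("SD(", sym[b], ")"), lab)
    lab <- sub(paste0("^rms_", b), paste0("RMS(", sym[b], ")"), lab)
    lab <- sub(paste0("^rpsd_", b), paste0("RPSD(", sym[b], ")"), lab)
    lab <- sub(paste0("^apsd_", b), paste0("APSD(", sym[b], ")"), lab)
    lab <- sub(paste0("^sampen_", b), paste0("SampEn(", sym[b], ")"), lab)
  }
  lab[lab == "ratio_thetaalpha_beta"] <- "(θ+α)/β"
  lab[lab == "ratio_alpha_delta"] <- "α/δ"
  lab[lab == "ratio_alpha_theta"] <- "α/θ"
  lab[lab == "ratio_alpha_beta"] <- "α/β"
  tibble::tibble(
    feature = nm,
    label = lab,
    domain = rep(c("time", "frequency", "nonlinear"), c(12L, 12L, 4L))
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Time-domain features of a band split
#'
#' Arithmetic mean, population standard deviation and root mean square of
#' each band-limited reconstruction.
#'
#' @param bands A `band_signals` object from [dwt_band_split()].
#' @return Named numeric vector of 12 values.
#' @export
time_features <- function(bands) {
  stopifnot(inherits(bands, "band_signals"))
  out <- numeric(0)
  for (stat in c("mean", "sd", "rms")) {
    f <- switch(stat, mean = mean, sd = pop_sd,
                rms = function(x) sqrt(mean(x^2)))
    v <- vapply(.bands4, function(b) f(bands[[b]]), numeric(1))
    names(v) <- paste0(stat, "_", .bands4)
    out <- c(out, v)
  }
  out
}

#' Spectral ratio features
#'
#' The four band-power ratios (theta+alpha)/beta, alpha/delta, alpha/theta
#' and alpha/beta, computed from relative band power (equivalently from
#' absolute power — the common denominator cancels).
#'
#' @param rpsd Named numeric vector of relative band powers (percent).
#' @return Named numeric vector of 4 values.
#' @export
ratio_features <- function(rpsd) {
  stopifnot(all(.bands4 %in% names(rpsd)))
  r <- rpsd[.bands4]
  if (any(r[c("delta", "theta", "beta")] == 0)) {
    stop_degenerate_epoch("zero band power in a ratio denominator")
  }
  c(ratio_thetaalpha_beta = unname((r["theta"] + r["alpha"]) / r["beta"]),
    ratio_alpha_delta = unname(r["alpha"] / r["delta"]),
    ratio_alpha_theta = unname(r["alpha"] / r["theta"]),
    ratio_alpha_beta = unname(r["alpha"] / r["beta"]))
}

#' Sample entropy
#'
#' SampEn(m, r) by the standard template-counting definition: the negative
#' log of the conditional probability that sequences matching for `m`
#' points (Chebyshev distance <= r, self-matches excluded) also match at
#' `m + 1` points. The tolerance is `r_frac` times the series' population
#' standard deviation. Defaults m = 5, r = 0.2 SD.
#'
#' Conventions for edge cases, applied identically by the test oracle: a
#' constant series (SD = 0) returns 0; if no length-m templates match
#' (B = 0) the value is 0; if templates match at m but never at m + 1
#' (A = 0) the value is capped at log(B).
#'
#' @param signal Numeric series of length >= `m_max + 2`.
#' @param m_max Template length m (default 5).
#' @param r_frac Tolerance as a fraction of the series SD (default 0.2).
#' @param all_m If `TRUE`, return SampEn at every template length
#'   1..`m_max` (named vector) instead of only `m_max`.
#' @return Numeric value (or named vector when `all_m = TRUE`).
#' @examples
#' sample_entropy(rep(1, 100))            # 0 by convention
#' sample_entropy(sin(1:200), m_max = 2)
#' @export
sample_entropy <- function(signal, m_max = 5L, r_frac = 0.2, all_m = FALSE) {
  stopifnot(is.numeric(signal), m_max >= 1L, r_frac > 0, r_frac < 1)
  n <- length(signal)
  if (n < m_max + 2L) {
    stop("series of length ", n, " too short for template length ", m_max,
         call. = FALSE)
  }
  sdv <- pop_sd(signal)
  ms <- if (all_m) seq_len(m_max) else m_max
  if (sdv == 0) {
    out <- rep(0, length(ms))
    names(out) <- paste0("m", ms)
    return(if (all_m) out else unname(out))
  }
  r <- r_frac * sdv
  out <- vapply(ms, function(m) {
    ab <- sampen_counts(as.numeric(signal), as.integer(m), r)
    a <- ab[1]; b <- ab[2]
    if (b == 0) 0 else if (a == 0) log(b) else -log(a / b)
  }, numeric(1))
  names(out) <- paste0("m", ms)
  if (all_m) out else unname(out)
}

#' Full 28-feature vector for one epoch signal
#'
#' Runs the band decomposition, Welch band power, ratio and sample-entropy
#' stages on a single epoch and returns the canonical named vector (see
#' [feature_names()]).
#'
#' @param signal Numeric epoch (mV).
#' @param fs Sampling rate (Hz; power of two >= 64).
#' @param sampen_m,sampen_r Sample-entropy template length and tolerance
#'   fraction.
#' @param ... Passed to [welch_psd()].
#' @return Named numeric vector of 28 features.
#' @export
epoch_features <- function(signal, fs, sampen_m = 5L, sampen_r = 0.2, ...) {
  if (pop_sd(signal) == 0) {
    stop_degenerate_epoch("zero-variance signal")
  }
  bands <- dwt_band_split(signal, fs)
  pw <- band_powerset(bands, ...)
  sampen <- vapply(.bands4, function(b) {
    sample_entropy(bands[[b]], m_max = sampen_m, r_frac = sampen_r)
  }, numeric(1))
  names(sampen) <- paste0("sampen_", .bands4)
  apsd <- pw$apsd; names(apsd) <- paste0("apsd_", .bands4)
  rp <- pw$rpsd; names(rp) <- paste0("rpsd_", .bands4)
  out <- c(time_features(bands), rp, ratio_features(pw$rpsd), apsd, sampen)
  out[feature_names()]
}

#' Extract features for a table of REM epochs
#'
#' Maps [epoch_features()] over an epoch table (as produced by
#' [extract_rem_epochs()]). Degenerate epochs (zero variance or zero band
#' power) are excluded, not returned as NA rows; the exclusions, with
#' reasons, are attached as the `"exclusions"` attribute and reported via
#' a message.
#'
#' @param epochs Tibble with columns `subject_id`, `group`, `channel`,
#'   `onset`, `fs` and list-column `signal`.
#' @param ... Passed to [epoch_features()].
#' @return Tibble with the epoch identifiers followed by the 28 feature
#'   columns; attribute `exclusions` holds a tibble of dropped epochs.
#' @export
extract_features <- function(epochs, ...) {
  stopifnot(all(c("subject_id", "group", "channel", "onset", "fs",
                  "signal") %in% names(epochs)))
  res <- purrr::map(seq_len(nrow(epochs)), function(i) {
    tryCatch(
      list(ok = TRUE,
           values = epoch_features(epochs$signal[[i]], epochs$fs[i], ...)),
      remband_degenerate_epoch = function(e) {
        list(ok = FALSE, reason = conditionMessage(e))
      }
    )
  })
  ok <- vapply(res, `[[`, logical(1), "ok")
  meta <- dplyr::select(epochs, "subject_id", "group", "channel", "onset")
  feat <- NULL
  if (any(ok)) {
    feat <- dplyr::bind_cols(
      meta[ok, ],
      tibble::as_tibble(do.call(rbind, lapply(res[ok], `[[`, "values")))
    )
  } else {
    feat <- dplyr::bind_cols(
      meta[0, ],
      tibble::as_tibble(matrix(numeric(0), 0, 28,
                               dimnames = list(NULL, feature_names())))
    )
  }
  excl <- meta[!ok, ]
  excl$reason <- vapply(res[!ok], `[[`, character(1), "reason")
  if (nrow(excl) > 0) {
    message(nrow(excl), " epoch(s) excluded as degenerate")
  }
  attr(feat, "exclusions") <- excl
  feat
}
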