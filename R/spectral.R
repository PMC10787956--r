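# Welch power spectral density and absolute / relative band power.

#' Nominal EEG band edges (Hz)
#'
#' Delta 1–4, theta 4–8, alpha 8–13, beta 13–30 Hz. Band power is always
#' integrated over these nominal ranges, regardless of the dyadic edges of
#' the wavelet split.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
band_edges <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into overlapping
#' segments, each mean-detrended, multiplied by a periodic Hamming window,
#' zero-padded to `nfft` points and Fourier transformed; squared magnitudes
#' are averaged and scaled to a one-sided density (power per Hz), so the
#' integral of the density approximates the signal variance.
#'
#' Defaults follow the study configuration: 128-sample window, 50%
#' overlap, 256 FFT points. A 30-s epoch at 512 Hz gives 239 segments on a
#' 2-Hz grid with 129 one-sided bins.
#'
#' No detrending is applied by default: subtracting each 0.25-s segment's
#' mean would act as a high-pass well into the delta band and strip slow
#' activity (`detrend = "constant"` enables per-segment mean removal for
#' sensitivity analysis).
#'
#' @param signal Numeric series.
#' @param fs Sampling rate (Hz).
#' @param window_len Segment length in samples (default 128).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param nfft FFT length; >= `window_len` (default 256).
#' @param detrend `"none"` (default) or `"constant"` (per-segment mean
#'   removal).
#' @return Object of class `psd_estimate`: list with `freq` (Hz), `density`
#'   (signal units squared per Hz), `fs`, `n_segments` and `params`.
#' @examples
#' psd <- welch_psd(rnorm(15360), fs = 512)
#' psd$n_segments
#' sum(diff(psd$freq) * (head(psd$density, -1) + tail(psd$density, -1)) / 2)
#' @export
welch_psd <- function(signal, fs, window_len = 128L, overlap = 0.5,
                      nfft = 256L, detrend = c("none", "constant")) {
  detrend <- match.arg(detrend)
  stopifnot(is.numeric(signal), fs > 0, nfft >= window_len,
            overlap >= 0, overlap < 1)
  n <- length(signal)
  if (n < window_len) {
    stop("signal (", n, " samples) shorter than the Welch window (",
         window_len, ")", call. = FALSE)
  }
  step <- as.integer(round(window_len * (1 - overlap)))
  nseg <- (n - window_len) %/% step + 1L
  k <- 0:(window_len - 1L)
  win <- 0.54 - 0.46 * cos(2 * pi * k / window_len) # periodic Hamming
  starts <- seq.int(1L, by = step, length.out = nseg)
  seg <- matrix(0, nrow = nfft, ncol = nseg)
  for (j in seq_len(nseg)) {
    s <- signal[starts[j]:(starts[j] + window_len - 1L)]
    if (detrend == "constant") s <- s - mean(s)
    seg[seq_len(window_len), j] <- s * win
  }
  spec <- Mod(stats::mvfft(seg))^2
  pxx <- rowMeans(spec) / (fs * sum(win^2))
  half <- nfft %/% 2L + 1L
  pxx <- pxx[seq_len(half)]
  pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)] # fold onto one side
  structure(
    list(
      freq = (0:(half - 1L)) * fs / nfft,
      density = pxx,
      fs = fs,
      n_segments = nseg,
      params = list(window_len = window_len, overlap = overlap, nfft = nfft,
                    window = "hamming", detrend = detrend)
    ),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat("<psd_estimate> ", length(x$freq), " bins, 0-", max(x$freq),
      " Hz (spacing ", x$freq[2], " Hz), ", x$n_segments, " segments\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.psd_estimate <- function(x, ...) {
  data.frame(freq = x$freq, density = x$density)
}

#' Absolute band power from a PSD estimate
#'
#' Trapezoidal integral of the one-sided density over a frequency band.
#' The density is linearly interpolated at the band edges, so adjacent
#' bands partition the spectrum without double counting.
#'
#' @param psd A [welch_psd()] estimate.
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`) or a
#'   numeric `c(lo, hi)` in Hz.
#' @return Integrated power (signal units squared).
#' @export
band_apsd <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (is.character(band)) {
    band <- band_edges()[[match.arg(band, names(band_edges()))]]
  }
  stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
  lo <- band[1]; hi <- band[2]
  fmax <- max(psd$freq)
  if (lo < 0 || hi > fmax) {
    stop("band [", lo, ", ", hi, "] Hz outside the PSD grid [0, ", fmax,
         "]", call. = FALSE)
  }
  grid <- psd$freq[psd$freq > lo & psd$freq < hi]
  f <- c(lo, grid, hi)
  d <- stats::approx(psd$freq, psd$density, xout = f)$y
  sum(diff(f) * (d[-length(d)] + d[-1]) / 2)
}

#' Relative band power (percent of total 1–30 Hz power)
#'
#' Each band's absolute power divided by the summed power of the four
#' bands, times 100.
#'
#' @param powers Named numeric vector of absolute band powers with names
#'   `delta`, `theta`, `alpha`, `beta`.
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' rpsd(c(delta = 1, theta = 1, alpha = 1, beta = 1))
#' @export
rpsd <- function(powers) {
  bands <- names(band_edges())
  stopifnot(all(bands %in% names(powers)))
  powers <- powers[bands]
  if (any(powers < 0) || anyNA(powers)) {
    stop("band powers must be finite and non-negative", call. = FALSE)
  }
  total <- sum(powers)
  if (total <= 0) {
    stop_degenerate_epoch("zero total band power")
  }
  powers / total * 100
}

#' Per-band absolute and relative power of a band-split epoch
#'
#' Runs [welch_psd()] on each band-reconstructed signal and takes the
#' total power of its spectrum (trapezoidal integral over the full
#' one-sided grid); relative power is then computed across the four
#' bands. Because each input is already band-limited by the wavelet
#' split, its full-spectrum power is its band power; re-integrating over
#' the nominal band edges would instead discard the spectral spread of
#' the short Welch segments (a 128-sample window cannot confine 1–4 Hz
#' power to 1–4 Hz) and bias relative power against the narrow slow
#' bands.
#'
#' @param bands A `band_signals` object from [dwt_band_split()].
#' @param ... Passed to [welch_psd()].
#' @return List with named vectors `apsd` and `rpsd`.
#' @export
band_powerset <- function(bands, ...) {
  stopifnot(inherits(bands, "band_signals"))
  nm <- names(band_edges())
  apsd <- vapply(nm, function(b) {
    psd <- welch_psd(bands[[b]], bands$fs, ...)
    band_apsd(psd, c(0, bands$fs / 2))
  }, numeric(1))
  list(apsd = apsd, rpsd = rpsd(apsd))
}

# condition for epochs that cannot be analysed (zero power etc.)
stop_degenerate_epoch <- function(reason) {
  cond <- structure(
    class = c("remband_degenerate_epoch", "error", "condition"),
    list(message = paste0("degenerate epoch: ", reason), call = NULL)
  )
  stop(cond)
}
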