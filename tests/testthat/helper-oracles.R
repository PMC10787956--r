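# Independent brute-force oracles used to validate the package's core
# statistics. These deliberately share no code with the implementation.

# Sample-entropy template-pair counts by direct O(N^2) enumeration:
# templates x[i..i+m-1], i = 1..N-m; Chebyshev distance <= r.
oracle_sampen_counts <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    js <- (i + 1):nt
    d <- abs(x[i] - x[js])
    if (m > 1) for (k in 1:(m - 1)) d <- pmax(d, abs(x[i + k] - x[js + k]))
    match_m <- d <= r
    B <- B + sum(match_m)
    A <- A + sum(match_m & abs(x[i + m] - x[js + m]) <= r)
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m, r_frac = 0.2) {
  sdv <- sqrt(mean((x - mean(x))^2))
  if (sdv == 0) return(0)
  ab <- oracle_sampen_counts(x, m, r_frac * sdv)
  if (ab["B"] == 0) 0 else if (ab["A"] == 0) log(ab[["B"]]) else
    -log(ab[["A"]] / ab[["B"]])
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n, n1)
# assignments of ranks to the first sample (tie-free data only).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(seq_len(n)[combos], nrow = n1)) -
    n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(U = u_obs, p_value = p)
}

# Exhaustive best first split: all features, all midpoints between
# consecutive distinct sorted values; weighted Gini decrease; any valid
# candidate of an impure node is eligible (even zero decrease); ties
# broken by lowest feature then lowest threshold. Returns NULL for pure
# or unsplittable nodes.
oracle_first_split <- function(X, y01) {
  if (length(unique(y01)) < 2) return(NULL)
  imp <- function(v) {
    if (length(v) == 0) return(0)
    p <- mean(v)
    length(v) * (1 - p^2 - (1 - p)^2)
  }
  best <- NULL
  for (f in seq_len(ncol(X))) {
    cuts <- sort(unique(X[, f]))
    if (length(cuts) < 2) next
    for (i in seq_len(length(cuts) - 1)) {
      thr <- (cuts[i] + cuts[i + 1]) / 2
      left <- X[, f] < thr
      dec <- imp(y01) - imp(y01[left]) - imp(y01[!left])
      # same tie rule as the implementation: within 1e-9 keeps the
      # earlier candidate in (feature, threshold) scan order
      if (is.null(best) || dec > best$decrease + 1e-9) {
        best <- list(feature = f, threshold = thr, decrease = dec)
      }
    }
  }
  best
}

# Total 1-30 Hz power fraction inside a nominal band, measured at high
# spectral resolution (long Welch window) on a raw epoch.
band_power_fraction <- function(x, fs, band) {
  psd <- welch_psd(x, fs, window_len = 1024L, nfft = 2048L)
  band_apsd(psd, band) / band_apsd(psd, c(1, 30))
}

# Small fast cohort for pipeline-level tests: 8-s epochs at 128 Hz,
# uncalibrated two-group profiles with a clear band-power contrast.
tiny_cohort_spec <- function(seed = 1L, epochs = 6L, subjects = 2L,
                             channels = psg_channels(),
                             identical_groups = FALSE) {
  healthy <- band_profile_from_rpsd(
    c(delta = 60, theta = 24, alpha = 9, beta = 7), total_sd = 8)
  bruxism <- if (identical_groups) healthy else band_profile_from_rpsd(
    c(delta = 60, theta = 16, alpha = 13, beta = 11), total_sd = 8)
  cohort_spec(n_subjects_per_group = subjects, epochs_per_subject = epochs,
              epoch_len = 8, fs = 128,
              group_profiles = list(healthy = healthy, bruxism = bruxism),
              channels = channels, seed = seed)
}
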