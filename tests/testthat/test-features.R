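# The 28-feature vector: time-domain statistics, spectral ratios, sample
# entropy, and the assembled per-epoch vector.

make_bands <- function(...) {
  vals <- list(...)
  structure(c(vals, list(residual = numeric(length(vals[[1]])), fs = 128)),
            class = "band_signals")
}

test_that("time features reduce to mean, population SD and RMS per band", {
  b <- make_bands(delta = rep(3, 8), theta = c(3, -3, 3, -3, 3, -3, 3, -3),
                  alpha = rep(0, 8), beta = 1:8)
  tf <- time_features(b)
  expect_length(tf, 12)
  expect_equal(tf[["mean_delta"]], 3)
  expect_equal(tf[["sd_delta"]], 0)
  expect_equal(tf[["rms_delta"]], 3)
  expect_equal(tf[["mean_theta"]], 0)
  expect_equal(tf[["sd_theta"]], 3)
  expect_equal(tf[["rms_theta"]], 3)
  # RMS^2 = SD^2 + Mean^2 on arbitrary data
  set.seed(11)
  b2 <- make_bands(delta = rnorm(100), theta = runif(100),
                   alpha = rnorm(100, 5), beta = rexp(100))
  tf2 <- time_features(b2)
  for (band in c("delta", "theta", "alpha", "beta")) {
    expect_equal(tf2[[paste0("rms_", band)]]^2,
                 tf2[[paste0("sd_", band)]]^2 +
                   tf2[[paste0("mean_", band)]]^2,
                 tolerance = 1e-9)
  }
})

test_that("spectral ratios follow their definitions and reject zero
           denominators", {
  r1 <- ratio_features(c(delta = 25, theta = 25, alpha = 25, beta = 25))
  expect_equal(unname(r1), c(2, 1, 1, 1))
  r2 <- ratio_features(c(delta = 50, theta = 25, alpha = 12.5, beta = 12.5))
  expect_equal(unname(r2), c(3, 0.25, 0.5, 1))
  expect_error(ratio_features(c(delta = 50, theta = 25, alpha = 25,
                                beta = 0)),
               class = "remband_degenerate_epoch")
})

test_that("sample entropy equals the brute-force counting oracle", {
  x_per <- rep(c(1, 2, 3), 20)
  expect_identical(sample_entropy(x_per, m_max = 2),
                   oracle_sampen(x_per, 2))
  set.seed(12)
  u <- runif(500)
  expect_identical(sample_entropy(u, m_max = 5), oracle_sampen(u, 5))
  expect_gt(sample_entropy(u, m_max = 2), sample_entropy(x_per, m_max = 2))
  expect_equal(sample_entropy(rep(7, 60)), 0)
  expect_error(sample_entropy(rnorm(5), m_max = 5), "too short")
  allm <- sample_entropy(u, m_max = 3, all_m = TRUE)
  expect_named(allm, c("m1", "m2", "m3"))
  expect_identical(allm[["m3"]], oracle_sampen(u, 3))
})

test_that("an epoch yields exactly the 28 canonical features", {
  set.seed(13)
  x <- synth_epoch(band_profile(delta = 3, theta = 1.5, alpha = 1,
                                beta = 0.7), 128, 8)
  fv <- epoch_features(x, 128)
  expect_length(fv, 28)
  expect_identical(names(fv), feature_names())
  cat28 <- feature_catalogue()
  expect_equal(as.integer(table(cat28$domain)[c("time", "frequency",
                                                "nonlinear")]),
               c(12L, 12L, 4L))
  expect_error(epoch_features(numeric(1024), 128),
               class = "remband_degenerate_epoch")
})

test_that("a 10 Hz tone is dominated by relative alpha power", {
  t <- seq(0, 8 - 1 / 128, by = 1 / 128)
  fv <- epoch_features(sin(2 * pi * 10 * t), 128)
  rp <- fv[paste0("rpsd_", c("delta", "theta", "alpha", "beta"))]
  expect_equal(names(which.max(rp)), "rpsd_alpha")
})

test_that("feature scaling laws hold under amplitude scaling", {
  set.seed(14)
  x <- synth_epoch(band_profile(delta = 2, theta = 1, alpha = 0.6,
                                beta = 0.5), 128, 8)
  f1 <- epoch_features(x, 128)
  f3 <- epoch_features(3 * x, 128)
  lin <- c(paste0("mean_", c("delta", "theta", "alpha", "beta")),
           paste0("sd_", c("delta", "theta", "alpha", "beta")),
           paste0("rms_", c("delta", "theta", "alpha", "beta")))
  quad <- paste0("apsd_", c("delta", "theta", "alpha", "beta"))
  inv <- c(paste0("rpsd_", c("delta", "theta", "alpha", "beta")),
           "ratio_thetaalpha_beta", "ratio_alpha_delta",
           "ratio_alpha_theta", "ratio_alpha_beta",
           paste0("sampen_", c("delta", "theta", "alpha", "beta")))
  expect_equal(f3[lin], 3 * f1[lin], tolerance = 1e-9)
  expect_equal(f3[quad], 9 * f1[quad], tolerance = 1e-9)
  expect_equal(f3[inv], f1[inv], tolerance = 1e-9)
})

test_that("extract_features drops degenerate epochs with a recorded
           reason", {
  set.seed(15)
  good <- synth_epoch(band_profile(delta = 1, theta = 0.5, alpha = 0.3,
                                   beta = 0.2), 128, 8)
  epochs <- tibble::tibble(
    subject_id = c("s1", "s1"), group = "healthy", channel = "C4P4",
    onset = c(0, 8), fs = 128,
    signal = list(good, numeric(1024)))
  expect_message(feat <- extract_features(epochs), "excluded")
  expect_equal(nrow(feat), 1L)
  excl <- attr(feat, "exclusions")
  expect_equal(nrow(excl), 1L)
  expect_match(excl$reason, "zero-variance")
})
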