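# Synthetic polysomnography generator.

test_that("synth_epoch is seeded-deterministic and honours zero profiles", {
  p <- band_profile(delta = 2, theta = 1, alpha = 0.5, beta = 0.3,
                    drift_amp = 0.2, hf_amp = 0.1)
  a <- synth_epoch(p, 128, 4, seed = 5)
  b <- synth_epoch(p, 128, 4, seed = 5)
  expect_identical(a, b)
  expect_length(a, 512L)
  expect_true(all(synth_epoch(band_profile(), 128, 4) == 0))
  expect_error(synth_epoch(p, 128, -1), "positive")
  expect_error(synth_epoch(p, 128, 0.5), "integer >= 256")
  expect_error(band_profile(delta = -1), ">= 0")
})

test_that("a single-band profile concentrates its power in that band", {
  set.seed(16)
  for (band in c("delta", "theta", "alpha", "beta")) {
    args <- stats::setNames(as.list(rep(0, 4)),
                            c("delta", "theta", "alpha", "beta"))
    args[[band]] <- 1
    x <- synth_epoch(do.call(band_profile, args), 512, 30)
    expect_gte(band_power_fraction(x, 512, band), 0.9)
  }
})

test_that("drift and high-frequency contamination fall outside 1-30 Hz", {
  set.seed(17)
  p <- band_profile(alpha = 1, drift_amp = 3, hf_amp = 3)
  x <- synth_epoch(p, 512, 30)
  psd <- welch_psd(x, 512, window_len = 2048L, nfft = 4096L)
  below <- band_apsd(psd, c(0.05, 1))
  above <- band_apsd(psd, c(30, 256))
  inband <- band_apsd(psd, c(1, 30))
  expect_gt(below, inband)  # 3 mV sinusoid vs 1 mV noise
  expect_gt(above, inband)
  # the band split discards both contaminants
  b <- dwt_band_split(x, 512)
  kept <- stats::var(b$delta + b$theta + b$alpha + b$beta)
  expect_lt(kept, 2 * stats::var(synth_epoch(band_profile(alpha = 1),
                                             512, 30, seed = 1)))
})

test_that("profile targets set the band SDs of the generated components", {
  set.seed(18)
  p <- band_profile(delta = 4, theta = 2, alpha = 1, beta = 0.5)
  x <- synth_epoch(p, 256, 16)
  tot <- sqrt(mean((x - mean(x))^2))
  expect_equal(tot, sqrt(sum(c(4, 2, 1, 0.5)^2)), tolerance = 0.05)
})

test_that("cohorts have the declared shape and are reproducible", {
  spec <- tiny_cohort_spec(seed = 77, epochs = 10, subjects = 2)
  cohort <- generate_cohort(spec)
  expect_length(cohort$recordings, 4L)
  expect_equal(nrow(cohort$manifest), 4L)
  rem_total <- vapply(cohort$hypnograms, function(h) {
    sum(h$duration[h$stage == "REM"])
  }, numeric(1))
  expect_true(all(rem_total == 10 * 8))
  # all five channels present at the cohort rate
  rec <- cohort$recordings[[1]]
  expect_setequal(names(rec$channels), psg_channels())
  expect_true(all(rec$fs == 128))
  # same spec, same draws
  cohort2 <- generate_cohort(tiny_cohort_spec(seed = 77, epochs = 10,
                                              subjects = 2))
  expect_identical(cohort$recordings[[2]]$channels,
                   cohort2$recordings[[2]]$channels)
})

test_that("the epoch extractor recovers exactly the generated REM epochs", {
  spec <- tiny_cohort_spec(seed = 31, epochs = 7)
  cohort <- generate_cohort(spec)
  for (sid in cohort$manifest$subject_id) {
    eps <- extract_rem_epochs(
      cohort$recordings[[sid]], cohort$hypnograms[[sid]],
      channel = "C4P4",
      group = cohort$manifest$group[cohort$manifest$subject_id == sid],
      epoch_len = 8)
    expect_equal(nrow(eps), 7L)
    expect_true(all(lengths(eps$signal) == 8 * 128))
  }
})

test_that("fixtures round-trip through EDF and hypnogram files", {
  spec <- tiny_cohort_spec(seed = 41, epochs = 4, subjects = 1)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_fixture(cohort, dir)
  expect_equal(nrow(manifest), 2L)
  expect_equal(anyDuplicated(manifest$subject_id), 0L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    rec <- read_recording(manifest$edf_path[i])
    orig <- cohort$recordings[[sid]]
    expect_setequal(names(rec$channels), names(orig$channels))
    # EDF quantises to 16 bits over +/- 8 x max band SD
    qstep <- 16 * max(cohort$spec$group_profiles[[
      manifest$group[i]]]$band_sd) / 65535
    expect_lt(max(abs(rec$channels$C4P4 - orig$channels$C4P4)), qstep)
    hyp <- read_hypnogram(manifest$hypnogram_path[i])
    expect_equal(hyp, cohort$hypnograms[[sid]])
  }
})
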