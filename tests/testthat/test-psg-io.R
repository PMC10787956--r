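# EDF reading, hypnogram parsing, REM epoch extraction and accounting.

write_hyp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("hypnogram files parse, with comments and blank lines ignored", {
  hyp <- read_hypnogram(write_hyp_lines(c(
    "# scored by tester", "W 0 60", "", "REM 60 90  # a block",
    "W 150 60")))
  expect_equal(nrow(hyp), 3L)
  expect_equal(hyp$stage, c("W", "REM", "W"))
  expect_equal(hyp$duration, c(60, 90, 60))
  empty <- read_hypnogram(write_hyp_lines(character()))
  expect_equal(nrow(empty), 0L)
})

test_that("malformed hypnograms fail with located errors", {
  expect_error(read_hypnogram(write_hyp_lines(c("W 0 60", "XX 60 30"))),
               "line 2.*unknown stage")
  expect_error(read_hypnogram(write_hyp_lines(c("W 100 60", "REM 0 30"))),
               "non-decreasing")
  expect_error(read_hypnogram(write_hyp_lines(c("W 0 60", "REM 30 30"))),
               "overlap")
  expect_error(read_hypnogram(write_hyp_lines("REM 0")), "expected")
  expect_error(read_hypnogram(write_hyp_lines("REM 0 -5")), "positive")
})

test_that("REM intervals are tiled into whole epochs, remainders dropped", {
  fs <- 512
  rec <- remband:::new_psg_recording(
    "s1", list(C4P4 = rnorm(300 * fs)), c(C4P4 = fs), c(C4P4 = "mV"))
  hyp <- tibble::tibble(stage = c("W", "REM", "S2", "REM"),
                        onset = c(0, 30, 120, 190),
                        duration = c(30, 90, 70, 75))
  eps <- extract_rem_epochs(rec, hyp, "C4P4", "healthy")
  # 90 s -> 3 epochs; 75 s -> 2 epochs + discarded 15 s remainder
  expect_equal(nrow(eps), 5L)
  expect_true(all(lengths(eps$signal) == 15360L))
  expect_equal(eps$onset, c(30, 60, 90, 190, 220))
  # extracted samples match the raw trace
  expect_identical(eps$signal[[1]], rec$channels$C4P4[(30 * fs + 1):(60 * fs)])
  # no REM at all -> empty table
  none <- extract_rem_epochs(rec, tibble::tibble(
    stage = "W", onset = 0, duration = 300), "C4P4", "healthy")
  expect_equal(nrow(none), 0L)
  expect_error(extract_rem_epochs(rec, hyp, "Fp1F3", "healthy"),
               "not present")
})

test_that("contiguous REM annotations merge into one maximal interval", {
  fs <- 64
  rec <- remband:::new_psg_recording(
    "s1", list(C4A1 = rnorm(400 * fs)), c(C4A1 = fs), c(C4A1 = "mV"))
  hyp <- tibble::tibble(stage = c("REM", "REM", "W", "REM"),
                        onset = c(0, 50, 100, 160),
                        duration = c(50, 50, 60, 40))
  eps <- extract_rem_epochs(rec, hyp, "C4A1", "bruxism")
  # [0,100) tiles 3 epochs; [160,200) tiles 1
  expect_equal(eps$onset, c(0, 30, 60, 160))
})

test_that("epoch counts are conserved across random hypnograms", {
  set.seed(22)
  fs <- 64
  for (i in 1:10) {
    durs <- sample(10:100, 6)
    stages <- c("W", "REM", "S2", "REM", "S1", "REM")
    onsets <- cumsum(c(0, durs[-6]))
    hyp <- tibble::tibble(stage = stages, onset = onsets, duration = durs)
    rec <- remband:::new_psg_recording(
      "s", list(C4P4 = rnorm(sum(durs) * fs)), c(C4P4 = fs),
      c(C4P4 = "mV"))
    eps <- extract_rem_epochs(rec, hyp, "C4P4", "healthy")
    expect_equal(nrow(eps), sum(floor(durs[stages == "REM"] / 30)))
    # no epoch crosses its annotation's end
    for (j in seq_len(nrow(eps))) {
      ann <- hyp[hyp$stage == "REM" & hyp$onset <= eps$onset[j] &
                   hyp$onset + hyp$duration > eps$onset[j], ]
      expect_lte(eps$onset[j] + 30, ann$onset[1] + ann$duration[1])
    }
  }
})

test_that("accounting totals per subject, group and cohort", {
  counts <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    group = c("bruxism", "bruxism", "healthy"),
    epoch_count = c(3, 2, 4))
  acc <- rem_accounting(counts)
  expect_equal(acc$total_seconds[acc$subject_id == "a"], 90)
  expect_equal(acc$epoch_count[acc$subject_id == "total" &
                                 acc$group == "bruxism"], 5)
  expect_equal(acc$epoch_count[acc$group == "total"], 9)
  expect_equal(acc$total_seconds[acc$group == "total"], 270)
})

test_that("EDF supports per-channel sampling rates without resampling", {
  rec <- remband:::new_psg_recording(
    "mix", list(C4P4 = sin(2 * pi * 5 * (0:639) / 64),
                EMG = rnorm(320)),
    c(C4P4 = 64, EMG = 32), c(C4P4 = "mV", EMG = "uV"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, phys_range = c(-4, 4))
  back <- read_recording(path)
  expect_equal(unname(back$fs), c(64, 32))
  expect_equal(back$units, c(C4P4 = "mV", EMG = "uV"))
  expect_lt(max(abs(back$channels$C4P4 - rec$channels$C4P4)), 8 / 32768)
})

test_that("truncated or missing EDF files fail loudly", {
  expect_error(read_recording(file.path(tempdir(), "nope.edf")),
               "not found")
  rec <- remband:::new_psg_recording(
    "t", list(C4P4 = rnorm(640)), c(C4P4 = 64), c(C4P4 = "mV"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, phys_range = c(-6, 6))
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[1:(length(full) - 100)], path)
  expect_error(read_recording(path), "truncated|inconsistent")
})
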