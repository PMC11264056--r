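make_recording <- function(seconds, fs = 100, extra_channels = list()) {
  f <- withr::local_tempfile(fileext = ".edf", .local_envir = parent.frame())
  n <- seconds * fs
  sigs <- c(list(rnorm(n), rnorm(n)), extra_channels)
  labs <- c("EEG Fpz-Cz", "EEG Pz-Oz", names(extra_channels))
  write_edf(f, sigs, labs, fs = fs)
  f
}

test_that("read_recording extracts exactly the two EEG derivations", {
  f <- make_recording(60, extra_channels = list("EOG horizontal" = rnorm(6000)))
  rec <- read_recording(f)
  expect_s3_class(rec, "sleep_recording")
  expect_equal(dim(rec$signal), c(2L, 6000L))
  expect_equal(rownames(rec$signal), c("Fpz-Cz", "Pz-Oz"))
  expect_equal(rec$fs, 100)
})

test_that("a missing required channel is an error naming the channel", {
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, list(rnorm(6000)), "EEG Fpz-Cz", fs = 100)
  expect_error(read_recording(f), "Pz-Oz")
})

test_that("channel names resolve case-insensitively", {
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, list(rnorm(3000), rnorm(3000)),
            c("EEG FPZ-CZ", "eeg pz-oz"), fs = 100)
  expect_silent(rec <- read_recording(f))
  expect_equal(ncol(rec$signal), 3000L)
})

test_that("R&K labels map onto the five AASM stages with N3/N4 merged", {
  expect_equal(map_stage_label(c("Sleep stage W", "Sleep stage 1",
                                 "Sleep stage 2", "Sleep stage 3",
                                 "Sleep stage 4", "Sleep stage R")),
               c("W", "N1", "N2", "N3", "N3", "R"))
  expect_equal(map_stage_label(c("Movement time", "Sleep stage ?")),
               c("EXCLUDED", "EXCLUDED"))
  expect_equal(map_stage_label(c("W", "3", "4", "R")), c("W", "N3", "N3", "R"))
  expect_error(map_stage_label("Sleep stage Z"), "unrecognized")
})

test_that("age groups follow the cohort tertile boundaries", {
  expect_equal(age_group_of(c(25, 45, 46, 69, 70, 101)),
               c("young", "young", "middle", "middle", "old", "old"))
  expect_error(age_group_of(24), "range")
})

test_that("segment_epochs tiles annotations into labelled 30 s epochs", {
  f <- make_recording(120)
  rec <- read_recording(f)
  meta <- subject_meta(30, "female")
  ann <- data.frame(onset = c(0, 60), duration = c(60, 60),
                    label = c("Sleep stage W", "Sleep stage 1"))
  eps <- segment_epochs(rec, ann, meta)
  expect_length(eps, 4)
  expect_equal(vapply(eps, `[[`, character(1), "stage"),
               c("W", "W", "N1", "N1"))
  expect_true(all(vapply(eps, function(e) ncol(e$signal), integer(1)) == 3000L))
  # epoch signal matches the corresponding slice of the recording
  expect_equal(eps[[3]]$signal[1, ], rec$signal[1, 6001:9000])
})

test_that("excluded windows are dropped and partial windows discarded", {
  f <- make_recording(100)
  rec <- read_recording(f)
  meta <- subject_meta(50, "male")
  expect_length(segment_epochs(rec, data.frame(onset = 0, duration = 90,
                                               label = "Movement time"), meta),
                0)
  eps <- segment_epochs(rec, data.frame(onset = 0, duration = 100,
                                        label = "Sleep stage W"), meta)
  expect_length(eps, 3)  # floor(100 / 30)
})

test_that("annotations past the end of the recording are truncated with a warning", {
  f <- make_recording(90)
  rec <- read_recording(f)
  expect_warning(
    eps <- segment_epochs(rec, data.frame(onset = 0, duration = 120,
                                          label = "Sleep stage 2"),
                          subject_meta(70, "female")),
    "truncat")
  expect_length(eps, 3)
})

test_that("epoch counts follow the floor(duration/30) rule over mixed labels", {
  f <- make_recording(300)
  rec <- read_recording(f)
  ann <- data.frame(onset = c(0, 60, 150, 240),
                    duration = c(60, 90, 90, 60),
                    label = c("Sleep stage W", "Sleep stage 2",
                              "Movement time", "Sleep stage R"))
  eps <- segment_epochs(rec, ann, subject_meta(30, "male"))
  mapped <- map_stage_label(ann$label)
  expected <- sum(floor(ann$duration[mapped != "EXCLUDED"] / 30))
  expect_length(eps, expected)
  expect_true(all(vapply(eps, `[[`, character(1), "stage") %in%
                  c("W", "N1", "N2", "N3", "R")))
})

test_that("wake trimming keeps only W epochs near the sleep period", {
  f <- make_recording(300)
  rec <- read_recording(f)
  ann <- data.frame(onset = c(0, 120, 150),
                    duration = c(120, 30, 150),
                    label = c("Sleep stage W", "Sleep stage 2", "Sleep stage W"))
  meta <- subject_meta(30, "female")
  expect_length(segment_epochs(rec, ann, meta), 10)
  trimmed <- segment_epochs(rec, ann, meta, wake_trim_minutes = 1)
  # W epochs allowed within 60 s of the single N2 epoch at onset 120
  onsets <- vapply(trimmed, `[[`, numeric(1), "onset")
  expect_equal(onsets, c(60, 90, 120, 150, 180))
  expect_equal(vapply(trimmed, `[[`, integer(1), "epoch_index"), 1:5)
})

test_that("epoch manifest carries stage and subject metadata", {
  eps <- list(toy_epoch(matrix(rnorm(6000), 2), stage = "N2", age = 71,
                        sex = "male", subject_id = "A"))
  m <- epoch_manifest(eps)
  expect_equal(m$stage, "N2")
  expect_equal(m$age_group, "old")
  expect_equal(m$sex, "male")
})
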