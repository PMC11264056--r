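test_that("coupling table defaults encode the intended group structure", {
  tab <- coupling_table()
  expect_equal(dim(tab), c(6, 5, 3, 2))
  expect_true(all(tab >= 0 & tab < 1))
  # delta and beta coupling rise monotonically W -> N3
  for (b in c("delta", "beta"))
    expect_true(all(diff(tab[b, c("W", "N1", "N2", "N3"), "middle", "male"]) > 0))
  # female >= male in the bands at/above 8 Hz, strictly in at least one
  for (b in c("alpha", "beta", "spindle"))
    expect_true(all(tab[b, , , "female"] >= tab[b, , , "male"]))
  expect_gt(tab["alpha", "W", "young", "female"],
            tab["alpha", "W", "young", "male"])
  # young differs from old in the spindle band
  expect_true(all(tab["spindle", , "young", ] != tab["spindle", , "old", ]))
})

test_that("epoch generation is deterministic in the seed", {
  meta <- subject_meta(40, "male")
  e1 <- generate_epoch("N2", meta, seed = 123)
  e2 <- generate_epoch("N2", meta, seed = 123)
  e3 <- generate_epoch("N2", meta, seed = 124)
  expect_identical(e1$signal, e2$signal)
  expect_false(identical(e1$signal, e3$signal))
  expect_equal(dim(e1$signal), c(2L, 3000L))
})

test_that("generation does not disturb the session RNG", {
  set.seed(99)
  before <- .Random.seed
  generate_epoch("W", subject_meta(30, "female"), seed = 5)
  expect_identical(.Random.seed, before)
})

test_that("cohort size follows subjects x stages x epochs_per_stage", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 2, epochs_per_stage = 10,
                                        seed = 1))
  expect_equal(nrow(cohort$manifest), 12 * 5 * 10)
  expect_equal(as.vector(table(cohort$manifest$stage)), rep(120L, 5))
  counts <- table(cohort$manifest$age_group, cohort$manifest$sex)
  expect_true(all(counts == 100))
})

test_that("cohorts are reproducible from the seed and vary across seeds", {
  c1 <- generate_cohort(cohort_spec(1, 1, seed = 7))
  c2 <- generate_cohort(cohort_spec(1, 1, seed = 7))
  c3 <- generate_cohort(cohort_spec(1, 1, seed = 8))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$epochs[[1]]$signal, c2$epochs[[1]]$signal)
  expect_false(identical(c1$epochs[[1]]$signal, c3$epochs[[1]]$signal))
  expect_equal(dim(c3$manifest), dim(c1$manifest))
})

test_that("a delta-only coupled epoch shows maximal delta MI", {
  base <- matrix(0, 6, 5, dimnames = list(band_scheme()$band,
                                          c("W", "N1", "N2", "N3", "R")))
  base["delta", ] <- 0.9
  coup <- coupling_table(base = base, sex_shift = 0, age_shift = 0)
  meta <- subject_meta(30, "female")
  wins <- sum(vapply(1:40, function(i) {
    cv <- epoch_connectivity(generate_epoch("W", meta, coup, seed = 4000 + i))
    names(which.max(cv)) == "delta"
  }, logical(1)))
  expect_gte(wins / 40, 0.95)
})

test_that("estimated MI is monotone in the coupling coefficient", {
  rhos <- c(0, 0.3, 0.6, 0.9)
  mis <- vapply(rhos, function(rho) {
    mean(vapply(1:20, function(i) {
      pair <- coupled_band_noise(3000, 8, 13, rho, seed = 100 * i + round(100 * rho))
      estimate_mi(pair[1, ], pair[2, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("cohorts round-trip through EDF within quantization tolerance", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(1, 1, seed = 21))
  write_cohort_edf(cohort, dir)
  psg <- list.files(dir, pattern = "-PSG\\.edf$", full.names = TRUE)
  hyp <- list.files(dir, pattern = "-Hypnogram\\.edf$", full.names = TRUE)
  expect_length(psg, 6)
  expect_length(hyp, 6)
  expect_true(file.exists(file.path(dir, "metadata.csv")))

  sid <- sub("-PSG\\.edf$", "", basename(psg[1]))
  rec <- read_recording(psg[1], subject_id = sid)
  ann <- read_hypnogram(hyp[1])
  meta_csv <- read.csv(file.path(dir, "metadata.csv"))
  row <- meta_csv[meta_csv$subject_id == sid, ]
  eps <- segment_epochs(rec, ann, subject_meta(row$age, row$sex))
  orig <- Filter(function(e) e$subject_id == sid, cohort$epochs)
  expect_length(eps, length(orig))
  expect_equal(vapply(eps, `[[`, character(1), "stage"),
               vapply(orig, `[[`, character(1), "stage"))
  qtol <- 2 * max(abs(orig[[1]]$signal)) / 65535
  expect_lt(max(abs(eps[[1]]$signal - orig[[1]]$signal)), qtol)
})
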