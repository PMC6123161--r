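# tiny but complete study configuration used by the pipeline tests
tiny_cfg <- function(...) {
  study_config(n_subjects = 1, grid_shape = c(32, 32, 24),
               spacing_mm = c(6, 6, 10), n_phases = 4,
               reg = reg_params(n_levels = 1, iters_per_level = 8),
               auto_outlier_rate = 0, irregularity = 0.08, seed = 21, ...)
}

test_that("a noise-free static study is exactly perfect", {
  cfg <- tiny_cfg(
    rater1 = rater_profile(0, 0, 0), rater2 = rater_profile(0, 0, 0),
    include_bellows = FALSE, auto_correct = FALSE,
    phantom_overrides = list(noise_sigma = 0,
                             diaphragm_amplitude_right_mm = 0,
                             diaphragm_amplitude_left_mm = 0))
  st <- run_study(cfg)
  expect_equal(nrow(st$errors), 0)
  expect_true(all(st$records$jaccard == 1))
  expect_true(all(st$records$sensitivity == 1))
  expect_true(all(st$records$specificity == 1))
  expect_true(all(st$variability$pctV == 0))
  expect_true(all(st$irv$increase_pct == 0))
  expect_true(all(st$diaphragm$range_mm == 0))
})

test_that("the study is deterministic and the contour audit adds up", {
  cfg <- tiny_cfg()
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_equal(s1$records, s2$records)
  expect_equal(s1$irv, s2$irv)
  expect_equal(s1$audit$expected_contours,
               1 * 4 * 4 * 4 * 2)  # subjects x phases x sources x organ sets x series
  expect_equal(s1$audit$record_rows, s1$audit$expected_contours)
  # every configured cell is present (or carries an explicit error entry)
  grid <- expand.grid(organ = c("lungs", "heart", "liver", "stomach"),
                      phase = 0:3,
                      source = c("manual-U1", "manual-U2", "auto-U1", "auto-U2"),
                      series = c("navigator", "bellows"))
  have <- paste(s1$records$organ, s1$records$phase, s1$records$source,
                s1$records$series)
  expect_setequal(have, paste(grid$organ, grid$phase, grid$source, grid$series))
})

test_that("broom-style accessors and the study plot work", {
  cfg <- tiny_cfg(include_bellows = FALSE)
  st <- run_study(cfg)
  expect_identical(tidy(st), st$records)
  g <- glance(st)
  expect_equal(nrow(g), 1)
  expect_true(g$jaccard_manual > 0.5)
  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
})

test_that("the rigid pre-alignment hook is the identity", {
  x <- list(U1 = list(a = 1), U2 = list(b = 2))
  expect_identical(irv4d:::align_series(x), x)
})

test_that("the gross-flaw detector finds SI truncations and corrects them", {
  m <- sphere_mask(20, c(40, 40, 40), dim = c(40, 40, 20), spacing = c(2, 2, 4))
  phase_masks <- rep(list(m), 6)
  bad <- m
  bad$data <- irv4d:::corrupt_si_edge(bad$data, superior = FALSE,
                                      extend = FALSE, k = 3)
  phase_masks[[4]] <- bad
  fl <- irv4d:::detect_gross_flaws(phase_masks)
  expect_identical(which(fl), 4L)
  fixed <- irv4d:::correct_gross_flaws(phase_masks, fl)
  expect_identical(fixed[[4]]$data, m$data)
})

test_that("volumes, masks and fields roundtrip through NIfTI", {
  dir <- withr::local_tempdir()
  v <- vol3d(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(2, 2, 5))
  p <- write_volume(v, file.path(dir, "v.nii.gz"))
  v2 <- read_volume(p)
  expect_equal(v2$spacing, c(2, 2, 5))
  expect_lt(max(abs(v2$data - v$data)), 1e-5)

  m <- sphere_mask(6, c(8, 8, 10), dim = c(8, 8, 4), spacing = c(2, 2, 5))
  m2 <- read_mask(write_mask(m, file.path(dir, "m.nii.gz")))
  expect_identical(m2$data, m$data)
  expect_equal(m2$spacing, c(2, 2, 5))

  f <- shift_dvf(c(8, 8, 4), c(2, 2, 5), c(1.25, -0.5, 3))
  f$uz[3, 3, 2] <- 7.125
  f2 <- read_dvf(write_dvf(f, file.path(dir, "u.nii.gz")))
  expect_lt(max(abs(f2$uz - f$uz)), 1e-5)
  expect_lt(max(abs(f2$ux - f$ux)), 1e-5)

  ph <- build_phantom(small_config(n_phases = 2))
  export_phantom(ph, file.path(dir, "subj"))
  man <- read_manifest(file.path(dir, "subj", "manifest.json"))
  expect_equal(man$phases, 2)
  expect_setequal(man$organs, organ_names())
})

test_that("table-summary verification reproduces the printed rows", {
  v <- reproduce_table_summaries()
  expect_true(v$pass)
  cells <- v$cells
  # spot checks straight off the printed tables
  lungs_manual <- cells[cells$table == "table2" & cells$block == "similarity" &
                        cells$column == "lungs_manual", ]
  expect_equal(lungs_manual$recomputed_mean, 0.92)
  expect_true(lungs_manual$mean_match)
  liver_pv <- cells[cells$table == "table1" & cells$column == "pctV_liver", ]
  expect_equal(liver_pv$recomputed_mean, 1.2)
  expect_equal(liver_pv$recomputed_sd, 0.6)
  # the heart volume-variation cell is the documented exception
  heart_pv <- cells[cells$table == "table1" & cells$column == "pctV_heart", ]
  expect_true(heart_pv$known_exception)
  expect_false(heart_pv$mean_match)

  # a missing fixture fails loudly rather than passing silently
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject", empty)
  expect_error(reproduce_table_summaries(table1_path = empty), "empty|fixture")
  expect_error(reproduce_table_summaries(table1_path = "no/such.csv"),
               "fixture")
})
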