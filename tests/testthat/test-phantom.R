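test_that("anatomy contains every label with segmentable contrast", {
  an <- small_anatomy()
  expect_setequal(sort(unique(as.integer(an$labels))), 0:6)
  cfg <- an$config
  means <- vapply(organ_names(), function(o)
    mean(an$reference$data[an$labels == cfg$organ_geometry[[o]]$label]),
    numeric(1))
  for (o in organ_names())
    expect_gte(sum(an$labels == cfg$organ_geometry[[o]]$label), 100)
  # organ mean intensities pairwise separated by at least 3 x noise sd
  # (the two lungs deliberately share one intensity)
  orgs <- organ_names()
  for (i in seq_along(orgs)) for (j in seq_len(i - 1)) {
    if (setequal(c(orgs[i], orgs[j]), c("right_lung", "left_lung"))) next
    expect_gte(abs(means[orgs[i]] - means[orgs[j]]), 3 * cfg$noise_sigma)
  }
})

test_that("noise-free, texture-free reference is piecewise constant", {
  cfg <- small_config(noise_sigma = 0, texture_amp = 0, edge_sigma_mm = 0)
  an <- build_anatomy(cfg)
  for (lab in 0:6) {
    v <- an$reference$data[an$labels == lab]
    expect_equal(sd(v), 0)
  }
})

test_that("phantom generation is bit-identical for a repeated seed", {
  cfg <- small_config()
  p1 <- build_phantom(cfg)
  p2 <- build_phantom(cfg)
  expect_identical(p1$phases[[3]]$data, p2$phases[[3]]$data)
  expect_identical(p1$truth[[7]]$masks$liver$data, p2$truth[[7]]$masks$liver$data)
})

test_that("an undersized grid fails naming the violating organ", {
  expect_error(build_anatomy(phantom_config(grid_shape = c(12, 12, 6),
                                            spacing_mm = c(16, 16, 40))),
               "organ")
})

test_that("motion field honours amplitude bounds and dome displacement", {
  cfg <- small_config()
  an <- small_anatomy()
  expect_error(analytic_motion_field(cfg, -0.1), "phase_amplitude")
  expect_error(analytic_motion_field(cfg, 1.2), "phase_amplitude")

  f0 <- analytic_motion_field(cfg, 0, an)
  expect_true(all(f0$uz == 0) && all(f0$ux == 0) && all(f0$uy == 0))

  f1 <- analytic_motion_field(cfg, 1, an)
  dR <- an$domes$right$voxel
  dL <- an$domes$left$voxel
  expect_equal(f1$uz[dR[1], dR[2], dR[3]], cfg$diaphragm_amplitude_right_mm)
  expect_equal(f1$uz[dL[1], dL[2], dL[3]], cfg$diaphragm_amplitude_left_mm)
  # smoothness: discrete Laplacian bounded
  lap <- irv4d:::cpp_laplacian3(as.numeric(f1$uz), dim(f1$uz), cfg$spacing_mm)
  expect_lt(max(abs(lap)), 1)
})

test_that("warped liver volume matches the Jacobian-weighted integral", {
  cfg <- small_config()
  an <- small_anatomy()
  f <- analytic_motion_field(cfg, 1, an)
  liver <- organ_mask(an, "liver")
  warped <- warp_mask(liver, f)
  # numeric Jacobian of the pull-back map x -> x + u(x) over warped voxels
  d <- dim(f$uz)
  g <- irv4d:::cpp_gradient3(as.numeric(f$uz), as.integer(d), cfg$spacing_mm)
  detj <- 1 + array(g$gz, d)    # SI-only field: det(I + du) = 1 + duz/dz
  jac_vol <- sum(detj[warped$data]) * voxel_volume(liver)
  expect_lt(abs(jac_vol - mask_volume(liver)) / mask_volume(liver), 0.015)
})

test_that("rendering is exact for identity and shifts organ COMs correctly", {
  an <- small_anatomy()
  d <- dim(an$reference$data)
  zero <- shift_dvf(d, an$config$spacing_mm, c(0, 0, 0))
  r <- render_phase(an, zero, noise_sigma = 0, phase = 0)
  expect_identical(r$volume$data, an$reference$data)

  ten <- shift_dvf(d, an$config$spacing_mm, c(0, 0, 10))
  r10 <- render_phase(an, ten, noise_sigma = 0, phase = 1)
  for (o in c("liver", "heart")) {
    shift <- mask_com(organ_mask(an, o))[3] - mask_com(r10$truth$masks[[o]])[3]
    expect_lt(abs(shift - 10), an$config$spacing_mm[3] / 2 + 1e-9)
  }
})

test_that("noise realizations differ between seeds but masks do not", {
  an <- small_anatomy()
  f <- analytic_motion_field(an$config, 0.5, an)
  r1 <- render_phase(an, f, noise_sigma = 10, seed = 1, phase = 4)
  r2 <- render_phase(an, f, noise_sigma = 10, seed = 2, phase = 4)
  expect_identical(r1$truth$masks$stomach$data, r2$truth$masks$stomach$data)
  expect_false(identical(r1$volume$data, r2$volume$data))
})

test_that("non-lung organ volumes are conserved across the breathing cycle", {
  ph <- small_phantom()
  for (o in c("heart", "liver", "stomach")) {
    vols <- vapply(seq_along(ph$truth), function(p)
      mask_volume(ph$truth[[p]]$masks[[o]]), numeric(1))
    expect_lte(volume_variation_pct(vols), 1.5)
  }
})

test_that("organ COM excursion does not exceed the ipsilateral dome motion", {
  ph <- small_phantom()
  n <- length(ph$truth)
  dia <- list(
    right = diaphragm_excursion(lapply(seq_len(n), function(p)
      ph$truth[[p]]$masks$right_lung), "right")$range_mm,
    left = diaphragm_excursion(lapply(seq_len(n), function(p)
      ph$truth[[p]]$masks$left_lung), "left")$range_mm)
  for (o in c("liver", "stomach")) {
    side <- if (o == "liver") "right" else "left"
    ex <- com_trajectory(lapply(seq_len(n), function(p)
      ph$truth[[p]]$masks[[o]]))$si_excursion_mm
    expect_lte(ex, dia[[side]] + ph$config$spacing_mm[3] / 2)
  }
})
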