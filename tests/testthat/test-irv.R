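test_that("static contours give a zero IRV increase", {
  m <- sphere_mask(15, c(36, 36, 36))
  irv <- compute_irv(list(m, m, m))
  expect_equal(irv$increase_pct, 0)
  expect_equal(irv$irv_volume_mm3, mask_volume(m))
})

test_that("the stepped-sphere union matches a brute-force voxel count", {
  masks <- stepped_spheres()
  irv <- compute_irv(masks)
  # brute force: per-voxel occupancy count across phases, union = count > 0
  occ <- Reduce(`+`, lapply(masks, function(m) m$data + 0))
  union_count <- sum(occ > 0)
  v <- voxel_volume(masks[[1]])
  expect_identical(sum(irv$irv_mask$data), union_count)
  expect_equal(irv$irv_volume_mm3, union_count * v)
  mean_vol <- mean(vapply(masks, function(m) sum(m$data) * v, numeric(1)))
  expect_equal(irv$increase_pct, 100 * (union_count * v / mean_vol - 1))
  expect_gt(irv$increase_pct, 0)
})

test_that("the union is monotone and order-independent", {
  masks <- stepped_spheres(n_phases = 5)
  v9 <- compute_irv(masks[1:4])$irv_volume_mm3
  v10 <- compute_irv(masks)$irv_volume_mm3
  expect_gte(v10, v9)
  perm <- compute_irv(masks[c(3, 1, 5, 2, 4)])
  expect_identical(perm$irv_mask$data, compute_irv(masks)$irv_mask$data)
})

test_that("empty phases are flagged but still contribute to the union", {
  masks <- stepped_spheres(n_phases = 4)
  masks[[2]]$data[] <- FALSE
  irv <- compute_irv(masks)
  expect_equal(irv$empty_phases, 1L)
  expect_gt(irv$irv_volume_mm3, 0)
  td <- tidy(irv)
  expect_true(td$empty[td$phase == 1])
})

test_that("boundary-noise contours inflate the IRV beyond the true one", {
  ph <- small_phantom()
  n <- length(ph$truth)
  truth <- lapply(seq_len(n), function(p) ph$truth[[p]]$masks$stomach)
  noisy <- lapply(seq_len(n), function(p)
    simulate_rater(truth[[p]], rater_profile(boundary_sigma_mm = 2),
                   seed = irv4d:::derive_seed(5, p)))
  expect_gt(compute_irv(noisy)$increase_pct, compute_irv(truth)$increase_pct)
})

test_that("stomach sweeps relatively more of its volume than the liver", {
  ph <- small_phantom()
  n <- length(ph$truth)
  inc <- vapply(c("liver", "stomach"), function(o)
    compute_irv(lapply(seq_len(n), function(p) ph$truth[[p]]$masks[[o]]))$increase_pct,
    numeric(1))
  expect_gt(inc["stomach"], inc["liver"])
})

test_that("COM trajectories track stepped motion and symmetric blobs", {
  m <- sphere_mask(15, c(36, 36, 36))
  expect_equal(com_trajectory(list(m, m, m))$si_excursion_mm, 0)

  masks <- stepped_spheres(span_mm = 12)
  tr <- com_trajectory(masks)
  expect_lt(abs(tr$si_excursion_mm - 12), masks[[1]]$spacing[3] / 2 + 1e-9)

  # two equal blobs moving oppositely: COM stationary
  two <- lapply(0:3, function(s) {
    a <- sphere_mask(8, c(20, 36, 30 + 2 * s))
    b <- sphere_mask(8, c(52, 36, 42 - 2 * s))
    mask3d(a$data | b$data, a$spacing)
  })
  expect_lt(com_trajectory(two)$si_excursion_mm, 0.5)

  masks[[3]]$data[] <- FALSE
  tr2 <- com_trajectory(masks)
  expect_equal(tr2$trajectory$error[3], "empty mask")
  expect_false(anyNA(tr2$si_excursion_mm))
})

test_that("diaphragm excursion reads the phantom amplitudes per side", {
  cfg <- small_config(diaphragm_amplitude_right_mm = 16,
                      diaphragm_amplitude_left_mm = 30)
  ph <- build_phantom(cfg)
  n <- length(ph$truth)
  right <- diaphragm_excursion(lapply(seq_len(n), function(p)
    ph$truth[[p]]$masks$right_lung), "right")
  left <- diaphragm_excursion(lapply(seq_len(n), function(p)
    ph$truth[[p]]$masks$left_lung), "left")
  expect_lte(abs(right$range_mm - 16), cfg$spacing_mm[3])
  expect_lte(abs(left$range_mm - 30), cfg$spacing_mm[3])
  expect_gt(left$range_mm, right$range_mm)

  static <- diaphragm_excursion(rep(list(ph$truth[[1]]$masks$right_lung), 3),
                                "right")
  expect_equal(static$range_mm, 0)
  expect_error(diaphragm_excursion(list(mask3d(array(FALSE, c(4, 4, 4)))),
                                   "left"), "left")
})
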