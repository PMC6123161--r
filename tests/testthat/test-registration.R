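test_that("energy has its closed forms on trivial inputs", {
  d <- c(8, 8, 8); sp <- c(2, 2, 5)
  zero <- shift_dvf(d, sp, c(0, 0, 0))
  a <- vol3d(array(rnorm(prod(d)), d), sp)
  expect_equal(dir_energy(a, a, zero), 0)

  IA <- vol3d(array(0, d), sp)
  IB <- vol3d(array(3, d), sp)
  expect_equal(dir_energy(IA, IB, zero, lambda_smooth = 0),
               9 * prod(d) * prod(sp))

  roi <- array(FALSE, d); roi[1:4, , ] <- TRUE
  expect_equal(dir_energy(IA, IB, zero, lambda_smooth = 0, roi = roi),
               9 * sum(roi) * prod(sp))
})

test_that("smoothness energy of a linear ramp matches brute-force summation", {
  d <- c(6, 5, 4); sp <- c(2, 2, 5)
  slope <- 0.3
  x_mm <- array((seq_len(d[1]) - 1) * sp[1], d)
  u1 <- slope * x_mm
  dvf <- dvf3d(u1, array(0, d), array(0, d), sp)
  img <- vol3d(array(5, d), sp)
  lambda <- 0.1

  # independent brute-force evaluation with explicit loops over voxels,
  # central differences inside, one-sided at the faces
  grad_sq <- 0
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    for (ax in 1:3) {
      comp <- u1  # only u1 is nonzero
      idx <- c(i, j, k)
      n_ax <- d[ax]
      step <- sp[ax]
      get <- function(off) {
        q <- idx; q[ax] <- q[ax] + off
        comp[q[1], q[2], q[3]]
      }
      g <- if (idx[ax] == 1) (get(1) - get(0)) / step
      else if (idx[ax] == n_ax) (get(0) - get(-1)) / step
      else (get(1) - get(-1)) / (2 * step)
      grad_sq <- grad_sq + g^2
    }
  }
  expected <- lambda * grad_sq * prod(sp)
  expect_equal(dir_energy(img, img, dvf, lambda), expected, tolerance = 1e-12)
  # which for an exact ramp is lambda * a^2 * N * v
  expect_equal(expected, lambda * slope^2 * prod(d) * prod(sp))
})

test_that("registering an image to itself returns a negligible field", {
  img <- blob_volume(c(30, 30, 30))
  reg <- dir_register(img, img, reg_params(n_levels = 2, iters_per_level = 20))
  mag <- sqrt(reg$dvf$ux^2 + reg$dvf$uy^2 + reg$dvf$uz^2)
  expect_lte(mean(mag), 0.1)
  expect_true(reg$converged)
})

test_that("a 4 mm SI translation of a smooth blob is recovered within 1 mm", {
  fixed <- blob_volume(c(32, 32, 28))
  moving <- blob_volume(c(32, 32, 32))  # fixed is moving shifted -4 mm in z
  reg <- dir_register(fixed, moving,
                      reg_params(iters_per_level = 60, roi = NULL))
  blob <- fixed$data > 30
  expect_lt(abs(mean(reg$dvf$uz[blob]) - 4), 1)
  expect_true(all(diff(reg$energy_trace) <= 1e-9))
})

test_that("energy at the solution never exceeds the zero-field energy", {
  for (s in 1:3) {
    set.seed(s)
    base <- blob_volume(c(30 + 2 * s, 30, 30))
    noisy <- vol3d(base$data + rnorm(length(base$data), sd = 2), base$spacing)
    target <- blob_volume(c(30, 30, 30 - 2 * s))
    reg <- dir_register(target, noisy,
                        reg_params(n_levels = 2, iters_per_level = 15))
    zero <- shift_dvf(dim(base$data), base$spacing, c(0, 0, 0))
    roi <- irv4d:::auto_roi(target)
    e_zero <- dir_energy(target, noisy, zero, 0.1, roi)
    e_sol <- dir_energy(target, noisy, reg$dvf, 0.1, roi)
    expect_lte(e_sol, e_zero + 1e-6)
  }
})

test_that("translating both images together leaves the relative field stable", {
  fixed <- blob_volume(c(32, 32, 28))
  moving <- blob_volume(c(32, 32, 32))
  p <- reg_params(n_levels = 2, iters_per_level = 60, roi = NULL)
  r1 <- dir_register(fixed, moving, p)
  fixed2 <- blob_volume(c(38, 32, 28))
  moving2 <- blob_volume(c(38, 32, 32))
  r2 <- dir_register(fixed2, moving2, p)
  blob1 <- fixed$data > 30
  blob2 <- fixed2$data > 30
  expect_lt(abs(mean(r1$dvf$uz[blob1]) - mean(r2$dvf$uz[blob2])), 0.5)
})

test_that("constant images degenerate to a zero field with a warning", {
  img <- vol3d(array(5, c(12, 12, 8)), c(2, 2, 5))
  expect_warning(reg <- dir_register(img, img), "degenerate")
  expect_true(reg$degenerate)
  expect_true(all(reg$dvf$uz == 0))
})

test_that("mask warping thresholds at 0.5 and preserves shape under shifts", {
  m <- sphere_mask(20, c(40, 40, 40), dim = c(40, 40, 24), spacing = c(2, 2, 5))
  d <- dim(m$data)
  zero <- shift_dvf(d, m$spacing, c(0, 0, 0))
  expect_identical(warp_mask(m, zero)$data, m$data)

  empty <- mask3d(array(FALSE, d), m$spacing)
  expect_equal(sum(warp_mask(empty, shift_dvf(d, m$spacing, c(0, 0, 7)))$data), 0)

  ten <- shift_dvf(d, m$spacing, c(0, 0, 10))
  w <- warp_mask(m, ten)
  expect_lt(abs((mask_com(m)[3] - mask_com(w)[3]) - 10), m$spacing[3] / 2 + 1e-9)
  expect_lt(abs(mask_volume(w) - mask_volume(m)) / mask_volume(m), 0.05)
})

test_that("propagating through identical volumes returns the references", {
  an <- small_anatomy()
  cfg <- an$config
  vol <- vol3d(an$reference$data, cfg$spacing_mm, phase = 0L)
  series <- list(vol, vol, vol)
  refs <- list(liver = organ_mask(an, "liver"), heart = organ_mask(an, "heart"))
  prop <- propagate_contours(series, refs,
                             reg_params(n_levels = 1, iters_per_level = 5))
  for (p in 1:3) for (o in names(refs)) {
    expect_equal(jaccard(prop$masks[[p]][[o]], refs[[o]]), 1.0)
    expect_identical(prop$masks[[p]][[o]]$source, "auto")
  }
  expect_true(all(is.na(prop$errors)))
})

test_that("the propagation direction pins fixed = target, moving = reference", {
  # phase 1 is the reference translated 8 mm inferior; the recovered mask
  # must follow the anatomy downward
  ref <- blob_volume(c(32, 32, 40), dim = c(32, 32, 32), spacing = c(2, 2, 4))
  tgt <- blob_volume(c(32, 32, 32), dim = c(32, 32, 32), spacing = c(2, 2, 4))
  m <- sphere_mask(12, c(32, 32, 40), dim = c(32, 32, 32), spacing = c(2, 2, 4))
  prop <- propagate_contours(list(ref, tgt), list(blob = m),
                             reg_params(n_levels = 2, iters_per_level = 60,
                                        roi = NULL))
  com0 <- mask_com(prop$masks[[1]]$blob)[3]
  com1 <- mask_com(prop$masks[[2]]$blob)[3]
  expect_lt(com1, com0 - 4)  # moved inferior with the target anatomy
})
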