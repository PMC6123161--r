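# shared fixtures, built once per test run and cached

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fix)) assign(name, builder(), envir = .fix)
  get(name, envir = .fix)
}

# coarse phantom: same 190 x 190 x 230 mm anatomy on a 48 x 48 x 24 grid
small_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48, 48, 24), spacing_mm = c(4, 4, 10),
         noise_sigma = 10, seed = 7),
    list(...))
  do.call(phantom_config, args)
}

small_anatomy <- function() fixture("small_anatomy", function()
  build_anatomy(small_config()))

small_phantom <- function() fixture("small_phantom", function()
  build_phantom(small_config()))

# full-resolution default phantom (used by the DIR-recovery and
# volume-conservation checks)
default_phantom <- function() fixture("default_phantom", function()
  build_phantom(phantom_config(seed = 11)))

# voxelized sphere mask on an isotropic grid
sphere_mask <- function(radius_mm, center_mm, dim = c(40, 40, 40),
                        spacing = c(2, 2, 2)) {
  co <- irv4d:::coord_arrays_mm(dim, spacing)
  inside <- (co$x - center_mm[1])^2 + (co$y - center_mm[2])^2 +
    (co$z - center_mm[3])^2 <= radius_mm^2
  mask3d(inside, spacing)
}

# uniform-translation displacement field
shift_dvf <- function(dim, spacing, shift_mm) {
  mk <- function(v) array(v, dim)
  dvf3d(mk(shift_mm[1]), mk(shift_mm[2]), mk(shift_mm[3]), spacing)
}

# smooth Gaussian-blob image for registration tests
blob_volume <- function(center_mm, dim = c(32, 32, 32), spacing = c(2, 2, 2),
                        sigma_mm = 12, amplitude = 100) {
  co <- irv4d:::coord_arrays_mm(dim, spacing)
  r2 <- (co$x - center_mm[1])^2 + (co$y - center_mm[2])^2 +
    (co$z - center_mm[3])^2
  vol3d(amplitude * exp(-r2 / (2 * sigma_mm^2)), spacing)
}

# per-phase masks of a sphere stepped along the SI axis
stepped_spheres <- function(n_phases = 10, span_mm = 12, radius = 15,
                            dim = c(36, 36, 36), spacing = c(2, 2, 2)) {
  lapply(seq_len(n_phases), function(p) {
    z <- 36 - span_mm * (p - 1) / (n_phases - 1)
    m <- sphere_mask(radius, c(36, 36, z), dim = dim, spacing = spacing)
    m$organ <- "sphere"; m$phase <- p - 1L
    m
  })
}
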