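#' Configuration of the synthetic 4D respiratory phantom
#'
#' The phantom emulates a coronal T2-weighted respiratory-correlated 4D MRI
#' acquisition: ten amplitude-binned phases on an anisotropic grid
#' (2 x 2 mm in-plane, 5 mm slices by default), five organs (right/left
#' lung, heart, liver, stomach) embedded in a body ellipse, and a single
#' SI-dominant respiratory displacement mode whose peak equals the
#' diaphragm-dome excursion on each side.
#'
#' Non-lung organs (heart, liver, stomach) translate rigidly inside
#' "capsule" plateaus of the motion field that cover their full swept
#' range, so their ground-truth volumes are conserved across phases by
#' construction; lung tissue compresses toward the apex.
#'
#' @param grid_shape integer length 3, voxels per axis (axis 3 = SI).
#' @param spacing_mm voxel size in mm per axis.
#' @param n_phases number of respiratory bins (phase 0 = full exhalation).
#' @param diaphragm_amplitude_right_mm,diaphragm_amplitude_left_mm peak SI
#'   excursion of the right/left diaphragm dome in mm.
#' @param com_fraction organ centre-of-mass excursion of liver/stomach as a
#'   fraction of the ipsilateral diaphragm excursion.
#' @param heart_fraction heart excursion as a fraction of the mean
#'   diaphragm amplitude.
#' @param noise_sigma Gaussian intensity noise (arbitrary T2W-like units).
#' @param texture_amp amplitude of the smooth multiplicative intensity
#'   texture inside the body (0 disables; gives DIR volumetric landmarks).
#' @param edge_sigma_mm Gaussian blur of tissue boundaries in the reference
#'   intensity volume (0 gives a strictly piecewise-constant reference).
#' @param organ_geometry list of organ shape definitions as produced by
#'   [default_organ_geometry()]; positions/semi-axes in mm.
#' @param seed RNG seed for everything derived from this configuration.
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 48),
                           spacing_mm = c(2, 2, 5),
                           n_phases = 10,
                           diaphragm_amplitude_right_mm = 16,
                           diaphragm_amplitude_left_mm = 17,
                           com_fraction = 0.75,
                           heart_fraction = 0.6,
                           noise_sigma = 15,
                           texture_amp = 0.06,
                           edge_sigma_mm = 1.5,
                           organ_geometry = default_organ_geometry(),
                           seed = 1L) {
  if (n_phases < 1) stop("n_phases must be >= 1", call. = FALSE)
  if (diaphragm_amplitude_right_mm < 0 || diaphragm_amplitude_left_mm < 0)
    stop("diaphragm amplitudes must be >= 0", call. = FALSE)
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  if (com_fraction < 0 || com_fraction > 1)
    stop("com_fraction must be in [0, 1]", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 n_phases = as.integer(n_phases),
                 diaphragm_amplitude_right_mm = diaphragm_amplitude_right_mm,
                 diaphragm_amplitude_left_mm = diaphragm_amplitude_left_mm,
                 com_fraction = com_fraction,
                 heart_fraction = heart_fraction,
                 noise_sigma = noise_sigma,
                 texture_amp = texture_amp,
                 edge_sigma_mm = edge_sigma_mm,
                 organ_geometry = organ_geometry,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default phantom organ geometry
#'
#' Ellipsoidal organ models in mm, laid out for a 192 x 192 x 240 mm field
#' of view: lungs superiorly with their bases (the diaphragm domes) at
#' z = 130 mm, the heart between the lungs, the liver under the right
#' dome and the stomach under the left. Intensities are T2W-like arbitrary
#' units with pairwise organ contrast of at least 50.
#'
#' @return named list of organ definitions (label, centre, semi-axes,
#'   intensity, motion class).
#' @export
default_organ_geometry <- function() {
  list(
    right_lung = list(label = 1L, center = c(55, 95, 180), semi = c(30, 34, 50),
                      intensity = 80, motion = "lung"),
    left_lung  = list(label = 2L, center = c(137, 95, 182), semi = c(28, 32, 48),
                      intensity = 80, motion = "lung"),
    heart      = list(label = 3L, center = c(98, 108, 140), semi = c(25, 23, 27),
                      intensity = 420, motion = "rigid"),
    liver      = list(label = 4L, center = c(58, 98, 78), semi = c(38, 36, 27),
                      intensity = 300, motion = "rigid"),
    stomach    = list(label = 5L, center = c(133, 102, 80), semi = c(21, 19, 23),
                      intensity = 520, motion = "rigid")
  )
}

# intensity of non-organ tissue / exterior air
.body_intensity <- 350
.air_intensity <- 20
.body_label <- 6L

#' Organ display order used throughout the package
#' @export
organ_names <- function() c("right_lung", "left_lung", "heart", "liver", "stomach")

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# full-amplitude SI excursion of each rigid organ (mm)
organ_peak_displacement <- function(config) {
  aR <- config$diaphragm_amplitude_right_mm
  aL <- config$diaphragm_amplitude_left_mm
  c(heart = config$heart_fraction * (aR + aL) / 2,
    liver = config$com_fraction * aR,
    stomach = config$com_fraction * aL)
}

# Full-amplitude SI motion scalar m(x) >= 0 (mm): lateral right/left blend
# times an SI envelope, with exact-constant capsule plateaus over each
# volume-conserving organ's swept range.
build_motion_scalar <- function(config) {
  d <- config$grid_shape
  co <- coord_arrays_mm(d, config$spacing_mm)
  aR <- config$diaphragm_amplitude_right_mm
  aL <- config$diaphragm_amplitude_left_mm
  fov_x <- (d[1] - 1) * config$spacing_mm[1]
  xmid <- fov_x / 2
  w <- 1 - smoothstep((co$x - (xmid - 15)) / 30)   # 1 on right, 0 on left
  A <- aR * w + aL * (1 - w)

  # SI envelope: plateau 1 around the domes, cosine decay to the apex,
  # com_fraction plateau over the abdominal organs, decay to 0 at the pelvis
  z <- co$z
  f <- config$com_fraction
  z_apex <- 230; z_pt <- 140; z_hi1 <- 125; z_hi0 <- 110; z_lo1 <- 45; z_lo0 <- 5
  e <- array(0, d)
  up <- z > z_pt
  e[up] <- 0.5 * (1 + cos(pi * pmin((z[up] - z_pt) / (z_apex - z_pt), 1)))
  mid <- z >= z_hi1 & z <= z_pt
  e[mid] <- 1
  tr <- z >= z_hi0 & z < z_hi1
  e[tr] <- f + (1 - f) * smoothstep((z[tr] - z_hi0) / (z_hi1 - z_hi0))
  ab <- z >= z_lo1 & z < z_hi0
  e[ab] <- f
  lo <- z >= z_lo0 & z < z_lo1
  e[lo] <- f * smoothstep((z[lo] - z_lo0) / (z_lo1 - z_lo0))
  m <- A * e

  # rigid-organ capsules: constant displacement over organ + swept range
  disp <- organ_peak_displacement(config)
  geom <- config$organ_geometry
  for (org in c("heart", "liver", "stomach")) {
    g <- geom[[org]]
    if (is.null(g) || !identical(g$motion, "rigid")) next
    d_o <- disp[[org]]
    xi <- co$z - pmin(pmax(co$z, g$center[3] - d_o), g$center[3])
    rho <- sqrt(((co$x - g$center[1]) / g$semi[1])^2 +
                ((co$y - g$center[2]) / g$semi[2])^2 +
                (xi / g$semi[3])^2)
    B <- smoothstep((1.30 - rho) / 0.24)
    m <- m * (1 - B) + d_o * B
  }
  m
}

#' Per-phase amplitude fractions of the respiratory cycle
#'
#' Phase 0 is full exhalation (fraction 0) and the last phase full
#' inhalation (fraction 1); intermediate phases follow a
#' `(1 - cos(pi * t)) / 2` profile of the phase fraction `t`.
#'
#' @param n_phases number of amplitude bins.
#' @return numeric vector of length `n_phases` in `[0, 1]`.
#' @export
phase_amplitudes <- function(n_phases) {
  if (n_phases == 1) return(0)
  (1 - cos(pi * (seq_len(n_phases) - 1) / (n_phases - 1))) / 2
}

#' Build the phantom anatomy and reference intensity volume
#'
#' Paints the body and the five organs as ellipsoids into an integer label
#' map (0 background, 1 right lung, 2 left lung, 3 heart, 4 liver,
#' 5 stomach, 6 other body), builds the noise-free reference (full
#' exhalation) intensity volume, and precomputes the full-amplitude motion
#' scalar field.
#'
#' @param config a [phantom_config()].
#' @return list of class `"irv_anatomy"` with elements `labels` (integer
#'   array), `reference` ([vol3d()] at phase 0), `motion_mm` (full-amplitude
#'   SI displacement array, mm), `config`, and `domes` (right/left dome
#'   voxel index and z position in mm).
#' @export
build_anatomy <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  sp <- config$spacing_mm
  co <- coord_arrays_mm(d, sp)
  fov <- (d - 1) * sp

  labels <- array(0L, d)
  body <- ((co$x - fov[1] / 2) / (0.45 * fov[1]))^2 +
          ((co$y - fov[2] / 2) / (0.41 * fov[2]))^2 <= 1
  labels[body] <- .body_label

  for (org in names(config$organ_geometry)) {
    g <- config$organ_geometry[[org]]
    inside <- ((co$x - g$center[1]) / g$semi[1])^2 +
              ((co$y - g$center[2]) / g$semi[2])^2 +
              ((co$z - g$center[3]) / g$semi[3])^2 <= 1
    if (sum(inside) < 100)
      stop(sprintf("grid too small to place organ '%s' (%d voxels)", org,
                   sum(inside)), call. = FALSE)
    if (any(inside & !body))
      stop(sprintf("organ '%s' extends outside the body outline", org),
           call. = FALSE)
    labels[inside] <- g$label
  }

  intens <- array(.air_intensity, d)
  intens[labels == .body_label] <- .body_intensity
  for (org in names(config$organ_geometry)) {
    g <- config$organ_geometry[[org]]
    intens[labels == g$label] <- g$intensity
  }
  if (config$edge_sigma_mm > 0)
    intens <- gaussian_smooth3(intens, config$edge_sigma_mm, sp)
  if (config$texture_amp > 0) {
    tex <- 1 + config$texture_amp *
      sin(2 * pi * co$x / 41) * sin(2 * pi * co$y / 37) * sin(2 * pi * co$z / 53)
    intens[labels > 0] <- intens[labels > 0] * tex[labels > 0]
  }

  domes <- list()
  for (side in c("right", "left")) {
    lung <- labels == config$organ_geometry[[paste0(side, "_lung")]]$label
    if (!any(lung)) stop("lung missing for dome localization", call. = FALSE)
    idx <- which(lung, arr.ind = TRUE)
    com_ij <- round(colMeans(idx[, 1:2, drop = FALSE]))
    col_z <- idx[idx[, 1] == com_ij[1] & idx[, 2] == com_ij[2], 3]
    if (length(col_z) == 0) col_z <- idx[, 3]
    k <- min(col_z)
    domes[[side]] <- list(voxel = c(com_ij, k),
                          z_mm = (k - 1) * sp[3])
  }

  structure(list(labels = labels,
                 reference = vol3d(intens, sp, phase = 0L),
                 motion_mm = build_motion_scalar(config),
                 domes = domes,
                 config = config),
            class = "irv_anatomy")
}

#' Extract one organ's ground-truth mask from the anatomy
#' @param anatomy an `"irv_anatomy"`.
#' @param organ organ name (see [organ_names()]).
#' @export
organ_mask <- function(anatomy, organ) {
  g <- anatomy$config$organ_geometry[[organ]]
  if (is.null(g)) stop("unknown organ: ", organ, call. = FALSE)
  mask3d(anatomy$labels == g$label, anatomy$config$spacing_mm,
         organ = organ, phase = 0L, source = "truth")
}

#' Analytic respiratory displacement field at a given amplitude
#'
#' Returns the pull-back displacement field from a target phase at
#' fractional amplitude `phase_amplitude` to the full-exhalation reference:
#' sampling the reference at `x + u(x)` renders the target phase. The SI
#' component at the right diaphragm dome equals
#' `phase_amplitude * diaphragm_amplitude_right_mm` exactly.
#'
#' @param config a [phantom_config()].
#' @param phase_amplitude fraction of full inhalation in `[0, 1]`.
#' @param anatomy optional precomputed [build_anatomy()] result (avoids
#'   rebuilding the motion scalar).
#' @return a [dvf3d()].
#' @export
analytic_motion_field <- function(config, phase_amplitude, anatomy = NULL) {
  if (!is.finite(phase_amplitude) || phase_amplitude < 0 || phase_amplitude > 1)
    stop("phase_amplitude must be in [0, 1]", call. = FALSE)
  m <- if (!is.null(anatomy)) anatomy$motion_mm else build_motion_scalar(config)
  zero <- array(0, dim(m))
  dvf3d(zero, zero, phase_amplitude * m, config$spacing_mm)
}

#' Render one respiratory phase of the phantom
#'
#' Warps the noise-free reference intensity by the phase displacement
#' field, adds Gaussian noise, and warps every organ label to produce the
#' phase's ground-truth masks (trilinear indicator warp thresholded at
#' 0.5, the same convention as [warp_mask()]).
#'
#' @param anatomy an `"irv_anatomy"`.
#' @param dvf phase displacement field ([dvf3d()]) on the anatomy grid.
#' @param noise_sigma intensity noise sd (0 for noise-free).
#' @param seed RNG seed for the noise realization.
#' @param phase phase index stored in the outputs.
#' @return list with `volume` ([vol3d()]) and `truth` (named organ masks +
#'   the `dvf` used).
#' @export
render_phase <- function(anatomy, dvf, noise_sigma = anatomy$config$noise_sigma,
                         seed = anatomy$config$seed, phase = NA_integer_) {
  assert_same_grid(anatomy$reference, dvf)
  warped <- warp_array(anatomy$reference$data, dvf)
  if (noise_sigma > 0) {
    noise <- withr::with_seed(derive_seed(seed, 577), {
      array(rnorm(length(warped), sd = noise_sigma), dim(warped))
    })
    warped <- warped + noise
  }
  masks <- list()
  for (org in names(anatomy$config$organ_geometry)) {
    g <- anatomy$config$organ_geometry[[org]]
    ref_mask <- mask3d(anatomy$labels == g$label, anatomy$config$spacing_mm,
                       organ = org, phase = as.integer(phase), source = "truth")
    masks[[org]] <- warp_mask(ref_mask, dvf)
    masks[[org]]$phase <- as.integer(phase)
  }
  list(volume = vol3d(warped, anatomy$config$spacing_mm,
                      phase = as.integer(phase)),
       truth = list(masks = masks, dvf = dvf))
}

#' Build the complete phantom subject
#'
#' Renders all `n_phases` amplitude-binned phases with their ground-truth
#' masks and displacement fields. Deterministic for a fixed config + seed.
#'
#' @param config a [phantom_config()].
#' @return list of class `"irv_phantom"`: `anatomy`, `amplitudes`,
#'   `phases` (list of [vol3d()]), `truth` (per-phase masks and fields).
#' @export
build_phantom <- function(config) {
  anatomy <- build_anatomy(config)
  amps <- phase_amplitudes(config$n_phases)
  phases <- vector("list", config$n_phases)
  truth <- vector("list", config$n_phases)
  for (p in seq_len(config$n_phases)) {
    dvf <- analytic_motion_field(config, amps[p], anatomy)
    r <- render_phase(anatomy, dvf, config$noise_sigma,
                      seed = derive_seed(config$seed, p), phase = p - 1L)
    phases[[p]] <- r$volume
    truth[[p]] <- r$truth
  }
  structure(list(anatomy = anatomy, amplitudes = amps, phases = phases,
                 truth = truth, config = config),
            class = "irv_phantom")
}

# deterministic sub-seed derivation (numeric or character parts), kept
# inside 32-bit integer range
derive_seed <- function(seed, ...) {
  parts <- list(seed, ...)
  s <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else
      sum(as.numeric(p))
    s <- (s * 7919 + v + 1) %% 2147483629
  }
  as.integer(s)
}
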