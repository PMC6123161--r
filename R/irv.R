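#' Internal organ-at-risk volume (IRV) from per-phase contours
#'
#' The IRV is the Boolean (OR) union of one organ's masks over all
#' respiratory phases. Its relative increase over the mean per-phase organ
#' volume, `%V = (IRV / Vbar - 1) * 100`, quantifies how much of the
#' surrounding space the moving organ sweeps. Phases where the organ is
#' absent (e.g. an outlier truncation) still contribute to the union and
#' are flagged rather than dropped.
#'
#' @param masks list of per-phase [mask3d()] for one organ, shared grid.
#' @param organ,source,subject optional provenance (defaults from the
#'   first mask's tags).
#' @return list of class `"irv4d_irv"`: `irv_mask`, `irv_volume_mm3`,
#'   `mean_organ_volume_mm3`, `increase_pct`, `phase_volumes_mm3`,
#'   `empty_phases`, provenance tags.
#' @export
compute_irv <- function(masks, organ = NULL, source = NULL, subject = NULL) {
  if (length(masks) < 1) stop("need at least one phase mask", call. = FALSE)
  for (m in masks[-1]) assert_same_grid(masks[[1]], m)
  v <- voxel_volume(masks[[1]])
  uni <- Reduce(`|`, lapply(masks, function(m) m$data))
  vols <- vapply(masks, function(m) sum(m$data) * v, numeric(1))
  irv_vol <- sum(uni) * v
  vbar <- mean(vols)
  ref <- masks[[1]]
  structure(list(
    irv_mask = mask3d(uni, ref$spacing, ref$origin,
                      organ = organ %||% ref$organ,
                      source = source %||% ref$source),
    irv_volume_mm3 = irv_vol,
    mean_organ_volume_mm3 = vbar,
    increase_pct = if (vbar > 0) 100 * (irv_vol / vbar - 1) else NA_real_,
    phase_volumes_mm3 = vols,
    empty_phases = which(vols == 0) - 1L,
    organ = organ %||% ref$organ, source = source %||% ref$source,
    subject = subject),
    class = "irv4d_irv")
}

#' @export
tidy.irv4d_irv <- function(x, ...) {
  tibble::tibble(phase = seq_along(x$phase_volumes_mm3) - 1L,
                 volume_mm3 = x$phase_volumes_mm3,
                 empty = (seq_along(x$phase_volumes_mm3) - 1L) %in% x$empty_phases)
}

#' @export
glance.irv4d_irv <- function(x, ...) {
  tibble::tibble(organ = x$organ %||% NA_character_,
                 source = x$source %||% NA_character_,
                 irv_volume_mm3 = x$irv_volume_mm3,
                 mean_organ_volume_mm3 = x$mean_organ_volume_mm3,
                 increase_pct = x$increase_pct,
                 n_phases = length(x$phase_volumes_mm3),
                 n_empty_phases = length(x$empty_phases))
}

#' @export
print.irv4d_irv <- function(x, ...) {
  cat(sprintf("<irv4d_irv>%s IRV %.0f mm^3, mean OAR %.0f mm^3, +%.1f%%\n",
              if (!is.null(x$organ)) paste0(" ", x$organ, ":") else "",
              x$irv_volume_mm3, x$mean_organ_volume_mm3, x$increase_pct))
  invisible(x)
}

#' Centre-of-mass trajectory across respiratory phases
#'
#' Voxel-centre centroid of each phase's mask in mm; the SI excursion is
#' the range (max - min) of the SI component over phases with a nonempty
#' mask. Empty phases produce an error entry rather than aborting.
#'
#' @param masks list of per-phase [mask3d()], shared grid.
#' @return list of class `"irv4d_trajectory"`: `trajectory` tibble
#'   (`phase`, `com_x/y/z_mm`, `error`), `si_excursion_mm`.
#' @export
com_trajectory <- function(masks) {
  for (m in masks[-1]) assert_same_grid(masks[[1]], m)
  rows <- lapply(seq_along(masks), function(p) {
    m <- masks[[p]]
    if (!any(m$data))
      return(tibble::tibble(phase = p - 1L, com_x_mm = NA_real_,
                            com_y_mm = NA_real_, com_z_mm = NA_real_,
                            error = "empty mask"))
    com <- mask_com(m)
    tibble::tibble(phase = p - 1L, com_x_mm = com[1], com_y_mm = com[2],
                   com_z_mm = com[3], error = NA_character_)
  })
  tr <- dplyr::bind_rows(rows)
  z <- tr$com_z_mm[is.na(tr$error)]
  structure(list(trajectory = tr,
                 si_excursion_mm = if (length(z) > 0) max(z) - min(z) else NA_real_),
            class = "irv4d_trajectory")
}

#' Diaphragm dome SI position and excursion from per-phase lung masks
#'
#' The dome is operationalized as the most inferior occupied slice of the
#' given lung within a 3x3 column of voxels around the lung's in-plane
#' centre of mass; its representative SI coordinate is the slice's z
#' position in mm. The excursion is the max - min dome position across
#' phases.
#'
#' @param lung_masks list of per-phase [mask3d()] of one lung.
#' @param side `"right"` or `"left"` (used in error messages).
#' @return list: `dome` tibble (`phase`, `dome_z_mm`), `range_mm`, `side`.
#' @export
diaphragm_excursion <- function(lung_masks, side = c("right", "left")) {
  side <- match.arg(side)
  rows <- lapply(seq_along(lung_masks), function(p) {
    m <- lung_masks[[p]]
    if (!any(m$data))
      stop(sprintf("empty %s lung mask at phase %d", side, p - 1L),
           call. = FALSE)
    idx <- which(m$data, arr.ind = TRUE)
    com_ij <- round(colMeans(idx[, 1:2, drop = FALSE]))
    near <- abs(idx[, 1] - com_ij[1]) <= 1 & abs(idx[, 2] - com_ij[2]) <= 1
    if (!any(near))
      stop(sprintf("vanishing %s lung dome column at phase %d", side, p - 1L),
           call. = FALSE)
    k <- min(idx[near, 3])
    tibble::tibble(phase = p - 1L,
                   dome_z_mm = m$origin[3] + (k - 1) * m$spacing[3])
  })
  dome <- dplyr::bind_rows(rows)
  list(dome = dome, range_mm = max(dome$dome_z_mm) - min(dome$dome_z_mm),
       side = side)
}
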