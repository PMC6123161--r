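#' Registration parameters for the free-form DIR solver
#'
#' @param lambda_smooth weight of the displacement smoothness penalty
#'   relative to the voxel-volume-weighted SSD data term.
#' @param n_levels multi-resolution pyramid depth; in-plane axes are
#'   downsampled by 2 per level, the slice axis only while at least 16
#'   slices would remain.
#' @param iters_per_level iteration cap, recycled across levels
#'   (coarsest first).
#' @param step_mm initial trust-region step: the maximum displacement
#'   update per accepted iteration, in mm.
#' @param stop_tol relative energy-decrease tolerance for convergence.
#' @param roi `"auto"` (bounding box of body voxels of the fixed image,
#'   excluding exterior air), `NULL` (whole grid) or a logical array.
#' @param presmooth_vox Gaussian pre-smoothing of both images at each
#'   level, in voxels.
#' @param grad_smooth_mm Sobolev preconditioning: the descent direction is
#'   the Gaussian-smoothed energy gradient at this scale (mm), which
#'   carries boundary forces into flat-intensity interiors; 0 disables.
#' @return list of class `"reg_params"`.
#' @export
reg_params <- function(lambda_smooth = 0.1, n_levels = 3, iters_per_level = 100,
                       step_mm = 2, stop_tol = 1e-4, roi = "auto",
                       presmooth_vox = 0.8, grad_smooth_mm = 16) {
  if (lambda_smooth < 0) stop("lambda_smooth must be >= 0", call. = FALSE)
  if (n_levels < 1) stop("n_levels must be >= 1", call. = FALSE)
  structure(list(lambda_smooth = lambda_smooth, n_levels = as.integer(n_levels),
                 iters_per_level = as.integer(iters_per_level),
                 step_mm = step_mm, stop_tol = stop_tol, roi = roi,
                 presmooth_vox = presmooth_vox, grad_smooth_mm = grad_smooth_mm),
            class = "reg_params")
}

# internal: trilinear warp of a plain array by a dvf3d (nearest-edge padding)
warp_array <- function(a, dvf) {
  d <- dim(a)
  out <- cpp_warp_trilinear(as.numeric(a), as.integer(d),
                            as.numeric(dvf$ux) / dvf$spacing[1],
                            as.numeric(dvf$uy) / dvf$spacing[2],
                            as.numeric(dvf$uz) / dvf$spacing[3])
  array(out, d)
}

# internal: trilinear sample of array `a` at 0-based voxel coords (vectors)
trilinear_sample <- function(a, qx, qy, qz) {
  d <- dim(a)
  qx <- pmin(pmax(qx, 0), d[1] - 1)
  qy <- pmin(pmax(qy, 0), d[2] - 1)
  qz <- pmin(pmax(qz, 0), d[3] - 1)
  x0 <- pmin(floor(qx), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(qy), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(qz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- 0
  if (d[2] == 1) y0 <- 0
  if (d[3] == 1) z0 <- 0
  fx <- qx - x0; fy <- qy - y0; fz <- qz - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  ix <- function(i, j, k) 1 + i + j * d[1] + k * d[1] * d[2]
  v <- as.numeric(a)
  c00 <- v[ix(x0, y0, z0)] * (1 - fx) + v[ix(x1, y0, z0)] * fx
  c10 <- v[ix(x0, y1, z0)] * (1 - fx) + v[ix(x1, y1, z0)] * fx
  c01 <- v[ix(x0, y0, z1)] * (1 - fx) + v[ix(x1, y0, z1)] * fx
  c11 <- v[ix(x0, y1, z1)] * (1 - fx) + v[ix(x1, y1, z1)] * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

#' Warp an intensity volume by a displacement field
#'
#' Output voxel `x` takes the value of the input at `x + u(x)` by trilinear
#' interpolation with nearest-edge padding.
#'
#' @param image a [vol3d()].
#' @param dvf a [dvf3d()] on the same grid.
#' @return a [vol3d()].
#' @export
warp_image <- function(image, dvf) {
  assert_same_grid(image, dvf)
  vol3d(warp_array(image$data, dvf), image$spacing, image$origin, image$phase)
}

#' Warp a binary mask by a displacement field
#'
#' The mask is warped as a real-valued indicator (trilinear interpolation)
#' and thresholded at 0.5; interpolated values exactly equal to 0.5 map to
#' foreground.
#'
#' @param mask a [mask3d()].
#' @param dvf a [dvf3d()] on the same grid.
#' @return a [mask3d()] carrying the input's provenance tags.
#' @export
warp_mask <- function(mask, dvf) {
  assert_same_grid(mask, dvf)
  w <- warp_array(mask$data + 0, dvf)
  mask3d(w >= 0.5, mask$spacing, mask$origin, organ = mask$organ,
         phase = mask$phase, source = mask$source, series = mask$series)
}

#' Free-form registration energy
#'
#' Voxel-volume-weighted sum-of-squared-differences data term over the
#' region of interest plus a smoothness penalty on the displacement
#' gradients, both in physical units:
#' `sum_roi (I_B(x+u) - I_A(x))^2 v + lambda * sum_i sum |grad u_i|^2 v`
#' with `v` the voxel volume in mm^3. Gradients use central differences,
#' out-of-bounds samples take the nearest-edge value.
#'
#' @param fixed,moving [vol3d()] volumes on a shared grid.
#' @param dvf candidate displacement field ([dvf3d()]).
#' @param lambda_smooth smoothness weight.
#' @param roi optional logical array restricting the data term.
#' @return scalar energy.
#' @export
dir_energy <- function(fixed, moving, dvf, lambda_smooth = 0.1, roi = NULL) {
  assert_same_grid(fixed, moving)
  assert_same_grid(fixed, dvf)
  if (!all(is.finite(dvf$ux)) || !all(is.finite(dvf$uy)) || !all(is.finite(dvf$uz)))
    stop("non-finite displacement field", call. = FALSE)
  v <- voxel_volume(fixed)
  r <- warp_array(moving$data, dvf) - fixed$data
  data_term <- if (is.null(roi)) sum(r^2) else sum(r[roi]^2)
  smooth_term <- 0
  if (lambda_smooth > 0) {
    d <- as.integer(dim(fixed$data))
    for (comp in list(dvf$ux, dvf$uy, dvf$uz)) {
      g <- cpp_gradient3(as.numeric(comp), d, fixed$spacing)
      smooth_term <- smooth_term + sum(g$gx^2) + sum(g$gy^2) + sum(g$gz^2)
    }
  }
  (data_term + lambda_smooth * smooth_term) * v
}

# auto ROI: bounding box of body voxels of the fixed image (excludes most
# exterior air), padded by 2 voxels
auto_roi <- function(fixed) {
  a <- fixed$data
  thr <- min(a) + 0.12 * (max(a) - min(a))
  body <- a > thr
  box <- mask_bbox(body)
  if (is.null(box)) return(NULL)
  bbox_to_mask(dilate_bbox(box, c(2L, 2L, 2L), dim(a)), dim(a))
}

# block downsample (smooth + stride 2 on selected axes)
downsample_level <- function(a, spacing, fac) {
  sig <- ifelse(fac > 1, 0.7 * spacing * fac, 0)
  s <- gaussian_smooth3(a, sig, spacing)
  d <- dim(a)
  ix <- lapply(1:3, function(ax) seq(1, d[ax], by = fac[ax]))
  s[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# iterated-box approximation of a Gaussian at sigma_mm (3 passes per axis)
box_smooth3 <- function(a, sigma_mm, spacing) {
  sv <- sigma_mm / spacing
  w <- ifelse(sv > 0.4, round(sqrt(4 * sv^2 + 1)), 1)
  w <- as.integer(w + (w %% 2 == 0))  # odd widths
  if (all(w <= 1)) return(a)
  array(cpp_box_smooth3(as.numeric(a), as.integer(dim(a)), w), dim(a))
}

# single-level energy-descent solver; returns u components + trace
solve_level <- function(IA, IB, spacing, u, lambda, roi, iters, step0, stop_tol,
                        grad_smooth_mm = 0) {
  d <- as.integer(dim(IA))
  v <- prod(spacing)
  no_roi <- logical(0)
  roi_l <- if (is.null(roi)) no_roi else as.logical(roi)
  energy_of <- function(w, uu) {
    sm <- 0
    if (lambda > 0)
      for (comp in uu)
        sm <- sm + cpp_grad_sq_sum(as.numeric(comp), d, spacing)
    (cpp_ssd(as.numeric(w), as.numeric(IA), roi_l) + lambda * sm) * v
  }
  warp_u <- function(uu)
    array(cpp_warp_trilinear(as.numeric(IB), d,
                             as.numeric(uu[[1]]) / spacing[1],
                             as.numeric(uu[[2]]) / spacing[2],
                             as.numeric(uu[[3]]) / spacing[3]), d)
  u_cur <- u
  w_cur <- warp_u(u_cur)
  E_cur <- energy_of(w_cur, u_cur)
  trace <- E_cur
  step <- step0
  converged <- FALSE
  for (it in seq_len(iters)) {
    g <- cpp_descent_force(as.numeric(w_cur), as.numeric(IA), roi_l,
                           as.numeric(u_cur[[1]]), as.numeric(u_cur[[2]]),
                           as.numeric(u_cur[[3]]), d, spacing, lambda)
    g <- lapply(g, array, dim = d)
    if (grad_smooth_mm > 0)
      g <- lapply(g, box_smooth3, sigma_mm = grad_smooth_mm,
                  spacing = spacing)
    gmax <- max(abs(g[[1]]), abs(g[[2]]), abs(g[[3]]))
    if (gmax < 1e-12) { converged <- TRUE; break }
    accepted <- FALSE
    for (try in 1:10) {
      sc <- step / gmax
      u_try <- list(u_cur[[1]] - sc * g[[1]],
                    u_cur[[2]] - sc * g[[2]],
                    u_cur[[3]] - sc * g[[3]])
      w_try <- warp_u(u_try)
      E_try <- energy_of(w_try, u_try)
      if (is.finite(E_try) && E_try <= E_cur) {
        rel <- (E_cur - E_try) / max(E_cur, 1e-12)
        u_cur <- u_try; w_cur <- w_try; E_cur <- E_try
        trace <- c(trace, E_cur)
        step <- min(step * 1.2, step0 * 4)
        accepted <- TRUE
        if (rel < stop_tol) converged <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-4) break
    }
    if (!accepted || converged) {
      if (!accepted) converged <- TRUE
      break
    }
  }
  list(u = u_cur, trace = trace, converged = converged)
}

#' Free-form intensity-based deformable registration
#'
#' Minimizes the SSD-plus-smoothness energy of [dir_energy()] by
#' multi-resolution energy-descent iterations: at each level the update
#' direction combines the intensity force
#' `(I_B(x+u) - I_A(x)) * grad I_B(x+u)` with the negative Laplacian of the
#' field weighted by `lambda_smooth`; a trial step is accepted only if the
#' energy does not increase, otherwise the step is halved. The returned
#' field lives on the fixed-image grid and maps fixed points into the
#' moving image, so masks defined on the moving (reference) frame can be
#' pulled onto the fixed frame with [warp_mask()].
#'
#' @param fixed,moving [vol3d()] volumes on a shared grid.
#' @param params a [reg_params()].
#' @param init optional initial [dvf3d()] (e.g. the previous phase's
#'   solution when sweeping a respiratory series).
#' @return list of class `"irv4d_registration"`: `dvf`, `energy_trace`
#'   (finest level, accepted iterations), `converged`, `levels_run`,
#'   `degenerate`.
#' @export
dir_register <- function(fixed, moving, params = reg_params(), init = NULL) {
  assert_same_grid(fixed, moving)
  if (!all(is.finite(fixed$data)) || !all(is.finite(moving$data)))
    stop("images must be finite", call. = FALSE)
  d <- dim(fixed$data)
  zero <- array(0, d)
  if (sd(as.numeric(fixed$data)) < 1e-12 && sd(as.numeric(moving$data)) < 1e-12) {
    warning("degenerate (constant) images: returning zero field")
    return(structure(list(dvf = dvf3d(zero, zero, zero, fixed$spacing, fixed$origin),
                          energy_trace = 0, converged = TRUE, levels_run = 0L,
                          degenerate = TRUE),
                     class = "irv4d_registration"))
  }

  roi_full <- if (identical(params$roi, "auto")) auto_roi(fixed)
              else if (is.array(params$roi)) params$roi else NULL

  # pyramid factors, coarsest first; z halved only while >= 16 slices remain
  facs <- vector("list", params$n_levels)
  facs[[params$n_levels]] <- c(1L, 1L, 1L)
  if (params$n_levels > 1) {
    for (l in seq(params$n_levels - 1, 1)) {
      f_finer <- facs[[l + 1]]
      f <- f_finer * c(2L, 2L, 1L)
      if (d[3] %/% f_finer[3] >= 32L) f[3] <- f_finer[3] * 2L
      facs[[l]] <- f
    }
  }

  iters <- rep(params$iters_per_level, length.out = length(facs))
  u <- NULL
  trace <- NULL
  converged <- FALSE
  for (li in seq_along(facs)) {
    f <- facs[[li]]
    IA <- downsample_level(fixed$data, fixed$spacing, f)
    IB <- downsample_level(moving$data, fixed$spacing, f)
    sp_l <- fixed$spacing * f
    if (params$presmooth_vox > 0) {
      IA <- gaussian_smooth3(IA, params$presmooth_vox * sp_l, sp_l)
      IB <- gaussian_smooth3(IB, params$presmooth_vox * sp_l, sp_l)
    }
    dl <- dim(IA)
    roi_l <- if (!is.null(roi_full)) {
      rl <- downsample_level(roi_full + 0, fixed$spacing, f) > 0.25
      if (!any(rl)) NULL else rl
    } else NULL

    if (is.null(u)) {
      if (!is.null(init)) {
        u <- lapply(list(init$ux, init$uy, init$uz), function(cmp)
          resample_to(cmp, d, dl))
      } else {
        u <- list(array(0, dl), array(0, dl), array(0, dl))
      }
    } else {
      u <- lapply(u, function(cmp) resample_to(cmp, dim(cmp), dl))
    }

    # at the finest level never start worse than the zero field
    if (li == length(facs)) {
      z3 <- list(array(0, dl), array(0, dl), array(0, dl))
      E_u <- level_energy(IA, IB, sp_l, u, params$lambda_smooth, roi_l)
      E_0 <- level_energy(IA, IB, sp_l, z3, params$lambda_smooth, roi_l)
      if (E_0 < E_u) u <- z3
    }

    res <- solve_level(IA, IB, sp_l, u, params$lambda_smooth, roi_l,
                       iters[li], params$step_mm, params$stop_tol,
                       params$grad_smooth_mm)
    u <- res$u
    if (li == length(facs)) {
      trace <- res$trace
      converged <- res$converged
    }
  }

  dvf <- dvf3d(u[[1]], u[[2]], u[[3]], fixed$spacing, fixed$origin)
  structure(list(dvf = dvf, energy_trace = trace, converged = converged,
                 levels_run = length(facs), degenerate = FALSE,
                 folding_fraction = mean(dvf_jacobian(dvf) <= 0)),
            class = "irv4d_registration")
}

# energy of a field at one pyramid level (helper shared with dir_register)
level_energy <- function(IA, IB, spacing, u, lambda, roi) {
  d <- as.integer(dim(IA))
  w <- array(cpp_warp_trilinear(as.numeric(IB), d,
                                as.numeric(u[[1]]) / spacing[1],
                                as.numeric(u[[2]]) / spacing[2],
                                as.numeric(u[[3]]) / spacing[3]), d)
  r <- w - IA
  data <- if (is.null(roi)) sum(r^2) else sum(r[roi]^2)
  sm <- 0
  if (lambda > 0)
    for (comp in u) {
      g <- cpp_gradient3(as.numeric(comp), d, spacing)
      sm <- sm + sum(g$gx^2) + sum(g$gy^2) + sum(g$gz^2)
    }
  (data + lambda * sm) * prod(spacing)
}

# resample a 3D array from its grid to a target dimension (same physical
# extent), used for pyramid transfers of displacement components
resample_to <- function(a, from_dim, to_dim) {
  from_dim <- dim(a)
  if (identical(from_dim, to_dim)) return(a)
  q <- lapply(1:3, function(ax) {
    if (to_dim[ax] == 1) return(rep(0, to_dim[ax]))
    (seq_len(to_dim[ax]) - 1) * (from_dim[ax] - 1) / (to_dim[ax] - 1)
  })
  qx <- array(q[[1]], to_dim)
  qy <- array(rep(q[[2]], each = to_dim[1]), to_dim)
  qz <- array(rep(q[[3]], each = to_dim[1] * to_dim[2]), to_dim)
  array(trilinear_sample(a, as.numeric(qx), as.numeric(qy), as.numeric(qz)),
        to_dim)
}

#' @export
glance.irv4d_registration <- function(x, ...) {
  tibble::tibble(converged = x$converged, degenerate = x$degenerate,
                 levels_run = x$levels_run,
                 folding_fraction = x$folding_fraction %||% 0,
                 n_accepted = length(x$energy_trace) - 1L,
                 initial_energy = x$energy_trace[1],
                 final_energy = x$energy_trace[length(x$energy_trace)])
}

#' Propagate reference contours through a respiratory series
#'
#' Registers every phase `p != 0` of the series (fixed = phase `p`,
#' moving = phase 0) and pulls the full-exhalation reference masks onto
#' each phase with the resulting field. Phase-0 masks pass through
#' unchanged. Registration of consecutive phases can be warm-started from
#' the previous phase's field.
#'
#' @param series list of [vol3d()] in phase order (element 1 = phase 0).
#' @param reference_masks named list of [mask3d()] on the phase-0 grid.
#' @param params a [reg_params()].
#' @param warm_start initialize each phase from the previous solution.
#' @return list of class `"irv4d_propagation"`: `masks` (per phase, named
#'   per organ, provenance `"auto"`), `registrations` (per-phase glance
#'   rows), `errors` (per-phase error messages or `NA`).
#' @export
propagate_contours <- function(series, reference_masks, params = reg_params(),
                               warm_start = TRUE) {
  stopifnot(length(series) >= 1)
  for (m in reference_masks) assert_same_grid(series[[1]], m)
  P <- length(series)
  out_masks <- vector("list", P)
  errors <- rep(NA_character_, P)
  glances <- vector("list", P)
  out_masks[[1]] <- lapply(reference_masks, function(m) {
    m$source <- "auto"; m$phase <- 0L; m
  })
  prev <- NULL
  for (p in seq_len(P)[-1]) {
    res <- tryCatch({
      # consecutive phases differ little, so once a solution exists the
      # sweep refines it at the finest level only
      p_use <- params
      if (warm_start && !is.null(prev)) {
        p_use$n_levels <- 1L
        p_use$iters_per_level <- utils::tail(rep(params$iters_per_level,
                                                 length.out = params$n_levels), 1)
      }
      reg <- dir_register(series[[p]], series[[1]], p_use,
                          init = if (warm_start) prev else NULL)
      prev <<- reg$dvf
      glances[[p]] <- glance(reg)
      lapply(reference_masks, function(m) {
        w <- warp_mask(m, reg$dvf)
        w$source <- "auto"; w$phase <- as.integer(p - 1L)
        w
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[p] <- conditionMessage(res)
    } else {
      out_masks[[p]] <- res
    }
  }
  structure(list(masks = out_masks,
                 registrations = dplyr::bind_rows(glances),
                 errors = errors),
            class = "irv4d_propagation")
}

#' Jacobian determinant of the deformation x -> x + u(x)
#'
#' Full 3x3 determinant from central-difference gradients of the field
#' components in physical units. Values <= 0 indicate folding.
#'
#' @param dvf a [dvf3d()].
#' @return array of determinants on the field grid.
#' @export
dvf_jacobian <- function(dvf) {
  d <- as.integer(dim(dvf$ux))
  g <- lapply(list(dvf$ux, dvf$uy, dvf$uz), function(cmp)
    cpp_gradient3(as.numeric(cmp), d, dvf$spacing))
  a11 <- 1 + g[[1]]$gx; a12 <- g[[1]]$gy; a13 <- g[[1]]$gz
  a21 <- g[[2]]$gx; a22 <- 1 + g[[2]]$gy; a23 <- g[[2]]$gz
  a31 <- g[[3]]$gx; a32 <- g[[3]]$gy; a33 <- 1 + g[[3]]$gz
  array(a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
          a13 * (a21 * a32 - a22 * a31), d)
}
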