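#' Simulated human rater profile
#'
#' A rater perturbs the true organ boundary with smooth spatially
#' correlated noise (Gaussian-filtered level-set perturbation, not i.i.d.
#' voxel flips -- human contouring errors are smooth), applies a
#' systematic in/out bias, and with a small probability produces a gross
#' outlier at the superior or inferior organ edge (truncation or
#' over-extension by at least two slices), the characteristic failure mode
#' of propagated contours.
#'
#' @param boundary_sigma_mm scale of the random boundary displacement
#'   (mm).
#' @param bias_mm systematic boundary offset; positive expands the
#'   contour.
#' @param outlier_rate probability in `[0, 1]` of a gross SI-edge flaw.
#' @param corr_mm spatial correlation length of the boundary noise.
#' @param edge_sigma_mm width of the smoothed indicator used as a
#'   level-set (controls how crisply the bias maps to mm).
#' @param seed RNG seed.
#' @return list of class `"rater_profile"`.
#' @export
rater_profile <- function(boundary_sigma_mm = 1.5, bias_mm = 0,
                          outlier_rate = 0, corr_mm = 12, edge_sigma_mm = 3,
                          seed = 1L) {
  if (boundary_sigma_mm < 0) stop("boundary_sigma_mm must be >= 0", call. = FALSE)
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must be in [0, 1]", call. = FALSE)
  structure(list(boundary_sigma_mm = boundary_sigma_mm, bias_mm = bias_mm,
                 outlier_rate = outlier_rate, corr_mm = corr_mm,
                 edge_sigma_mm = edge_sigma_mm, seed = as.integer(seed)),
            class = "rater_profile")
}

# gross SI-edge corruption: truncate or over-extend the most superior or
# inferior occupied slices by k >= 2 slices
corrupt_si_edge <- function(data, superior, extend, k) {
  occ <- which(apply(data, 3, any))
  if (length(occ) == 0) return(data)
  nz <- dim(data)[3]
  if (extend) {
    edge <- if (superior) max(occ) else min(occ)
    steps <- if (superior) seq_len(min(k, nz - edge)) else -seq_len(min(k, edge - 1))
    for (s in steps) data[, , edge + s] <- data[, , edge]
  } else {
    drop <- if (superior) tail(occ, k) else head(occ, k)
    data[, , drop] <- FALSE
  }
  data
}

#' Simulate a human delineation of a true organ mask
#'
#' @param true_mask a nonempty [mask3d()].
#' @param profile a [rater_profile()].
#' @param seed RNG seed (defaults to the profile's).
#' @param noise_field optional precomputed unit-sd correlated noise field
#'   shared across organs of one (rater, phase) sitting.
#' @return a [mask3d()] tagged `source = "manual"`.
#' @export
simulate_rater <- function(true_mask, profile, seed = profile$seed,
                           noise_field = NULL) {
  if (!any(true_mask$data)) stop("rater needs a non-empty mask", call. = FALSE)
  d <- dim(true_mask$data)
  out <- true_mask$data
  identity_profile <- profile$boundary_sigma_mm == 0 && profile$bias_mm == 0
  if (!identity_profile) {
    sm <- gaussian_smooth3(true_mask$data + 0, profile$edge_sigma_mm,
                           true_mask$spacing)
    if (profile$boundary_sigma_mm > 0) {
      if (is.null(noise_field))
        noise_field <- withr::with_seed(derive_seed(seed, 211L),
          smooth_noise_field(d, true_mask$spacing, profile$corr_mm))
      shift <- profile$bias_mm + profile$boundary_sigma_mm * noise_field
    } else {
      shift <- array(profile$bias_mm, d)
    }
    out <- sm >= pnorm(-shift / profile$edge_sigma_mm)
  }
  if (profile$outlier_rate > 0) {
    out <- withr::with_seed(derive_seed(seed, 409L), {
      if (runif(1) < profile$outlier_rate)
        corrupt_si_edge(out, superior = runif(1) < 0.5,
                        extend = runif(1) < 0.5, k = sample(2:3, 1))
      else out
    })
  }
  mask3d(out, true_mask$spacing, true_mask$origin, organ = true_mask$organ,
         phase = true_mask$phase, source = "manual", series = true_mask$series)
}

#' Calibrate a rater profile to a target contour quality
#'
#' Bisection on the boundary-noise scale so that the mean Jaccard overlap
#' between the simulated and true mask over `n_draws` seeded draws lands
#' inside the requested interval (contour quality is monotone decreasing
#' in the noise scale).
#'
#' @param true_mask reference [mask3d()] to contour.
#' @param target Jaccard interval to land in.
#' @param n_draws seeded draws averaged per candidate.
#' @param bias_mm,corr_mm,edge_sigma_mm passed to [rater_profile()].
#' @param seed base RNG seed.
#' @param max_iter bisection iterations.
#' @return list: calibrated `profile`, `achieved` mean Jaccard.
#' @export
calibrate_rater <- function(true_mask, target = c(0.88, 0.94), n_draws = 20,
                            bias_mm = 0, corr_mm = 12, edge_sigma_mm = 3,
                            seed = 1L, max_iter = 25) {
  mean_j <- function(sigma) {
    pr <- rater_profile(sigma, bias_mm, 0, corr_mm, edge_sigma_mm, seed)
    js <- vapply(seq_len(n_draws), function(i) {
      jaccard(simulate_rater(true_mask, pr, seed = derive_seed(seed, i)),
              true_mask)
    }, numeric(1))
    mean(js)
  }
  lo <- 0.05; hi <- 12
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    j <- mean_j(mid)
    if (j >= target[1] && j <= target[2]) {
      return(list(profile = rater_profile(mid, bias_mm, 0, corr_mm,
                                          edge_sigma_mm, seed),
                  achieved = j))
    }
    if (j > target[2]) lo <- mid else hi <- mid
  }
  stop("calibration failed to reach the target interval", call. = FALSE)
}
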