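#' Amplitude binning of a respiratory surrogate
#'
#' Bin edges divide the `[min, max]` range of a training prefix of the
#' trace (the acquisition's first seconds of breathing) into `n_bins`
#' equal amplitude intervals. Intervals are left-closed/right-open with
#' the top bin closed; samples outside the training range clamp to the
#' extreme bins. A value exactly on an interior edge goes to the higher
#' bin.
#'
#' @param values numeric surrogate samples.
#' @param n_bins number of amplitude bins (>= 2).
#' @param training samples defining the bin range (default: all of
#'   `values`).
#' @return integer bin index per sample, 0-based (`0 .. n_bins - 1`).
#' @export
amplitude_bin <- function(values, n_bins, training = values) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  tr <- training[is.finite(training)]
  if (length(tr) == 0) stop("no finite training samples", call. = FALSE)
  lo <- min(tr); hi <- max(tr)
  if (hi - lo <= 0)
    stop("degenerate binning: constant training trace", call. = FALSE)
  b <- floor((values - lo) / (hi - lo) * n_bins)
  as.integer(pmin(pmax(b, 0), n_bins - 1))
}

#' Simulate navigator and bellows respiratory surrogates
#'
#' Generates a slice-acquisition event stream over a quasi-periodic
#' breathing waveform. The navigator channel is the phantom's analytic
#' right diaphragm dome SI position (exact by construction); the bellows
#' channel is the same breathing fraction delayed by `bellows_lag_s`,
#' passed through a monotone amplitude distortion (`x^bellows_gamma`) and
#' perturbed with additive Gaussian noise. Acquisition continues (slices
#' cycled in an interleaved order) until every (slice, bin) cell of both
#' surrogates' binning tables is covered, emulating a guaranteed-fill
#' protocol.
#'
#' @param config a [phantom_config()].
#' @param period_s mean breathing period.
#' @param irregularity relative sd of per-cycle amplitude and period
#'   (0 gives strictly periodic breathing).
#' @param bellows_lag_s bellows phase lag in seconds.
#' @param bellows_noise additive noise sd on the normalized bellows signal.
#' @param bellows_gamma exponent of the monotone amplitude distortion.
#' @param dt_s time between slice-acquisition events.
#' @param training_s duration of the training prefix used to set bin
#'   edges.
#' @param seed RNG seed.
#' @param max_events acquisition cap before an unfillable-cell error.
#' @return list of class `"irv_surrogate_trace"`: `events` tibble
#'   (`time_s`, `slice`, `navigator_mm`, `depth_mm`, `bellows`,
#'   `nav_bin`, `bell_bin`), `n_bins`, `dome_z0_mm`,
#'   `bin_disagreement` (fraction of events whose two bins differ).
#' @export
simulate_surrogates <- function(config, period_s = 4, irregularity = 0.05,
                                bellows_lag_s = 1, bellows_noise = 0.02,
                                bellows_gamma = 1.3, dt_s = 0.18,
                                training_s = 10, seed = config$seed,
                                max_events = 2e5) {
  if (period_s <= 0) stop("period_s must be positive", call. = FALSE)
  n_bins <- config$n_phases
  nz <- config$grid_shape[3]
  aR <- config$diaphragm_amplitude_right_mm
  anatomy_dome <- 130  # analytic dome z at full exhalation (mm)

  # quasi-periodic breathing fraction in [0, ~1]: per-cycle amplitude and
  # period jitter; b(t) resolves the cycle containing t
  withr::with_seed(derive_seed(seed, 31L), {
    n_cyc <- ceiling(max_events * dt_s / (period_s * 0.5)) + 4
    amp_c <- pmax(0.3, 1 + irregularity * rnorm(n_cyc))
    per_c <- pmax(0.3 * period_s, period_s * (1 + irregularity * rnorm(n_cyc)))
    noise_b <- rnorm(max_events, sd = bellows_noise)
  })
  cyc_end <- cumsum(per_c)
  breath <- function(t) {
    ci <- findInterval(t, cyc_end) + 1
    t0 <- ifelse(ci == 1, 0, cyc_end[pmax(ci - 1, 1)])
    pmin(amp_c[ci] * (1 - cos(2 * pi * (t - t0) / per_c[ci])) / 2, 1.15)
  }

  # interleaved slice ordering (odd slices then even), repeated
  order1 <- c(seq(1, nz, by = 2), seq(2, nz, by = 2))

  grow <- 4 * nz * n_bins
  times <- slice <- depth <- bell <- numeric(0)
  nav_filled <- matrix(FALSE, nz, n_bins)
  bell_filled <- matrix(FALSE, nz, n_bins)
  edges_set <- FALSE
  n_ev <- 0
  repeat {
    if (n_ev >= max_events) {
      miss <- which(!(nav_filled & bell_filled), arr.ind = TRUE)[1, ]
      stop(sprintf("acquisition-coverage error: cell (slice %d, bin %d) unfillable",
                   miss[1], miss[2] - 1L), call. = FALSE)
    }
    k <- min(grow, max_events - n_ev)
    tt <- (n_ev + seq_len(k)) * dt_s
    sl <- order1[((n_ev + seq_len(k) - 1) %% nz) + 1]
    b_now <- breath(tt)
    b_lag <- breath(pmax(tt - bellows_lag_s, 0))
    dp <- aR * b_now
    bl <- b_lag^bellows_gamma + noise_b[n_ev + seq_len(k)]
    times <- c(times, tt); slice <- c(slice, sl)
    depth <- c(depth, dp); bell <- c(bell, bl)
    n_ev <- n_ev + k

    train_idx <- which(times <= training_s)
    if (length(train_idx) < 2) next
    if (n_bins >= 2) {
      nav_bin <- amplitude_bin(depth, n_bins, training = depth[train_idx])
      bell_bin <- amplitude_bin(bell, n_bins, training = bell[train_idx])
    } else {
      nav_bin <- bell_bin <- rep(0L, length(depth))
    }
    nav_filled[cbind(slice, nav_bin + 1)] <- TRUE
    bell_filled[cbind(slice, bell_bin + 1)] <- TRUE
    if (all(nav_filled) && all(bell_filled)) break
  }

  events <- tibble::tibble(time_s = times, slice = as.integer(slice),
                           navigator_mm = anatomy_dome - depth,
                           depth_mm = depth, bellows = bell,
                           nav_bin = nav_bin, bell_bin = bell_bin)
  structure(list(events = events, n_bins = n_bins,
                 dome_z0_mm = anatomy_dome,
                 bin_disagreement = mean(nav_bin != bell_bin)),
            class = "irv_surrogate_trace")
}

#' Assemble a reconstructed 4D series from rendered phases and a surrogate
#'
#' Fills the (slice, bin) table with the first acquisition event whose
#' chosen surrogate's bin matches, then stitches each output phase
#' slice-by-slice from the rendered phase matching the event's *navigator*
#' (true-amplitude) bin. With the navigator surrogate every slice comes
#' from its own phase (artifact-free); with the lagged bellows surrogate a
#' fraction of slices is taken from the wrong phase, creating the
#' through-plane discontinuities of surrogate mis-binning.
#'
#' @param phantom an `"irv_phantom"` from [build_phantom()].
#' @param trace an `"irv_surrogate_trace"`.
#' @param surrogate `"navigator"` or `"bellows"`.
#' @return list of class `"irv_series"`: `volumes` (per-phase [vol3d()]),
#'   `masks` (per phase, named per organ: apparent ground-truth masks of
#'   the stitched series), `provenance` (nz x n_bins matrix of source
#'   phases), `misbin_fraction`, `surrogate`.
#' @export
assemble_series <- function(phantom, trace, surrogate = c("navigator", "bellows")) {
  surrogate <- match.arg(surrogate)
  n_bins <- phantom$config$n_phases
  if (trace$n_bins != n_bins)
    stop("trace bin count does not match the phantom", call. = FALSE)
  nz <- phantom$config$grid_shape[3]
  ev <- trace$events
  key_bin <- if (surrogate == "navigator") ev$nav_bin else ev$bell_bin

  source_phase <- matrix(NA_integer_, nz, n_bins)
  for (i in seq_len(nrow(ev))) {
    s <- ev$slice[i]; b <- key_bin[i] + 1L
    if (is.na(source_phase[s, b])) source_phase[s, b] <- ev$nav_bin[i]
  }
  if (anyNA(source_phase)) {
    miss <- which(is.na(source_phase), arr.ind = TRUE)[1, ]
    stop(sprintf("acquisition-coverage error: cell (slice %d, bin %d) unfillable",
                 miss[1], miss[2] - 1L), call. = FALSE)
  }

  organs <- names(phantom$config$organ_geometry)
  sp <- phantom$config$spacing_mm
  volumes <- vector("list", n_bins)
  masks <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    vdat <- phantom$phases[[b]]$data
    mdat <- lapply(organs, function(o) phantom$truth[[b]]$masks[[o]]$data)
    names(mdat) <- organs
    for (s in seq_len(nz)) {
      src <- source_phase[s, b] + 1L
      if (src != b) {
        vdat[, , s] <- phantom$phases[[src]]$data[, , s]
        for (o in organs)
          mdat[[o]][, , s] <- phantom$truth[[src]]$masks[[o]]$data[, , s]
      }
    }
    volumes[[b]] <- vol3d(vdat, sp, phase = b - 1L)
    masks[[b]] <- lapply(organs, function(o)
      mask3d(mdat[[o]], sp, organ = o, phase = b - 1L, source = "truth",
             series = surrogate))
    names(masks[[b]]) <- organs
  }
  misbin <- mean(source_phase != matrix(0:(n_bins - 1), nz, n_bins, byrow = TRUE))
  structure(list(volumes = volumes, masks = masks,
                 provenance = source_phase, misbin_fraction = misbin,
                 surrogate = surrogate),
            class = "irv_series")
}
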