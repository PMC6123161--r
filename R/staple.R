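#' Binary STAPLE consensus over multiple contour sets
#'
#' Expectation-maximization estimate of the latent true segmentation and of
#' each rater's sensitivity `p_j` / specificity `q_j` from two or more
#' binary masks. The E-step computes the per-voxel posterior probability of
#' true foreground
#' `W = a / (a + b)` with
#' `a = pi * prod_j p_j^d_j (1-p_j)^(1-d_j)` and
#' `b = (1-pi) * prod_j (1-q_j)^d_j q_j^(1-d_j)`;
#' the M-step re-estimates
#' `p_j = sum(W d_j)/sum(W)` and `q_j = sum((1-W)(1-d_j))/sum(1-W)`.
#' Iterations stop when the maximum absolute posterior change falls below
#' `tol` or after `max_iter` E-steps. Rater performances are clamped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' The computation is restricted to an evaluation domain (by default the
#' bounding box of the union of the input masks dilated by 10 voxels
#' in-plane and 2 slices); the posterior is zero outside it.
#'
#' @param masks list of at least two [mask3d()] on a shared grid.
#' @param prior_pi spatially constant foreground prior; default the mean
#'   foreground fraction of the input masks within the domain.
#' @param init_p,init_q initial sensitivities/specificities.
#' @param tol convergence tolerance on the maximum posterior change.
#' @param max_iter iteration cap.
#' @param domain optional logical array evaluation domain.
#' @param confidence threshold of the consensus mask (S95 uses 0.95).
#' @return list of class `"irv4d_staple"`: `posterior` (array), `s95`
#'   ([mask3d()] of voxels with posterior >= `confidence`), `performances`
#'   (tibble with `rater`, `sensitivity_p`, `specificity_q`),
#'   `n_iterations`, `converged`, `prior_pi`, `domain`.
#' @export
staple <- function(masks, prior_pi = NULL, init_p = 0.99, init_q = 0.99,
                   tol = 1e-6, max_iter = 100, domain = NULL,
                   confidence = 0.95) {
  if (length(masks) < 2) stop("need at least two contour sets", call. = FALSE)
  for (m in masks[-1]) assert_same_grid(masks[[1]], m)
  dgrid <- dim(masks[[1]]$data)
  if (!any(vapply(masks, function(m) any(m$data), TRUE)))
    stop("degenerate input: all masks are empty", call. = FALSE)

  if (is.null(domain)) {
    uni <- Reduce(`|`, lapply(masks, function(m) m$data))
    domain <- bbox_to_mask(dilate_bbox(mask_bbox(uni), c(10L, 10L, 2L), dgrid),
                           dgrid)
  }
  idx <- which(domain)
  J <- length(masks)
  D <- vapply(masks, function(m) as.numeric(m$data[idx]), numeric(length(idx)))
  D <- matrix(D, ncol = J)

  eps <- 1e-6
  clamp01 <- function(x) pmin(pmax(x, eps), 1 - eps)
  pi0 <- if (is.null(prior_pi)) mean(D) else prior_pi
  pi0 <- clamp01(pi0)
  p <- rep(init_p, J)
  q <- rep(init_q, J)

  W_old <- NULL
  converged <- FALSE
  n_it <- 0L
  for (it in seq_len(max_iter)) {
    n_it <- it
    la <- log(pi0) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - pi0) + D %*% log(1 - q) + (1 - D) %*% log(q)
    a <- exp(la); b <- exp(lb)
    W <- as.numeric(a / (a + b))
    if (!is.null(W_old) && max(abs(W - W_old)) < tol) {
      converged <- TRUE
      break
    }
    W_old <- W
    sw <- sum(W); swc <- sum(1 - W)
    p <- clamp01(colSums(W * D) / max(sw, eps))
    q <- clamp01(colSums((1 - W) * (1 - D)) / max(swc, eps))
  }

  posterior <- array(0, dgrid)
  posterior[idx] <- W
  ref <- masks[[1]]
  s95 <- mask3d(posterior >= confidence, ref$spacing, ref$origin,
                organ = ref$organ, phase = ref$phase, source = "s95",
                series = ref$series)
  raters <- vapply(seq_along(masks), function(j) {
    s <- masks[[j]]$source
    if (is.null(s)) paste0("rater", j) else paste0(s, j)
  }, character(1))
  structure(list(posterior = posterior, s95 = s95,
                 performances = tibble::tibble(rater = raters,
                                               sensitivity_p = p,
                                               specificity_q = q),
                 n_iterations = n_it, converged = converged,
                 prior_pi = pi0, domain = domain),
            class = "irv4d_staple")
}

#' Threshold a STAPLE posterior at a confidence level
#'
#' @param posterior an `"irv4d_staple"` result or a probability array in
#'   `[0, 1]`.
#' @param confidence inclusion threshold; voxels with posterior >=
#'   `confidence` are foreground (`confidence = 0.95` gives the S95 mask).
#' @param spacing,origin grid geometry when `posterior` is a bare array.
#' @return a [mask3d()].
#' @export
s95_threshold <- function(posterior, confidence = 0.95,
                          spacing = c(2, 2, 5), origin = c(0, 0, 0)) {
  if (inherits(posterior, "irv4d_staple")) {
    s <- posterior$s95
    return(mask3d(posterior$posterior >= confidence, s$spacing, s$origin,
                  organ = s$organ, phase = s$phase, source = "s95",
                  series = s$series))
  }
  if (any(posterior < 0 | posterior > 1))
    stop("posterior must lie in [0, 1]", call. = FALSE)
  mask3d(posterior >= confidence, spacing, origin, source = "s95")
}

#' @export
tidy.irv4d_staple <- function(x, ...) x$performances

#' @export
glance.irv4d_staple <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations, converged = x$converged,
                 prior_pi = x$prior_pi,
                 consensus_voxels = sum(x$s95$data),
                 domain_voxels = sum(x$domain))
}

#' @export
print.irv4d_staple <- function(x, ...) {
  cat(sprintf("<irv4d_staple> %d raters, %d EM iterations%s, consensus %d voxels\n",
              nrow(x$performances), x$n_iterations,
              if (x$converged) " (converged)" else "", sum(x$s95$data)))
  invisible(x)
}
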