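# Brute-force scalar-loop STAPLE EM used as the independent oracle.
# Iterates the same two formulas as the package implementation but voxel
# by voxel and rater by rater, with no vectorization or shared code.
staple_oracle <- function(bits, prior_pi = NULL, init_p = 0.99, init_q = 0.99,
                          tol = 1e-6, max_iter = 100) {
  J <- length(bits)
  n <- length(bits[[1]])
  eps <- 1e-6
  clamp <- function(x) min(max(x, eps), 1 - eps)
  if (is.null(prior_pi)) {
    tot <- 0
    for (j in 1:J) for (i in 1:n) tot <- tot + bits[[j]][i]
    prior_pi <- tot / (J * n)
  }
  prior_pi <- clamp(prior_pi)
  p <- rep(init_p, J)
  q <- rep(init_q, J)
  W_old <- NULL
  W <- numeric(n)
  for (it in 1:max_iter) {
    for (i in 1:n) {
      a <- prior_pi
      b <- 1 - prior_pi
      for (j in 1:J) {
        d <- bits[[j]][i]
        a <- a * (if (d == 1) p[j] else 1 - p[j])
        b <- b * (if (d == 1) 1 - q[j] else q[j])
      }
      W[i] <- a / (a + b)
    }
    if (!is.null(W_old)) {
      dmax <- 0
      for (i in 1:n) dmax <- max(dmax, abs(W[i] - W_old[i]))
      if (dmax < tol) break
    }
    W_old <- W
    sw <- sum(W)
    swc <- n - sw
    for (j in 1:J) {
      num_p <- 0; num_q <- 0
      for (i in 1:n) {
        num_p <- num_p + W[i] * bits[[j]][i]
        num_q <- num_q + (1 - W[i]) * (1 - bits[[j]][i])
      }
      p[j] <- clamp(num_p / max(sw, eps))
      q[j] <- clamp(num_q / max(swc, eps))
    }
  }
  list(W = W, p = p, q = q)
}

# wrap 0/1 vectors as 1-D masks on a shared n x 1 x 1 grid
line_masks <- function(...) {
  lapply(list(...), function(b)
    mask3d(array(b == 1, c(length(b), 1, 1)), c(1, 1, 1)))
}

full_domain <- function(n) array(TRUE, c(n, 1, 1))
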