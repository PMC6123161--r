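test_that("unanimous raters yield their mask with near-perfect performance", {
  ms <- line_masks(c(0, 1, 1, 1, 0, 0, 0, 0), c(0, 1, 1, 1, 0, 0, 0, 0),
                   c(0, 1, 1, 1, 0, 0, 0, 0))
  s <- staple(ms, domain = full_domain(8))
  expect_identical(s$s95$data, ms[[1]]$data)
  expect_true(all(s$performances$sensitivity_p > 0.999))
  expect_true(all(s$performances$specificity_q > 0.999))
  expect_true(s$converged)
})

test_that("empty and mismatched inputs are rejected", {
  m <- line_masks(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_error(staple(m), "empty")
  a <- line_masks(c(1, 0))[[1]]
  b <- mask3d(array(TRUE, c(3, 1, 1)), c(1, 1, 1))
  expect_error(staple(list(a, b)), "grid mismatch")
  expect_error(staple(line_masks(c(1, 0))), "at least two")
})

test_that("the EM matches the brute-force oracle on the 3-rater toy case", {
  bits <- list(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
               c(0, 1, 1, 1, 1, 1, 0, 0, 0, 0),
               c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  s <- staple(do.call(line_masks, bits), prior_pi = 0.5, init_p = 0.9,
              init_q = 0.9, domain = full_domain(10))
  o <- staple_oracle(bits, prior_pi = 0.5, init_p = 0.9, init_q = 0.9)
  expect_equal(as.numeric(s$posterior), o$W, tolerance = 1e-12)
  expect_equal(s$performances$sensitivity_p, o$p, tolerance = 1e-12)
  expect_equal(s$performances$specificity_q, o$q, tolerance = 1e-12)
})

test_that("posterior is monotone along an inclusion of raters", {
  # one mask strictly inside the other: consensus must favour the
  # intersection over the symmetric difference
  bits <- list(c(0, 1, 1, 1, 1, 1, 1, 0, 0, 0),
               c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  s <- staple(do.call(line_masks, bits), domain = full_domain(10))
  W <- as.numeric(s$posterior)
  inter <- bits[[1]] == 1 & bits[[2]] == 1
  symdiff <- xor(bits[[1]] == 1, bits[[2]] == 1)
  expect_gt(min(W[inter]), max(W[symdiff]))
  o <- staple_oracle(bits)
  expect_equal(W, o$W, tolerance = 1e-12)
})

test_that("rater order does not change the consensus", {
  bits <- list(c(1, 1, 1, 1, 0, 0, 0, 0), c(0, 1, 1, 1, 1, 0, 0, 0),
               c(1, 1, 0, 1, 0, 0, 1, 0))
  s1 <- staple(do.call(line_masks, bits), domain = full_domain(8))
  s2 <- staple(do.call(line_masks, rev(bits)), domain = full_domain(8))
  expect_equal(s1$posterior, s2$posterior, tolerance = 1e-12)
  expect_identical(s1$s95$data, s2$s95$data)
  expect_equal(s1$performances$sensitivity_p,
               rev(s2$performances$sensitivity_p), tolerance = 1e-12)
})

test_that("duplicating a rater pulls the posterior toward that rater", {
  bits <- list(c(1, 1, 1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 1, 1, 0, 0))
  w2 <- staple_oracle(bits)$W
  w3 <- staple_oracle(c(bits, bits[1]))$W
  on <- bits[[1]] == 1
  expect_true(all(w3[on] >= w2[on] - 1e-12))
  expect_true(all(w3[!on] <= w2[!on] + 1e-12))
  # and the vectorized implementation agrees with the oracle
  s3 <- staple(do.call(line_masks, c(bits, bits[1])), domain = full_domain(8))
  expect_equal(as.numeric(s3$posterior), w3, tolerance = 1e-12)
})

test_that("thresholding behaves at the boundaries", {
  post <- array(0, c(6, 1, 1)); post[2:4] <- 1
  m <- s95_threshold(post, 0.95, spacing = c(1, 1, 1))
  expect_identical(which(m$data), 2:4)
  expect_equal(sum(s95_threshold(array(0.94, c(5, 1, 1)), 0.95)$data), 0)
  expect_equal(sum(s95_threshold(array(0.3, c(5, 1, 1)), 0)$data), 5)
  expect_error(s95_threshold(array(1.4, c(2, 1, 1))), "posterior")
})

test_that("the default evaluation domain restricts the computation", {
  # masks far from the grid corner: the domain excludes remote background,
  # so the background prior reflects the local neighbourhood
  big <- array(FALSE, c(40, 40, 10))
  big[10:20, 10:20, 4:6] <- TRUE
  m1 <- mask3d(big, c(1, 1, 1))
  big2 <- big; big2[21, 10:20, 4:6] <- TRUE
  m2 <- mask3d(big2, c(1, 1, 1))
  s <- staple(list(m1, m2))
  expect_lt(sum(s$domain), length(big))
  expect_true(all((m1$data | m2$data)[!s$domain] == FALSE))
  expect_true(all(s$posterior[!s$domain] == 0))
})
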