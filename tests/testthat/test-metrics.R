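line_mask <- function(idx, n = 12) {
  d <- array(FALSE, c(n, 1, 1)); d[idx] <- TRUE
  mask3d(d, c(1, 1, 1))
}

test_that("jaccard handles identity, disjoint and counted-by-hand cases", {
  A <- line_mask(1:4); B <- line_mask(3:6)
  expect_equal(jaccard(A, A), 1)
  expect_equal(jaccard(A, line_mask(7:9)), 0)
  expect_equal(jaccard(A, B), 2 / 6)
  expect_equal(jaccard(A, B), jaccard(B, A))
  empty <- line_mask(integer(0))
  expect_equal(jaccard(empty, empty), 1)
})

test_that("sensitivity and specificity match the enumerated example", {
  G <- line_mask(1:4); D <- line_mask(3:6)
  expect_equal(sensitivity(D, G), 0.5)
  dom <- array(TRUE, c(12, 1, 1))
  expect_equal(specificity(D, G, dom), 6 / 8)
  expect_equal(sensitivity(G, G), 1)
  expect_equal(specificity(G, G, dom), 1)
  # over-segmentation: D contains G
  D2 <- line_mask(1:6)
  expect_equal(sensitivity(D2, G), 1)
  expect_lt(specificity(D2, G, dom), 1)
  expect_error(sensitivity(D, line_mask(integer(0))), "empty reference")
  expect_error(specificity(D, G, array(FALSE, c(12, 1, 1))), "domain")
})

test_that("jaccard never exceeds sensitivity and metrics ignore padding", {
  set.seed(42)
  for (i in 1:20) {
    D <- line_mask(sample(1:12, sample(1:8, 1)))
    G <- line_mask(sample(1:12, sample(1:8, 1)))
    if (sum(G$data) == 0) next
    expect_lte(jaccard(D, G), sensitivity(D, G))
  }
  # padding the grid outside the evaluation domain leaves metrics unchanged
  D <- line_mask(3:6, 12); G <- line_mask(1:4, 12)
  Dp <- line_mask(3:6, 30); Gp <- line_mask(1:4, 30)
  dom <- array(c(rep(TRUE, 12), rep(FALSE, 18)), c(30, 1, 1))
  expect_equal(jaccard(D, G), jaccard(Dp, Gp))
  expect_equal(specificity(D, G, array(TRUE, c(12, 1, 1))),
               specificity(Dp, Gp, dom))
})

test_that("volume variation implements SD/mean x 100 with sample SD", {
  expect_equal(volume_variation_pct(c(100, 100, 100)), 0)
  expect_equal(volume_variation_pct(c(98, 100, 102)), 2)
  expect_error(volume_variation_pct(100), "two")
  expect_error(volume_variation_pct(c(-2, 0, 2)), "positive")
})

test_that("inter-observer similarity difference is signed and antisymmetric", {
  expect_equal(similarity_relative_diff_pct(0.9, 0.9), 0)
  expect_equal(similarity_relative_diff_pct(0.9, 0.8), 200 * 0.1 / 1.7)
  expect_equal(similarity_relative_diff_pct(0.8, 0.9),
               -similarity_relative_diff_pct(0.9, 0.8))
  expect_error(similarity_relative_diff_pct(0, 0), "positive")
})

test_that("paired t-test applies the documented degenerate rules", {
  a <- c(1, 2, 3, 4)
  tie <- paired_t_test(a, a)
  expect_equal(tie$p, 1); expect_equal(tie$flag, "tie")
  sh <- paired_t_test(a, a + 1)
  expect_equal(sh$p, 0); expect_true(is.infinite(sh$t))
  expect_equal(sh$flag, "zero-variance-shift")

  x <- c(0.91, 0.92, 0.90, 0.94); y <- c(0.89, 0.93, 0.88, 0.92)
  res <- paired_t_test(x, y)
  # hand computation: d = (0.02, -0.01, 0.02, 0.02), mean 0.0125, sd 0.015
  expect_equal(res$t, 0.0125 / (0.015 / 2), tolerance = 1e-9)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * stats::pt(-0.0125 / (0.015 / 2), 3), tolerance = 1e-9)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("column summaries use half-up rounding and drop missing cells", {
  cs <- column_summary(c(rep(4.25, 3)), decimals = 1)
  expect_equal(cs$sd, 0)
  expect_equal(cs$mean_rounded, 4.3)   # half-up, not half-even
  cs2 <- column_summary(c(1.5, NA, 2.5, 3.5), decimals = 1)
  expect_equal(cs2$n, 3)
  expect_equal(cs2$mean, 2.5)
  expect_error(column_summary(c(1, NA)), "two")
})

test_that("sss_record carries provenance tags through", {
  G <- line_mask(1:4); D <- line_mask(3:6)
  D$organ <- "liver"; D$phase <- 3L; D$source <- "auto-U1"; D$series <- "navigator"
  rec <- sss_record(D, G, domain = array(TRUE, c(12, 1, 1)))
  expect_equal(rec$organ, "liver")
  expect_equal(rec$phase, 3L)
  expect_equal(rec$jaccard, 2 / 6)
  expect_equal(rec$specificity, 6 / 8)
})
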