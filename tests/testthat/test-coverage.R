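test_that("bimodal GMM recovers generating parameters", {
  set.seed(1)
  px <- c(rnorm(70000, 25, 5), rnorm(30000, 180, 12))
  fit <- fit_bimodal_gmm(px, seed = 1)
  fg <- fit[fit$foreground, ]
  bg <- fit[!fit$foreground, ]
  expect_lt(abs(fg$mean - 180), 2)
  expect_lt(abs(fg$sd - 12), 2)
  expect_lt(abs(bg$mean - 25), 2)
  expect_equal(sum(fit$weight), 1, tolerance = 1e-6)
  expect_true(all(fit$sd > 0))
})

test_that("two-valued and degenerate inputs are handled", {
  img <- matrix(rep(c(0, 255), each = 200), 20, 20)
  fit <- fit_bimodal_gmm(img)
  expect_equal(sort(fit$mean), c(0, 255), tolerance = 1e-6)
  expect_equal(fit$mean[fit$foreground], 255)
  expect_error(fit_bimodal_gmm(matrix(7, 20, 20)), "degenerate")
  expect_error(fit_bimodal_gmm(rep(1, 50)), "at least 100")
})

test_that("threshold cutoff is mu_fg + lambda * sigma_fg and monotone", {
  fit <- tibble::tibble(component = 1:2, mean = c(25, 180), sd = c(5, 12),
                        weight = c(0.7, 0.3),
                        foreground = c(FALSE, TRUE))
  class(fit) <- c("gmm_fit", class(fit))
  img <- matrix(seq(0, 255, length.out = 256), 16, 16)
  # lambda = 0: cutoff exactly mu_fg
  expect_equal(threshold_foreground(img, fit, 0), img >= 180)
  # lambda = 1: cutoff 180 + 12 = 192
  expect_equal(threshold_foreground(img, fit, 1), img >= 192)
  # monotone in lambda for arbitrary images
  set.seed(2)
  rimg <- matrix(rnorm(400, 100, 60), 20, 20)
  n <- sapply(c(-1, 0, 1), function(l) sum(threshold_foreground(rimg, fit, l)))
  expect_true(n[1] >= n[2] && n[2] >= n[3])
})

test_that("coverage fraction is cell area over well area", {
  b <- well_boundary("circle", c(32.5, 32.5), 25, 25, 2, c(64, 64))
  expect_equal(compute_coverage(matrix(FALSE, 64, 64), b)$fraction, 0)
  expect_equal(compute_coverage(b$mask, b)$fraction, 1)
  half <- b$mask & col(b$mask) <= 32
  fr <- compute_coverage(half, b)$fraction
  expect_lt(abs(fr - 0.5), 0.02)
  expect_error(compute_coverage(matrix(FALSE, 32, 32), b), "dimensions")
})

test_that("coverage pipeline recovers fixture fractions", {
  for (f in c(0, 0.25, 0.5, 1)) {
    fx <- make_well_fixture(f, size = 256, seed = 7)
    cov <- analyze_coverage(fx$image, fx$boundary, lambda = -3)
    expect_lt(abs(cov$fraction - fx$true_fraction), 0.03)
    expect_gte(cov$fraction, 0)
    expect_lte(cov$fraction, 1)
  }
})

test_that("coverage is invariant under affine intensity rescaling", {
  fx <- make_well_fixture(0.4, size = 256, seed = 3)
  c1 <- analyze_coverage(fx$image, fx$boundary, lambda = -3)
  c2 <- analyze_coverage(2.4 * fx$image + 120, fx$boundary, lambda = -3)
  expect_equal(c1$fraction, c2$fraction, tolerance = 0.01)
})
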