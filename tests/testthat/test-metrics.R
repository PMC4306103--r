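# Similarity metrics and the before/after verdict

test_that("identical images give the degenerate metric values", {
  img <- blob_image(32, 32)
  m <- compute_metrics(img, img, mi_bins = 32)
  expect_equal(m$rms, 0)
  expect_identical(m$psnr, Inf)
  expect_equal(m$cor, 1)
  # MI(A, A) equals the marginal entropy at the same binning
  idx <- pmin(floor(img * 32) + 1, 32)
  p <- tabulate(idx, 32) / length(idx)
  p <- p[p > 0]
  expect_equal(m$mi, -sum(p * log2(p)), tolerance = 1e-9)
})

test_that("PSNR follows 20*log10(1/RMS) exactly", {
  ref <- matrix(0, 10, 10)
  other <- matrix(0.1, 10, 10)
  m <- compute_metrics(ref, other, mi_bins = 16)
  expect_equal(m$rms, 0.1, tolerance = 1e-15)
  expect_equal(m$psnr, 20, tolerance = 1e-12)
  set.seed(2)
  for (k in 1:20) {
    a <- matrix(runif(256), 16, 16)
    b <- matrix(runif(256), 16, 16)
    m <- compute_metrics(a, b, mi_bins = 16)
    expect_equal(m$psnr, 20 * log10(1 / m$rms), tolerance = 1e-9)
  }
})

test_that("correlation is invariant under affine intensity maps", {
  set.seed(3)
  a <- matrix(runif(400), 20, 20)
  b <- matrix(runif(400), 20, 20)
  c0 <- compute_metrics(a, b, 16)$cor
  c1 <- cor(as.numeric(0.25 * a + 0.3), as.numeric(b))
  expect_equal(c0, c1, tolerance = 1e-9)
  flat <- compute_metrics(matrix(0.5, 20, 20), b, 16)
  expect_equal(flat$cor, 0)
  expect_true(flat$constant_image)
})

test_that("mutual information is symmetric and vanishes for independence", {
  set.seed(4)
  a <- matrix(runif(65536), 256, 256)
  b <- matrix(runif(65536), 256, 256)
  m_ab <- compute_metrics(a, b, mi_bins = 16)
  m_ba <- compute_metrics(b, a, mi_bins = 16)
  expect_identical(m_ab$mi, m_ba$mi)
  # independence limit at a binning where the plug-in estimator bias
  # (~(B-1)^2 / (2 N ln 2)) is negligible
  expect_lt(m_ab$mi, 0.05)
  # dependent images carry substantial MI
  expect_gt(compute_metrics(a, a, mi_bins = 16)$mi, 1)
})

test_that("warp_image is the identity for zero flow and shifts exactly", {
  img <- blob_image(32, 32)
  z <- matrix(0, 32, 32)
  expect_identical(warp_image(img, flow_field(z, z)), img)
  out <- warp_image(img, flow_field(z + 3, z - 2))
  expect_equal(out[3:32, 1:29], img[1:30, 4:32])
  expect_true(all(out[, 30:32] == 0))   # zero fill
})

test_that("warping a phantom by its truth flow restores the geometry", {
  p <- mono_phantom(deform_study(), seed = 6L)
  reg <- warp_image(p$masked_float, p$truth_flow)
  d <- dice(reg > 0.4, p$masked_ref > 0.4)
  expect_gt(d, 0.95)
})

test_that("the before/after verdict implements the normal-variation rule", {
  set.seed(5)
  ref <- blob_image(32, 32)
  floating <- blob_image(32, 32, dx = 3)
  v <- compare_before_after(ref, floating, ref, mi_bins = 16)
  expect_true(v$normal_variation)
  expect_lt(v$delta[["rms"]], 0)
  expect_gt(v$delta[["psnr"]], 0)
  v2 <- compare_before_after(ref, floating, floating, mi_bins = 16)
  expect_false(v2$normal_variation)
  expect_true(all(abs(v2$delta) < 1e-12))
})

test_that("metrics reject mismatched or out-of-range input", {
  a <- matrix(0.5, 8, 8)
  expect_error(compute_metrics(a, matrix(0.5, 4, 4)), "grids")
  expect_error(compute_metrics(a, a * 3), "normalized")
})
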