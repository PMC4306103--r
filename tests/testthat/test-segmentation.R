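# Region-based active-contour segmentation

test_that("energy vanishes for constant images and perfect partitions", {
  pr <- chanvese_params(mu = 0, nu = 0, intensity_scale = 1)
  img <- matrix(0.37, 8, 8)
  phi <- matrix(rnorm(64), 8, 8)
  expect_equal(as.numeric(chanvese_energy(img, phi, pr)), 0)
  # two-valued image with phi exactly separating the halves (the
  # regularized Heaviside reaches the exact partition as |phi| grows)
  img2 <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  phi2 <- cbind(matrix(-1e9, 8, 4), matrix(1e9, 8, 4))
  expect_lt(as.numeric(chanvese_energy(img2, phi2, pr)), 1e-6)
})

test_that("energy matches a direct summation of the discrete formula", {
  set.seed(42)
  img <- matrix(runif(16), 4, 4)
  phi <- matrix(rnorm(16), 4, 4)
  for (par in list(c(mu = 0, nu = 3, l11 = 1, l22 = 1),
                   c(mu = 0.7, nu = 150, l11 = 2, l22 = 0.5))) {
    pr <- chanvese_params(mu = par[["mu"]], nu = par[["nu"]],
                          lambda11 = par[["l11"]], lambda22 = par[["l22"]],
                          intensity_scale = 255)
    got <- chanvese_energy(img, phi, pr)
    want <- brute_chanvese_energy(img, phi, par[["mu"]], par[["nu"]],
                                  par[["l11"]], par[["l22"]], eps = 1,
                                  scale = 255)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }
})

test_that("fit terms scale quadratically with image intensity", {
  set.seed(1)
  img <- matrix(runif(64), 8, 8) * 0.2
  phi <- matrix(rnorm(64), 8, 8)
  pr <- chanvese_params(mu = 0, nu = 0, intensity_scale = 1)
  e1 <- as.numeric(chanvese_energy(img, phi, pr))
  e3 <- as.numeric(chanvese_energy(img * 3, phi, pr))
  expect_equal(e3, 9 * e1, tolerance = 1e-9)
})

test_that("an empty region is flagged and its mean term defined as zero", {
  img <- matrix(runif(16), 4, 4)
  phi <- matrix(1, 4, 4)    # everything inside
  e <- chanvese_energy(img, phi, chanvese_params(intensity_scale = 1))
  expect_true(attr(e, "empty_region"))
  expect_true(is.finite(as.numeric(e)))
})

test_that("a bright disc is segmented to the thresholding oracle", {
  h <- 64; w <- 64
  xs <- coord_x(h, w); ys <- coord_y(h, w)
  disc <- (sqrt((xs - 32)^2 + (ys - 30)^2) <= 12) * 1
  res <- evolve_contour(disc,
                        list(type = "circle", center = c(32, 30), radius = 20),
                        chanvese_params(mu = 0, nu = 0))
  # mask equals the 0.5-threshold oracle up to a 1-pixel boundary band
  mismatch <- res$mask != (disc > 0.5)
  expect_lt(sum(mismatch) / sum(disc), 0.1)
  expect_gt(dice(res$mask, disc > 0.5), 0.95)
  expect_identical(res$masked_image, disc * res$mask)
})

test_that("a constant image does not produce a spurious object", {
  img <- matrix(0.5, 32, 32)
  res <- evolve_contour(img, NULL, chanvese_params(max_iters = 50))
  expect_true(res$collapsed || res$converged)
})

test_that("degenerate initializations are rejected", {
  img <- matrix(runif(64), 8, 8)
  expect_error(evolve_contour(img, matrix(1, 8, 8)), "both signs")
})

test_that("energy trace is non-increasing at small step size", {
  set.seed(9)
  for (k in 1:4) {
    img <- blob_image(48, 48) + matrix(rnorm(48 * 48, sd = 0.02), 48, 48)
    img <- pmin(pmax(img, 0), 1)
    pr <- chanvese_params(nu = 100, max_iters = 40, step_size = 0.1)
    res <- evolve_contour(img, NULL, pr)
    tr <- res$energy_trace
    expect_lte(max(diff(tr)), 1e-6 * abs(tr[1]))
  }
})

test_that("re-running from the converged level set barely changes the mask", {
  img <- blob_image(64, 64)
  pr <- chanvese_params(nu = 100, max_iters = 400)
  r1 <- evolve_contour(img, NULL, pr)
  expect_true(r1$converged)
  r2 <- evolve_contour(img, r1$state$phi, pr)
  changed <- mean(r1$mask != r2$mask)
  expect_lt(changed, 0.005)
})

test_that("enhanced phantoms segment much better than unenhanced ones", {
  seg <- function(enh) {
    p <- render_phantom(phantom_spec(enhancement = enh, seed = 3L))
    pr <- chanvese_params(nu = select_nu(enh), max_iters = 120)
    init <- list(type = "circle", center = c(128.5, 128.5), radius = 115)
    r <- evolve_contour(p$floating, init, pr)
    dice(r$mask, p$truth_mask_float)
  }
  d1 <- seg(TRUE)
  d0 <- seg(FALSE)
  expect_gt(d1, d0)
  expect_gt(d1, 0.8)
})

test_that("area-weight lookup follows the published operating points", {
  expect_identical(select_nu(FALSE), 100)
  expect_identical(select_nu(TRUE), 2000)
  expect_identical(select_nu(TRUE, override = 500), 500)
})
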