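# Synthetic dual-modality phantom generator

test_that("identical spec and seed give bit-identical pairs", {
  a <- render_phantom(phantom_spec(seed = 11L, deform = deform_study()))
  b <- render_phantom(phantom_spec(seed = 11L, deform = deform_study()))
  expect_identical(a$reference, b$reference)
  expect_identical(a$floating, b$floating)
  expect_identical(a$truth_flow, b$truth_flow)
  c_ <- render_phantom(phantom_spec(seed = 12L, deform = deform_study()))
  expect_false(identical(a$floating, c_$floating))
})

test_that("images are normalized and masks consistent", {
  p <- render_phantom(phantom_spec(seed = 2L))
  expect_true(all(p$reference >= 0 & p$reference <= 1))
  expect_true(all(p$floating >= 0 & p$floating <= 1))
  expect_type(p$truth_mask_ref, "logical")
  expect_gt(sum(p$truth_mask_ref), 0.02 * length(p$truth_mask_ref))
})

test_that("identity deformation yields zero flow and an undeformed scene", {
  p <- render_phantom(phantom_spec(seed = 4L, deform = deform_identity()))
  expect_true(all(p$truth_flow$u == 0))
  expect_true(all(p$truth_flow$v == 0))
  expect_identical(p$truth_mask_ref, p$truth_mask_float)
})

test_that("pure translation encodes a constant truth flow", {
  p <- render_phantom(phantom_spec(seed = 4L,
                                   deform = deform_translation(3, -2)))
  expect_equal(unique(as.numeric(p$truth_flow$u)), 3)
  expect_equal(unique(as.numeric(p$truth_flow$v)), -2)
})

test_that("enhancement brightens the US ROI and darkens the MRI tube", {
  p0 <- render_phantom(phantom_spec(enhancement = FALSE, seed = 7L))
  p1 <- render_phantom(phantom_spec(enhancement = TRUE, seed = 7L))
  us_roi0 <- mean(p0$floating[p0$truth_mask_float])
  us_roi1 <- mean(p1$floating[p1$truth_mask_float])
  expect_gt(us_roi1, us_roi0)
  # Weber contrast of the US ROI against background
  weber <- function(p) {
    bg <- mean(p$floating[!p$truth_mask_float])
    (mean(p$floating[p$truth_mask_float]) - bg) / bg
  }
  expect_gt(weber(p1), weber(p0))
  mri_roi0 <- mean(p0$reference[p0$truth_mask_ref])
  mri_roi1 <- mean(p1$reference[p1$truth_mask_ref])
  expect_lt(mri_roi1, mri_roi0)
})

test_that("warping the floating scene by the truth flow recovers the reference", {
  # translation: analytic rendering makes the identity exact in the interior
  p <- mono_phantom(deform_translation(3, -2), seed = 3L)
  w <- apply_deformation(p$floating_clean, p$truth_flow)
  expect_lt(mean(abs(w - p$reference_clean)), 1e-6)
  # smooth non-rigid: interpolation tolerance of 2 gray levels of 256
  p2 <- mono_phantom(deform_study(), seed = 3L)
  w2 <- apply_deformation(p2$floating_clean, p2$truth_flow)
  expect_lt(mean(abs(w2 - p2$reference_clean)), 2 / 256)
  # the warped floating mask matches the reference mask up to the boundary
  mwarp <- apply_deformation(p2$truth_mask_float * 1, p2$truth_flow) > 0.5
  expect_gt(dice(mwarp, p2$truth_mask_ref), 0.98)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(tube_inner_radius = 20, tube_outer_radius = 18),
               "inner")
  expect_error(phantom_spec(target_radius = 30), "lumen")
  expect_error(phantom_spec(us_speckle_sd = NaN), "finite")
  expect_error(phantom_spec(grid_size = c(64, 64)), "fit")  # 18 px tube
  big <- deform_translation(200, 0)
  expect_error(render_phantom(phantom_spec(deform = big)), "grid_size/4")
})

test_that("apply_deformation warps exactly for trivial flows", {
  img <- blob_image(32, 32)
  z <- matrix(0, 32, 32)
  expect_identical(apply_deformation(img, flow_field(z, z)), img)
  # integer translation equals a roll in the interior
  fl <- flow_field(z + 2, z)
  out <- apply_deformation(img, fl)
  expect_equal(out[, 1:30], img[, 3:32])
  # non-integer shift on a linear ramp: values move by half the ramp step
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32) / 32
  half <- apply_deformation(ramp, flow_field(z + 0.5, z))
  expect_equal(half[, 2:31], ramp[, 2:31] + 0.5 / 32, tolerance = 1e-12)
  expect_error(apply_deformation(img, flow_field(matrix(0, 16, 16),
                                                 matrix(0, 16, 16))),
               "grids")
})

test_that("phantom pairs round-trip to disk", {
  dir <- withr::local_tempdir()
  p <- render_phantom(phantom_spec(seed = 5L, deform = deform_study()))
  write_phantom(p, dir)
  expect_true(file.exists(file.path(dir, "phantom_spec.yaml")))
  fl <- read_flo(file.path(dir, "truth_flow.flo"))
  expect_equal(fl$u, p$truth_flow$u, tolerance = 1e-6)
  expect_equal(fl$v, p$truth_flow$v, tolerance = 1e-6)
  img <- read_image(file.path(dir, "reference.png"))
  expect_lt(max(abs(img - p$reference)), 1 / 255)   # 8-bit quantization
})
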