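# Synthetic dual-modality phantom: a "U"-shaped fluid-filled tube (silicone
# wall, 9 mm outer / 7 mm inner diameter) holding three 5 mm disc targets,
# rendered once as a speckle-corrupted ultrasound analogue and once as a
# smooth T2*-weighted MRI analogue. With contrast enhancement (magnetic
# microbubbles in the tube) the US lumen/targets brighten and the MRI tube
# signal drops. A known smooth deformation separates the floating (US) from
# the reference (MRI) rendering, so ground-truth flow and masks exist for
# every pair.

# ---- deformation families ----------------------------------------------

#' Deformation specifications
#'
#' Constructors for the deformation families a phantom pair can carry. All
#' of them define a displacement field `t(x, y)` on the reference grid; the
#' ground-truth flow of a pair is `t` sampled at the pixel centers, and the
#' floating image is rendered analytically at the inverse-mapped
#' coordinates, so the pair satisfies
#' `warp(floating, truth_flow) == reference` up to interpolation and noise.
#'
#' * `deform_identity()`: zero displacement.
#' * `deform_translation(tx, ty)`: global shift in pixels.
#' * `deform_affine(A, b, center)`: displacement
#'   `A (p - center) + b + center - p`, mimicking a probe pose difference
#'   (small rotation/scale/shear plus shift).
#' * `deform_bumps(centers, amplitudes, sigma)`: sum of Gaussian bumps,
#'   displacement `sum_k a_k exp(-|p - c_k|^2 / (2 sigma^2))` — smooth local
#'   deformation.
#' * `deform_compose(...)`: sum of the component displacement fields.
#' * `deform_study(grid_size)`: the standard evaluation deformation used in
#'   the package's experiments — a global translation plus two smooth local
#'   bumps (both the "global" and "local" regimes the registration must
#'   handle), scaled to the grid.
#'
#' @param tx,ty Translation in pixels (x = columns, y = rows).
#' @param A 2x2 matrix; `b` length-2 offset; `center` length-2 fixed point
#'   (defaults to the grid center at render time).
#' @param grid_size `c(H, W)` grid for which to scale the study deformation.
#' @param centers k x 2 matrix of bump centers (x, y) in pixels.
#' @param amplitudes k x 2 matrix of bump displacement amplitudes (pixels).
#' @param sigma Bump standard deviation in pixels.
#' @param ... Deformation specs to sum.
#' @return An object of class `deform_spec`.
#' @name deform_spec
NULL

new_deform <- function(.type, ...) {
  structure(c(list(type = .type), list(...)), class = "deform_spec")
}

#' @rdname deform_spec
#' @export
deform_identity <- function() new_deform("identity")

#' @rdname deform_spec
#' @export
deform_translation <- function(tx, ty) {
  stopifnot(is.finite(tx), is.finite(ty))
  new_deform("translation", tx = tx, ty = ty)
}

#' @rdname deform_spec
#' @export
deform_affine <- function(A = diag(2), b = c(0, 0), center = NULL) {
  stopifnot(all(is.finite(A)), all(is.finite(b)), all(dim(A) == c(2, 2)))
  new_deform("affine", A = A, b = b, center = center)
}

#' @rdname deform_spec
#' @export
deform_bumps <- function(centers, amplitudes, sigma = 40) {
  centers <- rbind(centers); amplitudes <- rbind(amplitudes)
  stopifnot(ncol(centers) == 2, ncol(amplitudes) == 2,
            nrow(centers) == nrow(amplitudes),
            all(is.finite(centers)), all(is.finite(amplitudes)),
            is.finite(sigma), sigma > 0)
  new_deform("bumps", centers = centers, amplitudes = amplitudes,
             sigma = sigma)
}

#' @rdname deform_spec
#' @export
deform_study <- function(grid_size = c(256, 256)) {
  s <- min(grid_size) / 256
  deform_compose(
    deform_translation(3 * s, -2 * s),
    deform_bumps(centers = s * rbind(c(100, 100), c(170, 160)),
                 amplitudes = s * rbind(c(4, -3), c(-3, 4)),
                 sigma = 40 * s))
}

#' @rdname deform_spec
#' @export
deform_compose <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, TRUE, "deform_spec")))
  new_deform("composite", parts = parts)
}

# Displacement (dx, dy) of a deform_spec at continuous coordinates.
deform_displacement <- function(deform, xs, ys, grid = NULL) {
  switch(deform$type,
    identity = list(dx = xs * 0, dy = ys * 0),
    translation = list(dx = xs * 0 + deform$tx, dy = ys * 0 + deform$ty),
    affine = {
      ctr <- deform$center
      if (is.null(ctr)) ctr <- (rev(grid) + 1) / 2   # (x, y) grid center
      px <- xs - ctr[1]; py <- ys - ctr[2]
      A <- deform$A
      list(dx = A[1, 1] * px + A[1, 2] * py + deform$b[1] - px,
           dy = A[2, 1] * px + A[2, 2] * py + deform$b[2] - py)
    },
    bumps = {
      dx <- xs * 0; dy <- ys * 0
      s2 <- 2 * deform$sigma^2
      for (k in seq_len(nrow(deform$centers))) {
        g <- exp(-((xs - deform$centers[k, 1])^2 +
                   (ys - deform$centers[k, 2])^2) / s2)
        dx <- dx + deform$amplitudes[k, 1] * g
        dy <- dy + deform$amplitudes[k, 2] * g
      }
      list(dx = dx, dy = dy)
    },
    composite = {
      dx <- xs * 0; dy <- ys * 0
      for (p in deform$parts) {
        d <- deform_displacement(p, xs, ys, grid)
        dx <- dx + d$dx; dy <- dy + d$dy
      }
      list(dx = dx, dy = dy)
    },
    stop("unknown deformation type: ", deform$type, call. = FALSE))
}

# Inverse map of y = h + t(h): fixed-point iteration h <- y - t(h).
deform_inverse_coords <- function(deform, xs, ys, grid, iters = 30L,
                                  tol = 1e-8) {
  hx <- xs; hy <- ys
  for (i in seq_len(iters)) {
    d <- deform_displacement(deform, hx, hy, grid)
    nx <- xs - d$dx; ny <- ys - d$dy
    delta <- max(abs(nx - hx), abs(ny - hy))
    hx <- nx; hy <- ny
    if (delta < tol) break
  }
  list(x = hx, y = hy)
}

# ---- phantom specification ---------------------------------------------

#' Specify a synthetic dual-modality phantom
#'
#' Geometry defaults follow the physical phantom: a "U"-shaped tube of 9 mm
#' outer / 7 mm inner diameter holding three ~5 mm disc targets, at a
#' default scale of 4 px/mm on a 256 x 256 grid. The region of interest
#' (truth mask) is the tube lumen together with the targets.
#'
#' @param grid_size `c(H, W)` in pixels.
#' @param px_per_mm Scale used to convert the physical sizes to pixels.
#' @param tube_outer_radius,tube_inner_radius Tube wall radii in pixels
#'   (defaults: 9 mm and 7 mm diameters at `px_per_mm`).
#' @param target_radius Disc target radius in pixels (default 5 mm diameter).
#' @param enhancement Logical; simulate the microbubble contrast agent
#'   (brightens US lumen/targets, darkens the MRI tube signal).
#' @param us_speckle_sd Standard deviation of the multiplicative speckle
#'   field applied to the US rendering.
#' @param mri_noise_sigma Additive Gaussian noise sd of the MRI rendering.
#' @param deform A [deform_spec] giving the ground-truth deformation between
#'   the reference and floating renderings.
#' @param modalities Named character vector choosing the modality of the
#'   `reference` and `floating` renderings (`"mri"` or `"us"`); the default
#'   matches the acquisition protocol (MRI reference, US floating). Using
#'   the same modality twice yields mono-modality pairs for methodological
#'   ground-truth experiments.
#' @param edge_softness Width (pixels) of the analytic smooth edges.
#' @param seed Integer seed; identical spec + seed gives bit-identical pairs.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(256, 256),
                         px_per_mm = 4,
                         tube_outer_radius = 9 * px_per_mm / 2,
                         tube_inner_radius = 7 * px_per_mm / 2,
                         target_radius = 5 * px_per_mm / 2,
                         enhancement = TRUE,
                         us_speckle_sd = 0.2,
                         mri_noise_sigma = 0.015,
                         deform = deform_identity(),
                         modalities = c(reference = "mri", floating = "us"),
                         edge_softness = 0.5,
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  nums <- c(px_per_mm, tube_outer_radius, tube_inner_radius, target_radius,
            us_speckle_sd, mri_noise_sigma, edge_softness)
  if (any(!is.finite(nums)))
    stop("phantom_spec parameters must be finite", call. = FALSE)
  if (tube_inner_radius >= tube_outer_radius)
    stop("tube_inner_radius must be < tube_outer_radius", call. = FALSE)
  if (target_radius > tube_inner_radius)
    stop("target_radius must fit inside the tube lumen", call. = FALSE)
  stopifnot(length(grid_size) == 2, all(grid_size >= 32),
            all(modalities %in% c("us", "mri")),
            inherits(deform, "deform_spec"))
  h <- grid_size[1]; w <- grid_size[2]
  # U geometry (fractions of the grid): two vertical arms joined by a lower
  # semicircular bend.
  cx <- (w + 1) / 2
  arm_dx <- round(0.172 * w)          # half-distance between the arms
  arc_r <- arm_dx
  top_y <- round(0.14 * h)
  bend_y <- round(0.586 * h)
  geom <- list(
    left_x = cx - arm_dx, right_x = cx + arm_dx,
    top_y = top_y, bend_y = bend_y, arc_cx = cx, arc_cy = bend_y,
    arc_r = arc_r,
    targets = rbind(c(cx - arm_dx, round(0.235 * h)),
                    c(cx, bend_y + arc_r),
                    c(cx + arm_dx, round(0.235 * h))))
  lo_y <- geom$bend_y + geom$arc_r + tube_outer_radius
  hi_x <- geom$right_x + tube_outer_radius
  if (lo_y > h - 2 || hi_x > w - 2 || top_y - tube_outer_radius < 2)
    stop("phantom geometry does not fit inside the grid", call. = FALSE)
  structure(list(grid_size = grid_size, px_per_mm = px_per_mm,
                 tube_outer_radius = tube_outer_radius,
                 tube_inner_radius = tube_inner_radius,
                 target_radius = target_radius,
                 enhancement = isTRUE(enhancement),
                 us_speckle_sd = us_speckle_sd,
                 mri_noise_sigma = mri_noise_sigma,
                 deform = deform, modalities = modalities,
                 edge_softness = edge_softness,
                 geom = geom, seed = as.integer(seed)),
            class = "phantom_spec")
}

# distance from continuous points to a vertical segment x = sx, y in [y0,y1]
dist_vseg <- function(xs, ys, sx, y0, y1) {
  yc <- pmin(pmax(ys, y0), y1)
  sqrt((xs - sx)^2 + (ys - yc)^2)
}

# distance to the tube centerline (two arms + lower semicircular bend)
centerline_distance <- function(xs, ys, geom) {
  d <- dist_vseg(xs, ys, geom$left_x, geom$top_y, geom$bend_y)
  d <- pmin(d, dist_vseg(xs, ys, geom$right_x, geom$top_y, geom$bend_y))
  rc <- sqrt((xs - geom$arc_cx)^2 + (ys - geom$arc_cy)^2)
  on_arc <- ys >= geom$arc_cy
  d_arc <- abs(rc - geom$arc_r)
  d_arc[!on_arc] <- Inf              # arc endpoints coincide with the arms
  pmin(d, d_arc)
}

target_distance <- function(xs, ys, geom) {
  d <- Inf
  for (k in seq_len(nrow(geom$targets)))
    d <- pmin(d, sqrt((xs - geom$targets[k, 1])^2 +
                      (ys - geom$targets[k, 2])^2))
  d
}

# modality intensity tables; enhancement brightens the US lumen/targets and
# darkens the MRI tube signal (T2* drop)
modality_intensities <- function(modality, enhancement) {
  if (modality == "us") {
    list(bg = 0.22,
         wall = if (enhancement) 0.45 else 0.24,
         lumen = if (enhancement) 0.75 else 0.06,
         target = if (enhancement) 0.92 else 0.32)
  } else {
    list(bg = 0.40, wall = 0.30,
         lumen = if (enhancement) 0.62 else 0.80,
         target = 0.88)
  }
}

# Noise-free analytic rendering at continuous coordinates.
render_scene <- function(xs, ys, spec, modality) {
  ii <- modality_intensities(modality, spec$enhancement)
  d <- centerline_distance(xs, ys, spec$geom)
  dt <- target_distance(xs, ys, spec$geom)
  s <- function(t) stats::plogis(t / spec$edge_softness)
  m_outer <- s(spec$tube_outer_radius - d)
  m_inner <- s(spec$tube_inner_radius - d)
  m_targ <- s(spec$target_radius - dt)
  img <- ii$bg + (ii$wall - ii$bg) * m_outer + (ii$lumen - ii$wall) * m_inner
  img <- img + (ii$target - img) * m_targ
  img
}

scene_mask <- function(xs, ys, spec) {
  d <- centerline_distance(xs, ys, spec$geom)
  dt <- target_distance(xs, ys, spec$geom)
  (d <= spec$tube_inner_radius) | (dt <= spec$target_radius)
}

# Correlated multiplicative speckle field in material coordinates: speckle
# is the deterministic interference texture of the medium, so it deforms
# with the tissue. Both renderings of a pair sample one field (the
# floating one at the inverse-deformed coordinates).
make_speckle_field <- function(h, w, sd) {
  n <- matrix(rnorm(h * w), h, w)
  n <- im_gauss(n, 1)
  n / sd(n) * sd
}

apply_modality_noise <- function(img, spec, modality, speckle = NULL,
                                 xs = NULL, ys = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (modality == "us") {
    if (spec$us_speckle_sd <= 0 || is.null(speckle)) return(clamp01(img))
    n <- matrix(bilinear_sample(speckle, xs, ys, fill = "replicate"), h, w)
    clamp01(img * (1 + n))
  } else {
    if (spec$mri_noise_sigma <= 0) return(clamp01(img))
    clamp01(im_gauss(img, 0.8) +
              matrix(rnorm(h * w, sd = spec$mri_noise_sigma), h, w))
  }
}

#' Render a synthetic dual-modality phantom pair
#'
#' Renders the reference scene (default: MRI analogue) on the pixel grid and
#' the floating scene (default: US analogue) at the inverse-deformed
#' coordinates, so that backward-warping the floating image by the returned
#' ground-truth flow reproduces the reference geometry. Modality noise
#' (multiplicative correlated speckle for US, additive Gaussian for MRI) is
#' injected after the deformation, so `truth_flow` relates the noiseless
#' geometry of the two renderings.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_pair` with elements `reference`,
#'   `floating` (noisy images in `[0, 1]`), `reference_clean`,
#'   `floating_clean` (pre-noise renderings), `truth_flow` (a
#'   [flow_field()] mapping floating onto reference), `truth_mask_ref`,
#'   `truth_mask_float` (logical ROI masks: lumen plus targets), and `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$grid_size[1]; w <- spec$grid_size[2]
  xs <- grid_x(h, w); ys <- grid_y(h, w)
  d <- deform_displacement(spec$deform, xs, ys, grid = c(h, w))
  if (any(!is.finite(d$dx)) || any(!is.finite(d$dy)))
    stop("deformation produces non-finite displacements", call. = FALSE)
  maxdisp <- max(abs(d$dx), abs(d$dy))
  if (maxdisp > min(h, w) / 4)
    stop(sprintf("max displacement %.1f px exceeds grid_size/4", maxdisp),
         call. = FALSE)
  truth_flow <- flow_field(u = d$dx, v = d$dy)
  ref_clean <- matrix(render_scene(xs, ys, spec, spec$modalities[["reference"]]), h, w)
  inv <- deform_inverse_coords(spec$deform, xs, ys, grid = c(h, w))
  float_clean <- matrix(render_scene(inv$x, inv$y, spec,
                                     spec$modalities[["floating"]]), h, w)
  mask_ref <- matrix(scene_mask(xs, ys, spec), h, w)
  mask_float <- matrix(scene_mask(inv$x, inv$y, spec), h, w)
  pair <- with_seed(spec$seed, {
    speckle <- if (spec$us_speckle_sd > 0)
      make_speckle_field(h, w, spec$us_speckle_sd) else NULL
    reference <- apply_modality_noise(ref_clean, spec,
                                      spec$modalities[["reference"]],
                                      speckle, xs, ys)
    floating <- apply_modality_noise(float_clean, spec,
                                     spec$modalities[["floating"]],
                                     speckle, inv$x, inv$y)
    list(reference = reference, floating = floating)
  })
  structure(list(reference = pair$reference, floating = pair$floating,
                 reference_clean = ref_clean, floating_clean = float_clean,
                 truth_flow = truth_flow,
                 truth_mask_ref = mask_ref, truth_mask_float = mask_float,
                 spec = spec),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(
    "<phantom_pair %dx%d>  %s reference / %s floating, enhancement=%s\n",
    nrow(x$reference), ncol(x$reference),
    toupper(x$spec$modalities[["reference"]]),
    toupper(x$spec$modalities[["floating"]]),
    x$spec$enhancement))
  cat(sprintf("  deformation: %s, max |d| = %.2f px\n", x$spec$deform$type,
              max(abs(x$truth_flow$u), abs(x$truth_flow$v))))
  invisible(x)
}

#' Backward-warp an image by a displacement field
#'
#' Samples `image` at `(x + u, y + v)` with bilinear interpolation.
#' Out-of-grid samples are filled by border replication (the generator's
#' documented rule; see [warp_image()] for the zero-fill variant used in
#' evaluation).
#'
#' @param image Numeric matrix.
#' @param flow A [flow_field()] on the same grid.
#' @return The warped image.
#' @export
apply_deformation <- function(image, flow) {
  assert_image(image)
  assert_flow(flow, image)
  warp_by_flow(image, flow, fill = "replicate")
}

#' Write a phantom pair to disk
#'
#' Writes the two images (PNG), the ground-truth flow (Middlebury
#' `.flo`), the ROI masks (PNG) and a YAML sidecar echoing the generation
#' parameters.
#'
#' @param pair A [render_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(pair$reference, file.path(dir, "reference.png"))
  write_image(pair$floating, file.path(dir, "floating.png"))
  write_image(pair$truth_mask_ref * 1, file.path(dir, "mask_reference.png"))
  write_image(pair$truth_mask_float * 1, file.path(dir, "mask_floating.png"))
  write_flo(pair$truth_flow, file.path(dir, "truth_flow.flo"))
  spec <- pair$spec
  side <- list(grid_size = spec$grid_size, px_per_mm = spec$px_per_mm,
               tube_outer_radius = spec$tube_outer_radius,
               tube_inner_radius = spec$tube_inner_radius,
               target_radius = spec$target_radius,
               enhancement = spec$enhancement,
               us_speckle_sd = spec$us_speckle_sd,
               mri_noise_sigma = spec$mri_noise_sigma,
               deform_type = spec$deform$type,
               modalities = as.list(spec$modalities),
               seed = spec$seed)
  yaml::write_yaml(side, file.path(dir, "phantom_spec.yaml"))
  invisible(dir)
}
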