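# Rigid baseline: FFT phase correlation. The normalized cross-power
# spectrum of the two images inverse-transforms to a correlation surface
# whose peak is the translation between them; a local centroid refines it
# to subpixel precision. Translation-only by default.

#' Rigid registration by FFT phase correlation
#'
#' Finds the translation `(tx, ty)` maximizing the inverse transform of the
#' normalized cross-power spectrum, refined by a 3x3 centroid around the
#' peak. Sign convention matches the flow fields: backward-warping
#' `floating` by the constant flow `(tx, ty)` aligns it to `reference`.
#'
#' @param reference,floating Images on one grid.
#' @return An object of class `rigid_transform`: `tx`, `ty` (pixels),
#'   `response` (peak height of the correlation surface), `flat_spectrum`
#'   (TRUE with zero transform when an image is constant).
#' @export
phase_correlate <- function(reference, floating) {
  assert_image(reference); assert_image(floating)
  assert_same_grid(reference, floating)
  h <- nrow(reference); w <- ncol(reference)
  if (sd(reference) == 0 || sd(floating) == 0) {
    return(structure(list(tx = 0, ty = 0, response = 0,
                          flat_spectrum = TRUE),
                     class = "rigid_transform"))
  }
  F1 <- fft(reference)
  F2 <- fft(floating)
  R <- F1 * Conj(F2)
  R <- R / pmax(Mod(R), 1e-12)
  surf <- Re(fft(R, inverse = TRUE)) / (h * w)
  pk <- arrayInd(which.max(surf), dim(surf))
  # peak at index m (0-based) means floating = reference shifted by s with
  # m = -s mod N; wrap to signed shifts
  wrap <- function(m, n) ifelse(m > n / 2, m - n, m)
  # subpixel: centroid of the 3x3 circular neighborhood of the peak
  centroid <- function(m0, n, along) {
    idx <- ((m0 - 1L + (-1:1)) %% n) + 1L
    if (along == "row") v <- surf[idx, pk[2]] else v <- surf[pk[1], idx]
    v <- pmax(v, 0)
    if (sum(v) == 0) return(m0 - 1)
    (m0 - 1) + sum((-1:1) * v) / sum(v)
  }
  my <- centroid(pk[1], h, "row")
  mx <- centroid(pk[2], w, "col")
  structure(list(tx = -wrap(mx %% w, w), ty = -wrap(my %% h, h),
                 response = max(surf), flat_spectrum = FALSE),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform>  tx = %.3f, ty = %.3f px (response %.3f%s)\n",
              x$tx, x$ty, x$response,
              if (x$flat_spectrum) ", flat spectrum" else ""))
  invisible(x)
}

#' Apply a rigid transform as a constant flow field
#'
#' @param image Image to resample.
#' @param transform A [phase_correlate()] result.
#' @return The translated image (zero fill).
#' @export
apply_rigid <- function(image, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  h <- nrow(image); w <- ncol(image)
  warp_image(image, flow_field(matrix(transform$tx, h, w),
                               matrix(transform$ty, h, w)))
}

#' Constant flow field from a rigid transform
#'
#' @param transform A [phase_correlate()] result.
#' @param dim Grid size `c(H, W)`.
#' @return A [flow_field()].
#' @export
rigid_to_flow <- function(transform, dim) {
  flow_field(matrix(transform$tx, dim[1], dim[2]),
             matrix(transform$ty, dim[1], dim[2]))
}
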