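# Registration-quality metrics on [0,1] images: root-mean-square intensity
# difference, peak signal-to-noise ratio (20*log10(1/RMS) for unit-range
# images), Pearson correlation over all pixels, and mutual information from
# the joint intensity histogram (equal-width bins on [0,1], base-2 logs,
# 0*log0 = 0). A registration shows the "normal variation" pattern when RMS
# decreases while PSNR, COR and MI all increase.

#' Backward-warp an image by an estimated flow
#'
#' Bilinear backward warp with zero fill outside the grid — the convention
#' used when resampling a floating segmentation into the reference frame
#' for evaluation.
#'
#' @param image Numeric matrix.
#' @param flow A [flow_field()] on the same grid.
#' @return The warped image.
#' @export
warp_image <- function(image, flow) {
  assert_image(image)
  assert_flow(flow, image)
  warp_by_flow(image, flow, fill = "zero", fill_value = 0)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

bin_index <- function(x, bins) pmin(floor(x * bins) + 1L, bins)

#' Similarity metrics between two images
#'
#' @param reference,other Numeric matrices in `[0, 1]` on one grid.
#' @param mi_bins Number of equal-width histogram bins per axis for the
#'   mutual-information estimate.
#' @return An object of class `metrics_report`: `rms`, `psnr` (dB; `Inf`
#'   when `rms == 0`), `cor` (0 with a `constant_image` flag when either
#'   image is constant), `mi` (bits), `n_pixels`, `mi_bins`.
#' @export
compute_metrics <- function(reference, other, mi_bins = 256L) {
  assert_image(reference); assert_image(other)
  assert_same_grid(reference, other)
  if (min(reference, other) < -1e-9 || max(reference, other) > 1 + 1e-9)
    stop("metrics expect images normalized to [0, 1]", call. = FALSE)
  n <- length(reference)
  rms <- sqrt(mean((reference - other)^2))
  psnr <- if (rms > 0) 20 * log10(1 / rms) else Inf
  constant <- sd(reference) == 0 || sd(other) == 0
  cor_ <- if (constant) 0 else cor(as.numeric(reference), as.numeric(other))
  bi <- bin_index(clamp01(reference), mi_bins)
  bj <- bin_index(clamp01(other), mi_bins)
  joint <- tabulate((bj - 1L) * mi_bins + bi, nbins = mi_bins * mi_bins) / n
  pi_ <- tabulate(bi, nbins = mi_bins) / n
  pj <- tabulate(bj, nbins = mi_bins) / n
  mi <- entropy_bits(pi_) + entropy_bits(pj) - entropy_bits(joint)
  mi <- max(mi, 0)
  structure(list(rms = rms, psnr = psnr, cor = cor_, mi = mi,
                 n_pixels = n, mi_bins = as.integer(mi_bins),
                 constant_image = constant),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report>  RMS %.4f | PSNR %.4f dB | COR %.4f | MI %.4f bits (%d bins, %d px)\n",
              x$rms, x$psnr, x$cor, x$mi, x$mi_bins, x$n_pixels))
  invisible(x)
}

#' Before/after registration comparison
#'
#' Computes the metric report of the floating image and of the registered
#' image against the reference, their signed differences (after - before),
#' and the normal-variation verdict: RMS decreased while PSNR, COR and MI
#' all increased.
#'
#' @param ref Reference image.
#' @param floating Floating image before registration.
#' @param registered Floating image after registration (warped).
#' @param mi_bins Histogram bins for MI.
#' @return An object of class `comparison_verdict` with fields `before`,
#'   `after`, `delta` (named numeric), `normal_variation`.
#' @export
compare_before_after <- function(ref, floating, registered,
                                 mi_bins = 256L) {
  before <- compute_metrics(ref, floating, mi_bins)
  after <- compute_metrics(ref, registered, mi_bins)
  delta <- c(rms = after$rms - before$rms,
             psnr = after$psnr - before$psnr,
             cor = after$cor - before$cor,
             mi = after$mi - before$mi)
  normal <- (after$rms < before$rms) && (after$psnr > before$psnr) &&
    (after$cor > before$cor) && (after$mi > before$mi)
  structure(list(before = before, after = after, delta = delta,
                 normal_variation = normal),
            class = "comparison_verdict")
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat("<comparison_verdict>\n  before: ")
  print(x$before)
  cat("  after:  ")
  print(x$after)
  cat(sprintf("  %s variation (dRMS %+0.4f, dPSNR %+0.4f, dCOR %+0.4f, dMI %+0.4f)\n",
              if (x$normal_variation) "NORMAL" else "abnormal",
              x$delta["rms"], x$delta["psnr"], x$delta["cor"], x$delta["mi"]))
  invisible(x)
}
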