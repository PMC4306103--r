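# Shared raster helpers: images are plain numeric matrices [row = y, col = x]
# with intensities in [0, 1]. Flow fields displace in pixels: u along x
# (columns), v along y (rows).

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

assert_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Construct a flow field
#'
#' A flow field stores per-pixel displacements in pixels: `u` along x
#' (columns), `v` along y (rows). Backward-warping an image `I` by a flow
#' samples `I` at `(x + u, y + v)`.
#'
#' @param u,v Numeric matrices of equal dimension (horizontal and vertical
#'   displacement, pixels).
#' @return An object of class `flow_field` (list with elements `u`, `v`).
#' @export
flow_field <- function(u, v) {
  assert_image(u, "u"); assert_image(v, "v")
  assert_same_grid(u, v, "flow components")
  structure(list(u = u, v = v), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<flow_field %dx%d>  mean |d| = %.4f px, max |d| = %.4f px\n",
              nrow(x$u), ncol(x$u), mean(mag), max(mag)))
  invisible(x)
}

is_flow <- function(x) inherits(x, "flow_field")

assert_flow <- function(flow, image = NULL) {
  if (!is_flow(flow)) stop("`flow` must be a flow_field", call. = FALSE)
  if (anyNA(flow$u) || any(!is.finite(flow$u)) ||
      anyNA(flow$v) || any(!is.finite(flow$v)))
    stop("flow field contains non-finite values", call. = FALSE)
  if (!is.null(image)) assert_same_grid(flow$u, image, "flow and image")
  invisible(flow)
}

# x/y coordinate matrices of a grid (1-based pixel centers)
grid_x <- function(h, w) matrix(rep(seq_len(w), each = h), h, w)
grid_y <- function(h, w) matrix(rep(seq_len(h), times = w), h, w)

# Bilinear sampling of `img` at continuous coordinates (xs, ys), 1-based.
# fill = "replicate": out-of-grid coordinates are clamped to the border;
# fill = "zero": out-of-grid samples are set to `fill_value`.
bilinear_sample <- function(img, xs, ys, fill = c("replicate", "zero"),
                            fill_value = 0) {
  fill <- match.arg(fill)
  stopifnot(nrow(img) >= 2, ncol(img) >= 2)
  vec_in <- !is.matrix(xs)
  if (vec_in) { xs <- rbind(xs); ys <- rbind(ys) }
  samp <- cpp_bilinear(img, xs, ys)
  v <- samp$value
  if (fill == "zero") v[samp$outside == 1L] <- fill_value
  if (vec_in) as.numeric(v) else v
}

# Backward warp: out[y, x] = img[y + v, x + u], bilinear.
warp_by_flow <- function(img, flow, fill = "replicate", fill_value = 0) {
  h <- nrow(img); w <- ncol(img)
  xs <- grid_x(h, w) + flow$u
  ys <- grid_y(h, w) + flow$v
  matrix(bilinear_sample(img, xs, ys, fill = fill, fill_value = fill_value),
         h, w)
}

# Gaussian smoothing with replicate borders; kernel size adapts so EBImage's
# filter never exceeds the image.
im_gauss <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  size <- min(size, 2L * ((min(dim(img)) - 1L) %/% 2L) + 1L)
  if (size < 3L) return(img)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

# Bilinear resize to h x w rows/cols (EBImage's first dimension is the
# matrix's first dimension).
im_resize <- function(img, h, w) {
  as.matrix(EBImage::resize(img, w = h, h = w, filter = "bilinear"))
}

#' Read a grayscale image
#'
#' Reads PNG or TIFF, converts multi-channel data to luminance by averaging,
#' and returns intensities in `[0, 1]`.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  mx <- max(img)
  if (mx > 1) img <- img / mx
  clamp01(img)
}

#' Write a grayscale image
#'
#' Writes a `[0, 1]` matrix as 8-bit PNG or 32-bit float TIFF depending on
#' the extension (use TIFF where full precision matters).
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  ext <- tolower(tools::file_ext(path))
  img <- clamp01(img)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L),
    stop("unsupported image extension: ", ext, call. = FALSE))
  invisible(path)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
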