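# Shared fixtures: everything is generated in code, deterministically.

# coordinate matrices
coord_x <- function(h, w) matrix(rep(seq_len(w), each = h), h, w)
coord_y <- function(h, w) matrix(rep(seq_len(h), times = w), h, w)

# smooth multi-blob test image in [0, 1]
blob_image <- function(h = 128, w = 128, dx = 0, dy = 0) {
  xs <- coord_x(h, w); ys <- coord_y(h, w)
  g <- function(cx, cy, s, a)
    a * exp(-((xs - cx - dx)^2 + (ys - cy - dy)^2) / (2 * s^2))
  img <- g(0.45 * w, 0.4 * h, 0.06 * w, 0.8) +
    g(0.65 * w, 0.62 * h, 0.045 * w, 0.6) +
    g(0.35 * w, 0.7 * h, 0.05 * w, 0.7)
  pmin(img, 1)
}

# small mono-modality phantom pair (US reference and US floating) with its
# masked images
mono_phantom <- function(deform = deform_identity(), seed = 1L,
                         grid = c(256, 256), px_per_mm = 4, ...) {
  spec <- phantom_spec(grid_size = grid, px_per_mm = px_per_mm,
                       deform = deform, seed = seed,
                       modalities = c(reference = "us", floating = "us"),
                       ...)
  pair <- render_phantom(spec)
  pair$masked_ref <- pair$reference * pair$truth_mask_ref
  pair$masked_float <- pair$floating * pair$truth_mask_float
  pair
}

# brute-force 1-D minimizer of  l2*(x-u)^2 + l3*sum|x-n| on a fine grid
scan_prox_min <- function(u, nb, l2, l3, pad = NULL) {
  if (is.null(pad)) pad <- length(nb) * l3 / (2 * l2)
  lo <- min(c(u, nb)) - pad
  hi <- max(c(u, nb)) + pad
  xs <- seq(lo, hi, length.out = 20001L)
  f <- l2 * (xs - u)^2 + l3 * colSums(abs(outer(nb, xs, "-")))
  xs[which.min(f)]
}

# direct double-loop evaluation of the classical flow objective (quadratic
# or blended penalty), the independent oracle for classical_energy
brute_classical_energy <- function(I1, I2, u, v, lambda, alpha = 0,
                                   a = 0.45, eps = 0.001) {
  rho <- function(x) (1 - alpha) * x^2 + alpha * (x^2 + eps^2)^a
  h <- nrow(I1); w <- ncol(I1)
  interp <- function(x, y) {
    x <- min(max(x, 1), w); y <- min(max(y, 1), h)
    x0 <- min(floor(x), w - 1); y0 <- min(floor(y), h - 1)
    fx <- x - x0; fy <- y - y0
    (1 - fx) * (1 - fy) * I2[y0, x0] + fx * (1 - fy) * I2[y0, x0 + 1] +
      (1 - fx) * fy * I2[y0 + 1, x0] + fx * fy * I2[y0 + 1, x0 + 1]
  }
  e <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    e <- e + rho(I1[i, j] - interp(j + u[i, j], i + v[i, j]))
    if (j < w) e <- e + lambda * (rho(u[i, j] - u[i, j + 1]) +
                                  rho(v[i, j] - v[i, j + 1]))
    if (i < h) e <- e + lambda * (rho(u[i, j] - u[i + 1, j]) +
                                  rho(v[i, j] - v[i + 1, j]))
  }
  e
}

# direct evaluation of the nonlocal L1 neighborhood sum
brute_nonlocal_l1 <- function(au, av, radius) {
  h <- nrow(au); w <- ncol(au)
  s <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (ii in max(1, i - radius):min(h, i + radius))
      for (jj in max(1, j - radius):min(w, j + radius)) {
        if (ii == i && jj == j) next
        s <- s + abs(au[i, j] - au[ii, jj]) + abs(av[i, j] - av[ii, jj])
      }
  }
  s
}

# direct summation of the Chan-Vese discrete energy (mu = 0 case plus
# optional length term), the independent oracle for chanvese_energy
brute_chanvese_energy <- function(img, phi, mu, nu, l11, l22, eps = 1,
                                  scale = 1) {
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  c1 <- sum(H * img) / sum(H)
  c2 <- sum((1 - H) * img) / sum(1 - H)
  e <- nu * sum(H) + l11 * scale^2 * sum(H * (img - c1)^2) +
    l22 * scale^2 * sum((1 - H) * (img - c2)^2)
  if (mu > 0) {
    h <- nrow(phi); w <- ncol(phi)
    gx <- (phi[, c(2:w, w)] - phi[, c(1, 1:(w - 1))]) / 2
    gy <- (phi[c(2:h, h), ] - phi[c(1, 1:(h - 1)), ]) / 2
    delta <- (eps / pi) / (eps^2 + phi^2)
    e <- e + mu * sum(delta * sqrt(gx^2 + gy^2))
  }
  e
}
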