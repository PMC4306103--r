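# Robust optical flow between a reference image I1 and a floating image I2.
# The classical discrete objective
#
#   E(u, v) = sum rhoD(I1 - I2(x+u, y+v))
#           + lambda * sum_pairs [rhoS(du) + rhoS(dv)]
#
# is made robust by coupling (u, v) quadratically (weight lambda2) to an
# auxiliary field (u_hat, v_hat) that carries a nonlocal L1 neighborhood
# term (weight lambda3). Alternating minimization: the flow subproblem is a
# linearized, iteratively reweighted sparse system; the auxiliary
# subproblem has a closed-form per-pixel solution, the median of the
# neighbor values unioned with a data candidate set spaced lambda3/lambda2
# around u. The schedule is a coarse-to-fine Gaussian pyramid with a fixed
# number of warping steps per level, run once with quadratic penalties and
# once with the non-convex generalized Charbonnier penalty (two-stage
# graduated non-convexity); after every warping step (u, v) <- (u_hat,
# v_hat), and the auxiliary field of the last warp is the final estimate.

#' Robust optical-flow parameters
#'
#' Defaults follow the published operating point `lambda1 = 5`,
#' `lambda2 = 1e2`, `lambda3 = 1` with two GNC stages and three warping
#' steps per pyramid level.
#'
#' @param lambda1 Smoothness weight.
#' @param lambda2 Flow/auxiliary-field coupling weight.
#' @param lambda3 Nonlocal (neighborhood L1) weight of the auxiliary field.
#' @param gnc_stages Number of graduated-non-convexity stages (stage 1:
#'   quadratic penalties; final stage: generalized Charbonnier).
#' @param warps_per_level Warping steps per pyramid level.
#' @param pyramid_factor Downsampling factor per level, in (0, 1).
#' @param min_level_size Smallest allowed image side at the coarsest level.
#' @param median_radius Neighborhood radius of the auxiliary median update
#'   (radius 2 = 5x5 window, 24 neighbors).
#' @param median_sweeps Jacobi sweeps of the auxiliary update per call.
#' @param alternations Alternations of the flow solve and the auxiliary
#'   median update within each warping step.
#' @param coupling_ramp Continuation factor of the coupling weight across
#'   the alternations of a warp: alternation `a` of `A` runs at
#'   `lambda2 * coupling_ramp^(a - A)`, reaching `lambda2` on the last one.
#' @param solver_iters Gauss-Seidel sweeps per reweighting iteration.
#' @param irls_iters Reweighting iterations of the flow subproblem.
#' @param sor_omega Over-relaxation factor of the sweeps.
#' @param charbonnier_a,charbonnier_eps Exponent and epsilon of the
#'   generalized Charbonnier penalty `(x^2 + eps^2)^a`.
#' @param intensity_scale Gray-level scale applied to the images inside
#'   [estimate_flow()] (images are `[0, 1]`; the published lambdas balance
#'   against data residuals on the 0-255 scale).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(lambda1 = 5, lambda2 = 1e2, lambda3 = 1,
                        gnc_stages = 2L, warps_per_level = 3L,
                        pyramid_factor = 0.5, min_level_size = 16L,
                        median_radius = 2L, median_sweeps = 1L,
                        alternations = 4L, coupling_ramp = 100,
                        solver_iters = 12L, irls_iters = 2L,
                        sor_omega = 1.8,
                        charbonnier_a = 0.45, charbonnier_eps = 0.001,
                        intensity_scale = 255) {
  stopifnot(lambda1 > 0, lambda2 > 0, lambda3 >= 0,
            pyramid_factor > 0, pyramid_factor < 1,
            warps_per_level >= 1, gnc_stages >= 1, median_radius >= 1,
            solver_iters >= 1, irls_iters >= 1, alternations >= 1,
            intensity_scale > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 gnc_stages = as.integer(gnc_stages),
                 warps_per_level = as.integer(warps_per_level),
                 pyramid_factor = pyramid_factor,
                 min_level_size = as.integer(min_level_size),
                 median_radius = as.integer(median_radius),
                 median_sweeps = as.integer(median_sweeps),
                 alternations = as.integer(alternations),
                 coupling_ramp = coupling_ramp,
                 solver_iters = as.integer(solver_iters),
                 irls_iters = as.integer(irls_iters),
                 sor_omega = sor_omega,
                 charbonnier_a = charbonnier_a,
                 charbonnier_eps = charbonnier_eps,
                 intensity_scale = intensity_scale),
            class = "flow_params")
}

# Penalty rho_alpha(x): GNC blend of quadratic (alpha = 0) and generalized
# Charbonnier (alpha = 1).
rho_penalty <- function(x, alpha, params) {
  q <- x^2
  if (alpha <= 0) return(q)
  c_ <- (q + params$charbonnier_eps^2)^params$charbonnier_a
  if (alpha >= 1) c_ else (1 - alpha) * q + alpha * c_
}

# IRLS weight rho'(x) / (2x) of the blended penalty.
rho_weight <- function(x, alpha, params) {
  if (alpha <= 0) return(x * 0 + 1)
  a <- params$charbonnier_a
  cw <- a * (x^2 + params$charbonnier_eps^2)^(a - 1)
  if (alpha >= 1) cw else (1 - alpha) + alpha * cw
}

forward_diffs <- function(m) {
  h <- nrow(m); w <- ncol(m)
  list(dx = m[, -1, drop = FALSE] - m[, -w, drop = FALSE],
       dy = m[-1, , drop = FALSE] - m[-h, , drop = FALSE])
}

#' Classical optical-flow energy
#'
#' Discrete objective `sum rhoD(I1(i,j) - I2(i+u, j+v)) + lambda1 *
#' sum rhoS` over the four forward-difference pairs of `u` and `v`.
#' Subpixel samples of `I2` use bilinear interpolation with border
#' replication.
#'
#' @param I1,I2 Reference and floating images on one grid.
#' @param flow A [flow_field()].
#' @param params A [flow_params()]; `lambda1` is the smoothness weight.
#' @param alpha GNC blend of the penalties (0 = quadratic, 1 = generalized
#'   Charbonnier).
#' @return Scalar energy.
#' @export
classical_energy <- function(I1, I2, flow, params = flow_params(),
                             alpha = 0) {
  assert_image(I1); assert_image(I2)
  assert_same_grid(I1, I2)
  assert_flow(flow, I1)
  I2w <- warp_by_flow(I2, flow, fill = "replicate")
  du <- forward_diffs(flow$u); dv <- forward_diffs(flow$v)
  a <- params$charbonnier_a; e <- params$charbonnier_eps
  cpp_rho_sum(I1 - I2w, alpha, a, e) +
    params$lambda1 * (cpp_rho_sum(du$dx, alpha, a, e) +
                      cpp_rho_sum(du$dy, alpha, a, e) +
                      cpp_rho_sum(dv$dx, alpha, a, e) +
                      cpp_rho_sum(dv$dy, alpha, a, e))
}

aux_field <- function(u_hat, v_hat) {
  structure(list(u_hat = u_hat, v_hat = v_hat), class = "aux_flow")
}

as_aux <- function(x) {
  if (inherits(x, "aux_flow")) return(x)
  if (is_flow(x)) return(aux_field(x$u, x$v))
  stop("expected a flow_field or aux_flow", call. = FALSE)
}

# lambda2 coupling + lambda3 nonlocal part of the coupled objective
aux_energy <- function(flow, aux, params) {
  aux <- as_aux(aux)
  params$lambda2 * (sum((flow$u - aux$u_hat)^2) +
                    sum((flow$v - aux$v_hat)^2)) +
    (if (params$lambda3 > 0)
       params$lambda3 * cpp_nonlocal_l1(aux$u_hat, aux$v_hat,
                                        params$median_radius)
     else 0)
}

#' Coupled flow/auxiliary-field energy
#'
#' The classical terms (weight `lambda1`) plus the quadratic coupling
#' `lambda2 (||u - u_hat||^2 + ||v - v_hat||^2)` and the nonlocal L1 term
#' `lambda3 * sum_{(i,j)} sum_{(i',j') in N} |u_hat_ij - u_hat_i'j'| +
#' |v_hat_ij - v_hat_i'j'|` over the median neighborhood.
#'
#' @inheritParams classical_energy
#' @param aux Auxiliary field: a [flow_field()] or the result of
#'   [median_update_aux()].
#' @return Scalar energy.
#' @export
coupled_energy <- function(I1, I2, flow, aux, params = flow_params(),
                           alpha = 0) {
  classical_energy(I1, I2, flow, params, alpha) +
    aux_energy(flow, aux, params)
}

#' Per-pixel proximal median
#'
#' Closed-form minimizer of the scalar objective
#' `lambda2 (x - u)^2 + lambda3 sum_k |x - n_k|`: the median of the `m`
#' neighbor values unioned with the `m + 1` data candidates
#' `u + (2k - m) lambda3 / (2 lambda2)`, `k = 0..m` (spacing
#' `lambda3/lambda2`). This is the update applied at every pixel of the
#' auxiliary field.
#'
#' @param u Numeric vector of data values (one per instance).
#' @param neighbors Matrix with one row of neighbor values per instance.
#' @param lambda2,lambda3 Coupling and nonlocal weights (scalars or vectors
#'   recycled across instances).
#' @return Numeric vector of minimizers.
#' @export
prox_median <- function(u, neighbors, lambda2, lambda3) {
  neighbors <- rbind(neighbors)
  stopifnot(length(u) == nrow(neighbors), all(lambda2 > 0))
  cpp_prox_median(as.numeric(u), neighbors, as.numeric(lambda2),
                  as.numeric(lambda3))
}

#' Median update of the auxiliary flow field
#'
#' Minimizes the auxiliary subproblem `lambda2 (||u - u_hat||^2 +
#' ||v - v_hat||^2) + lambda3 * nonlocal_L1(u_hat, v_hat)` by Jacobi sweeps
#' of the per-pixel proximal median ([prox_median()]), starting from
#' `u_hat = u`. A sweep that does not lower the field objective is rolled
#' back and the iteration stops. When a previous auxiliary field is passed
#' as `aux`, it serves as a descent baseline: if the freshly swept field
#' does not reach its subproblem energy, the previous field is returned
#' instead, so the coupled energy is monotone across an alternation.
#'
#' @param flow A [flow_field()].
#' @param params A [flow_params()] (`lambda2` must be positive).
#' @param sweeps Number of Jacobi sweeps (default `params$median_sweeps`).
#' @param aux Optional previous auxiliary field used as descent baseline.
#' @return An object of class `aux_flow` (fields `u_hat`, `v_hat`).
#' @export
median_update_aux <- function(flow, params = flow_params(), sweeps = NULL,
                              aux = NULL) {
  assert_flow(flow)
  if (params$lambda2 <= 0)
    stop("lambda2 must be > 0: the coupling is undefined", call. = FALSE)
  if (is.null(sweeps)) sweeps <- params$median_sweeps
  if (params$lambda3 <= 0) return(aux_field(flow$u, flow$v))  # Data = {u}
  baseline <- if (is.null(aux)) NULL else as_aux(aux)
  aux <- aux_field(flow$u, flow$v)     # u_hat^(0) = u
  e <- aux_energy(flow, aux, params)
  for (s in seq_len(sweeps)) {
    nxt <- cpp_median_sweep(aux$u_hat, aux$v_hat, flow$u, flow$v,
                            params$lambda2, params$lambda3,
                            params$median_radius)
    cand <- aux_field(nxt$u_hat, nxt$v_hat)
    e2 <- aux_energy(flow, cand, params)
    if (e2 > e) break                    # safeguard: keep descent exact
    delta <- max(abs(cand$u_hat - aux$u_hat), abs(cand$v_hat - aux$v_hat))
    aux <- cand
    e <- e2
    if (delta < 1e-12) break
  }
  if (!is.null(baseline) && aux_energy(flow, baseline, params) < e)
    return(baseline)
  aux
}

# 5-point derivative filter h = [-1 8 0 -8 1]/12 along x / y, replicate
# borders (applied to the average of I1 and the warped I2).
deriv5 <- function(m, axis = c("x", "y")) {
  axis <- match.arg(axis)
  h <- nrow(m); w <- ncol(m)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  if (axis == "x") {
    ( -m[, idx(seq_len(w) + 2L, w), drop = FALSE] +
      8 * m[, idx(seq_len(w) + 1L, w), drop = FALSE] -
      8 * m[, idx(seq_len(w) - 1L, w), drop = FALSE] +
      m[, idx(seq_len(w) - 2L, w), drop = FALSE]) / 12
  } else {
    ( -m[idx(seq_len(h) + 2L, h), , drop = FALSE] +
      8 * m[idx(seq_len(h) + 1L, h), , drop = FALSE] -
      8 * m[idx(seq_len(h) - 1L, h), , drop = FALSE] +
      m[idx(seq_len(h) - 2L, h), , drop = FALSE]) / 12
  }
}

# Eq-(4)-style objective (classical terms + coupling, nonlocal term held
# constant) used for the descent certificate of the flow subproblem.
flow_subproblem_energy <- function(I1, I2, flow, aux, params, alpha) {
  aux <- as_aux(aux)
  classical_energy(I1, I2, flow, params, alpha) +
    params$lambda2 * (sum((flow$u - aux$u_hat)^2) +
                      sum((flow$v - aux$v_hat)^2))
}

#' Solve the flow subproblem with the auxiliary field fixed
#'
#' One warping step: the floating image is warped by `init`, the data term
#' is linearized at `init` with a 5-point derivative filter on the average
#' of `I1` and the warped `I2`, and the resulting sparse normal equations
#' (iteratively reweighted for the non-convex penalty) are relaxed by
#' Gauss-Seidel sweeps. The quadratic coupling to `aux` acts as a proximal
#' anchor. The returned flow never has higher subproblem energy than
#' `init`: if the relaxed solution (or its step-halved backtrackings)
#' fails to descend, `init` is returned with a `diverged` attribute.
#'
#' @inheritParams classical_energy
#' @param aux Auxiliary field (a [flow_field()] or `aux_flow`).
#' @param init Initial flow (linearization point).
#' @param alpha GNC blend in `[0, 1]`.
#' @return A [flow_field()].
#' @export
# Linearize the data term at `lin_point`: warp I2, derivatives of the
# average image with the 5-point filter, temporal difference, and an
# out-of-bounds indicator that down-weights invalid warp samples.
flow_linearize <- function(I1, I2, lin_point) {
  h <- nrow(I1); w <- ncol(I1)
  xs <- grid_x(h, w) + lin_point$u
  ys <- grid_y(h, w) + lin_point$v
  samp <- cpp_bilinear(I2, xs, ys)
  I2w <- samp$value
  Iavg <- 0.5 * (I1 + I2w)
  list(Ix = deriv5(Iavg, "x"), Iy = deriv5(Iavg, "y"), It = I2w - I1,
       valid = 1 - samp$outside, u0 = lin_point$u, v0 = lin_point$v,
       h = h, w = w)
}

# Reweighted Gauss-Seidel relaxation of the linearized subproblem (no
# descent certificate; used inside the alternation loop and by the public
# solver below).
solve_flow_core <- function(lin, aux, init, params, alpha) {
  U <- init$u; V <- init$v
  n_irls <- if (alpha <= 0) 1L else params$irls_iters
  pad_h <- function(d) cbind(d, 0)   # pair weights live at the lower index
  pad_v <- function(d) rbind(d, 0)
  for (k in seq_len(n_irls)) {
    r <- lin$It + lin$Ix * (U - lin$u0) + lin$Iy * (V - lin$v0)
    wD <- lin$valid * rho_weight(r, alpha, params)
    du <- forward_diffs(U); dv <- forward_diffs(V)
    wsu_h <- pad_h(rho_weight(du$dx, alpha, params))
    wsu_v <- pad_v(rho_weight(du$dy, alpha, params))
    wsv_h <- pad_h(rho_weight(dv$dx, alpha, params))
    wsv_v <- pad_v(rho_weight(dv$dy, alpha, params))
    U <- U + 0; V <- V + 0                 # force copies: C++ writes in place
    cpp_sor_flow(lin$Ix, lin$Iy, lin$It, wD, lin$u0, lin$v0,
                 aux$u_hat, aux$v_hat,
                 U, V, wsu_h, wsu_v, wsv_h, wsv_v,
                 params$lambda1, params$lambda2,
                 params$solver_iters, params$sor_omega)
  }
  lim <- max(lin$h, lin$w) / 2
  flow_field(pmin(pmax(U, -lim), lim), pmin(pmax(V, -lim), lim))
}

solve_flow_given_aux <- function(I1, I2, aux, init, params = flow_params(),
                                 alpha = 0) {
  assert_image(I1); assert_image(I2); assert_same_grid(I1, I2)
  assert_flow(init, I1)
  aux <- as_aux(aux)
  lin <- flow_linearize(I1, I2, init)
  out <- solve_flow_core(lin, aux, init, params, alpha)
  e0 <- flow_subproblem_energy(I1, I2, init, aux, params, alpha)
  e1 <- flow_subproblem_energy(I1, I2, out, aux, params, alpha)
  tries <- 0L
  while (e1 > e0 && tries < 6L) {          # backtrack toward init
    out <- flow_field((out$u + init$u) / 2, (out$v + init$v) / 2)
    e1 <- flow_subproblem_energy(I1, I2, out, aux, params, alpha)
    tries <- tries + 1L
  }
  if (e1 > e0) {
    out <- init
    attr(out, "diverged") <- TRUE
  }
  out
}

gaussian_pyramid <- function(img, params) {
  f <- params$pyramid_factor
  n <- max(1L, floor(log(min(dim(img)) / params$min_level_size,
                         base = 1 / f)) + 1L)
  levels <- vector("list", n)
  levels[[1]] <- img
  for (l in seq_len(n - 1L)) {
    prev <- levels[[l]]
    smoothed <- im_gauss(prev, 1)
    levels[[l + 1L]] <- im_resize(smoothed,
                                  max(2L, round(nrow(prev) * f)),
                                  max(2L, round(ncol(prev) * f)))
  }
  levels
}

resize_flow <- function(flow, h, w) {
  su <- w / ncol(flow$u)
  sv <- h / nrow(flow$u)
  flow_field(im_resize(flow$u, h, w) * su,
             im_resize(flow$v, h, w) * sv)
}

# One warping step: linearize once at the current flow, then alternate the
# flow solve (anchored to the auxiliary field) and the auxiliary median
# update; finish with (u,v) <- (u_hat, v_hat). If the warp as a whole fails
# to lower the classical objective it is rolled back.
warp_step <- function(I1, I2, flow, params, alpha) {
  lin <- flow_linearize(I1, I2, flow)
  aux <- aux_field(flow$u, flow$v)               # u_hat^(0) = u
  cur <- flow
  A <- params$alternations
  for (a in seq_len(A)) {
    # coupling continuation: early alternations use a small lambda2 so the
    # smoothness term can propagate flow into flat/aperture-limited
    # regions (and the auxiliary update acts as a wide median filter);
    # the last alternation runs at the configured lambda2
    p2 <- params
    p2$lambda2 <- params$lambda2 * params$coupling_ramp^(a - A)
    cur <- solve_flow_core(lin, aux, cur, p2, alpha)
    aux <- median_update_aux(cur, p2, aux = aux)
  }
  out <- flow_field(aux$u_hat, aux$v_hat)        # (u,v) <- (u_hat, v_hat)
  # divergence guard only: the median step may legitimately raise the
  # classical objective a little (it lowers the coupled one)
  e0 <- classical_energy(I1, I2, flow, params, alpha)
  e1 <- classical_energy(I1, I2, out, params, alpha)
  if (e1 > 2 * e0 + 1e-12) flow else out
}

# One coarse-to-fine pass at a fixed GNC blend. Later GNC stages refine at
# the finest level only (`levels`), keeping the structure recovered by the
# convex stage.
run_pyramid <- function(pyr1, pyr2, params, alpha, init_flow = NULL,
                        levels = NULL) {
  n <- length(pyr1)
  if (is.null(levels)) levels <- rev(seq_len(n))
  flow <- NULL
  for (l in levels) {
    I1 <- pyr1[[l]]; I2 <- pyr2[[l]]
    h <- nrow(I1); w <- ncol(I1)
    flow <- if (is.null(flow)) {
      if (is.null(init_flow)) flow_field(matrix(0, h, w), matrix(0, h, w))
      else resize_flow(init_flow, h, w)
    } else resize_flow(flow, h, w)
    for (wstep in seq_len(params$warps_per_level))
      flow <- warp_step(I1, I2, flow, params, alpha)
  }
  flow
}

#' Estimate the displacement field between two images
#'
#' Full robust-flow schedule: Gaussian pyramids of both images, coarse-to-
#' fine warping with `warps_per_level` alternations of the linearized flow
#' solve and the auxiliary median update per level, run once per GNC stage
#' (stage 1 quadratic, the final stage with the generalized Charbonnier
#' penalty, initialized from the previous stage). The auxiliary field of
#' the last warp is the estimate. The procedure is deterministic.
#'
#' @param I1 Reference image (`[0, 1]` matrix).
#' @param I2 Floating image on the same grid.
#' @param params A [flow_params()].
#' @return A [flow_field()] mapping `I2` onto `I1` (backward-warp
#'   convention).
#' @export
estimate_flow <- function(I1, I2, params = flow_params()) {
  assert_image(I1); assert_image(I2); assert_same_grid(I1, I2)
  h <- nrow(I1); w <- ncol(I1)
  zero <- flow_field(matrix(0, h, w), matrix(0, h, w))
  if (all(I1 == 0) && all(I2 == 0)) return(zero)
  s <- params$intensity_scale
  J1 <- I1 * s; J2 <- I2 * s
  pyr1 <- gaussian_pyramid(J1, params)
  pyr2 <- gaussian_pyramid(J2, params)
  if (length(pyr1) < 2L && min(h, w) > 2 * params$min_level_size)
    warning("image too small for a multi-level pyramid; running one level")
  alphas <- if (params$gnc_stages == 1L) 0 else
    seq(0, 1, length.out = params$gnc_stages)
  flow <- NULL
  for (stage in seq_along(alphas))
    flow <- run_pyramid(pyr1, pyr2, params, alphas[stage], init_flow = flow,
                        levels = if (stage == 1L) NULL else 1L)
  flow
}
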