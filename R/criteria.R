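#' Velocity-gradient tensor field with symmetric/antisymmetric split
#'
#' Computes the velocity-gradient tensor grad(u) by finite differences:
#' second-order central differences at voxels whose +/-1 neighbors are both
#' valid on an axis, first-order one-sided differences where only one
#' neighbor is valid, invalid where neither is. The tensor is split exactly
#' into the rate-of-strain tensor `S = (grad + grad^T)/2` and the vorticity
#' tensor `W = (grad - grad^T)/2`.
#'
#' @param field a [velocity_field()] (velocity mm/s on a mm grid, so tensor
#'   entries are 1/s).
#' @return an object of class `gradient_field`: list with `grid`, `grad`
#'   (array `c(dims, 3, 3)`, `grad[,,,i,j]` = d u_i / d x_j) and `valid`.
#' @export
velocity_gradient <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  d <- field$grid$dims
  h <- field$grid$spacing
  v <- field$valid
  grad <- array(NA_real_, dim = c(d, 3L, 3L))
  valid_out <- array(TRUE, dim = d)

  shift <- function(a, axis, by) {
    # shift array contents by `by` along `axis`, padding with NA/FALSE
    out <- array(if (is.logical(a)) FALSE else NA_real_, dim = dim(a))
    n <- dim(a)[axis]
    src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst <- src
    if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
    else { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }

  for (axis in 1:3) {
    vp <- shift(v, axis, -1)   # validity of the +1 neighbor, aligned to center
    vm <- shift(v, axis, +1)
    axis_valid <- v & (vp | vm)
    valid_out <- valid_out & axis_valid
    for (comp in 1:3) {
      u <- field$velocity[, , , comp]
      up <- shift(u, axis, -1)
      um <- shift(u, axis, +1)
      g <- array(NA_real_, dim = d)
      both <- v & vp & vm
      g[both] <- (up[both] - um[both]) / (2 * h[axis])
      fwd <- v & vp & !vm
      g[fwd] <- (up[fwd] - u[fwd]) / h[axis]
      bwd <- v & !vp & vm
      g[bwd] <- (u[bwd] - um[bwd]) / h[axis]
      grad[, , , comp, axis] <- g
    }
  }
  if (!any(valid_out))
    stop(errorCondition("no voxel has a valid neighbor on every axis: empty gradient",
                        class = c("vortexstab_empty_gradient", "error", "condition")))
  structure(list(grid = field$grid, grad = grad, valid = valid_out),
            class = "gradient_field")
}

#' Rate-of-strain and vorticity tensors of a gradient field
#' @param g a `gradient_field`.
#' @return list with `S` and `W` arrays `c(dims, 3, 3)` such that
#'   `S + W == grad`, `S` symmetric, `W` antisymmetric.
#' @export
strain_vorticity <- function(g) {
  gr <- g$grad
  gt <- aperm(gr, c(1, 2, 3, 5, 4))
  list(S = (gr + gt) / 2, W = (gr - gt) / 2)
}

criterion_field <- function(grid, values, method, valid) {
  structure(list(grid = grid, values = values, method = method, valid = valid),
            class = "criterion_field")
}

#' @export
print.criterion_field <- function(x, ...) {
  rng <- if (any(x$valid)) range(x$values[x$valid]) else c(NA, NA)
  cat(sprintf("criterion_field (%s): %d valid voxels, range [%.4g, %.4g]\n",
              x$method, sum(x$valid), rng[1], rng[2]))
  invisible(x)
}

# TRUE for methods whose vortex voxels are positive (Q-type)
is_q_type <- function(method) method %in% c("Q", "Q_norm")

#' Q-criterion field
#'
#' `Q = (||W||_F^2 - ||S||_F^2) / 2` per voxel (Frobenius norms): positive
#' where the vorticity tensor dominates the rate of strain, the classic
#' vortex-region definition of Hunt et al.
#'
#' @param g a `gradient_field` from [velocity_gradient()].
#' @return a `criterion_field` with method `"Q"` (units 1/s^2).
#' @export
q_field <- function(g) {
  sw <- strain_vorticity(g)
  fro2 <- function(a) {
    out <- 0
    for (i in 1:3) for (j in 1:3) out <- out + a[, , , i, j]^2
    out
  }
  q <- (fro2(sw$W) - fro2(sw$S)) / 2
  q[!g$valid] <- NA_real_
  criterion_field(g$grid, q, "Q", g$valid)
}

#' lambda2 criterion field
#'
#' Per voxel, forms the symmetric tensor `M = S^2 + W^2` and returns its
#' middle (second) eigenvalue, computed with the closed-form trigonometric
#' symmetric 3x3 eigen-solver. Vortex regions are where lambda2 < 0 (Jeong &
#' Hussain).
#'
#' @param g a `gradient_field` from [velocity_gradient()].
#' @return a `criterion_field` with method `"lambda2"` (units 1/s^2).
#' @export
lambda2_field <- function(g) {
  sw <- strain_vorticity(g)
  S <- sw$S; W <- sw$W
  # M = S^2 + W^2, symmetric; build its 6 unique components vectorized
  mcomp <- function(i, j) {
    out <- 0
    for (k in 1:3)
      out <- out + S[, , , i, k] * S[, , , k, j] + W[, , , i, k] * W[, , , k, j]
    out
  }
  m11 <- mcomp(1, 1); m22 <- mcomp(2, 2); m33 <- mcomp(3, 3)
  m12 <- mcomp(1, 2); m13 <- mcomp(1, 3); m23 <- mcomp(2, 3)
  l2 <- symmetric3_middle_eigenvalue(m11, m22, m33, m12, m13, m23)
  l2[!g$valid] <- NA_real_
  criterion_field(g$grid, array(l2, dim = g$grid$dims), "lambda2", g$valid)
}

# middle eigenvalue of symmetric 3x3 matrices, vectorized trigonometric form
symmetric3_middle_eigenvalue <- function(m11, m22, m33, m12, m13, m23) {
  p1 <- m12^2 + m13^2 + m23^2
  q <- (m11 + m22 + m33) / 3
  p2 <- (m11 - q)^2 + (m22 - q)^2 + (m33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  # det((M - qI)/p) / 2, guarded for the isotropic case p == 0
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (m11 - q) / safe_p; b22 <- (m22 - q) / safe_p; b33 <- (m33 - q) / safe_p
  b12 <- m12 / safe_p; b13 <- m13 / safe_p; b23 <- m23 / safe_p
  r <- (b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)) / 2
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  ifelse(p2 <= 0, q, e2)
}

#' Normalize a criterion field by the squared local speed
#'
#' Divides Q or lambda2 by |u|^2 at each voxel, condensing the criterion's
#' dynamic range before thresholding (units become 1/mm^2). Voxels with
#' `|u| < eps * max|u|` (per-phase maximum over valid voxels) are marked
#' invalid and excluded from all downstream statistics rather than set to 0.
#'
#' @param crit a `criterion_field` with method `"Q"` or `"lambda2"`.
#' @param field the [velocity_field()] the criterion was computed from.
#' @param eps relative zero-velocity guard (default 1e-6).
#' @return a `criterion_field` with method `"Q_norm"` or `"lambda2_norm"`.
#' @export
normalize_criterion <- function(crit, field, eps = 1e-6) {
  stopifnot(inherits(crit, "criterion_field"), inherits(field, "velocity_field"))
  if (!crit$method %in% c("Q", "lambda2"))
    stop("criterion is already normalized")
  stopifnot_same_grid(crit$grid, field$grid, "criterion and field")
  sp2 <- field$velocity[, , , 1]^2 + field$velocity[, , , 2]^2 +
         field$velocity[, , , 3]^2
  vmax2 <- max(sp2[field$valid])
  ok <- crit$valid & field$valid & sp2 > (eps^2) * vmax2
  vals <- array(NA_real_, dim = crit$grid$dims)
  vals[ok] <- crit$values[ok] / sp2[ok]
  criterion_field(crit$grid, vals, paste0(crit$method, "_norm"), ok)
}

#' Compute a criterion field series for all cardiac phases
#'
#' Convenience wrapper: per phase, velocity gradient, criterion, optional
#' velocity normalization, optional sac masking.
#'
#' @param series a [velocity_series()].
#' @param method one of `"Q"`, `"lambda2"`, `"Q_norm"`, `"lambda2_norm"`.
#' @param mask optional [sac_mask()] applied after the criterion is computed
#'   (gradients use all valid voxels, so sac-boundary stencils see the full
#'   flow; set `mask_before = TRUE` to mask the velocity first).
#' @param eps zero-velocity guard for the normalized variants.
#' @param mask_before logical; mask the velocity before differentiation.
#' @return list of `criterion_field` objects, one per phase.
#' @export
criterion_series <- function(series, method = c("Q_norm", "Q", "lambda2", "lambda2_norm"),
                             mask = NULL, eps = 1e-6, mask_before = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(series, "velocity_series"))
  lapply(series$phases, function(f) {
    if (mask_before && !is.null(mask)) f <- apply_mask(f, mask)
    g <- velocity_gradient(f)
    crit <- if (method %in% c("Q", "Q_norm")) q_field(g) else lambda2_field(g)
    if (method %in% c("Q_norm", "lambda2_norm"))
      crit <- normalize_criterion(crit, f, eps = eps)
    if (!is.null(mask) && !mask_before) crit <- apply_mask(crit, mask)
    crit
  })
}
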