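# trilinear interpolation of one or more arrays at arbitrary points.
# Returns list(values = n x k matrix, valid = logical n): a point is valid
# only if all 8 stencil corners are in bounds and valid (no extrapolation,
# no clamping).
trilinear_sample <- function(grid, arrays, valid, pts) {
  d <- grid$dims
  t1 <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  t2 <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  t3 <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  i0 <- floor(t1); j0 <- floor(t2); k0 <- floor(t3)
  fx <- t1 - i0; fy <- t2 - j0; fz <- t3 - k0
  # snap points sitting exactly on the last sample plane into the last cell
  snap <- function(i0, f, n) {
    hit <- i0 == n - 1 & f == 0
    list(i0 = ifelse(hit, i0 - 1, i0), f = ifelse(hit, 1, f))
  }
  s <- snap(i0, fx, d[1]); i0 <- s$i0; fx <- s$f
  s <- snap(j0, fy, d[2]); j0 <- s$i0; fy <- s$f
  s <- snap(k0, fz, d[3]); k0 <- s$i0; fz <- s$f
  inb <- i0 >= 0 & i0 <= d[1] - 2 & j0 >= 0 & j0 <= d[2] - 2 &
         k0 >= 0 & k0 <= d[3] - 2
  n <- nrow(pts)
  k_arr <- length(arrays)
  vals <- matrix(NA_real_, n, k_arr)
  ok <- rep(FALSE, n)
  idx <- which(inb)
  if (length(idx)) {
    ii <- i0[idx]; jj <- j0[idx]; kk <- k0[idx]
    wx <- fx[idx]; wy <- fy[idx]; wz <- fz[idx]
    base <- ii + d[1] * (jj + d[2] * kk) + 1   # linear index of (i0,j0,k0)
    stride_y <- d[1]; stride_z <- d[1] * d[2]
    acc <- matrix(0, length(idx), k_arr)
    all_valid <- rep(TRUE, length(idx))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      off <- base + dx + dy * stride_y + dz * stride_z
      w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
           (if (dz) wz else 1 - wz)
      all_valid <- all_valid & valid[off]
      for (a in seq_len(k_arr)) acc[, a] <- acc[, a] + w * arrays[[a]][off]
    }
    ok[idx] <- all_valid
    vals[idx, ] <- acc
    vals[idx[!all_valid], ] <- NA_real_
  }
  list(values = vals, valid = ok)
}

#' Resample a velocity field onto a new voxel spacing
#'
#' Trilinear interpolation at the new voxel centers (the resampling used to
#' standardize velocity data across resolutions, default target 0.2 mm). The
#' new grid keeps the source origin and covers the source bounding box up to
#' one voxel. A target voxel is invalid whenever its interpolation stencil
#' touches any invalid or out-of-bounds source voxel — boundary values are
#' never extrapolated or clamped.
#'
#' @param field a [velocity_field()].
#' @param target_spacing new voxel edge length (mm), scalar or length 3.
#' @return a [velocity_field()] on the new grid.
#' @export
resample_field <- function(field, target_spacing) {
  stopifnot(inherits(field, "velocity_field"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  extent <- (field$grid$dims - 1) * field$grid$spacing
  if (any(target_spacing > extent))
    grid_error("degenerate grid: target_spacing exceeds the domain extent")
  new_dims <- pmax(3L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  new_grid <- voxel_grid(field$grid$origin, target_spacing, new_dims)
  pts <- voxel_centers(new_grid)
  arrays <- list(field$velocity[, , , 1], field$velocity[, , , 2],
                 field$velocity[, , , 3])
  s <- trilinear_sample(field$grid, arrays, field$valid, pts)
  vel <- s$values
  vel[!s$valid, ] <- 0
  velocity_field(new_grid, vel, valid = array(s$valid, dim = new_dims))
}

#' Resample a velocity series onto a new voxel spacing
#' @param series a [velocity_series()].
#' @param target_spacing new voxel edge length (mm).
#' @return a [velocity_series()] on the new grid.
#' @export
resample_series <- function(series, target_spacing) {
  stopifnot(inherits(series, "velocity_series"))
  velocity_series(lapply(series$phases, resample_field,
                         target_spacing = target_spacing),
                  cycle_duration = series$cycle_duration)
}

#' Resample a sac mask onto a new voxel spacing
#'
#' The inside indicator is interpolated trilinearly and thresholded at 0.5;
#' stencils touching the grid boundary are outside.
#'
#' @param mask a [sac_mask()].
#' @param target_spacing new voxel edge length (mm).
#' @return a [sac_mask()] on the new grid.
#' @export
resample_mask <- function(mask, target_spacing) {
  stopifnot(inherits(mask, "sac_mask"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  extent <- (mask$grid$dims - 1) * mask$grid$spacing
  if (any(target_spacing > extent))
    grid_error("degenerate grid: target_spacing exceeds the domain extent")
  new_dims <- pmax(3L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  new_grid <- voxel_grid(mask$grid$origin, target_spacing, new_dims)
  pts <- voxel_centers(new_grid)
  s <- trilinear_sample(mask$grid, list(array(as.double(mask$inside), mask$grid$dims)),
                        array(TRUE, mask$grid$dims), pts)
  inside <- s$valid & !is.na(s$values[, 1]) & s$values[, 1] >= 0.5
  sac_mask(new_grid, array(inside, dim = new_dims))
}
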