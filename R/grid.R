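#' Rectilinear voxel grid descriptor
#'
#' Describes a uniform voxel grid with voxel-centered samples. Index
#' `(1,1,1)` sits at `origin`; axis order is x, y, z; all coordinates in mm.
#' Volumes are `count * prod(spacing)`.
#'
#' @param origin numeric length 3, position of the first voxel center (mm).
#' @param spacing numeric length 3 (or length 1, recycled), voxel edge
#'   lengths (mm); strictly positive.
#' @param dims integer length 3, voxel counts per axis.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dims <- as.integer(dims)
  if (length(origin) != 3L || length(spacing) != 3L || length(dims) != 3L)
    stop("origin, spacing and dims must each have length 3")
  if (any(!is.finite(origin)) || any(!is.finite(spacing)))
    stop("origin and spacing must be finite")
  if (any(spacing <= 0)) stop("spacing must be strictly positive on all axes")
  if (any(dims < 1L)) stop("dims must be >= 1 per axis")
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_error <- function(msg) {
  stop(errorCondition(msg, class = c("vortexstab_grid_error", "error", "condition")))
}

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("vortexstab_format_error", "error", "condition")))
}

#' Axis coordinates of voxel centers
#' @param grid a `voxel_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-center coordinates along the axis (mm).
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Voxel-center coordinates for every voxel
#' @param grid a `voxel_grid`.
#' @return n-voxel x 3 matrix of positions (mm), in array (x fastest) order.
#' @export
voxel_centers <- function(grid) {
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  n <- prod(grid$dims)
  cbind(rep(cx, times = n / grid$dims[1]),
        rep(rep(cy, each = grid$dims[1]), times = grid$dims[3]),
        rep(cz, each = grid$dims[1] * grid$dims[2]))
}

#' Voxel volume of a grid (mm^3)
#' @param grid a `voxel_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Test two grids for equality
#' @param a,b `voxel_grid` objects.
#' @param tol absolute tolerance on origin and spacing (mm).
#' @export
grids_equal <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!grids_equal(a, b))
    grid_error(sprintf("grid mismatch between %s (dims/origin/spacing differ)", what))
  invisible(TRUE)
}

#' Velocity field on a rectilinear grid
#'
#' One cardiac phase's 3-component velocity sampled at voxel centers, with a
#' validity mask marking where velocity is defined (inside the vessel/sac).
#' Units: positions mm, velocity mm/s.
#'
#' @param grid a `voxel_grid`; all axes must have at least 3 voxels so that
#'   gradient stencils have interior voxels.
#' @param velocity 4-D numeric array `c(grid$dims, 3)`, or an n-voxel x 3
#'   matrix in array order.
#' @param valid logical array `grid$dims`; `TRUE` where velocity is defined.
#'   Defaults to all `TRUE`.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(grid, velocity, valid = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(grid$dims < 3L))
    grid_error("velocity fields need dims >= 3 per axis (gradient stencils need interior voxels)")
  n <- prod(grid$dims)
  if (is.matrix(velocity)) {
    if (nrow(velocity) != n || ncol(velocity) != 3L)
      grid_error("velocity matrix must be n_voxels x 3")
    velocity <- array(velocity, dim = c(grid$dims, 3L))
  }
  if (!identical(dim(velocity), c(grid$dims, 3L)))
    grid_error("velocity array must have dim c(dims, 3)")
  if (is.null(valid)) valid <- array(TRUE, dim = grid$dims)
  if (!identical(dim(valid), grid$dims))
    grid_error("valid array must have dim equal to grid dims")
  storage.mode(velocity) <- "double"
  vm <- matrix(velocity, ncol = 3L)
  if (any(valid) && !all(is.finite(vm[as.vector(valid), ])))
    stop("velocity must be finite wherever valid")
  structure(list(grid = grid, velocity = velocity, valid = valid),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- speed(x)
  cat("velocity_field\n")
  print(x$grid)
  cat(sprintf("  valid voxels: %d / %d; max speed %.4g mm/s\n",
              sum(x$valid), prod(x$grid$dims),
              if (any(x$valid)) max(sp[x$valid]) else NA_real_))
  invisible(x)
}

#' Speed (velocity magnitude) array of a field
#' @param field a `velocity_field`.
#' @return numeric array `grid$dims` of |u| (mm/s); NA outside valid voxels.
#' @export
speed <- function(field) {
  s <- sqrt(field$velocity[, , , 1]^2 + field$velocity[, , , 2]^2 +
              field$velocity[, , , 3]^2)
  s[!field$valid] <- NA_real_
  s
}

#' Time-resolved velocity series
#'
#' An ordered list of velocity fields sharing one grid and validity mask,
#' sampled at equally spaced points of one cardiac cycle.
#'
#' @param phases list of `velocity_field` objects on one grid.
#' @param cycle_duration cycle length in seconds (heart rate 60 bpm -> 1 s).
#' @return an object of class `velocity_series`.
#' @export
velocity_series <- function(phases, cycle_duration = 1) {
  if (!is.list(phases) || length(phases) < 2L)
    grid_error("a velocity series needs at least 2 phases")
  if (!all(vapply(phases, inherits, TRUE, "velocity_field")))
    stop("phases must be velocity_field objects")
  g <- phases[[1]]$grid
  for (k in seq_along(phases)[-1]) {
    stopifnot_same_grid(g, phases[[k]]$grid, sprintf("phases 1 and %d", k))
    if (!identical(phases[[1]]$valid, phases[[k]]$valid))
      grid_error(sprintf("validity masks differ between phases 1 and %d", k))
  }
  if (!is.numeric(cycle_duration) || cycle_duration <= 0)
    stop("cycle_duration must be a positive number of seconds")
  structure(list(phases = phases, n_phases = length(phases),
                 cycle_duration = as.numeric(cycle_duration), grid = g),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("velocity_series: %d phases over %g s cardiac cycle\n",
              x$n_phases, x$cycle_duration))
  print(x$grid)
  invisible(x)
}

#' Binary aneurysm-sac voxel mask
#'
#' @param grid a `voxel_grid`, registered with the velocity data.
#' @param inside logical array `grid$dims`, `TRUE` inside the sac.
#' @return an object of class `sac_mask`.
#' @export
sac_mask <- function(grid, inside) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(inside), grid$dims))
    grid_error("mask array must have dim equal to grid dims")
  if (!any(inside)) grid_error("sac mask has no inside voxel")
  structure(list(grid = grid, inside = inside), class = "sac_mask")
}

#' @export
print.sac_mask <- function(x, ...) {
  cat(sprintf("sac_mask: %d inside voxels (%.3f mm^3)\n",
              sum(x$inside), sum(x$inside) * voxel_volume(x$grid)))
  invisible(x)
}

#' Restrict a field to a sac mask
#'
#' Invalidates all voxels outside the mask; values inside are untouched.
#' Works on `velocity_field` and `criterion_field` objects.
#'
#' @param x a `velocity_field` or `criterion_field`.
#' @param mask a `sac_mask` on the same grid.
#' @return an object of the same class with `valid` intersected with the mask.
#'   If the intersection is empty the result carries attribute
#'   `empty_after_mask = TRUE`.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(mask, "sac_mask"))
  stopifnot_same_grid(x$grid, mask$grid, "field and mask")
  x$valid <- x$valid & mask$inside
  if (!any(x$valid)) attr(x, "empty_after_mask") <- TRUE
  x
}
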