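#' Analytic flow specification
#'
#' Describes an analytic velocity field used as a validation fixture with
#' known ground truth: rigid rotation (`solid_body`), a compact-core
#' Lamb-Oseen vortex (`lamb_oseen`), a plane shear (`pure_shear`), or a
#' `superposition` of such components.
#'
#' @param kind one of `"solid_body"`, `"lamb_oseen"`, `"pure_shear"`,
#'   `"superposition"`.
#' @param omega angular velocity (rad/s), solid_body only.
#' @param circulation circulation Gamma (mm^2/s), lamb_oseen only.
#' @param core_radius core radius r_c (mm) of the Lamb-Oseen vortex, > 0.
#' @param shear_rate shear rate gamma (1/s), pure_shear: u = (gamma*(y-c_y), 0, 0).
#' @param center position of the vortex center / shear reference (mm).
#' @param axis rotation axis direction (normalized internally).
#' @param components list of `flow_spec` objects, superposition only.
#' @param drift_path optional n_phases x 3 matrix of per-phase centers (mm);
#'   used by [make_series()].
#' @param noise_sd standard deviation (mm/s) of optional additive Gaussian
#'   velocity noise (seeded; default 0 = off).
#' @return an object of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("solid_body", "lamb_oseen", "pure_shear", "superposition"),
                      omega = NULL, circulation = NULL, core_radius = NULL,
                      shear_rate = NULL, center = c(0, 0, 0), axis = c(0, 0, 1),
                      components = NULL, drift_path = NULL, noise_sd = 0) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  na <- sqrt(sum(axis^2))
  if (na == 0) stop("axis must be a nonzero vector")
  axis <- axis / na
  spec <- structure(list(kind = kind, omega = omega, circulation = circulation,
                         core_radius = core_radius, shear_rate = shear_rate,
                         center = as.numeric(center), axis = axis,
                         components = components, drift_path = drift_path,
                         noise_sd = noise_sd),
                    class = "flow_spec")
  switch(kind,
    solid_body = if (is.null(omega)) stop("solid_body requires omega"),
    lamb_oseen = {
      if (is.null(circulation) || is.null(core_radius))
        stop("lamb_oseen requires circulation and core_radius")
      if (core_radius <= 0) stop("core_radius must be > 0")
    },
    pure_shear = if (is.null(shear_rate)) stop("pure_shear requires shear_rate"),
    superposition = {
      if (!is.list(components) || length(components) == 0 ||
          !all(vapply(components, inherits, TRUE, "flow_spec")))
        stop("superposition requires a list of flow_spec components")
    })
  if (!is.null(drift_path)) {
    drift_path <- as.matrix(drift_path)
    if (ncol(drift_path) != 3L) stop("drift_path must be an n_phases x 3 matrix")
    spec$drift_path <- drift_path
  }
  spec
}

# velocity (n x 3) of the analytic field at positions xyz (n x 3)
eval_flow <- function(spec, xyz, center = spec$center) {
  n <- nrow(xyz)
  a <- spec$axis
  rel <- cbind(xyz[, 1] - center[1], xyz[, 2] - center[2], xyz[, 3] - center[3])
  switch(spec$kind,
    solid_body = {
      # u = omega * a x (x - c)
      spec$omega * cbind(a[2] * rel[, 3] - a[3] * rel[, 2],
                         a[3] * rel[, 1] - a[1] * rel[, 3],
                         a[1] * rel[, 2] - a[2] * rel[, 1])
    },
    lamb_oseen = {
      # tangential speed Gamma/(2 pi r) (1 - exp(-r^2/rc^2)); r is the
      # distance from the axis line. Written as coef(r^2) * (a x rel) with
      # |a x rel| = r, so the r -> 0 limit Gamma/(2 pi rc^2) is explicit.
      tang <- cbind(a[2] * rel[, 3] - a[3] * rel[, 2],
                    a[3] * rel[, 1] - a[1] * rel[, 3],
                    a[1] * rel[, 2] - a[2] * rel[, 1])
      r2 <- tang[, 1]^2 + tang[, 2]^2 + tang[, 3]^2
      rc2 <- spec$core_radius^2
      coef <- ifelse(r2 < 1e-24,
                     spec$circulation / (2 * pi * rc2),
                     spec$circulation * (-expm1(-r2 / rc2)) / (2 * pi * r2))
      tang * coef
    },
    pure_shear = cbind(spec$shear_rate * rel[, 2], numeric(n), numeric(n)),
    superposition = {
      u <- matrix(0, n, 3)
      for (cmp in spec$components) u <- u + eval_flow(cmp, xyz)
      u
    })
}

#' Evaluate an analytic flow on a grid
#'
#' Voxel-center evaluation of the analytic velocity field described by a
#' [flow_spec()]. With `noise_sd > 0`, seeded Gaussian noise is added to
#' every component (bit-reproducible for a fixed seed).
#'
#' @param spec a `flow_spec`.
#' @param grid a `voxel_grid`.
#' @param center optional center override (used for drifting series).
#' @param seed RNG seed for the optional noise.
#' @return a [velocity_field()].
#' @export
make_field <- function(spec, grid, center = spec$center, seed = NULL) {
  u <- eval_flow(spec, voxel_centers(grid), center = center)
  if (!is.null(spec$noise_sd) && spec$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    u <- u + matrix(stats::rnorm(length(u), sd = spec$noise_sd), ncol = 3)
  }
  velocity_field(grid, u)
}

#' Pulsatile waveform
#'
#' Per-phase non-negative multipliers applied to a base analytic field to
#' emulate pulsatile flow over the cardiac cycle.
#'
#' @param samples numeric vector of n_phases finite, non-negative scalars,
#'   at least one nonzero.
#' @return an object of class `waveform` (a numeric vector with a class).
#' @export
waveform <- function(samples) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  if (any(samples < 0)) stop("waveform samples must be non-negative")
  if (all(samples == 0)) stop("waveform must have at least one nonzero sample")
  structure(samples, class = "waveform")
}

#' Default pulsatile waveform
#'
#' A smooth positive systole/diastole-like modulation, `1 + depth*sin(2*pi*t)`
#' over one cycle; mean 1 by construction.
#'
#' @param n_phases number of cardiac-cycle data points (default 21).
#' @param depth modulation depth in (0, 1).
#' @export
pulsatile_waveform <- function(n_phases = 21, depth = 0.5) {
  t <- (seq_len(n_phases) - 1) / n_phases
  waveform(1 + depth * sin(2 * pi * t))
}

#' Build a pulsatile velocity series from an analytic flow
#'
#' Phase k's field is `waveform[k]` times the base field, evaluated with the
#' center moved to `drift_path[k, ]` when the spec carries a drift path
#' (center fixed otherwise).
#'
#' @param spec a `flow_spec` (its `drift_path`, when present, must have one
#'   row per waveform sample).
#' @param wf a [waveform()] (its length sets n_phases).
#' @param grid a `voxel_grid`.
#' @param cycle_duration cardiac cycle length (s).
#' @param seed RNG seed for optional noise; phase k uses `seed + k`.
#' @return a [velocity_series()].
#' @export
make_series <- function(spec, wf, grid, cycle_duration = 1, seed = NULL) {
  stopifnot(inherits(spec, "flow_spec"), inherits(wf, "waveform"))
  n_phases <- length(wf)
  if (!is.null(spec$drift_path) && nrow(spec$drift_path) != n_phases)
    stop("drift_path length must equal the number of waveform samples")
  phases <- vector("list", n_phases)
  for (k in seq_len(n_phases)) {
    ctr <- if (is.null(spec$drift_path)) spec$center else spec$drift_path[k, ]
    f <- make_field(spec, grid, center = ctr,
                    seed = if (is.null(seed)) NULL else seed + k)
    f$velocity <- f$velocity * unclass(wf)[k]
    phases[[k]] <- f
  }
  velocity_series(phases, cycle_duration = cycle_duration)
}

#' Synthetic sealed aneurysm-sac mesh, ostium labels and voxel mask
#'
#' Builds a synthetic watertight sac surface — a hemispherical dome (or half
#' an ellipsoid) sealed by a flat triangulated ostium cap — with the cap
#' faces labeled, plus the matching binary voxel mask on a grid. The dome
#' points along +z; the ostium plane is `z = center[3]`.
#'
#' @param shape `"hemisphere"` or `"ellipsoid_cap"`.
#' @param radius dome radius (mm); for `ellipsoid_cap` a length-3 vector of
#'   semi-axes (a, b, c).
#' @param center ostium-plane center (mm).
#' @param grid a `voxel_grid` the mask is rasterized on; the sac must fit
#'   inside the grid bounds.
#' @param n_seg azimuthal segments of the tessellation (default 96).
#' @param n_rings polar rings pole-to-equator (default `n_seg %/% 2`).
#' @return list with `mesh` (a `surface_mesh` whose `cap` entry flags ostium
#'   faces) and `mask` (a [sac_mask()]).
#' @export
make_sac_mesh <- function(shape = c("hemisphere", "ellipsoid_cap"), radius,
                          center = c(0, 0, 0), grid = NULL,
                          n_seg = 96L, n_rings = NULL) {
  shape <- match.arg(shape)
  semi <- if (shape == "hemisphere") rep(radius[1], 3) else {
    if (length(radius) != 3) stop("ellipsoid_cap requires 3 semi-axes")
    as.numeric(radius)
  }
  if (is.null(n_rings)) n_rings <- max(8L, n_seg %/% 2L)
  # dome vertices: pole + rings at polar angle theta in (0, pi/2]
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  verts <- matrix(center, 1, 3, byrow = TRUE)          # 1: pole
  for (i in seq_len(n_rings)) {
    th <- i * (pi / 2) / n_rings
    verts <- rbind(verts, cbind(center[1] + semi[1] * sin(th) * cos(phi),
                                center[2] + semi[2] * sin(th) * sin(phi),
                                center[3] + semi[3] * cos(th)))
  }
  verts[1, 3] <- center[3] + semi[3]
  ring_start <- function(i) 2L + (i - 1L) * n_seg     # first vertex of ring i
  nxt <- c(seq_len(n_seg)[-1], 1L)
  faces <- NULL
  # pole fan (outward normals: counter-clockwise seen from +z outside)
  r1 <- ring_start(1L)
  faces <- rbind(faces, cbind(1L, r1 + seq_len(n_seg) - 1L, r1 + nxt - 1L))
  # ring bands
  for (i in seq_len(n_rings - 1L)) {
    a <- ring_start(i) + seq_len(n_seg) - 1L; a2 <- ring_start(i) + nxt - 1L
    b <- ring_start(i + 1L) + seq_len(n_seg) - 1L; b2 <- ring_start(i + 1L) + nxt - 1L
    faces <- rbind(faces, cbind(a, b, b2), cbind(a, b2, a2))
  }
  n_dome_faces <- nrow(faces)
  # ostium cap: fan from cap center to the equator ring, normals along -z
  cap_center_id <- nrow(verts) + 1L
  verts <- rbind(verts, center)
  e <- ring_start(n_rings) + seq_len(n_seg) - 1L; e2 <- ring_start(n_rings) + nxt - 1L
  faces <- rbind(faces, cbind(cap_center_id, e2, e))
  cap <- c(rep(FALSE, n_dome_faces), rep(TRUE, n_seg))
  mesh <- surface_mesh(verts, faces, cap = cap)
  mask <- NULL
  if (!is.null(grid)) {
    lo <- grid$origin; hi <- grid$origin + (grid$dims - 1) * grid$spacing
    if (any(apply(verts, 2, min) < lo - 1e-9) ||
        any(apply(verts, 2, max) > hi + 1e-9))
      stop("sac radius too large for grid: surface exceeds grid bounds")
    mask <- voxelize_surface(mesh, grid)
  }
  list(mesh = mesh, mask = mask)
}

#' Synthetic wall-shear-stress vector time series
#'
#' Fixture generator for the OSI / TA-WSS metrics: per-vertex WSS vectors
#' over the cardiac cycle with controllable directional reversal.
#'
#' Patterns: `constant` repeats the same vector every phase (OSI 0);
#' `full_reversal` flips the sign for the second half of the phases (OSI 0.5
#' for even n_phases); `partial_reversal` flips the sign on `round(fraction *
#' n_phases)` phases; `random` draws seeded iid normal components.
#'
#' @param n_vertices number of wall vertices.
#' @param n_phases number of cardiac-cycle data points (>= 2).
#' @param pattern one of `"constant"`, `"full_reversal"`,
#'   `"partial_reversal"`, `"random"`.
#' @param fraction fraction of phases with reversed sign
#'   (`partial_reversal`), in \[0, 1\].
#' @param magnitude base WSS magnitude (Pa).
#' @param seed RNG seed (used by `random`).
#' @return a [wall_series()].
#' @export
make_wall_series <- function(n_vertices, n_phases,
                             pattern = c("constant", "full_reversal",
                                         "partial_reversal", "random"),
                             fraction = 0.25, magnitude = 1, seed = 1) {
  pattern <- match.arg(pattern)
  if (n_phases < 2) stop("n_phases must be >= 2")
  if (pattern == "partial_reversal" && (fraction < 0 || fraction > 1))
    stop("fraction must lie in [0, 1]")
  base <- c(magnitude, 0, 0)
  tau <- array(0, dim = c(n_vertices, n_phases, 3))
  signs <- switch(pattern,
    constant = rep(1, n_phases),
    full_reversal = rep(c(1, -1), each = ceiling(n_phases / 2))[seq_len(n_phases)],
    partial_reversal = {
      k <- round(fraction * n_phases)
      c(rep(-1, k), rep(1, n_phases - k))
    },
    random = NULL)
  if (pattern == "random") {
    set.seed(seed)
    tau <- array(stats::rnorm(n_vertices * n_phases * 3), dim = dim(tau))
  } else {
    for (p in seq_len(n_phases))
      tau[, p, ] <- matrix(signs[p] * base, n_vertices, 3, byrow = TRUE)
  }
  vertices <- cbind(seq_len(n_vertices), 0, 0)
  wall_series(vertices, tau)
}
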