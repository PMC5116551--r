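#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, oriented with
#'   outward normals for closed surfaces.
#' @param cap optional logical vector of length m flagging ostium-cap faces.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, cap = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be m x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(cap) && length(cap) != nrow(faces))
    stop("cap labels must have one entry per face")
  structure(list(vertices = vertices, faces = faces, cap = cap),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$cap)) sprintf(" (%d ostium-cap faces)", sum(x$cap)) else ""))
  invisible(x)
}

# undirected edge keys of all faces, 3 per face (i < j packed into one double)
edge_keys <- function(faces, nv) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  (lo - 1) * as.double(nv) + hi
}

#' Check that a surface mesh is watertight and consistently oriented
#'
#' Every undirected edge must be shared by exactly two faces, and each
#' directed edge must appear exactly once (consistent orientation).
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE` invisibly, or an error describing the defect.
#' @export
check_watertight <- function(mesh) {
  nv <- nrow(mesh$vertices)
  tab <- table(edge_keys(mesh$faces, nv))
  if (any(tab != 2L))
    stop(errorCondition("mesh is not watertight: edges not shared by exactly 2 faces",
                        class = c("vortexstab_topology_error", "error", "condition")))
  dir <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  dkey <- (dir[, 1] - 1) * as.double(nv) + dir[, 2]
  if (anyDuplicated(dkey))
    stop(errorCondition("mesh orientation is inconsistent: repeated directed edge",
                        class = c("vortexstab_topology_error", "error", "condition")))
  invisible(TRUE)
}

#' Enclosed volume of a closed oriented mesh (divergence theorem)
#' @param mesh a `surface_mesh` (outward-oriented).
#' @return volume (mm^3), positive for outward orientation.
#' @export
mesh_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  sum(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz) / 6
}

face_areas <- function(mesh, which_faces = seq_len(nrow(mesh$faces))) {
  f <- mesh$faces[which_faces, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE] - a
  c3 <- mesh$vertices[f[, 3], , drop = FALSE] - a
  nx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  ny <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  nz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  0.5 * sqrt(nx^2 + ny^2 + nz^2)
}

# ordered boundary loop(s) of a face subset: edges used exactly once
boundary_loop <- function(mesh, face_ids) {
  f <- mesh$faces[face_ids, , drop = FALSE]
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1L))
  be <- e[key %in% once, , drop = FALSE]
  if (nrow(be) == 0L) stop("face subset has no boundary")
  # walk the loop
  nxt <- be[, 2]; names(nxt) <- be[, 1]
  if (anyDuplicated(be[, 1]) || length(unique(be[, 1])) != nrow(be))
    stop("ostium cap boundary is not a single simple loop")
  start <- be[1, 1]; loop <- start; cur <- start
  for (i in seq_len(nrow(be))) {
    cur <- nxt[as.character(cur)]
    if (is.na(cur)) stop("ostium cap boundary is not closed")
    if (cur == start) break
    loop <- c(loop, cur)
  }
  if (length(loop) != nrow(be))
    stop("ostium cap has multiple boundary loops")
  as.integer(loop)
}

#' Voxelize a closed surface into a binary sac mask
#'
#' A voxel is inside iff its center lies inside the closed surface, decided
#' by x-ray parity: for each (y, z) voxel column the crossings of the ray
#' with the triangles are counted and centers between odd/even crossings are
#' inside. Ray origins are nudged by a tiny constant offset so rays passing
#' exactly through mesh edges are avoided; the offset is identical for all
#' rays, preserving translation equivariance by whole voxels.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param grid a `voxel_grid`.
#' @return a [sac_mask()]. A surface entirely outside the grid gives an
#'   empty-mask error.
#' @export
voxelize_surface <- function(mesh, grid) {
  check_watertight(mesh)
  eps <- 1e-7 * max(grid$spacing)
  ys <- axis_coords(grid, 2) + eps
  zs <- axis_coords(grid, 3) + eps * 0.618
  xs <- axis_coords(grid, 1)
  ny <- grid$dims[2]; nz <- grid$dims[3]
  # per-ray list of crossing x positions, accumulated triangle by triangle
  cross_x <- vector("list", ny * nz)
  V <- mesh$vertices; F <- mesh$faces
  for (t in seq_len(nrow(F))) {
    p1 <- V[F[t, 1], ]; p2 <- V[F[t, 2], ]; p3 <- V[F[t, 3], ]
    ylo <- min(p1[2], p2[2], p3[2]); yhi <- max(p1[2], p2[2], p3[2])
    zlo <- min(p1[3], p2[3], p3[3]); zhi <- max(p1[3], p2[3], p3[3])
    iy <- which(ys >= ylo & ys <= yhi); iz <- which(zs >= zlo & zs <= zhi)
    if (!length(iy) || !length(iz)) next
    gy <- rep(ys[iy], times = length(iz)); gz <- rep(zs[iz], each = length(iy))
    # barycentric solve in the (y, z) plane
    d <- (p2[2] - p1[2]) * (p3[3] - p1[3]) - (p3[2] - p1[2]) * (p2[3] - p1[3])
    if (abs(d) < 1e-14) next                       # triangle parallel to ray
    wy <- gy - p1[2]; wz <- gz - p1[3]
    l2 <- (wy * (p3[3] - p1[3]) - wz * (p3[2] - p1[2])) / d
    l3 <- (wz * (p2[2] - p1[2]) - wy * (p2[3] - p1[3])) / d
    hit <- l2 >= 0 & l3 >= 0 & (l2 + l3) <= 1
    if (!any(hit)) next
    xh <- p1[1] + l2[hit] * (p2[1] - p1[1]) + l3[hit] * (p3[1] - p1[1])
    ray <- (rep(iz, each = length(iy))[hit] - 1L) * ny + rep(iy, times = length(iz))[hit]
    for (k in seq_along(ray))
      cross_x[[ray[k]]] <- c(cross_x[[ray[k]]], xh[k])
  }
  inside <- array(FALSE, dim = grid$dims)
  for (r in which(lengths(cross_x) > 0)) {
    cx <- sort(cross_x[[r]])
    if (length(cx) %% 2 != 0) next               # grazing hit; skip ray
    iy <- (r - 1L) %% ny + 1L; iz <- (r - 1L) %/% ny + 1L
    for (k in seq(1, length(cx), by = 2))
      inside[xs > cx[k] & xs < cx[k + 1], iy, iz] <- TRUE
  }
  if (!any(inside))
    grid_error("voxelized surface produced an empty mask (surface outside grid bounds?)")
  sac_mask(grid, inside)
}

#' Geometric characteristics of an aneurysm sac
#'
#' Computes the six standard morphological metrics from a sealed sac mesh
#' whose ostium-cap faces are labeled: sac volume (divergence theorem over
#' all faces), ostium area (cap face-area sum), ostium circumference (cap
#' boundary-loop length), aneurysm height (distance from the cap area
#' centroid to the farthest dome vertex), aspect ratio (height divided by the
#' widest ostium diameter, i.e. the maximum pairwise distance among cap
#' boundary vertices), and the volume / ostium-area ratio.
#'
#' @param mesh a watertight `surface_mesh` with a `cap` label vector whose
#'   boundary is a single closed loop.
#' @return an object of class `geometry_metrics`: a list with `volume_mm3`,
#'   `ostium_area_mm2`, `ostium_circumference_mm`, `height_mm`,
#'   `ostium_diameter_mm`, `aspect_ratio`, `volume_ostium_ratio_mm`.
#' @export
geometry_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(mesh$cap) || !any(mesh$cap))
    stop("mesh has no labeled ostium-cap faces")
  check_watertight(mesh)
  vol <- abs(mesh_volume(mesh))
  cap_ids <- which(mesh$cap)
  areas <- face_areas(mesh, cap_ids)
  ost_area <- sum(areas)
  # area-weighted centroid of the cap
  fc <- mesh$faces[cap_ids, , drop = FALSE]
  cent <- (mesh$vertices[fc[, 1], , drop = FALSE] +
           mesh$vertices[fc[, 2], , drop = FALSE] +
           mesh$vertices[fc[, 3], , drop = FALSE]) / 3
  cap_centroid <- colSums(cent * areas) / ost_area
  loop <- boundary_loop(mesh, cap_ids)
  lv <- mesh$vertices[loop, , drop = FALSE]
  seg <- lv[c(seq_len(nrow(lv))[-1], 1L), , drop = FALSE] - lv
  circumference <- sum(sqrt(rowSums(seg^2)))
  # farthest dome (non-cap) vertex from the cap centroid
  dome_v <- unique(as.vector(mesh$faces[!mesh$cap, , drop = FALSE]))
  dv <- mesh$vertices[dome_v, , drop = FALSE]
  height <- sqrt(max(rowSums(sweep(dv, 2, cap_centroid)^2)))
  diameter <- sqrt(max(stats::dist(lv)^2))
  structure(list(volume_mm3 = vol,
                 ostium_area_mm2 = ost_area,
                 ostium_circumference_mm = circumference,
                 height_mm = height,
                 ostium_diameter_mm = diameter,
                 aspect_ratio = height / diameter,
                 volume_ostium_ratio_mm = vol / ost_area),
            class = "geometry_metrics")
}

#' @export
print.geometry_metrics <- function(x, ...) {
  cat("Aneurysm sac geometry\n")
  cat(sprintf("  volume:               %8.3f mm^3\n", x$volume_mm3))
  cat(sprintf("  ostium area:          %8.3f mm^2\n", x$ostium_area_mm2))
  cat(sprintf("  ostium circumference: %8.3f mm\n", x$ostium_circumference_mm))
  cat(sprintf("  height:               %8.3f mm\n", x$height_mm))
  cat(sprintf("  aspect ratio:         %8.3f\n", x$aspect_ratio))
  cat(sprintf("  volume/ostium area:   %8.3f mm\n", x$volume_ostium_ratio_mm))
  invisible(x)
}
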