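#' Pooled criterion statistics for threshold selection
#'
#' Mean and sample standard deviation of the qualifying-sign criterion values
#' (Q-type: values > 0; lambda2-type: values < 0) over valid, in-mask voxels,
#' pooled across all phases of a case, so one fixed iso-level underlies every
#' phase's structure and the cycle-averaged structure.
#'
#' @param crits a `criterion_field` or a list of them (one per phase).
#' @param mask optional [sac_mask()] restricting the population.
#' @return list with `mean`, `sd`, `n` and `method`.
#' @export
criterion_statistics <- function(crits, mask = NULL) {
  if (inherits(crits, "criterion_field")) crits <- list(crits)
  method <- crits[[1]]$method
  qtype <- is_q_type(method)
  vals <- unlist(lapply(crits, function(cf) {
    if (cf$method != method) stop("criterion methods differ across phases")
    sel <- cf$valid
    if (!is.null(mask)) {
      stopifnot_same_grid(cf$grid, mask$grid, "criterion and mask")
      sel <- sel & mask$inside
    }
    v <- cf$values[sel]
    if (qtype) v[v > 0] else v[v < 0]
  }), use.names = FALSE)
  if (length(vals) < 2L)
    stop(errorCondition(
      sprintf("no vortex detected: fewer than 2 qualifying %s voxels", method),
      class = c("vortexstab_empty_population", "error", "condition")))
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals), method = method)
}

#' The five-threshold ladder
#'
#' Candidate iso-levels derived from the qualifying-sign statistics, in
#' ascending order: `[mean/4, mean/2, mean, mean + STD/2, mean + STD]` for
#' Q-type methods and `[mean - STD, mean - STD/2, mean, mean/2, mean/4]` for
#' lambda2-type methods (ascending because the mean is negative).
#'
#' @param mean,sd statistics from [criterion_statistics()] (or that list
#'   itself passed as `mean`).
#' @param method criterion method tag.
#' @return named numeric vector of 5 ascending thresholds; duplicated entries
#'   (possible when `sd` is 0) are kept but flagged with a warning.
#' @export
threshold_ladder <- function(mean, sd = NULL, method = NULL) {
  if (is.list(mean)) { sd <- mean$sd; method <- mean$method; mean <- mean$mean }
  qtype <- is_q_type(method)
  if (qtype && mean <= 0)
    stop("Q-type threshold statistics must have positive mean")
  if (!qtype && mean >= 0)
    stop("lambda2-type threshold statistics must have negative mean")
  if (sd < 0) stop("sd must be non-negative")
  lad <- if (qtype)
    c("mean/4" = mean / 4, "mean/2" = mean / 2, "mean" = mean,
      "mean+STD/2" = mean + sd / 2, "mean+STD" = mean + sd)
  else
    c("mean-STD" = mean - sd, "mean-STD/2" = mean - sd / 2, "mean" = mean,
      "mean/2" = mean / 2, "mean/4" = mean / 4)
  if (anyDuplicated(lad))
    warning("degenerate ladder: repeated threshold values (sd = 0?)")
  lad
}

#' Binarize a criterion field at a threshold
#'
#' Q-type: voxel is vortex if `value > threshold`; lambda2-type: if
#' `value < threshold`. Invalid and out-of-mask voxels are always FALSE.
#'
#' @param crit a `criterion_field`.
#' @param threshold iso-level, sign-consistent with the method.
#' @param mask optional [sac_mask()].
#' @return logical array of the grid dims.
#' @export
binarize <- function(crit, threshold, mask = NULL) {
  stopifnot(inherits(crit, "criterion_field"))
  qtype <- is_q_type(crit$method)
  if (qtype && threshold <= 0)
    stop("Q-type thresholds must be positive")
  if (!qtype && threshold >= 0)
    stop("lambda2-type thresholds must be negative")
  b <- array(FALSE, dim = crit$grid$dims)
  sel <- crit$valid
  if (!is.null(mask)) {
    stopifnot_same_grid(crit$grid, mask$grid, "criterion and mask")
    sel <- sel & mask$inside
  }
  b[sel] <- if (qtype) crit$values[sel] > threshold else crit$values[sel] < threshold
  b
}

# 26-connected neighbor offsets (positive half, 13 of them)
neighbor_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), , drop = FALSE]
  key <- off[, 1] + 3 * off[, 2] + 9 * off[, 3]
  off[key > 0, , drop = FALSE]
}

#' Label connected components of a binary voxel set
#'
#' 26-neighbor connectivity (voxels sharing a face, edge or corner belong to
#' one component). Labels are assigned deterministically in order of each
#' component's smallest linear voxel index.
#'
#' @param binary logical 3-D array.
#' @param grid optional [voxel_grid()] supplying the voxel volume; a plain
#'   spacing vector is also accepted.
#' @return list of class `labeled_components`: `labels` (integer array, 0 =
#'   background), `n`, `sizes` (voxel counts per label) and `volumes_mm3`
#'   (when a grid/spacing is given).
#' @export
label_components <- function(binary, grid = NULL) {
  d <- dim(binary)
  labels <- array(0L, dim = d)
  idx <- which(binary)
  if (length(idx) == 0L)
    return(structure(list(labels = labels, n = 0L, sizes = integer(0),
                          volumes_mm3 = numeric(0)),
                     class = "labeled_components"))
  # voxel coordinates of the set
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  off <- neighbor_offsets_26()
  edges_from <- integer(0); edges_to <- integer(0)
  for (o in seq_len(nrow(off))) {
    ni <- i + off[o, 1]; nj <- j + off[o, 2]; nk <- k + off[o, 3]
    inb <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
    nidx <- ni + d[1] * (nj + d[2] * nk) + 1L
    m <- match(nidx, idx)            # neighbor's position in the set
    m[!inb] <- NA_integer_
    hit <- which(!is.na(m))
    edges_from <- c(edges_from, hit)
    edges_to <- c(edges_to, m[hit])
  }
  g <- igraph::make_graph(rbind(edges_from, edges_to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # deterministic relabeling by smallest linear index per component
  first_idx <- tapply(idx, memb, min)
  ord <- order(first_idx)
  relab <- integer(length(first_idx)); relab[ord] <- seq_along(ord)
  lab <- relab[memb]
  labels[idx] <- lab
  sizes <- tabulate(lab)
  vol <- if (!is.null(grid)) {
    sp <- if (inherits(grid, "voxel_grid")) grid$spacing else rep(grid, length.out = 3)
    sizes * prod(sp)
  } else numeric(0)
  structure(list(labels = labels, n = length(sizes), sizes = sizes,
                 volumes_mm3 = vol),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("labeled_components: %d components, %d voxels total\n",
              x$n, sum(x$sizes)))
  invisible(x)
}

#' Filter labeled components by minimum volume
#'
#' Implements the small-structure filter: only connected vortex-core regions
#' whose volume meets the cutoff (default 0.5 mm^3) are counted as cores.
#'
#' @param lab a `labeled_components` with `volumes_mm3` (grid must have been
#'   supplied to [label_components()]).
#' @param min_volume volume cutoff (mm^3), default 0.5.
#' @param comparison `">="` (default) or `">"`.
#' @return list of class `vortex_structure`: `retained` (label ids), `n_cores`,
#'   `core_volumes_mm3`, `total_volume_mm3` and `voxels` (logical array of
#'   retained voxels).
#' @export
filter_components <- function(lab, min_volume = 0.5, comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(lab, "labeled_components"))
  if (lab$n > 0 && length(lab$volumes_mm3) == 0L)
    stop("label_components must be called with a grid to supply volumes")
  keep <- if (lab$n == 0L) integer(0)
    else which(if (comparison == ">=") lab$volumes_mm3 >= min_volume
               else lab$volumes_mm3 > min_volume)
  voxels <- array(lab$labels %in% keep & lab$labels > 0L, dim = dim(lab$labels))
  structure(list(retained = keep,
                 n_cores = length(keep),
                 core_volumes_mm3 = lab$volumes_mm3[keep],
                 total_volume_mm3 = sum(lab$volumes_mm3[keep]),
                 voxels = voxels,
                 labels = lab$labels),
            class = "vortex_structure")
}

#' @export
print.vortex_structure <- function(x, ...) {
  cat(sprintf("vortex_structure: %d retained core(s), total volume %.3f mm^3\n",
              x$n_cores, x$total_volume_mm3))
  invisible(x)
}

#' Segment the vortex structure of one criterion field
#'
#' Binarize at the threshold, label 26-connected components, apply the
#' minimum-volume filter.
#'
#' @param crit a `criterion_field`.
#' @param threshold iso-level (sign-consistent with the method).
#' @param mask optional [sac_mask()].
#' @param min_volume component volume cutoff (mm^3).
#' @param comparison volume-filter comparison, `">="` or `">"`.
#' @return a `vortex_structure` (see [filter_components()]).
#' @export
segment_structure <- function(crit, threshold, mask = NULL, min_volume = 0.5,
                              comparison = ">=") {
  b <- binarize(crit, threshold, mask)
  lab <- label_components(b, crit$grid)
  filter_components(lab, min_volume = min_volume, comparison = comparison)
}

#' Extract the iso-surface of a criterion field (marching tetrahedra)
#'
#' Triangulates the threshold level set of the criterion field for export and
#' visualization. Each grid cell is split into six tetrahedra and the linear
#' iso-surface is extracted per tetrahedron, giving a closed, consistently
#' oriented triangulation of the super-threshold region (lambda2-type fields
#' are negated internally so the vortex side is always the positive side).
#' Invalid voxels and a one-voxel pad around the domain count as outside, so
#' surfaces close at the boundary. Core counting and volumes use the voxel
#' set, not these surfaces; the enclosed volume reported here (divergence
#' theorem) is for reporting only.
#'
#' @param crit a `criterion_field`.
#' @param threshold iso-level (sign-consistent with the method).
#' @param mask optional [sac_mask()].
#' @return a [surface_mesh()] with attribute `enclosed_volume_mm3`, or `NULL`
#'   (with a warning) when the threshold lies outside the field range.
#' @export
extract_surfaces <- function(crit, threshold, mask = NULL) {
  stopifnot(inherits(crit, "criterion_field"))
  qtype <- is_q_type(crit$method)
  f <- crit$values
  sel <- crit$valid
  if (!is.null(mask)) {
    stopifnot_same_grid(crit$grid, mask$grid, "criterion and mask")
    sel <- sel & mask$inside
  }
  # signed level-set function: positive inside the vortex region
  f <- if (qtype) f - threshold else threshold - f
  f[!sel] <- -1
  if (all(f <= 0, na.rm = TRUE)) {
    warning("threshold outside field range: empty surface")
    return(NULL)
  }
  d <- dim(f)
  # pad with outside values so the surface closes at the domain boundary
  pd <- d + 2L
  fp <- array(-1, dim = pd)
  fp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- f
  xs <- c(axis_coords(crit$grid, 1)[1] - crit$grid$spacing[1],
          axis_coords(crit$grid, 1),
          axis_coords(crit$grid, 1)[d[1]] + crit$grid$spacing[1])
  ys <- c(axis_coords(crit$grid, 2)[1] - crit$grid$spacing[2],
          axis_coords(crit$grid, 2),
          axis_coords(crit$grid, 2)[d[2]] + crit$grid$spacing[2])
  zs <- c(axis_coords(crit$grid, 3)[1] - crit$grid$spacing[3],
          axis_coords(crit$grid, 3),
          axis_coords(crit$grid, 3)[d[3]] + crit$grid$spacing[3])
  tris <- marching_tetrahedra(fp, xs, ys, zs)
  if (is.null(tris) || nrow(tris$v1) == 0L) {
    warning("threshold outside field range: empty surface")
    return(NULL)
  }
  nt <- nrow(tris$v1)
  verts <- rbind(tris$v1, tris$v2, tris$v3)
  faces <- cbind(seq_len(nt), seq_len(nt) + nt, seq_len(nt) + 2L * nt)
  vol <- sum(tris$v1[, 1] * (tris$v2[, 2] * tris$v3[, 3] - tris$v2[, 3] * tris$v3[, 2]) +
             tris$v1[, 2] * (tris$v2[, 3] * tris$v3[, 1] - tris$v2[, 1] * tris$v3[, 3]) +
             tris$v1[, 3] * (tris$v2[, 1] * tris$v3[, 2] - tris$v2[, 2] * tris$v3[, 1])) / 6
  mesh <- surface_mesh(verts, faces)
  attr(mesh, "enclosed_volume_mm3") <- abs(vol)
  mesh
}

# vectorized marching tetrahedra over a padded scalar array.
# fp: values (positive = inside); xs/ys/zs: voxel-center coordinates.
# Returns list(v1, v2, v3): matched rows are triangle vertices, oriented so
# that the signed divergence-theorem volume of the closed surface is positive.
marching_tetrahedra <- function(fp, xs, ys, zs) {
  d <- dim(fp)
  nxc <- d[1] - 1L; nyc <- d[2] - 1L; nzc <- d[3] - 1L
  # cube corner offsets in (x, y, z), corners numbered 1..8
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  # 6-tetrahedra decomposition around the main diagonal corner1-corner7
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  # active cells: sign change among the 8 corners
  base <- which(array(TRUE, dim = c(nxc, nyc, nzc)))
  ci <- (base - 1L) %% nxc
  cj <- ((base - 1L) %/% nxc) %% nyc
  ck <- (base - 1L) %/% (nxc * nyc)
  corner_lin <- function(cn) {
    (ci + corner[cn, 1]) + d[1] * ((cj + corner[cn, 2]) + d[2] * (ck + corner[cn, 3])) + 1L
  }
  fmin <- fmax <- fp[corner_lin(1L)]
  for (cn in 2:8) {
    fc <- fp[corner_lin(cn)]
    fmin <- pmin(fmin, fc); fmax <- pmax(fmax, fc)
  }
  act <- which(fmin <= 0 & fmax > 0)
  if (!length(act)) return(NULL)
  ci <- ci[act]; cj <- cj[act]; ck <- ck[act]
  cl <- lapply(1:8, function(cn)
    (ci + corner[cn, 1]) + d[1] * ((cj + corner[cn, 2]) + d[2] * (ck + corner[cn, 3])) + 1L)
  fv <- lapply(cl, function(l) fp[l])
  px <- lapply(1:8, function(cn) xs[ci + corner[cn, 1] + 1L])
  py <- lapply(1:8, function(cn) ys[cj + corner[cn, 2] + 1L])
  pz <- lapply(1:8, function(cn) zs[ck + corner[cn, 3] + 1L])

  V1 <- V2 <- V3 <- vector("list", 0L)
  interp <- function(fa, fb, xa, xb) {
    t <- fa / (fa - fb)
    xa + t * (xb - xa)
  }
  emit <- function(ax, ay, az, bx, by, bz, cx, cy, cz, inx, iny, inz) {
    # orient so the normal points away from the inside reference point
    ux <- bx - ax; uy <- by - ay; uz <- bz - az
    vx <- cx - ax; vy <- cy - ay; vz <- cz - az
    nx <- uy * vz - uz * vy; ny <- uz * vx - ux * vz; nz <- ux * vy - uy * vx
    s <- nx * (inx - ax) + ny * (iny - ay) + nz * (inz - az)
    flip <- s > 0
    bx2 <- ifelse(flip, cx, bx); by2 <- ifelse(flip, cy, by); bz2 <- ifelse(flip, cz, bz)
    cx2 <- ifelse(flip, bx, cx); cy2 <- ifelse(flip, by, cy); cz2 <- ifelse(flip, bz, cz)
    V1[[length(V1) + 1L]] <<- cbind(ax, ay, az)
    V2[[length(V2) + 1L]] <<- cbind(bx2, by2, bz2)
    V3[[length(V3) + 1L]] <<- cbind(cx2, cy2, cz2)
  }

  for (t in seq_len(nrow(tets))) {
    tc <- tets[t, ]
    fa <- fv[[tc[1]]]; fb <- fv[[tc[2]]]; fc_ <- fv[[tc[3]]]; fd <- fv[[tc[4]]]
    ins <- cbind(fa > 0, fb > 0, fc_ > 0, fd > 0)
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    xs4 <- cbind(px[[tc[1]]], px[[tc[2]]], px[[tc[3]]], px[[tc[4]]])
    ys4 <- cbind(py[[tc[1]]], py[[tc[2]]], py[[tc[3]]], py[[tc[4]]])
    zs4 <- cbind(pz[[tc[1]]], pz[[tc[2]]], pz[[tc[3]]], pz[[tc[4]]])
    fs4 <- cbind(fa, fb, fc_, fd)
    one_inside <- list(c(1L, 2L, 3L, 4L), c(2L, 1L, 3L, 4L),
                       c(3L, 1L, 2L, 4L), c(4L, 1L, 2L, 3L))
    codes1 <- c(1L, 2L, 4L, 8L)
    for (v in 1:4) {
      # exactly vertex v inside
      rows <- which(code == codes1[v])
      rows_out <- which(code == 15L - codes1[v])   # exactly vertex v outside
      perm <- one_inside[[v]]
      for (mode in 1:2) {
        rr <- if (mode == 1) rows else rows_out
        if (!length(rr)) next
        a <- perm[1]; oth <- perm[2:4]
        fA <- fs4[rr, a]; xA <- xs4[rr, a]; yA <- ys4[rr, a]; zA <- zs4[rr, a]
        P <- lapply(oth, function(o) {
          fB <- fs4[rr, o]
          list(x = interp(fA, fB, xA, xs4[rr, o]),
               y = interp(fA, fB, yA, ys4[rr, o]),
               z = interp(fA, fB, zA, zs4[rr, o]))
        })
        # inside reference point: the single inside vertex (mode 1) or the
        # centroid of the three inside vertices (mode 2)
        if (mode == 1) { inx <- xA; iny <- yA; inz <- zA }
        else {
          inx <- rowMeans(xs4[rr, oth, drop = FALSE])
          iny <- rowMeans(ys4[rr, oth, drop = FALSE])
          inz <- rowMeans(zs4[rr, oth, drop = FALSE])
        }
        emit(P[[1]]$x, P[[1]]$y, P[[1]]$z, P[[2]]$x, P[[2]]$y, P[[2]]$z,
             P[[3]]$x, P[[3]]$y, P[[3]]$z, inx, iny, inz)
      }
    }
    # two-inside cases: quad split into two triangles
    pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
    for (pr in pairs) {
      inside2 <- pr; outside2 <- setdiff(1:4, pr)
      cd <- sum(2L^(inside2 - 1L))
      rr <- which(code == cd)
      if (!length(rr)) next
      iA <- inside2[1]; iB <- inside2[2]; oC <- outside2[1]; oD <- outside2[2]
      pt <- function(i, o) {
        fI <- fs4[rr, i]; fO <- fs4[rr, o]
        list(x = interp(fI, fO, xs4[rr, i], xs4[rr, o]),
             y = interp(fI, fO, ys4[rr, i], ys4[rr, o]),
             z = interp(fI, fO, zs4[rr, i], zs4[rr, o]))
      }
      pAC <- pt(iA, oC); pAD <- pt(iA, oD); pBC <- pt(iB, oC); pBD <- pt(iB, oD)
      inx <- (xs4[rr, iA] + xs4[rr, iB]) / 2
      iny <- (ys4[rr, iA] + ys4[rr, iB]) / 2
      inz <- (zs4[rr, iA] + zs4[rr, iB]) / 2
      emit(pAC$x, pAC$y, pAC$z, pAD$x, pAD$y, pAD$z, pBD$x, pBD$y, pBD$z, inx, iny, inz)
      emit(pAC$x, pAC$y, pAC$z, pBD$x, pBD$y, pBD$z, pBC$x, pBC$y, pBC$z, inx, iny, inz)
    }
  }
  if (!length(V1)) return(NULL)
  list(v1 = do.call(rbind, V1), v2 = do.call(rbind, V2), v3 = do.call(rbind, V3))
}
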