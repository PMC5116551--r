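#' Cycle-averaged vortex structure
#'
#' Voxelwise arithmetic mean of the criterion field over all cardiac phases
#' (a voxel's mean uses the phases where it is valid and the voxel is invalid
#' only if invalid at every phase), then binarize / label / volume-filter at
#' the same case threshold as the individual phases.
#'
#' @param crits list of `criterion_field` objects (>= 2 phases, one grid).
#' @param threshold case iso-level.
#' @param mask optional [sac_mask()].
#' @param min_volume component volume cutoff (mm^3).
#' @param comparison volume-filter comparison.
#' @return list with `structure` (a `vortex_structure`) and `mean_field`
#'   (the averaged `criterion_field`).
#' @export
cycle_average_structure <- function(crits, threshold, mask = NULL,
                                    min_volume = 0.5, comparison = ">=") {
  if (length(crits) < 2L) stop("cycle averaging needs >= 2 phases")
  g <- crits[[1]]$grid
  acc <- array(0, dim = g$dims)
  cnt <- array(0L, dim = g$dims)
  for (cf in crits) {
    stopifnot_same_grid(g, cf$grid, "criterion phases")
    v <- cf$values
    v[!cf$valid] <- 0
    acc <- acc + v
    cnt <- cnt + cf$valid
  }
  valid <- cnt > 0L
  if (!any(valid))
    stop(errorCondition("empty average population: no voxel valid at any phase",
                        class = c("vortexstab_empty_population", "error", "condition")))
  mean_vals <- array(NA_real_, dim = g$dims)
  mean_vals[valid] <- acc[valid] / cnt[valid]
  mf <- criterion_field(g, mean_vals, crits[[1]]$method, valid)
  list(structure = segment_structure(mf, threshold, mask, min_volume, comparison),
       mean_field = mf)
}

#' Degree of Vortex Overlap (DVO)
#'
#' Overlap in \[0, 1\] between two binary vortex-structure voxel sets on one
#' grid. The default score is the Jaccard index `|a & b| / |a | b|`; the Dice
#' coefficient `2|a & b| / (|a| + |b|)` is available for sensitivity checks.
#' When exactly one set is empty the DVO is 0 (a vanished vortex is maximal
#' instability); when both are empty it is `NA` (undefined, excluded from
#' means).
#'
#' @param a,b logical arrays of identical dims (post-filter voxel sets, or
#'   `vortex_structure` objects).
#' @param method `"jaccard"` (default) or `"dice"`.
#' @return scalar in \[0, 1\], or `NA` when both sets are empty.
#' @export
dvo <- function(a, b, method = c("jaccard", "dice")) {
  method <- match.arg(method)
  if (inherits(a, "vortex_structure")) a <- a$voxels
  if (inherits(b, "vortex_structure")) b <- b$voxels
  if (!identical(dim(a), dim(b)))
    grid_error("DVO inputs must share one grid")
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L) return(NA_real_)
  if (na == 0L || nb == 0L) return(0)
  inter <- sum(a & b)
  if (method == "jaccard") inter / (na + nb - inter) else 2 * inter / (na + nb)
}

#' Vortex-core temporal stability analysis
#'
#' The package's main entry point. For a time-resolved velocity series and a
#' sac mask it computes the chosen criterion field per cardiac phase, selects
#' the case threshold from the pooled qualifying-sign statistics (one of the
#' five ladder positions, default the mean), segments each phase's vortex
#' structure (binarize, 26-connected labeling, minimum-volume filter), builds
#' the cycle-averaged structure, and scores each phase's Degree of Vortex
#' Overlap against it. Aggregates follow the mean +/- sample-STD convention;
#' the coefficient of variation of core counts is `(STD/mean) * 100` (flagged
#' undefined when the mean count is 0).
#'
#' @param series a [velocity_series()] (21 phases over a 1 s cycle in the
#'   reference protocol).
#' @param mask a [sac_mask()] registered with the series grid.
#' @param method criterion: `"Q_norm"` (default), `"Q"`, `"lambda2"`,
#'   `"lambda2_norm"`.
#' @param ladder_position threshold choice: `"mean"` (default), `"mean/4"`,
#'   `"mean/2"`, `"mean+STD/2"`, `"mean+STD"` (Q-type) or `"mean-STD"`,
#'   `"mean-STD/2"`, `"mean/2"`, `"mean/4"` (lambda2-type).
#' @param threshold optional explicit iso-level overriding the ladder.
#' @param min_volume core volume cutoff (mm^3), default 0.5.
#' @param comparison volume-filter comparison, `">="` (default) or `">"`.
#' @param overlap `"jaccard"` (default) or `"dice"`.
#' @param eps zero-velocity guard of the normalized criteria.
#' @param mask_before mask the velocity before differentiation (default
#'   FALSE: gradients use the full valid region, masking afterwards).
#' @return an object of class `vortex_stability` with, per phase, the number
#'   of retained cores, total vortex volume (mm^3) and DVO, plus aggregates
#'   (`mean_dvo`, `sd_dvo`, `mean_cores`, `sd_cores`, `cov_cores_pct`,
#'   `mean_volume_mm3`), the threshold ladder, the chosen threshold, the
#'   cycle-averaged structure and the per-phase structures.
#' @seealso [dvo()], [threshold_ladder()], [voxel_size_sweep()]
#' @export
vortex_stability <- function(series, mask,
                             method = c("Q_norm", "Q", "lambda2", "lambda2_norm"),
                             ladder_position = "mean", threshold = NULL,
                             min_volume = 0.5, comparison = ">=",
                             overlap = c("jaccard", "dice"), eps = 1e-6,
                             mask_before = FALSE) {
  method <- match.arg(method)
  overlap <- match.arg(overlap)
  stopifnot(inherits(series, "velocity_series"), inherits(mask, "sac_mask"))
  crits <- criterion_series(series, method, mask = mask, eps = eps,
                            mask_before = mask_before)
  stats <- criterion_statistics(crits, mask = mask)
  lad <- threshold_ladder(stats)
  if (is.null(threshold)) {
    if (!ladder_position %in% names(lad))
      stop("unknown ladder position: ", ladder_position,
           " (expected one of ", paste(names(lad), collapse = ", "), ")")
    threshold <- unname(lad[ladder_position])
  }
  structures <- lapply(crits, segment_structure, threshold = threshold,
                       mask = mask, min_volume = min_volume,
                       comparison = comparison)
  avg <- cycle_average_structure(crits, threshold, mask = mask,
                                 min_volume = min_volume, comparison = comparison)
  dvo_phase <- vapply(structures, dvo, numeric(1), b = avg$structure,
                      method = overlap)
  counts <- vapply(structures, function(s) s$n_cores, integer(1))
  volumes <- vapply(structures, function(s) s$total_volume_mm3, numeric(1))
  mean_cores <- mean(counts)
  sd_cores <- stats::sd(counts)
  per_phase <- data.frame(phase = seq_along(crits),
                          n_cores = counts,
                          total_volume_mm3 = volumes,
                          dvo = dvo_phase)
  structure(list(
    method = method,
    overlap = overlap,
    threshold = threshold,
    ladder = lad,
    ladder_position = ladder_position,
    statistics = stats,
    min_volume = min_volume,
    n_phases = length(crits),
    per_phase = per_phase,
    mean_dvo = mean(dvo_phase, na.rm = TRUE),
    sd_dvo = stats::sd(dvo_phase[!is.na(dvo_phase)]),
    mean_cores = mean_cores,
    sd_cores = sd_cores,
    cov_cores_pct = if (mean_cores > 0) 100 * sd_cores / mean_cores else NA_real_,
    mean_volume_mm3 = mean(volumes),
    average_structure = avg$structure,
    structures = structures,
    grid = series$grid),
    class = "vortex_stability")
}

#' @export
print.vortex_stability <- function(x, ...) {
  cat(sprintf("Vortex-core stability analysis (%s criterion, %s overlap)\n",
              x$method, x$overlap))
  cat(sprintf("  phases: %d; threshold: %.6g (%s of the ladder)\n",
              x$n_phases, x$threshold, x$ladder_position))
  cat(sprintf("  mean vortex volume: %.3f mm^3\n", x$mean_volume_mm3))
  cat(sprintf("  number of cores:    %.2f +/- %.2f  (CoV %s)\n",
              x$mean_cores, x$sd_cores,
              if (is.na(x$cov_cores_pct)) "undefined"
              else sprintf("%.1f%%", x$cov_cores_pct)))
  cat(sprintf("  DVO:                %.3f +/- %.3f\n", x$mean_dvo, x$sd_dvo))
  invisible(x)
}

#' @export
summary.vortex_stability <- function(object, ...) {
  structure(list(per_phase = object$per_phase,
                 aggregates = data.frame(
                   mean_dvo = object$mean_dvo, sd_dvo = object$sd_dvo,
                   mean_cores = object$mean_cores, sd_cores = object$sd_cores,
                   cov_cores_pct = object$cov_cores_pct,
                   mean_volume_mm3 = object$mean_volume_mm3,
                   threshold = object$threshold),
                 method = object$method),
            class = "summary.vortex_stability")
}

#' @export
print.summary.vortex_stability <- function(x, ...) {
  cat(sprintf("Per-phase vortex structure (%s criterion)\n", x$method))
  print(x$per_phase, row.names = FALSE)
  cat("\nAggregates over the cardiac cycle\n")
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' @export
plot.vortex_stability <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$per_phase$phase, x$per_phase$dvo, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "cardiac phase", ylab = "DVO",
                 main = sprintf("DVO vs cycle-averaged structure (mean %.2f)",
                                x$mean_dvo), ...)
  graphics::abline(h = x$mean_dvo, lty = 2)
  graphics::plot(x$per_phase$phase, x$per_phase$n_cores, type = "h", lwd = 3,
                 xlab = "cardiac phase", ylab = "retained cores",
                 main = sprintf("vortex cores (mean %.2f, CoV %s)",
                                x$mean_cores,
                                if (is.na(x$cov_cores_pct)) "undefined"
                                else sprintf("%.0f%%", x$cov_cores_pct)))
  invisible(x)
}

#' Voxel-size sensitivity sweep
#'
#' Re-runs the full stability pipeline after resampling the velocity series
#' (and mask) to each requested voxel spacing, to expose how spatial
#' resolution fragments or merges the extracted vortex cores.
#'
#' @param series a [velocity_series()].
#' @param mask a [sac_mask()] on the series grid.
#' @param spacings voxel edge lengths to test (mm), each within
#'   `(0, extent/4]`.
#' @param ... further arguments passed to [vortex_stability()].
#' @return data.frame with one row per spacing: `spacing_mm`, `mean_cores`,
#'   `sd_cores`, `mean_dvo`, `sd_dvo`, `mean_volume_mm3`, `threshold`.
#' @export
voxel_size_sweep <- function(series, mask, spacings, ...) {
  stopifnot(inherits(series, "velocity_series"))
  extent <- min((series$grid$dims - 1) * series$grid$spacing)
  if (any(spacings <= 0) || any(spacings > extent / 4))
    stop("spacings must lie in (0, domain extent / 4]")
  rows <- lapply(spacings, function(sp) {
    same <- all(abs(sp - series$grid$spacing) < 1e-12)
    s2 <- if (same) series else resample_series(series, sp)
    m2 <- if (same) mask else resample_mask(mask, sp)
    fit <- vortex_stability(s2, m2, ...)
    data.frame(spacing_mm = sp,
               mean_cores = fit$mean_cores, sd_cores = fit$sd_cores,
               mean_dvo = fit$mean_dvo, sd_dvo = fit$sd_dvo,
               mean_volume_mm3 = fit$mean_volume_mm3,
               threshold = fit$threshold)
  })
  do.call(rbind, rows)
}

#' Total vortex volume along the five-threshold ladder
#'
#' Runs the segmentation at every ladder threshold and reports the total
#' retained vortex volume per position, per phase — the threshold-sensitivity
#' experiment showing the volume collapse at strict thresholds.
#'
#' @param crits list of `criterion_field` objects (one per phase).
#' @param mask optional [sac_mask()].
#' @param min_volume core volume cutoff (mm^3).
#' @return data.frame: `position`, `threshold`, `phase`, `n_cores`,
#'   `total_volume_mm3`.
#' @export
ladder_volumes <- function(crits, mask = NULL, min_volume = 0.5) {
  stats <- criterion_statistics(crits, mask = mask)
  lad <- threshold_ladder(stats)
  out <- list()
  for (p in seq_along(lad)) {
    for (k in seq_along(crits)) {
      s <- segment_structure(crits[[k]], unname(lad[p]), mask, min_volume)
      out[[length(out) + 1L]] <- data.frame(position = names(lad)[p],
                                            threshold = unname(lad[p]),
                                            phase = k, n_cores = s$n_cores,
                                            total_volume_mm3 = s$total_volume_mm3)
    }
  }
  do.call(rbind, out)
}
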