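#' Wall-shear-stress vector time series
#'
#' Per-vertex WSS vectors on the sac wall across the cardiac cycle, the input
#' of the OSI and time-averaged WSS metrics.
#'
#' @param vertices n x 3 matrix of wall-vertex positions (mm).
#' @param tau numeric array `c(n_vertices, n_phases, 3)` of WSS vectors (Pa);
#'   finite, `n_phases >= 2`.
#' @return an object of class `wall_series`.
#' @export
wall_series <- function(vertices, tau) {
  vertices <- as.matrix(vertices)
  if (!is.array(tau) || length(dim(tau)) != 3L || dim(tau)[3] != 3L)
    stop("tau must be an n_vertices x n_phases x 3 array")
  if (dim(tau)[1] != nrow(vertices))
    stop("tau and vertices disagree on the number of vertices")
  if (dim(tau)[2] < 2L) stop("a wall series needs at least 2 phases")
  if (nrow(vertices) < 1L) stop("a wall series needs at least 1 vertex")
  if (!all(is.finite(tau))) stop("tau must be finite")
  structure(list(vertices = vertices, tau = tau,
                 n_vertices = nrow(vertices), n_phases = dim(tau)[2]),
            class = "wall_series")
}

#' @export
print.wall_series <- function(x, ...) {
  cat(sprintf("wall_series: %d vertices x %d phases\n", x$n_vertices, x$n_phases))
  invisible(x)
}

#' Time-averaged wall shear stress (TA-WSS)
#'
#' Per vertex, the mean over cardiac phases of the WSS vector magnitude
#' (magnitude first, then average — signs and direction reversals do not
#' cancel).
#'
#' @param w a [wall_series()].
#' @return numeric vector of per-vertex TA-WSS (Pa).
#' @export
ta_wss <- function(w) {
  stopifnot(inherits(w, "wall_series"))
  mag <- sqrt(w$tau[, , 1]^2 + w$tau[, , 2]^2 + w$tau[, , 3]^2)
  if (w$n_vertices == 1L) mean(mag) else rowMeans(matrix(mag, nrow = w$n_vertices))
}

weighted_vertex_mean <- function(x, weights) {
  if (is.null(weights)) return(mean(x, na.rm = TRUE))
  if (length(weights) != length(x)) stop("one weight per vertex required")
  if (any(weights < 0)) stop("weights must be non-negative")
  keep <- !is.na(x)
  tot <- sum(weights[keep])
  if (tot <= 0) stop("weights must have positive sum over defined vertices")
  sum(weights[keep] * x[keep]) / tot
}

#' Spatially and temporally averaged WSS (STA-WSS)
#'
#' Spatial average of the per-vertex TA-WSS over the sac wall; unweighted by
#' default, area-weighted when per-vertex weights are given.
#'
#' @param w a [wall_series()].
#' @param weights optional non-negative per-vertex weights (e.g. vertex
#'   areas) with positive sum.
#' @return scalar STA-WSS (Pa).
#' @export
sta_wss <- function(w, weights = NULL) weighted_vertex_mean(ta_wss(w), weights)

#' Oscillatory shear index (OSI)
#'
#' Per vertex, `OSI = (1 - |sum_t tau| / sum_t |tau|) / 2` with plain sums
#' over the T cardiac-cycle samples (the uniform phase spacing cancels in the
#' ratio; set `rule = "trapezoid"` for trapezoidal weights). 0 means
#' unidirectional shear, 0.5 fully oscillatory. Vertices whose total WSS
#' magnitude is zero are undefined (`NA`) and excluded from [sa_osi()].
#'
#' @param w a [wall_series()].
#' @param rule `"sum"` (default) or `"trapezoid"`.
#' @return numeric vector of per-vertex OSI in \[0, 0.5\] (or `NA`).
#' @export
osi <- function(w, rule = c("sum", "trapezoid")) {
  rule <- match.arg(rule)
  stopifnot(inherits(w, "wall_series"))
  np <- w$n_phases
  wt <- if (rule == "sum") rep(1, np) else c(0.5, rep(1, np - 2), 0.5)
  sum_w <- function(a) as.vector(matrix(a, nrow = w$n_vertices) %*% wt)
  sx <- sum_w(w$tau[, , 1]); sy <- sum_w(w$tau[, , 2]); sz <- sum_w(w$tau[, , 3])
  mag <- sqrt(w$tau[, , 1]^2 + w$tau[, , 2]^2 + w$tau[, , 3]^2)
  denom <- sum_w(mag)
  num <- sqrt(sx^2 + sy^2 + sz^2)
  out <- ifelse(denom > 0, 0.5 * (1 - num / denom), NA_real_)
  # clamp the tiny negative overshoot floating point can produce
  pmin(pmax(out, 0), 0.5)
}

#' Spatially averaged OSI (SA-OSI)
#'
#' Spatial average of per-vertex OSI over the sac wall; undefined vertices
#' are excluded. Unweighted by default, area-weighted when weights are given.
#'
#' @param w a [wall_series()].
#' @param weights optional non-negative per-vertex weights.
#' @param rule integration rule passed to [osi()].
#' @return scalar SA-OSI.
#' @export
sa_osi <- function(w, weights = NULL, rule = "sum")
  weighted_vertex_mean(osi(w, rule = rule), weights)
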