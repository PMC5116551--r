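# Independent brute-force oracles used to pin expected values. These must not
# share code paths with the package implementation.

# queue-based flood fill, 26-connectivity; returns integer label array
flood_fill_components <- function(binary) {
  d <- dim(binary)
  labels <- array(0L, dim = d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  cur <- 0L
  for (start in which(binary)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1L) %% d[1] + 1L
      j <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      k <- (v - 1L) %/% (d[1] * d[2]) + 1L
      for (o in seq_len(nrow(off))) {
        ni <- i + off[o, 1]; nj <- j + off[o, 2]; nk <- k + off[o, 3]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
        nv <- ni + d[1] * ((nj - 1) + d[2] * (nk - 1))
        if (binary[nv] && labels[nv] == 0L) {
          labels[nv] <- cur
          queue <- c(queue, nv)
        }
      }
    }
  }
  labels
}

# Jaccard index by explicit integer-set arithmetic on voxel index lists
jaccard_oracle <- function(a_idx, b_idx) {
  length(intersect(a_idx, b_idx)) / length(union(a_idx, b_idx))
}

# sphere indicator on a grid (voxel centers strictly inside radius)
sphere_voxels <- function(grid, center, radius) {
  ctr <- voxel_centers(grid)
  r2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2 +
    (ctr[, 3] - center[3])^2
  array(r2 < radius^2, dim = grid$dims)
}

# analytic-field Jacobian oracle: central differences of the closed-form
# velocity with a tiny step, evaluated at arbitrary points
numeric_jacobian <- function(spec, pts, h = 1e-6) {
  n <- nrow(pts)
  J <- array(NA_real_, dim = c(n, 3, 3))
  for (ax in 1:3) {
    dp <- dm <- pts
    dp[, ax] <- dp[, ax] + h
    dm[, ax] <- dm[, ax] - h
    J[, , ax] <- (vortexstab:::eval_flow(spec, dp) -
                    vortexstab:::eval_flow(spec, dm)) / (2 * h)
  }
  J
}

# explicit-summation statistics oracles
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  rho <- sxy / sqrt(sxx * syy)
  t <- rho * sqrt(n - 2) / sqrt(1 - rho^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(rho = rho, p = p)
}

brute_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1); vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df = df), df = df)
}

brute_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2), df = na + nb - 2)
}

brute_bland_altman <- function(a, b) {
  d <- b - a
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

# small centered grid helper: dims voxels at `spacing`, centered on origin
centered_grid <- function(n = 31, spacing = 0.2) {
  half <- (n - 1) / 2 * spacing
  voxel_grid(c(-half, -half, -half), spacing, c(n, n, n))
}

# the paired Lamb-Oseen study fixture: two counter-rotating-free vortices
# 4 r_c apart inside a hemispherical sac
lamb_oseen_pair <- function(circulation = 40, core_radius = 1) {
  flow_spec("superposition", components = list(
    flow_spec("lamb_oseen", circulation = circulation, core_radius = core_radius,
              center = c(-2 * core_radius, 0, 0)),
    flow_spec("lamb_oseen", circulation = circulation, core_radius = core_radius,
              center = c(2 * core_radius, 0, 0))))
}
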