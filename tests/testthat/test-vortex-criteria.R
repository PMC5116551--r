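interior_voxels <- function(grid) {
  d <- grid$dims
  a <- array(FALSE, d)
  a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  a
}

test_that("gradient of linear fields is exact and splits into S and W", {
  g <- centered_grid(15, 0.2)
  # pure shear: single nonzero entry du_x/dy = 3
  gr <- velocity_gradient(make_field(flow_spec("pure_shear", shear_rate = 3), g))
  inner <- interior_voxels(g)
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == 1 && j == 2) 3 else 0
    expect_lt(max(abs(gr$grad[, , , i, j][inner] - want)), 1e-12)
  }
  # solid body omega = 2, axis z: grad = [[0,-2,0],[2,0,0],[0,0,0]], S = 0
  gr2 <- velocity_gradient(make_field(flow_spec("solid_body", omega = 2), g))
  sw <- strain_vorticity(gr2)
  want <- matrix(c(0, 2, 0, -2, 0, 0, 0, 0, 0), 3)  # column-major [i,j]
  for (i in 1:3) for (j in 1:3) {
    expect_lt(max(abs(gr2$grad[, , , i, j][inner] - want[i, j])), 1e-12)
    expect_lt(max(abs(sw$S[, , , i, j][inner])), 1e-12)
    expect_lt(max(abs(sw$W[, , , i, j][inner] - want[i, j])), 1e-12)
  }
  # exact decomposition everywhere
  expect_equal(sw$S + sw$W, gr2$grad)
})

test_that("gradient of a Lamb-Oseen field converges to the analytic Jacobian
           at second order", {
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8)
  errs <- vapply(c(0.2, 0.1), function(h) {
    n <- round(4 / h) + 1
    g <- centered_grid(n, h)
    gr <- velocity_gradient(make_field(spec, g))
    inner <- interior_voxels(g)
    sel <- which(as.vector(inner))
    sel <- sel[seq(1, length(sel), by = 7)]   # subsample for speed
    J <- numeric_jacobian(spec, voxel_centers(g)[sel, ])
    m <- 0
    for (i in 1:3) for (j in 1:3)
      m <- max(m, max(abs(gr$grad[, , , i, j][sel] - J[, i, j])))
    m
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 3)   # ~O(h^2): halving h should quarter it
  expect_lt(errs[2], 0.15)
})

test_that("Q and lambda2 take their rigid-rotation and shear closed forms", {
  g <- centered_grid(15, 0.2)
  inner <- interior_voxels(g)
  grot <- velocity_gradient(make_field(flow_spec("solid_body", omega = 2), g))
  q <- q_field(grot); l2 <- lambda2_field(grot)
  expect_lt(max(abs(q$values[inner] - 4)), 1e-10)     # Q = omega^2
  # the closed-form eigensolver carries ~sqrt(eps) error at repeated roots
  expect_lt(max(abs(l2$values[inner] + 4)), 1e-7)     # lambda2 = -omega^2
  # lambda2 = -Q whenever S = 0
  expect_lt(max(abs(l2$values[inner] + q$values[inner])), 1e-7)
  gsh <- velocity_gradient(make_field(flow_spec("pure_shear", shear_rate = 3), g))
  expect_lt(max(abs(q_field(gsh)$values[inner])), 1e-12)
  expect_lt(max(abs(lambda2_field(gsh)$values[inner])), 1e-12)
})

test_that("Q and the middle eigenvalue match brute force on random tensors", {
  set.seed(7)
  for (rep in 1:50) {
    A <- matrix(rnorm(9), 3)
    S <- (A + t(A)) / 2; W <- (A - t(A)) / 2
    q_brute <- (sum(W^2) - sum(S^2)) / 2
    M <- S %*% S + W %*% W
    l2_brute <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)[2]
    # feed the tensor through the vectorized voxel solver
    l2_pkg <- vortexstab:::symmetric3_middle_eigenvalue(
      M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    expect_equal(l2_pkg, l2_brute, tolerance = 1e-10)
    # and via a constructed linear velocity field u = A x (exact gradients)
    g <- centered_grid(7, 0.2)
    u <- voxel_centers(g) %*% t(A)
    gr <- velocity_gradient(velocity_field(g, u))
    inner <- interior_voxels(g)
    expect_lt(max(abs(q_field(gr)$values[inner] - q_brute)), 1e-9)
    expect_lt(max(abs(lambda2_field(gr)$values[inner] - l2_brute)), 1e-9)
  }
})

test_that("middle eigenvalue handles diagonal and degenerate tensors", {
  expect_equal(vortexstab:::symmetric3_middle_eigenvalue(-5, -1, 2, 0, 0, 0), -1)
  expect_equal(vortexstab:::symmetric3_middle_eigenvalue(2, 2, 2, 0, 0, 0), 2)
  expect_equal(vortexstab:::symmetric3_middle_eigenvalue(-4, -4, 0, 0, 0, 0), -4)
})

test_that("criteria are Galilean invariant; the normalized variant is not", {
  g <- centered_grid(15, 0.2)
  base <- make_field(flow_spec("solid_body", omega = 2), g)
  shifted <- velocity_field(g, matrix(base$velocity, ncol = 3) +
                                 matrix(c(5, -3, 2), prod(g$dims), 3, byrow = TRUE))
  inner <- interior_voxels(g)
  q1 <- q_field(velocity_gradient(base))
  q2 <- q_field(velocity_gradient(shifted))
  l1 <- lambda2_field(velocity_gradient(base))
  l2 <- lambda2_field(velocity_gradient(shifted))
  expect_lt(max(abs(q1$values[inner] - q2$values[inner])), 1e-10)
  expect_lt(max(abs(l1$values[inner] - l2$values[inner])), 1e-7)
  qn1 <- normalize_criterion(q1, base)
  qn2 <- normalize_criterion(q2, shifted)
  expect_gt(max(abs(qn1$values[inner & qn1$valid & qn2$valid] -
                      qn2$values[inner & qn1$valid & qn2$valid])), 0.01)
})

test_that("normalization divides by |u|^2 and excludes near-zero-speed voxels", {
  g <- centered_grid(21, 0.2)
  f <- make_field(flow_spec("solid_body", omega = 2), g)
  qn <- normalize_criterion(q_field(velocity_gradient(f)), f)
  ctr <- voxel_centers(g)
  r2 <- ctr[, 1]^2 + ctr[, 2]^2
  # on-axis voxels (|u| = 0) are invalid and excluded
  on_axis <- array(r2 < 1e-12, g$dims)
  expect_false(any(qn$valid[on_axis]))
  # off-axis interior: Q/|u|^2 = omega^2 / (omega^2 r^2) = 1/r^2
  inner <- interior_voxels(g) & qn$valid
  expect_equal(qn$values[inner], 1 / r2[as.vector(inner)], tolerance = 1e-8)
  expect_error(normalize_criterion(qn, f), "already normalized")
})

test_that("criterion fields inherit the axial symmetry of a Lamb-Oseen vortex", {
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8)
  g <- centered_grid(41, 0.1)
  q <- q_field(velocity_gradient(make_field(spec, g)))
  ctr <- voxel_centers(g)
  r <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  inner <- as.vector(interior_voxels(g))
  # voxels at identical radius (by symmetry of the grid) agree
  mid <- abs(ctr[, 3]) < 1e-9 & inner
  on_x <- mid & abs(ctr[, 2]) < 1e-9 & ctr[, 1] > 0.2
  for (i in which(on_x)[1:5]) {
    twin <- which(mid & abs(ctr[, 2] - ctr[i, 1]) < 1e-9 & abs(ctr[, 1]) < 1e-9)
    expect_equal(q$values[twin[1]], q$values[i], tolerance = 1e-3)
  }
})

test_that("the positive-Q region matches the analytic-Jacobian oracle away
           from the sign boundary", {
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8)
  g <- centered_grid(31, 0.1)
  q <- q_field(velocity_gradient(make_field(spec, g)))
  sel <- which(as.vector(interior_voxels(g)))
  J <- numeric_jacobian(spec, voxel_centers(g)[sel, ])
  q_oracle <- vapply(seq_along(sel), function(m) {
    A <- J[m, , ]; S <- (A + t(A)) / 2; W <- (A - t(A)) / 2
    (sum(W^2) - sum(S^2)) / 2
  }, numeric(1))
  disagree <- (q$values[sel] > 0) != (q_oracle > 0)
  # disagreement allowed only within one spacing of the analytic boundary,
  # i.e. where the oracle value is itself near zero
  expect_true(all(abs(q_oracle[disagree]) < 25))
  expect_lt(mean(disagree), 0.02)
})

test_that("an all-invalid field raises an empty-gradient error", {
  g <- centered_grid(5, 0.2)
  v <- array(FALSE, g$dims); v[1, 1, 1] <- TRUE   # no valid neighbors
  f <- velocity_field(g, matrix(0, prod(g$dims), 3), valid = v)
  expect_error(velocity_gradient(f), class = "vortexstab_empty_gradient")
})
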