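test_that("velocity series round-trips through .vti files bit-for-bit", {
  g <- centered_grid(9, 0.2)
  ser <- make_series(flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8),
                     pulsatile_waveform(4), g)
  d <- withr::local_tempdir()
  paths <- save_velocity_series(ser, d)
  ser2 <- load_velocity_series(paths)
  expect_identical(length(paths), 4L)
  for (k in 1:4) {
    expect_identical(ser2$phases[[k]]$velocity, ser$phases[[k]]$velocity)
    expect_identical(ser2$phases[[k]]$valid, ser$phases[[k]]$valid)
  }
  expect_identical(ser2$grid$origin, ser$grid$origin)
  expect_identical(ser2$grid$spacing, ser$grid$spacing)
})

test_that("loading rejects mismatched grids and too-few phases", {
  g1 <- centered_grid(9, 0.2)
  g2 <- centered_grid(9, 0.3)
  f1 <- make_field(flow_spec("solid_body", omega = 1), g1)
  f2 <- make_field(flow_spec("solid_body", omega = 1), g2)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.vti"); p2 <- file.path(d, "b.vti")
  write_vti(p1, g1, list(velocity = f1$velocity))
  write_vti(p2, g2, list(velocity = f2$velocity))
  expect_error(load_velocity_series(c(p1, p2)), class = "vortexstab_grid_error")
  expect_error(load_velocity_series(p1), class = "vortexstab_grid_error")
  p3 <- file.path(d, "c.vti")
  write_vti(p3, g1, list(criterion = array(0, g1$dims)))
  expect_error(load_velocity_series(c(p1, p3)), class = "vortexstab_format_error")
})

test_that("legacy structured-points files are read", {
  g <- voxel_grid(c(0, 0, 0), 0.5, c(3, 3, 3))
  vals <- seq_len(27)
  p <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "legacy fixture", "ASCII",
               "DATASET STRUCTURED_POINTS", "DIMENSIONS 3 3 3",
               "ORIGIN 0 0 0", "SPACING 0.5 0.5 0.5", "POINT_DATA 27",
               "SCALARS criterion double", "LOOKUP_TABLE default",
               paste(vals, collapse = " ")), p)
  d <- read_vti(p)
  expect_equal(d$grid$spacing, rep(0.5, 3))
  expect_equal(as.vector(d$arrays$criterion), as.numeric(vals))
})

test_that("trilinear resampling is exact on fields affine in position", {
  # u = (3y, 0, 0) refined 0.1 -> 0.2 mm
  f <- make_field(flow_spec("pure_shear", shear_rate = 3),
                  voxel_grid(c(0, 0, 0), 0.1, c(21, 21, 21)))
  f2 <- resample_field(f, 0.2)
  expect_true(all(f2$valid))
  expected <- 3 * voxel_centers(f2$grid)[, 2]
  expect_lt(max(abs(matrix(f2$velocity, ncol = 3)[, 1] - expected)), 1e-10)
  expect_lt(max(abs(matrix(f2$velocity, ncol = 3)[, 2:3])), 1e-10)

  # solid-body rotation (linear in position) 0.2 -> 0.4 mm vs u = w x r
  g <- centered_grid(31, 0.2)
  fb <- resample_field(make_field(flow_spec("solid_body", omega = 2), g), 0.4)
  ua <- vortexstab:::eval_flow(flow_spec("solid_body", omega = 2),
                               voxel_centers(fb$grid))
  sel <- as.vector(fb$valid)
  expect_lt(max(abs(matrix(fb$velocity, ncol = 3)[sel, ] - ua[sel, ])), 1e-10)
})

test_that("resampling at the source spacing reproduces source values", {
  g <- centered_grid(15, 0.2)
  f <- make_field(flow_spec("lamb_oseen", circulation = 30, core_radius = 0.7), g)
  f2 <- resample_field(f, 0.2)
  expect_equal(f2$grid$dims, g$dims)
  expect_equal(f2$velocity[f2$valid], f$velocity[f2$valid], tolerance = 1e-12)
})

test_that("coarse resampling of a Lamb-Oseen field matches the directly
           evaluated interpolant", {
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.5)
  g <- voxel_grid(c(-1.5, -1.5, -0.2), 0.1, c(31, 31, 5))
  f <- make_field(spec, g)
  f8 <- resample_field(f, c(0.8, 0.8, 0.1))
  # oracle: re-evaluate the trilinear interpolant by hand at the new centers
  pts <- voxel_centers(f8$grid)
  manual <- function(pt) {
    t <- (pt - g$origin) / g$spacing
    i0 <- pmin(floor(t), g$dims - 2)
    fr <- t - i0
    acc <- numeric(3)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) fr[1] else 1 - fr[1]) * (if (dy) fr[2] else 1 - fr[2]) *
        (if (dz) fr[3] else 1 - fr[3])
      acc <- acc + w * f$velocity[i0[1] + 1 + dx, i0[2] + 1 + dy, i0[3] + 1 + dz, ]
    }
    acc
  }
  sel <- which(as.vector(f8$valid))
  got <- matrix(f8$velocity, ncol = 3)[sel, ]
  want <- t(vapply(sel, function(i) manual(pts[i, ]), numeric(3)))
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("stencils touching invalid voxels invalidate the output", {
  g <- voxel_grid(c(0, 0, 0), 0.1, c(11, 11, 11))
  valid <- array(TRUE, g$dims)
  valid[6, 6, 6] <- FALSE
  f <- velocity_field(g, matrix(1, prod(g$dims), 3), valid = valid)
  f2 <- resample_field(f, 0.11)
  # any new center whose 8-corner stencil includes (6,6,6) must be invalid
  pts <- voxel_centers(f2$grid)
  bad_center <- g$origin + c(5, 5, 5) * 0.1
  touches <- apply(abs(sweep(pts, 2, bad_center)), 1, max) < 0.1
  expect_false(any(f2$valid[array(touches, f2$grid$dims)]))
})

test_that("resampling coarser than the domain is a degenerate-grid error", {
  g <- voxel_grid(c(0, 0, 0), 0.1, c(5, 5, 5))
  f <- make_field(flow_spec("solid_body", omega = 1), g)
  expect_error(resample_field(f, 1.0), class = "vortexstab_grid_error")
})

test_that("voxelized sphere volume is within 2% of the analytic volume", {
  g <- centered_grid(51, 0.2)
  sac <- make_sac_mesh("hemisphere", 4, center = c(0.03, 0.05, -2.07), grid = g,
                       n_seg = 96)
  vol <- sum(sac$mask$inside) * voxel_volume(g)
  expect_equal(vol, 2 * pi * 4^3 / 3, tolerance = 0.02)
})

test_that("voxelization is equivariant under one-voxel translations", {
  g <- centered_grid(41, 0.2)
  a <- make_sac_mesh("hemisphere", 2, center = c(0, 0, -1), grid = g, n_seg = 48)
  b <- make_sac_mesh("hemisphere", 2, center = c(0.2, 0, -1), grid = g, n_seg = 48)
  d <- g$dims
  expect_identical(unname(a$mask$inside[1:(d[1] - 1), , ]),
                   unname(b$mask$inside[2:d[1], , ]))
})

test_that("a surface outside the grid gives an empty-mask error", {
  g <- voxel_grid(c(0, 0, 0), 0.2, c(10, 10, 10))
  sac <- make_sac_mesh("hemisphere", 1, center = c(50, 50, 50), n_seg = 24)
  expect_error(voxelize_surface(sac$mesh, g), class = "vortexstab_grid_error")
})

test_that("apply_mask invalidates outside voxels only", {
  g <- centered_grid(11, 0.2)
  f <- make_field(flow_spec("solid_body", omega = 1), g)
  full <- sac_mask(g, array(TRUE, g$dims))
  expect_identical(apply_mask(f, full)$valid, f$valid)
  half <- array(FALSE, g$dims); half[1:5, , ] <- TRUE
  fm <- apply_mask(f, sac_mask(g, half))
  expect_identical(sum(fm$valid), sum(half))
  expect_identical(fm$velocity, f$velocity)
  # empty intersection is flagged
  v0 <- array(FALSE, g$dims); v0[6:11, , ] <- TRUE
  f2 <- velocity_field(g, f$velocity, valid = v0)
  fe <- apply_mask(f2, sac_mask(g, half))
  expect_false(any(fe$valid))
  expect_true(isTRUE(attr(fe, "empty_after_mask")))
  # grid mismatch
  g2 <- centered_grid(11, 0.3)
  expect_error(apply_mask(f, sac_mask(g2, array(TRUE, g2$dims))),
               class = "vortexstab_grid_error")
})

test_that("unit metadata mismatches are rejected at load", {
  g <- centered_grid(9, 0.2)
  f <- make_field(flow_spec("solid_body", omega = 1), g)
  p <- withr::local_tempfile(fileext = ".vti")
  write_vti(p, g, list(velocity = f$velocity))
  txt <- sub("length=mm velocity=mm/s time=s", "length=m velocity=m/s time=s",
             readLines(p))
  writeLines(txt, p)
  expect_error(read_vti(p), class = "vortexstab_format_error")
})
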