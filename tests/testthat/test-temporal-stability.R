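test_that("DVO has the Jaccard closed forms and empty-set conventions", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[1:5, 1:5, 1:2] <- TRUE
  expect_equal(dvo(a, a), 1)
  b <- array(FALSE, d); b[6:10, 6:10, 9:10] <- TRUE
  expect_equal(dvo(a, b), 0)
  # a subset of half the size: |a n b| / |a u b| = 50 / 100
  sub <- array(FALSE, d); sub[1:5, 1:5, 1] <- TRUE    # 25 of a's 50
  expect_equal(dvo(sub, a), 25 / 50)
  # one empty set -> 0; both empty -> undefined
  e <- array(FALSE, d)
  expect_equal(dvo(a, e), 0)
  expect_true(is.na(dvo(e, e)))
  # symmetry and dice option
  expect_equal(dvo(a, sub), dvo(sub, a))
  expect_equal(dvo(sub, a, method = "dice"), 2 * 25 / (25 + 50))
  expect_error(dvo(a, array(FALSE, c(5, 5, 5))), class = "vortexstab_grid_error")
})

test_that("DVO of drifting spheres equals brute-force voxel enumeration", {
  g <- voxel_grid(c(0, 0, 0), 1, c(24, 16, 16))
  for (offset in c(0, 2, 5, 11)) {
    a <- sphere_voxels(g, c(7.5, 7.5, 7.5), 5)
    b <- sphere_voxels(g, c(7.5 + offset, 7.5, 7.5), 5)
    expect_identical(dvo(a, b), jaccard_oracle(which(a), which(b)))
  }
})

test_that("cycle averaging is the voxelwise mean with per-voxel validity", {
  g <- voxel_grid(c(0, 0, 0), 0.5, c(4, 4, 4))
  mk <- function(vals, valid) vortexstab:::criterion_field(
    g, array(vals, g$dims), "Q", array(valid, g$dims))
  # half the phases at 2, half at 0 -> mean 1
  crits <- list(mk(2, TRUE), mk(2, TRUE), mk(0, TRUE), mk(0, TRUE))
  avg <- cycle_average_structure(crits, threshold = 0.5, min_volume = 0)
  expect_equal(unique(as.vector(avg$mean_field$values)), 1)
  # time-constant series: average equals any single phase
  crits2 <- list(mk(3, TRUE), mk(3, TRUE))
  expect_equal(cycle_average_structure(crits2, 0.5, min_volume = 0)$mean_field$values,
               crits2[[1]]$values)
  # voxels invalid at some phases use the remaining phases only
  v <- array(TRUE, g$dims); v[1, 1, 1] <- FALSE
  crits3 <- list(mk(6, v), mk(2, TRUE))
  mf <- cycle_average_structure(crits3, 0.5, min_volume = 0)$mean_field
  expect_equal(mf$values[1, 1, 1], 2)      # only phase 2 is valid there
  expect_equal(mf$values[2, 2, 2], 4)
  expect_true(all(mf$valid))
})

test_that("a drifting averaged structure matches mean-then-threshold", {
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8,
                    drift_path = rbind(c(-0.6, 0, 0), c(0, 0, 0), c(0.6, 0, 0)))
  g <- centered_grid(25, 0.2)
  crits <- criterion_series(make_series(spec, waveform(rep(1, 3)), g), "Q")
  avg <- cycle_average_structure(crits, threshold = 5, min_volume = 0)
  stack <- (crits[[1]]$values + crits[[2]]$values + crits[[3]]$values) / 3
  expect_equal(avg$mean_field$values[avg$mean_field$valid],
               stack[avg$mean_field$valid], tolerance = 1e-14)
  expect_identical(avg$structure$voxels,
                   array(!is.na(stack) & stack > 5, g$dims))
})

test_that("a stationary pulsatile vortex has DVO 1 at every phase", {
  g <- centered_grid(33, 0.2)
  sac <- make_sac_mesh("hemisphere", 2.8, center = c(0, 0, -1.4), grid = g,
                       n_seg = 48)
  ser <- make_series(flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8),
                     pulsatile_waveform(7), g)
  fit <- vortex_stability(ser, sac$mask, method = "Q_norm")
  expect_equal(fit$per_phase$dvo, rep(1, 7))
  expect_equal(fit$mean_dvo, 1)
  expect_equal(fit$sd_dvo, 0)
  expect_equal(fit$cov_cores_pct, 0)
  expect_true(all(fit$per_phase$n_cores == fit$per_phase$n_cores[1]))
})

test_that("no-core phases drive the coefficient of variation toward and past
           100 percent", {
  # unnormalized Q scales with the waveform squared, so weak phases fall
  # below the pooled threshold and lose all cores, inflating the CoV
  g <- centered_grid(33, 0.2)
  sac <- make_sac_mesh("hemisphere", 2.8, center = c(0, 0, -1.4), grid = g,
                       n_seg = 48)
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8)
  ser <- make_series(spec, waveform(c(0.1, 0.1, 1)), g)
  fit <- vortex_stability(ser, sac$mask, method = "Q")
  counts <- fit$per_phase$n_cores
  expect_identical(counts, c(0L, 0L, 1L))
  expect_equal(fit$cov_cores_pct, 100 * sd(counts) / mean(counts))
  expect_gt(fit$cov_cores_pct, 100)
  # the no-core phases score DVO 0 against a non-empty averaged structure
  expect_equal(fit$per_phase$dvo[1:2], c(0, 0))
})

test_that("a drifting vortex lowers DVO below one", {
  g <- centered_grid(33, 0.2)
  sac <- make_sac_mesh("hemisphere", 2.8, center = c(0, 0, -1.4), grid = g,
                       n_seg = 48)
  drift <- cbind(seq(-0.5, 0.5, length.out = 5), 0, 0)  # 5 voxels of travel
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8,
                    drift_path = drift)
  fit <- vortex_stability(make_series(spec, waveform(rep(1, 5)), g), sac$mask,
                          method = "Q_norm")
  expect_true(all(fit$per_phase$dvo < 1))
  expect_lt(fit$mean_dvo, 1)
  expect_gt(fit$mean_dvo, 0)
})

test_that("stability reports are deterministic across repeated runs", {
  g <- centered_grid(25, 0.2)
  sac <- make_sac_mesh("hemisphere", 2, center = c(0, 0, -1), grid = g, n_seg = 32)
  ser <- make_series(flow_spec("lamb_oseen", circulation = 40, core_radius = 0.7),
                     pulsatile_waveform(4), g)
  f1 <- vortex_stability(ser, sac$mask)
  f2 <- vortex_stability(ser, sac$mask)
  expect_identical(f1$per_phase, f2$per_phase)
  expect_identical(f1$threshold, f2$threshold)
})

test_that("unnormalized-Q structures are invariant under waveform rescaling
           with a threshold rescaled by the square", {
  g <- centered_grid(25, 0.2)
  spec <- flow_spec("lamb_oseen", circulation = 40, core_radius = 0.7)
  ser1 <- make_series(spec, waveform(c(1, 1)), g)
  ser3 <- make_series(spec, waveform(c(3, 3)), g)
  c1 <- criterion_series(ser1, "Q")[[1]]
  c3 <- criterion_series(ser3, "Q")[[1]]
  expect_identical(binarize(c1, 5), binarize(c3, 45))
})

test_that("the voxel-size sweep is consistent and runs the full pipeline", {
  g <- centered_grid(33, 0.2)
  sac <- make_sac_mesh("hemisphere", 2.8, center = c(0, 0, -1.4), grid = g,
                       n_seg = 48)
  ser <- make_series(flow_spec("lamb_oseen", circulation = 40, core_radius = 0.8),
                     pulsatile_waveform(3), g)
  # a single-spacing sweep reproduces the plain stability report
  tab <- voxel_size_sweep(ser, sac$mask, 0.2, method = "Q_norm")
  fit <- vortex_stability(ser, sac$mask, method = "Q_norm")
  expect_equal(tab$mean_dvo, fit$mean_dvo)
  expect_equal(tab$mean_cores, fit$mean_cores)
  expect_equal(tab$threshold, fit$threshold)
  # invalid spacings are rejected
  expect_error(voxel_size_sweep(ser, sac$mask, c(0.2, 99)), "spacings")
})

test_that("print, summary and plot methods run", {
  g <- centered_grid(25, 0.2)
  sac <- make_sac_mesh("hemisphere", 2, center = c(0, 0, -1), grid = g, n_seg = 32)
  ser <- make_series(flow_spec("lamb_oseen", circulation = 40, core_radius = 0.7),
                     pulsatile_waveform(3), g)
  fit <- vortex_stability(ser, sac$mask)
  expect_output(print(fit), "Vortex-core stability")
  expect_output(print(summary(fit)), "Aggregates")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
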