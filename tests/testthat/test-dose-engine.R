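test_that("arc construction places uniform control points", {
  plan <- build_arc(c(0, 0, 0), n_cp = 72, collimator_deg = 355)
  ang <- vapply(plan$control_points, `[[`, numeric(1), "gantry_deg")
  expect_equal(ang, seq(0, 355, by = 5))
  expect_equal(plan$collimator_deg, 355)
  expect_equal(total_mu(plan), 0)
  expect_error(build_arc(c(0, 0, 0), n_cp = 4), "n_cp")
})

test_that("radiological depth reproduces closed forms", {
  g <- water_grid(21, 5)  # 105 mm water cube
  # ray through 100 mm of water between two voxel centres
  expect_equal(radiological_depth(g, c(0, -50, 0), c(0, 50, 0)), 10,
               tolerance = 0.06)
  air <- voxel_grid(array(0, c(11, 11, 11)), c(5, 5, 5), rep(-25, 3))
  expect_equal(radiological_depth(air, c(0, -200, 0), c(0, 200, 0)), 0)
  # 50 mm slab of density 0.3 -> 1.5 cm water-equivalent
  slab <- voxel_grid(array(0.3, c(21, 11, 11)), c(5, 5, 5),
                     c(-50, -25, -25))
  got <- radiological_depth(slab, c(-200, 0, 0), c(-25, 0, 0), step_mm = 1)
  # fine-step numeric oracle over the same geometry
  ts <- seq(0, 175, by = 0.05)
  inside <- (-200 + ts) >= -52.5 & (-200 + ts) <= -25
  oracle <- sum(inside) * 0.05 * 0.3 / 10
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("the pencil-beam kernel follows attenuation and inverse square", {
  g <- water_grid(21, 5)
  ext <- full_mask(g)
  mach <- beam_model()
  plan <- build_arc(c(0, 0, 0), n_cp = 8, collimator_deg = 0, machine = mach)
  infl <- influence_matrix(plan, g, ext, fluence_grid = list(u = 0, v = 0))
  col <- influence_column(infl, cp = 1, iu = 1, iv = 1)  # anterior beam
  expect_true(all(col$values >= 0))
  # central-axis voxels along AP at RL=CC=0
  i0 <- 11
  vals <- col$values[i0, , i0]
  ap <- g$origin[2] + (0:20) * 5
  d1 <- 6; d2 <- 14  # two depths on the axis (indices)
  depth1 <- (ap[d1] - (-52.5)) / 10  # cm below surface
  depth2 <- (ap[d2] - (-52.5)) / 10
  r1 <- mach$sad_mm + ap[d1]; r2 <- mach$sad_mm + ap[d2]
  want_ratio <- exp(-mach$mu_water_per_cm * (depth1 - depth2)) *
    (r2 / r1)^2
  expect_equal(vals[d1] / vals[d2], want_ratio, tolerance = 0.02)
  # depth monotonicity: primary dose decreases with depth along the axis
  expect_true(all(diff(vals[3:19]) < 0))
})

test_that("opposed beams on a symmetric phantom give mirrored dose", {
  g <- water_grid(21, 5)
  ext <- full_mask(g)
  plan <- build_arc(c(0, 0, 0), n_cp = 8, collimator_deg = 0)
  infl <- influence_matrix(plan, g, ext, fluence_grid = list(u = 0, v = 0))
  col0 <- influence_column(infl, cp = 1, iu = 1, iv = 1)    # gantry 0
  col180 <- influence_column(infl, cp = 5, iu = 1, iv = 1)  # gantry 180
  # gantry 180 mirrors gantry 0 through the AP midplane
  flipped <- col180$values[, 21:1, ]
  expect_equal(col0$values, flipped, tolerance = 1e-6)
})

test_that("dose is linear in the beamlet weights", {
  g <- water_grid(13, 5)
  ext <- full_mask(g)
  plan <- build_arc(c(0, 0, 0), n_cp = 8)
  infl <- influence_matrix(plan, g, ext,
                           fluence_grid = list(u = c(-5, 0, 5), v = c(-5, 0, 5)))
  nb <- c(3, 3, 8)
  w0 <- array(0, nb)
  expect_equal(max(abs(compute_dose(plan, infl, w0)$values)), 0)
  set.seed(7)
  w <- array(stats::runif(prod(nb)), nb)
  d1 <- compute_dose(plan, infl, w)
  d2 <- compute_dose(plan, infl, 2 * w)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  # two-beamlet case equals the sum of the kernel columns
  w2 <- array(0, nb); w2[1, 2, 3] <- 1.5; w2[3, 2, 6] <- 0.5
  dsum <- 1.5 * influence_column(infl, 3, 1, 2)$values +
          0.5 * influence_column(infl, 6, 3, 2)$values
  expect_equal(compute_dose(plan, infl, w2)$values, dsum, tolerance = 1e-10)
  expect_error(compute_dose(plan, infl, -w), "negative")
  expect_error(compute_dose(plan, infl, w[1:5]), "conformal")
})

test_that("dose is scored only inside the bounding ROI", {
  g <- water_grid(13, 5)
  inner <- sphere_mask(g, c(0, 0, 0), 20, "External")
  plan <- build_arc(c(0, 0, 0), n_cp = 8)
  infl <- influence_matrix(plan, g, inner,
                           fluence_grid = list(u = 0, v = 0))
  w <- array(1, c(1, 1, 8))
  d <- compute_dose(plan, infl, w)
  expect_true(all(d$values[!inner$voxels] == 0))
  expect_gt(max(d$values[inner$voxels]), 0)
  expect_error(influence_matrix(plan, g,
    roi_mask("External", array(FALSE, dim(g$values)), g$spacing, g$origin)),
    "empty")
})

test_that("output calibration maps one MU to one cGy at the isocentre", {
  g <- water_grid(21, 5)
  ext <- full_mask(g)
  plan <- build_arc(c(0, 0, 0), n_cp = 8)
  infl <- calibrate_output(influence_matrix(plan, g, ext,
    fluence_grid = list(u = 0, v = 0)))
  plan$machine <- infl$machine
  # mean over the arc of single-central-beamlet dose at iso = 0.01 Gy/MU
  w <- array(1 / 8, c(1, 1, 8))
  d <- compute_dose(plan, infl, w)
  # iso voxel: centre of the grid; blur spreads a little off-axis
  expect_equal(d$values[11, 11, 11], 0.01 * sum(arcplan:::blur_fluence(
    array(1, c(1, 1, 1)), infl)) / 1, tolerance = 0.05)
})

test_that("leaf sequencing reproduces simple fluence patterns", {
  g <- water_grid(13, 5)
  ext <- full_mask(g)
  plan <- build_arc(c(0, 0, 0), n_cp = 8)
  u <- seq(-15, 15, by = 5); v <- seq(-10, 10, by = 5)
  infl <- influence_matrix(plan, g, ext, fluence_grid = list(u = u, v = v))
  nb <- c(length(u), length(v), 8)

  # uniform fluence: leaves open to the field edges
  wu <- array(1, nb)
  sq <- sequence_leaves(plan, infl, wu, threshold_fraction = 0.5)
  cp <- sq$plan$control_points[[1]]
  expect_equal(cp$leaf_left_mm, rep(min(u) - 2.5, length(v)))
  expect_equal(cp$leaf_right_mm, rep(max(u) + 2.5, length(v)))

  # zero row: that leaf pair closes
  wz <- array(1, nb); wz[, 2, ] <- 0
  sq2 <- sequence_leaves(plan, infl, wz, threshold_fraction = 0.5)
  cp2 <- sq2$plan$control_points[[1]]
  expect_equal(cp2$leaf_left_mm[2], cp2$leaf_right_mm[2])

  # step fluence: the leaf edge sits at the step within one beamlet width
  ws <- array(0, nb); ws[u >= 0, , ] <- 1
  sq3 <- sequence_leaves(plan, infl, ws, threshold_fraction = 0.5)
  cp3 <- sq3$plan$control_points[[1]]
  expect_lte(abs(cp3$leaf_left_mm[1] - (-2.5)), 5)
  expect_equal(cp3$leaf_right_mm[1], max(u) + 2.5)

  expect_error(sequence_leaves(plan, infl, array(0, nb)), "zero")
})
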