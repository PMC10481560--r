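grid_with_dose <- function(vals, sp = 2) {
  voxel_grid(vals, rep(sp, 3), origin = rep(0, 3))
}

test_that("the cumulative DVH matches per-voxel threshold counting", {
  set.seed(42)
  vals <- array(stats::runif(6 * 5 * 4, 0, 50), c(6, 5, 4))
  g <- grid_with_dose(vals)
  m <- roi_mask("roi", array(stats::runif(120) < 0.6, c(6, 5, 4)),
                g$spacing, g$origin)
  dvh <- cumulative_dvh(g, m, bin_width_gy = 0.05)
  d <- vals[m$voxels]
  for (e in dvh$bin_edges_gy[seq(1, length(dvh$bin_edges_gy), by = 37)]) {
    expect_equal(dvh$cumulative_volume_fraction[dvh$bin_edges_gy == e],
                 mean(d >= e))
  }
  expect_equal(dvh$cumulative_volume_fraction[1], 1)
  expect_true(all(diff(dvh$cumulative_volume_fraction) <= 0))
  expect_equal(dvh$cumulative_volume_fraction[length(dvh$bin_edges_gy)], 0)
  expect_equal(dvh$total_cc, sum(m$voxels) * 8 / 1000)
  expect_error(cumulative_dvh(g, roi_mask("e", array(FALSE, c(6, 5, 4)),
                                          g$spacing, g$origin)), "empty")
})

test_that("Dx and Vx recover uniform and two-level cases", {
  g <- grid_with_dose(array(45, c(4, 4, 4)))
  m <- full_mask(g, "roi")
  dvh <- cumulative_dvh(g, m)
  expect_equal(dose_at_volume(dvh, 93), 45, tolerance = 0.05)
  expect_equal(volume_at_dose(dvh, 45)$pct, 100)
  expect_equal(volume_at_dose(dvh, 45.1)$pct, 0)
  expect_error(dose_at_volume(dvh, 0))
  expect_error(dose_at_volume(dvh, 101))

  vals <- array(10, c(2, 1, 1)); vals[2] <- 20
  g2 <- grid_with_dose(vals)
  dvh2 <- cumulative_dvh(g2, full_mask(g2, "roi"))
  expect_equal(volume_at_dose(dvh2, 15)$pct, 50, tolerance = 1)
})

test_that("a linear dose ramp puts D50 near mid-prescription", {
  n <- 101
  vals <- array(seq(0, 45, length.out = n), c(n, 1, 1))
  g <- grid_with_dose(vals)
  dvh <- cumulative_dvh(g, full_mask(g, "roi"))
  expect_equal(dose_at_volume(dvh, 50), 22.5, tolerance = 0.3)
})

test_that("Dx and Vx are consistent inverses on random DVHs", {
  set.seed(99)
  for (rep in 1:4) {
    vals <- array(stats::rgamma(400, 4, 0.2), c(20, 20, 1))
    g <- grid_with_dose(vals)
    dvh <- cumulative_dvh(g, full_mask(g, "roi"))
    for (x in c(10, 50, 93)) {
      dx <- dose_at_volume(dvh, x)
      expect_gte(volume_at_dose(dvh, dx)$pct, x - 1)  # one-bin tolerance
    }
  }
})

test_that("the conformity index follows its defining ratio", {
  # prescription isodose exactly covers the target
  vals <- array(0, c(10, 10, 10)); vals[3:7, 3:7, 3:7] <- 50
  g <- grid_with_dose(vals)
  tv <- roi_mask("t", vals >= 50, g$spacing, g$origin)
  expect_equal(conformity_index(g, tv, 45), 1.0)
  # PIV twice the fully covered TV -> CI = 0.5 (the 100 cc / 200 cc case)
  vals2 <- array(0, c(40, 25, 25))
  vals2[1:20, 1:25, 1:25] <- 50   # PIV: 12500 voxels
  g2 <- grid_with_dose(vals2)     # 8 mm^3 voxels
  tvv <- array(FALSE, c(40, 25, 25)); tvv[1:10, 1:25, 1:25] <- TRUE
  tv2 <- roi_mask("t", tvv, g2$spacing, g2$origin)  # 6250 voxels = 50 cc
  expect_equal(conformity_index(g2, tv2, 45), 6250^2 / (6250 * 12500))
  expect_equal(conformity_index(g2, tv2, 45), 0.5)
  # empty isodose -> CI 0 with a warning
  expect_warning(ci0 <- conformity_index(grid_with_dose(array(1, c(4, 4, 4))),
                                         full_mask(grid_with_dose(array(1, c(4, 4, 4))), "t"),
                                         45), "empty")
  expect_equal(ci0, 0)
})

test_that("the homogeneity index is zero for uniform dose and scale-free", {
  g <- grid_with_dose(array(45, c(6, 6, 6)))
  dvh <- cumulative_dvh(g, full_mask(g, "roi"))
  expect_equal(homogeneity_index(dvh, 45), 0, tolerance = 0.005)
  # (D2 - D98) / Rx on a crafted two-tail distribution
  d <- c(rep(1.046 * 45, 25), rep(45, 945), rep(0.952 * 45, 30))
  dvh2 <- arcplan:::dvh_from_vector(d, 0.008)
  hi <- homogeneity_index(dvh2, 45)
  expect_equal(hi, (1.046 * 45 - 0.952 * 45) / 45, tolerance = 0.01)
  expect_equal(hi, 0.094, tolerance = 0.01)
  # invariant under joint rescaling of dose and prescription
  dvh3 <- arcplan:::dvh_from_vector(2 * d, 0.008)
  expect_equal(homogeneity_index(dvh3, 90), hi, tolerance = 0.005)
})

test_that("plan sums add voxelwise", {
  set.seed(3)
  a <- grid_with_dose(array(stats::runif(64, 0, 40), c(4, 4, 4)))
  b <- grid_with_dose(array(stats::runif(64, 0, 5), c(4, 4, 4)))
  z <- grid_with_dose(array(0, c(4, 4, 4)))
  expect_equal(plan_sum(a, z)$values, a$values)
  expect_equal(plan_sum(a, b)$values, plan_sum(b, a)$values)
  s <- plan_sum(a, b)
  expect_equal(s$values[2, 3, 1], a$values[2, 3, 1] + b$values[2, 3, 1])
  b2 <- b; b2$origin <- b$origin + 1
  expect_error(plan_sum(a, b2), "mismatch")
})

test_that("clinical goal evaluation passes, fails and flags correctly", {
  d <- array(0, c(12, 12, 12))
  g <- grid_with_dose(d, sp = 5)
  ptv <- sphere_mask(g, c(27.5, 27.5, 27.5), 15, "PTV_initial")
  bl <- sphere_mask(g, c(27.5, 42.5, 27.5), 12, "Bladder")
  fem <- sphere_mask(g, c(45, 20, 27.5), 8, "FemoralHead_L")
  g$values[ptv$voxels] <- 45
  g$values[fem$voxels] <- 20
  structs <- structure_set(list(full_mask(g), ptv, bl, fem))

  goals <- list(
    clinical_goal("PTV_initial", "Dx", 93, ">", 98, "%Rx", "initial"),
    clinical_goal("FemoralHead_L", "Vx", 50, "<=", 0, "%vol", "initial"))
  rep1 <- evaluate_goals(list(initial = g), structs, goals,
                         prescriptions_gy = c(initial = 45))
  expect_equal(rep1$status, c("pass", "pass"))
  expect_equal(rep1$achieved[2], 0)

  # deliberately hot bladder outside the target: a clean failure
  g2 <- g; g2$values[bl$voxels & !ptv$voxels] <- 46
  rep2 <- evaluate_goals(list(plan_sum = g2), structs,
    list(clinical_goal("Bladder", "Vx", 45, "<", 30, "%vol", "plan_sum")),
    prescriptions_gy = c(plan_sum = 50.4))
  expect_equal(rep2$status, "fail")
  expect_gt(rep2$achieved, 30)

  # violation confined to the target overlap: flagged, not failed
  g3 <- g
  rep3 <- evaluate_goals(list(plan_sum = g3), structs,
    list(clinical_goal("Bladder", "Vx", 40, "<=", 0, "%vol", "plan_sum")),
    prescriptions_gy = c(plan_sum = 50.4))
  if (any(bl$voxels & ptv$voxels)) expect_equal(rep3$status, "flagged")

  # small-bowel style cc goal carries both units in the report
  rep4 <- evaluate_goals(list(plan_sum = g2), structs,
    list(clinical_goal("Bladder", "Vx", 45, "<", 900, "cc", "plan_sum")),
    prescriptions_gy = c(plan_sum = 50.4))
  expect_equal(rep4$status, "pass")
  expect_false(is.na(rep4$achieved_pct))
  expect_false(is.na(rep4$achieved_cc))

  expect_error(evaluate_goals(list(initial = g), structs,
    list(clinical_goal("Stomach", "Vx", 45, "<", 30, "%vol", "initial")),
    prescriptions_gy = c(initial = 45)), "unresolvable|Stomach")
})
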