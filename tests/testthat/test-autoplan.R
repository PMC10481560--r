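test_that("hotspot extraction thresholds relative to the prescription", {
  g <- voxel_grid(array(45, c(6, 6, 6)), c(5, 5, 5))
  ext <- full_mask(g)
  hs <- extract_hotspots(g, 45, 1.05, ext)
  expect_equal(sum(hs$voxels), 0L)
  g$values[3, 3, 3] <- 45 * 1.10
  hs2 <- extract_hotspots(g, 45, 1.05, ext)
  expect_equal(which(hs2$voxels), which(g$values >= 45 * 1.05))
  expect_equal(sum(hs2$voxels), 1L)
  expect_error(extract_hotspots(g, 45, 1.0), "exceed")
  expect_error(extract_hotspots(g, 45, 0.9), "exceed")
})

test_that("coverage escalation raises the coverage weight only when needed", {
  cfg <- autoplan_config()
  objs <- list(objective("min_dose", "PTV_initial", dose_gy = 44.3,
                         weight = 200),
               objective("max_dose", "External", dose_gy = 48, weight = 30))
  # already at goal: untouched
  r <- escalate_ptv_constraints(objs, d93_pct = 99.1, cfg)
  expect_equal(r$rounds, 0)
  expect_equal(r$objectives[[1]]$weight, 200)
  expect_false(r$objectives[[1]]$is_constraint)
  # below goal: weight multiplied and flagged as constraint
  r2 <- escalate_ptv_constraints(objs, d93_pct = 95, cfg)
  expect_gte(r2$rounds, 1)
  expect_equal(r2$objectives[[1]]$weight, 200 * cfg$escalation_factor)
  expect_true(r2$objectives[[1]]$is_constraint)
  expect_equal(r2$objectives[[2]]$weight, 30)
  # with a callback the loop runs until the goal or the round cap
  calls <- 0
  r3 <- escalate_ptv_constraints(objs, 90, cfg, reoptimize = function(o) {
    calls <<- calls + 1
    if (calls >= 2) 99 else 95
  })
  expect_equal(r3$rounds, 2)
  expect_equal(r3$objectives[[1]]$weight, 200 * cfg$escalation_factor^2)
  # the cap is honoured even when the goal is never met
  r4 <- escalate_ptv_constraints(objs, 90, cfg,
                                 reoptimize = function(o) 90)
  expect_equal(r4$rounds, cfg$max_escalations)
})

test_that("objective construction follows the goal set", {
  structs <- derive_optimization_rois(coarse_phantom()$structs)
  goals <- default_goals()
  objs <- build_objectives(structs, "PTV_initial", 45, goals = goals)
  kinds <- vapply(objs, `[[`, character(1), "kind")
  rois <- vapply(objs, `[[`, character(1), "roi")
  # exactly one dose fall-off per organ-at-risk helper structure
  fo <- rois[kinds == "dose_falloff"]
  expect_setequal(fo, c("z_Bladder_opt", "z_SmallBowel_opt",
                        "z_AnteriorShell", "FemoralHead_L", "FemoralHead_R"))
  expect_equal(length(fo), 5)
  # empty goal list: target objectives only
  objs0 <- build_objectives(structs, "PTV_initial", 45, goals = list())
  expect_true(all(vapply(objs0, `[[`, character(1), "roi") == "PTV_initial"))
  # boost plan: all dose levels scale with the 5.4 Gy prescription
  objsb <- build_objectives(structs, "PTV_boost", 5.4, goals = goals)
  uni <- objsb[[which(vapply(objsb, `[[`, character(1), "kind") == "uniform")]]
  expect_equal(uni$dose_gy, 5.4)
  fob <- objsb[[which(vapply(objsb, `[[`, character(1), "kind") ==
                        "dose_falloff")[1]]]
  expect_equal(fob$high_gy, 5.4)
  # goals on unknown ROIs are refused
  bad <- list(clinical_goal("Stomach", "Vx", 45, "<", 30, "%vol"))
  expect_error(build_objectives(structs, "PTV_initial", 45, goals = bad),
               "Stomach")
})

test_that("planning aborts before optimization when an ROI is missing", {
  ph <- coarse_phantom()
  broken <- ph$structs
  broken$masks$SmallBowel <- NULL
  t0 <- Sys.time()
  expect_error(run_autoplan(ph$density, broken), "SmallBowel")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
})

test_that("the pass configuration controls the staged workflow", {
  ph <- coarse_phantom()
  cfg <- autoplan_config(initial_opts = 1, hotspot_opts = 0,
                         inner_iterations = 3, max_escalations = 0,
                         n_cp = 8)
  res <- run_autoplan(ph$density, ph$structs, config = cfg)
  for (pl in c("initial", "boost")) {
    st <- res$log$stage[res$log$plan == pl]
    expect_equal(sum(st == "optimization_pass"), 1)
    expect_false(any(grepl("hotspot", st)))
    expect_true("ptv_constraint_escalation" %in% st)
    expect_true("final_optimization" %in% st)
  }
  expect_error(autoplan_config(initial_opts = 0), "at least one")
  expect_error(autoplan_config(hotspot_threshold_fraction = 1))
})

test_that("identical inputs reproduce identical plans", {
  ph <- coarse_phantom()
  cfg <- autoplan_config(initial_opts = 1, hotspot_opts = 1,
                         inner_iterations = 3, max_escalations = 1,
                         n_cp = 8)
  r1 <- run_autoplan(ph$density, ph$structs, config = cfg)
  r2 <- run_autoplan(ph$density, ph$structs, config = cfg)
  expect_identical(r1$dose_initial$values, r2$dose_initial$values)
  expect_identical(r1$dose_boost$values, r2$dose_boost$values)
  expect_equal(total_mu(r1$plan_initial), total_mu(r2$plan_initial))
  expect_identical(r1$goal_report$achieved, r2$goal_report$achieved)
})

test_that("plan sums and reports are assembled coherently", {
  ph <- coarse_phantom()
  cfg <- autoplan_config(initial_opts = 1, hotspot_opts = 0,
                         inner_iterations = 3, max_escalations = 0,
                         n_cp = 8)
  res <- run_autoplan(ph$density, ph$structs, config = cfg)
  expect_equal(res$dose_sum$values,
               res$dose_initial$values + res$dose_boost$values)
  expect_true(all(res$goal_report$status %in% c("pass", "fail", "flagged")))
  # PTV goals evaluated for both plans at their own prescriptions
  expect_true(any(res$goal_report$scope == "boost" &
                  res$goal_report$roi == "PTV"))
  expect_gt(total_mu(res$plan_initial), 0)
})
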