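test_that("NRRD volumes round-trip bit-exactly in the raw encoding", {
  g <- voxel_grid(array(stats::rnorm(4 * 5 * 6), c(4, 5, 6)),
                  c(2.5, 2.5, 2), origin = c(-10.25, 3, -7.125))
  p <- file.path(tempdir(), "vol.nrrd")
  write_volume(g, p)
  g2 <- read_volume(p)
  expect_identical(g2$values, g$values)
  expect_identical(g2$spacing, g$spacing)
  expect_identical(g2$origin, g$origin)
})

test_that("ascii encoding round-trips to full precision", {
  g <- voxel_grid(array(c(pi, exp(1), 1 / 3, 0), c(2, 2, 1)), c(1, 2, 3))
  p <- file.path(tempdir(), "vol_ascii.nrrd")
  write_volume(g, p, encoding = "ascii")
  g2 <- read_volume(p)
  expect_equal(g2$values, g$values, tolerance = 1e-15)
})

test_that("malformed NRRD inputs are rejected with the field named", {
  p <- file.path(tempdir(), "bad2d.nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 2", "sizes: 3 3",
               "space directions: (1,0) (0,1)", "space origin: (0,0)",
               "encoding: ascii", "", paste(rep("0", 9), collapse = " ")), p)
  expect_error(read_volume(p), "3D")
  p2 <- file.path(tempdir(), "nothdr.nrrd")
  writeLines("hello", p2)
  expect_error(read_volume(p2), "magic")
  expect_error(read_volume(file.path(tempdir(), "absent.nrrd")), "not found")
})

test_that("structure sets survive the bit-encoded label map round trip", {
  ph <- coarse_phantom()
  s <- derive_optimization_rois(ph$structs)
  pn <- file.path(tempdir(), "structs.nrrd")
  pj <- file.path(tempdir(), "structs.json")
  write_structures(s, pn, pj)
  s2 <- read_structures(pn, pj)
  expect_setequal(names(s2$masks), names(s$masks))
  for (nm in names(s$masks))
    expect_identical(s2$masks[[nm]]$voxels, s$masks[[nm]]$voxels)
  expect_setequal(s2$derived, s$derived)
})

test_that("the packaged goal set mirrors the clinical protocol table", {
  goals <- default_goals()
  expect_length(goals, 11)
  rois <- vapply(goals, `[[`, character(1), "roi")
  expect_setequal(unique(rois),
                  c("PTV", "SmallBowel", "Bladder", "FemoralHeads"))
  sb <- goals[rois == "SmallBowel"]
  expect_true(all(vapply(sb, `[[`, character(1), "units") == "cc"))
  expect_equal(vapply(sb, `[[`, numeric(1), "threshold"), c(230, 130, 90))
  ptv <- goals[rois == "PTV"]
  expect_equal(vapply(ptv, `[[`, numeric(1), "threshold"), c(98, 110))
  # round trip through JSON preserves comparators and units
  p <- file.path(tempdir(), "goals.json")
  write_goals(goals, p)
  goals2 <- read_goals(p)
  expect_equal(goals2, goals)
})

test_that("invalid goals are rejected with the offender cited", {
  p <- file.path(tempdir(), "badgoals.json")
  jsonlite::write_json(list(list(roi = "PTV", metric = "D105x",
                                 comparator = "<", threshold = 1,
                                 units = "%Rx")), p, auto_unbox = TRUE)
  expect_error(read_goals(p), "invalid goal #1")
  jsonlite::write_json(list(list(roi = "Bladder", metric = "Vx",
                                 parameter = 45, comparator = "<",
                                 threshold = 30, units = "Gy")), p,
                       auto_unbox = TRUE)
  expect_error(read_goals(p), "units|dose")
})

test_that("arc plans round-trip through JSON", {
  plan <- build_arc(c(1, 2, 3), n_cp = 8, collimator_deg = 355,
                    prescription_gy = 45)
  for (i in seq_along(plan$control_points)) {
    plan$control_points[[i]]$leaf_left_mm <- c(-30, -20)
    plan$control_points[[i]]$leaf_right_mm <- c(10, 25)
    plan$control_points[[i]]$mu <- i
  }
  plan$fluence_grid <- list(u = c(-5, 0, 5), v = c(-2.5, 2.5))
  p <- file.path(tempdir(), "plan.json")
  write_plan(plan, p)
  plan2 <- read_plan(p)
  expect_equal(total_mu(plan2), total_mu(plan))
  expect_equal(plan2$isocenter_mm, plan$isocenter_mm)
  expect_equal(plan2$control_points[[3]]$leaf_right_mm, c(10, 25))
  expect_equal(plan2$fluence_grid$u, plan$fluence_grid$u)
  expect_equal(modulation_complexity(plan2), modulation_complexity(plan))
})

test_that("DVH and dose-slice plots build without evaluation errors", {
  ph <- coarse_phantom()
  d <- ph$density
  d$values <- d$values * 10  # pseudo-dose: 10 Gy inside the body
  p1 <- plot_dvh(d, ph$structs)
  p2 <- plot_dose_slice(d, ph$structs)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
})

test_that("the CLI front-end handles help, usage errors and small jobs", {
  expect_equal(as.integer(suppressMessages(cli("--help"))), 0L)
  expect_output(cli("--help"), "subcommands")
  expect_equal(as.integer(suppressMessages(cli("frobnicate"))), 2L)
  expect_equal(as.integer(suppressMessages(
    cli(c("qa", "--ref", "nope.nrrd", "--eval", "nope.nrrd")))), 1L)

  # phantom generation end to end (coarse spacing for speed)
  out <- file.path(tempdir(), "cli_phantom")
  cfg <- file.path(tempdir(), "spec.json")
  jsonlite::write_json(list(spacing_mm = c(5, 5, 5)), cfg,
                       auto_unbox = FALSE)
  code <- suppressMessages(cli(c("phantom", "--seed", "42", "--config", cfg,
                                 "--out", out)))
  expect_equal(as.integer(code), 0L)
  expect_true(file.exists(file.path(out, "density.nrrd")))
  expect_true(file.exists(file.path(out, "structures.json")))

  # gamma QA between two written dose files
  g <- voxel_grid(array(stats::runif(64, 10, 40), c(4, 4, 4)), c(2, 2, 2))
  pa <- file.path(tempdir(), "da.nrrd"); pb <- file.path(tempdir(), "db.nrrd")
  write_volume(g, pa); write_volume(g, pb)
  qa_out <- file.path(tempdir(), "cli_qa")
  expect_equal(as.integer(suppressMessages(
    cli(c("qa", "--ref", pa, "--eval", pb, "--out", qa_out)))), 0L)
  qa <- jsonlite::fromJSON(file.path(qa_out, "qa.json"))
  expect_equal(qa$gamma_pass_rate_pct, 100)

  # paired comparison of two metric tables
  ca <- file.path(tempdir(), "a.csv"); cb <- file.path(tempdir(), "b.csv")
  utils::write.csv(data.frame(m = stats::rnorm(8)), ca, row.names = FALSE)
  utils::write.csv(data.frame(m = stats::rnorm(8)), cb, row.names = FALSE)
  cmp_out <- file.path(tempdir(), "cli_cmp")
  expect_equal(as.integer(suppressMessages(
    cli(c("compare", "--a", ca, "--b", cb, "--out", cmp_out)))), 0L)
  expect_true(file.exists(file.path(cmp_out, "comparison.csv")))
})
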