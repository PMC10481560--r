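test_that("expansion with zero margins is the identity", {
  g <- water_grid(9, 2)
  m <- sphere_mask(g, c(0, 0, 0), 4)
  out <- expand_mask(m, margins())
  expect_identical(out$voxels, m$voxels)
  expect_error(expand_mask(roi_mask("e", array(FALSE, dim(g$values)),
                                    g$spacing, g$origin), margins_isotropic(5)),
               "empty")
  expect_error(margins(anterior_mm = -1))
})

test_that("isotropic single-voxel expansion matches an exhaustive scan", {
  n <- 13
  v <- array(FALSE, rep(n, 3)); v[7, 7, 7] <- TRUE
  m <- roi_mask("pt", v, c(1, 1, 1), origin = -(rep(n, 3) - 1) / 2)
  out <- expand_mask(m, margins_isotropic(5))
  # independent scan: voxels whose centre lies within 5 mm
  pts <- voxel_centers_mm(m)
  want <- rowSums(pts^2) <= 25
  expect_identical(as.logical(out$voxels), want)
})

test_that("one-sided margins grow only the corresponding face", {
  n <- 25
  v <- array(FALSE, rep(n, 3)); v[12:16, 12:16, 12:16] <- TRUE
  m <- roi_mask("cube", v, c(1, 1, 1), origin = rep(0, 3))
  out <- expand_mask(m, margins(anterior_mm = 10))  # anterior = -AP
  bb_in <- apply(which(m$voxels, arr.ind = TRUE), 2, range)
  bb_out <- apply(which(out$voxels, arr.ind = TRUE), 2, range)
  expect_identical(bb_out[, 1], bb_in[, 1])            # RL unchanged
  expect_identical(bb_out[, 3], bb_in[, 3])            # CC unchanged
  expect_identical(bb_out[2, 2], bb_in[2, 2])          # posterior unchanged
  expect_identical(bb_out[1, 2], bb_in[1, 2] - 10L)    # anterior grew 10 mm
  expect_identical(out$voxels, expand_oracle(m, margins(anterior_mm = 10))$voxels)
})

test_that("expansion matches the exhaustive anisotropic oracle on random masks", {
  set.seed(301)
  for (rep in 1:4) {
    n <- sample(8:14, 3)
    sp <- sample(c(1, 2, 2.5), 3, replace = TRUE)
    v <- array(stats::runif(prod(n)) < 0.08, n)
    if (!any(v)) v[1, 1, 1] <- TRUE
    m <- roi_mask("r", v, sp, origin = c(0, 0, 0))
    mg <- margins(sample(0:8, 1), sample(0:8, 1), sample(0:8, 1),
                  sample(0:8, 1), sample(0:8, 1), sample(0:8, 1))
    expect_identical(expand_mask(m, mg)$voxels, expand_oracle(m, mg)$voxels)
  }
})

test_that("expansion is extensive and monotone in each margin", {
  g <- water_grid(15, 2)
  m <- sphere_mask(g, c(2, -2, 0), 5)
  small <- expand_mask(m, margins_isotropic(4))
  big <- expand_mask(m, margins_isotropic(8))
  expect_true(!any(m$voxels & !small$voxels))            # result superset
  expect_true(!any(small$voxels & !big$voxels))
})

test_that("composited expansions under-cover a single margin by at most one voxel per face", {
  n <- 41
  v <- array(FALSE, rep(n, 3)); v[21, 21, 21] <- TRUE
  m <- roi_mask("pt", v, c(2, 2, 2), origin = rep(0, 3))
  two <- expand_mask(expand_mask(m, margins(cranial_mm = 7)),
                     margins(cranial_mm = 6))
  one <- expand_mask(m, margins(cranial_mm = 13))
  # two-step never over-covers (triangle inequality) ...
  expect_true(!any(two$voxels & !one$voxels))
  # ... and per-axis extent falls short by at most one voxel
  ext <- function(x) diff(range(which(x$voxels, arr.ind = TRUE)[, 3]))
  expect_lte(ext(one) - ext(two), 1)
})

test_that("boolean mask algebra behaves as set operations", {
  g <- water_grid(12, 2.5)
  a <- sphere_mask(g, c(0, 0, 0), 8, "a")
  b <- sphere_mask(g, c(6, 0, 0), 8, "b")
  expect_identical(sum(boolean_op(a, a, "difference")$voxels), 0L)
  expect_gte(sum(boolean_op(a, b, "union")$voxels),
             max(sum(a$voxels), sum(b$voxels)))
  expect_identical(boolean_op(a, b, "intersection")$voxels,
                   a$voxels & b$voxels)
  # De Morgan: !(a | b) == !a & !b on the grid
  set.seed(5)
  for (rep in 1:3) {
    va <- array(stats::runif(prod(dim(g$values))) < 0.3, dim(g$values))
    vb <- array(stats::runif(prod(dim(g$values))) < 0.3, dim(g$values))
    u <- va | vb
    expect_identical(!u, (!va) & (!vb))
    expect_identical(va & !vb,
                     boolean_op(roi_mask("a", va, g$spacing, g$origin),
                                roi_mask("b", vb, g$spacing, g$origin),
                                "difference")$voxels)
  }
  b2 <- roi_mask("b", b$voxels, g$spacing, g$origin + 1)
  expect_error(boolean_op(a, b2), "mismatch")
})

test_that("volume and centroid follow from voxel counts and centres", {
  v <- array(FALSE, c(20, 20, 20)); v[6:15, 6:15, 6:15] <- TRUE
  m <- roi_mask("cube", v, c(2, 2, 2), origin = c(0, 0, 0))
  expect_equal(volume_cc(m), 8)
  expect_equal(as.numeric(centroid_mm(m)), c(19, 19, 19))
  expect_error(volume_cc(roi_mask("e", array(FALSE, c(2, 2, 2)), c(1, 1, 1))))
})

test_that("ROI name checking reports missing, unrecognized and duplicates", {
  ok <- check_roi_names(canonical_roi_names()$required)
  expect_true(ok$ok)
  expect_length(ok$missing, 0)

  r <- check_roi_names(c("External", "PTV_initial", "PTV_boost", "bladder",
                         "SmallBowel", "FemoralHead_L", "FemoralHead_R"))
  expect_false(r$ok)
  expect_identical(r$missing, "Bladder")
  expect_identical(unname(r$unrecognized["bladder"]), "Bladder")

  d <- check_roi_names(c(canonical_roi_names()$required, "PTV_initial"))
  expect_false(d$ok)
  expect_identical(d$duplicates, "PTV_initial")

  z <- check_roi_names(c(canonical_roi_names()$required, "z_AnteriorShell"))
  expect_true(z$ok)  # derived helper names are tolerated
})

test_that("optimization ROI derivation subtracts the target and builds the shell", {
  ph <- coarse_phantom()
  s <- derive_optimization_rois(ph$structs)
  ptv <- s[["PTV_initial"]]
  expect_identical(s[["z_Bladder_opt"]]$voxels,
                   s[["Bladder"]]$voxels & !ptv$voxels)
  expect_identical(sum(s[["z_AnteriorShell"]]$voxels & ptv$voxels), 0L)
  expect_gt(sum(s[["z_AnteriorShell"]]$voxels), 0)
  # shell lies anterior (smaller AP coordinate) of the target on average
  expect_lt(centroid_mm(s[["z_AnteriorShell"]])[2], centroid_mm(ptv)[2])
  expect_true(all(c("z_Bladder_opt", "z_SmallBowel_opt", "z_AnteriorShell")
                  %in% s$derived))
  # zero-overlap phantom: subtraction is a no-op
  p0 <- generate_phantom(coarse_spec(oar_overlap_fraction = 0))
  s0 <- derive_optimization_rois(p0$structs)
  expect_identical(s0[["z_Bladder_opt"]]$voxels, s0[["Bladder"]]$voxels)
  # missing canonical ROI is named
  broken <- p0$structs
  broken$masks$SmallBowel <- NULL
  expect_error(derive_optimization_rois(broken), "SmallBowel")
})
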