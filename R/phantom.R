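#' Specification of a synthetic pelvic phantom
#'
#' All geometry is parameterized in world mm on the patient axes (RL, AP,
#' CC), with the body centred at the world origin. The phantom is a pure
#' function of its spec: identical specs give bit-identical phantoms.
#'
#' @param seed integer seed driving the small random perturbation of organ
#'   shapes and positions.
#' @param spacing_mm voxel size (mm), default 2.5 mm isotropic.
#' @param body_semiaxes_mm semi-axes of the elliptical body (RL, AP, CC).
#' @param tumor_center_offset_mm displacement of the rectal tumour from its
#'   nominal posterior-midline position.
#' @param target_scale multiplicative scale on the tumour and nodal target
#'   geometry; PTV volume increases strictly with it.
#' @param oar_overlap_fraction in `[0, 1]`; scales how far the bladder is
#'   displaced posteriorly into the planning target. 0 guarantees an empty
#'   bladder/PTV intersection.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 42L,
                         spacing_mm = c(2.5, 2.5, 2.5),
                         body_semiaxes_mm = c(100, 68, 72),
                         tumor_center_offset_mm = c(0, 0, 0),
                         target_scale = 1,
                         oar_overlap_fraction = 0.2) {
  spacing_mm <- as.numeric(spacing_mm)
  body_semiaxes_mm <- as.numeric(body_semiaxes_mm)
  if (any(spacing_mm <= 0) || length(spacing_mm) != 3)
    stop("spacing_mm must be three positive values")
  if (any(body_semiaxes_mm <= 0) || length(body_semiaxes_mm) != 3)
    stop("body_semiaxes_mm must be three positive values")
  if (target_scale <= 0) stop("target_scale must be positive")
  if (oar_overlap_fraction < 0 || oar_overlap_fraction > 1)
    stop("oar_overlap_fraction must lie in [0, 1]")
  structure(
    list(seed = as.integer(seed), spacing_mm = spacing_mm,
         body_semiaxes_mm = body_semiaxes_mm,
         tumor_center_offset_mm = as.numeric(tumor_center_offset_mm),
         target_scale = target_scale,
         oar_overlap_fraction = oar_overlap_fraction),
    class = "phantom_spec"
  )
}

# Evaluate a superellipsoid membership on the grid: sum(|x-c|/a)^p <= 1.
superellipsoid_mask <- function(geom, center, semi, p = c(2, 2, 2), name = "roi") {
  d <- geom$dims
  ax <- geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1]
  ay <- geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2]
  az <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  tx <- (abs(ax - center[1]) / semi[1])^p[1]
  ty <- (abs(ay - center[2]) / semi[2])^p[2]
  tz <- (abs(az - center[3]) / semi[3])^p[3]
  v <- outer(outer(tx, ty, "+"), tz, "+") <= 1
  roi_mask(name, v, geom$spacing, geom$origin)
}

# run expr with a private, seeded RNG stream, restoring global state
with_phantom_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

erode_one_voxel <- function(mask) {
  inv <- mask
  inv$voxels <- !inv$voxels
  grown <- expand_mask(inv, margins_isotropic(max(mask$spacing)))
  out <- mask
  out$voxels <- mask$voxels & !grown$voxels
  out
}

#' Generate a synthetic pelvic phantom
#'
#' Builds a water-equivalent elliptical body on an air background together
#' with the canonical structure set the automated planner expects: a gross
#' rectal tumour, a concave nodal/mesorectal target wrapping posteriorly
#' around the anterior organ compartment, the derived CTV/PTV pair for
#' initial and boost plans, a bladder abutting (or overlapping) the target
#' anteriorly, anterior-superior small bowel, and two lateral femoral heads.
#' All organ masks lie strictly inside the body contour and
#' `PTV_boost` is contained in `PTV_initial`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `density` (a `voxel_grid`, body 1.0 / air 0.0),
#'   `structs` (a `structure_set`) and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  ba <- spec$body_semiaxes_mm
  pad <- 8
  couch_room <- 58
  ext_lo <- c(-(ba[1] + pad), -(ba[2] + pad), -(ba[3] + pad))
  ext_hi <- c(ba[1] + pad, ba[2] + pad + couch_room, ba[3] + pad)
  dims <- as.integer(ceiling((ext_hi - ext_lo) / sp)) + 1L
  origin <- ext_lo
  geom <- list(dims = dims, spacing = sp, origin = origin)

  jitter <- with_phantom_rng(spec$seed, {
    list(centers = matrix(stats::runif(18, -2, 2), ncol = 3),
         scales = stats::runif(6, 0.97, 1.03))
  })

  body <- superellipsoid_mask(geom, c(0, 0, 0), ba, p = c(2.5, 2.5, 8),
                              name = "External")
  inner <- erode_one_voxel(body)
  s <- spec$target_scale

  # gross rectal tumour, posterior midline
  gtv_c <- c(0, 28, -5) + spec$tumor_center_offset_mm + jitter$centers[1, ]
  gtv <- superellipsoid_mask(geom, gtv_c, c(20, 17, 34) * s * jitter$scales[1],
                             name = "GTV")

  fem_l <- superellipsoid_mask(geom, c(75, 6, -24), c(21, 21, 21) * jitter$scales[6],
                               name = "FemoralHead_L")
  fem_r <- superellipsoid_mask(geom, c(-75, 6, -24), c(21, 21, 21) * jitter$scales[6],
                               name = "FemoralHead_R")
  fem_both <- roi_mask("fems", fem_l$voxels | fem_r$voxels, sp, origin)

  # nodal/mesorectal compartment: posterior block minus the anterior
  # bowel-compartment lobe -> horseshoe opening anteriorly; the femoral
  # heads (plus clearance) are carved out as bone is when contouring nodes
  blk_c <- c(0, 14, 2) + jitter$centers[2, ]
  blk <- superellipsoid_mask(geom, blk_c, c(63, 47, 57) * s * jitter$scales[2],
                             p = c(2.2, 2, 2.2), name = "nodes")
  lobe <- superellipsoid_mask(geom, c(0, -26, 8) + jitter$centers[3, ],
                              semi = c(41, 36, 50), name = "lobe")
  blk$voxels <- blk$voxels & !lobe$voxels &
    !expand_mask(fem_both, margins_isotropic(7))$voxels

  for (nm in c("GTV")) {
    if (any(gtv$voxels & !inner$voxels))
      stop("infeasible geometry: structure 'GTV' exceeds the body contour")
  }
  blk$voxels <- blk$voxels & inner$voxels

  tgt <- build_targets(gtv, node_masks = list(blk), external = inner)
  ptv_init <- tgt$ptv; ptv_init$name <- "PTV_initial"
  ctv_init <- tgt$ctv; ctv_init$name <- "CTV"

  tgtb <- build_targets(gtv, node_masks = list(), external = inner)
  ptv_boost <- boolean_op(tgtb$ptv, ptv_init, "intersection")
  ptv_boost$name <- "PTV_boost"
  ctv_boost <- tgtb$ctv; ctv_boost$name <- "CTV_boost"

  # bladder: anterior-inferior; posterior displacement controlled by the
  # overlap knob (0 leaves a gap and is clipped to guarantee no overlap)
  bl_y <- -36 + 50 * spec$oar_overlap_fraction + jitter$centers[4, 2] *
    min(1, spec$oar_overlap_fraction * 5)
  bladder <- superellipsoid_mask(geom,
    c(jitter$centers[4, 1] * 0.5, bl_y, -16),
    c(33, 25, 34) * jitter$scales[3], name = "Bladder")
  if (spec$oar_overlap_fraction == 0)
    bladder$voxels <- bladder$voxels & !ptv_init$voxels

  # small bowel: anterior-superior blobs
  sb1 <- superellipsoid_mask(geom, c(-16, -30, 32) + jitter$centers[5, ],
                             c(33, 26, 29) * jitter$scales[4], name = "sb")
  sb2 <- superellipsoid_mask(geom, c(18, -26, 42) + jitter$centers[6, ],
                             c(31, 23, 26) * jitter$scales[5], name = "sb")
  sbowel <- roi_mask("SmallBowel",
                     (sb1$voxels | sb2$voxels) & !ptv_init$voxels & !bladder$voxels,
                     sp, origin)

  organs <- list(Bladder = bladder, SmallBowel = sbowel,
                 FemoralHead_L = fem_l, FemoralHead_R = fem_r)
  for (nm in names(organs)) {
    if (any(organs[[nm]]$voxels & !inner$voxels))
      stop("infeasible geometry: structure '", nm,
           "' exceeds the body contour")
  }

  density <- voxel_grid(array(as.numeric(body$voxels), dims), sp, origin)
  structs <- structure_set(list(
    body, ptv_init, ptv_boost, bladder, sbowel, fem_l, fem_r,
    gtv, ctv_init, ctv_boost))
  list(density = density, structs = structs, spec = spec)
}

#' Insert a virtual treatment couch into a density grid
#'
#' Adds a posterior slab of homogeneous density (a generic carbon-fibre-like
#' couch top) behind the patient; voxels inside the body are never changed.
#'
#' @param density `voxel_grid` of relative electron density.
#' @param external body `roi_mask` (used to locate the posterior surface and
#'   to refuse overlapping slabs).
#' @param thickness_mm slab thickness (mm); 0 returns the input unchanged.
#' @param density_rel slab density relative to water.
#' @param gap_mm air gap between the posterior body surface and the couch.
#' @return The density grid with the couch slab added.
#' @export
insert_virtual_couch <- function(density, external, thickness_mm = 50,
                                 density_rel = 0.3, gap_mm = 2.5) {
  stopifnot(inherits(density, "voxel_grid"), inherits(external, "roi_mask"))
  stop_if_geometry_differs(density, external)
  if (thickness_mm == 0) return(density)
  d <- dim(density$values)
  ap <- density$origin[2] + (seq_len(d[2]) - 1) * density$spacing[2]
  body_post <- max(ap[apply(external$voxels, 2, any)])
  y0 <- body_post + gap_mm
  y1 <- y0 + thickness_mm
  sel <- ap > y0 & ap <= y1
  if (!any(sel) || max(ap) < y1 - density$spacing[2])
    stop("couch slab does not fit posterior to the body within the grid")
  slab <- array(FALSE, d)
  slab[, sel, ] <- TRUE
  if (any(slab & external$voxels))
    stop("couch slab would overlap the body")
  out <- density
  out$values[slab] <- density_rel
  attr(out, "couch_mask") <- slab
  out
}
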