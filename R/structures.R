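#' Binary region-of-interest mask
#'
#' @param name ROI name.
#' @param voxels logical 3D array on the shared grid.
#' @param spacing,origin grid geometry (see [voxel_grid()]).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask contains NA")
  structure(
    list(name = as.character(name), voxels = voxels,
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         axes = c("RL", "AP", "CC")),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels (%.2f cc) on %s grid\n",
              x$name, sum(x$voxels), sum(x$voxels) * voxel_volume_cc(x),
              paste(dim(x$voxels), collapse = "x")))
  invisible(x)
}

#' @export
dim.roi_mask <- function(x) dim(x$voxels)

#' Named collection of ROI masks sharing one grid
#'
#' @param masks list of `roi_mask` objects (named by their ROI names).
#' @param derived character vector of names flagged as planner-derived
#'   helper structures.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, derived = character()) {
  if (length(masks) == 0) stop("empty structure set")
  for (m in masks) stopifnot(inherits(m, "roi_mask"))
  for (m in masks[-1]) stop_if_geometry_differs(masks[[1]], m)
  names(masks) <- vapply(masks, function(m) m$name, character(1))
  structure(
    list(masks = masks, dims = dim(masks[[1]]$voxels),
         spacing = masks[[1]]$spacing, origin = masks[[1]]$origin,
         derived = derived),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROIs on %s grid @ %s mm\n",
              length(x$masks), paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  for (m in x$masks) {
    tag <- if (m$name %in% x$derived) " [derived]" else ""
    cat(sprintf("  %-18s %8.2f cc%s\n", m$name,
                sum(m$voxels) * voxel_volume_cc(m), tag))
  }
  invisible(x)
}

#' @export
`[[.structure_set` <- function(x, name) {
  m <- x$masks[[name]]
  if (is.null(m)) stop("no ROI named '", name, "' in structure set")
  m
}

set_add <- function(structs, mask, derived = FALSE) {
  structs$masks[[mask$name]] <- mask
  if (derived) structs$derived <- union(structs$derived, mask$name)
  structs
}

#' Canonical ROI naming schema
#'
#' The required ROI names the automated planner expects from contouring,
#' plus optional names it tolerates. Derived helper structures are prefixed
#' `z_`, mirroring planner-generated structures, and are always tolerated.
#'
#' @return List with `required` and `optional` character vectors.
#' @export
canonical_roi_names <- function() {
  list(
    required = c("External", "PTV_initial", "PTV_boost", "Bladder",
                 "SmallBowel", "FemoralHead_L", "FemoralHead_R"),
    optional = c("GTV", "CTV", "CTV_boost", "Couch")
  )
}

#' Per-direction expansion margins (mm)
#'
#' Anisotropic margins along the patient axes; each direction (anterior,
#' posterior, left, right, cranial, caudal) carries its own non-negative
#' margin, so clinical prescriptions such as "0.5 cm AP/RL, 2 cm CC" map
#' directly.
#'
#' @param anterior_mm,posterior_mm,left_mm,right_mm,cranial_mm,caudal_mm
#'   non-negative margins in mm.
#' @return An object of class `margins`.
#' @export
margins <- function(anterior_mm = 0, posterior_mm = 0, left_mm = 0,
                    right_mm = 0, cranial_mm = 0, caudal_mm = 0) {
  m <- c(anterior_mm = anterior_mm, posterior_mm = posterior_mm,
         left_mm = left_mm, right_mm = right_mm,
         cranial_mm = cranial_mm, caudal_mm = caudal_mm)
  if (any(!is.finite(m)) || any(m < 0))
    stop("all margins must be finite and >= 0")
  structure(as.list(m), class = "margins")
}

#' Isotropic margins helper
#' @param mm margin applied in every direction.
#' @return A `margins` object.
#' @export
margins_isotropic <- function(mm) margins(mm, mm, mm, mm, mm, mm)

# Structuring-element voxel offsets for octant-wise anisotropic Euclidean
# dilation. An offset (in mm) dx,dy,dz is admitted when
#   (dx/m_x(sign))^2 + (dy/m_y(sign))^2 + (dz/m_z(sign))^2 <= 1,
# where the margin in each axis depends on the offset's direction along that
# axis (e.g. +AP uses the posterior margin). A zero margin admits only a
# zero component along that direction.
margin_offsets <- function(m, spacing) {
  # per axis: margin for negative offsets, margin for positive offsets
  # axis 1 RL: +index -> Left ; axis 2 AP: +index -> Posterior ;
  # axis 3 CC: +index -> Cranial
  neg <- c(m$right_mm, m$anterior_mm, m$caudal_mm)
  pos <- c(m$left_mm, m$posterior_mm, m$cranial_mm)
  rng <- function(k) {
    lo <- -floor(neg[k] / spacing[k])
    hi <- floor(pos[k] / spacing[k])
    seq.int(lo, hi)
  }
  g <- expand.grid(dx = rng(1), dy = rng(2), dz = rng(3))
  term <- function(d, k) {
    mm <- ifelse(d < 0, neg[k], pos[k])
    out <- numeric(length(d))
    nz <- d != 0
    out[nz] <- ifelse(mm[nz] > 0, ((d[nz] * spacing[k]) / mm[nz])^2, Inf)
    out
  }
  s <- term(g$dx, 1) + term(g$dy, 2) + term(g$dz, 3)
  as.matrix(g[s <= 1, , drop = FALSE])
}

#' Anisotropic Euclidean expansion of an ROI mask
#'
#' A voxel belongs to the expanded mask iff its centre lies within the
#' anisotropically scaled Euclidean distance of some source voxel centre,
#' with per-direction margins applied along the corresponding patient axis.
#' The result always contains the input.
#'
#' @param mask non-empty `roi_mask`.
#' @param m a [margins()] object.
#' @param name optional name for the result.
#' @return Expanded `roi_mask`.
#' @export
expand_mask <- function(mask, m, name = NULL) {
  stopifnot(inherits(mask, "roi_mask"), inherits(m, "margins"))
  if (!any(mask$voxels)) stop("cannot expand an empty mask")
  if (!identical(mask$axes, c("RL", "AP", "CC")))
    stop("unknown axis labelling on mask: ", paste(mask$axes, collapse = ","))
  off <- margin_offsets(m, mask$spacing)
  out <- cpp_dilate(as.logical(mask$voxels), dim(mask$voxels),
                    matrix(as.integer(off), ncol = 3))
  roi_mask(name %||% mask$name, array(out, dim(mask$voxels)),
           mask$spacing, mask$origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelwise boolean operation on two masks
#'
#' @param a,b `roi_mask` objects on the same grid.
#' @param op one of `"union"`, `"intersection"`, `"difference"`.
#' @return A `roi_mask` named from its operands.
#' @export
boolean_op <- function(a, b, op = c("union", "intersection", "difference")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  stop_if_geometry_differs(a, b)
  v <- switch(op,
    union = a$voxels | b$voxels,
    intersection = a$voxels & b$voxels,
    difference = a$voxels & !b$voxels)
  sym <- c(union = "|", intersection = "&", difference = "-")[[op]]
  roi_mask(paste0("(", a$name, sym, b$name, ")"), v, a$spacing, a$origin)
}

#' ROI volume in cubic centimetres
#' @param mask non-empty `roi_mask`.
#' @return Numeric scalar: voxel count times voxel volume (cc).
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  n <- sum(mask$voxels)
  if (n == 0) stop("volume of empty mask '", mask$name, "' requested")
  n * voxel_volume_cc(mask)
}

#' ROI centroid in world coordinates (mm)
#' @param mask non-empty `roi_mask`.
#' @return Numeric length-3 (RL, AP, CC) in mm.
#' @export
centroid_mm <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("centroid of empty mask '", mask$name, "' requested")
  colMeans(voxel_centers_mm(mask, idx))
}

#' Check structure-set ROI names against the canonical schema
#'
#' Report-only consistency check run before automated planning: lists
#' missing required names, unrecognized extras (with a nearest-name
#' suggestion) and duplicates.
#'
#' @param structs a `structure_set`, or a character vector of ROI names.
#' @return List with `ok`, `missing`, `unrecognized` (named character vector
#'   of suggestions), `duplicates`.
#' @export
check_roi_names <- function(structs) {
  nm <- if (is.character(structs)) structs
        else vapply(structs$masks, function(m) m$name, character(1))
  schema <- canonical_roi_names()
  known <- c(schema$required, schema$optional)
  missing <- setdiff(schema$required, nm)
  extras <- nm[!(nm %in% known) & !startsWith(nm, "z_")]
  sugg <- vapply(extras, function(e) {
    d <- utils::adist(e, known, ignore.case = TRUE)
    known[which.min(d)]
  }, character(1))
  dups <- unique(nm[duplicated(nm)])
  list(ok = length(missing) == 0 && length(extras) == 0 && length(dups) == 0,
       missing = missing, unrecognized = sugg, duplicates = dups)
}

#' Derive the optimization helper ROIs the automated planner uses
#'
#' Reproduces the automatic structure derivation step: the bladder and small
#' bowel are copied with the planning target removed (`z_Bladder_opt`,
#' `z_SmallBowel_opt`), and a bowel-bag-like control shell (`z_AnteriorShell`)
#' is built by expanding the target in the abdominal (anterior) direction and
#' subtracting an isotropic gap expansion, clipped to the body contour.
#'
#' @param structs `structure_set` containing the canonical ROIs.
#' @param target name of the planning target to subtract (default
#'   `"PTV_initial"`; the boost plan uses `"PTV_boost"`).
#' @param anterior_mm anterior expansion distance of the control shell (mm).
#' @param gap_mm isotropic gap between target and shell (mm).
#' @return The structure set with the derived ROIs added and flagged.
#' @export
derive_optimization_rois <- function(structs, target = "PTV_initial",
                                     anterior_mm = 30, gap_mm = 3) {
  req <- c(target, "Bladder", "SmallBowel", "External")
  nm <- names(structs$masks)
  for (r in req) if (!(r %in% nm)) stop("missing canonical ROI '", r, "'")
  ptv <- structs[[target]]
  ext <- structs[["External"]]

  bl <- boolean_op(structs[["Bladder"]], ptv, "difference")
  bl$name <- "z_Bladder_opt"
  sb <- boolean_op(structs[["SmallBowel"]], ptv, "difference")
  sb$name <- "z_SmallBowel_opt"

  ant <- expand_mask(ptv, margins(anterior_mm = anterior_mm))
  gap <- expand_mask(ptv, margins_isotropic(gap_mm))
  shell <- boolean_op(ant, gap, "difference")
  shell <- boolean_op(shell, ext, "intersection")
  shell$name <- "z_AnteriorShell"

  structs <- set_add(structs, bl, derived = TRUE)
  structs <- set_add(structs, sb, derived = TRUE)
  set_add(structs, shell, derived = TRUE)
}

#' Grow clinical and planning target volumes from a gross tumour volume
#'
#' The clinical target volume (CTV) is the gross tumour expanded by 5 mm in
#' the anterior-posterior and right-left directions and 20 mm craniocaudally,
#' united with any metastatic node masks (nodes are not expanded). The
#' planning target volume (PTV) adds a 5 mm isotropic setup margin to the
#' CTV. Both are clipped to the body contour.
#'
#' @param gtv non-empty `roi_mask` of the gross tumour volume.
#' @param node_masks list of `roi_mask` objects (may be empty).
#' @param external optional body `roi_mask` used for clipping.
#' @param ap_rl_mm,cc_mm,setup_mm the three margin magnitudes (mm).
#' @return List with `ctv` and `ptv` masks.
#' @export
build_targets <- function(gtv, node_masks = list(), external = NULL,
                          ap_rl_mm = 5, cc_mm = 20, setup_mm = 5) {
  stopifnot(inherits(gtv, "roi_mask"))
  if (!any(gtv$voxels)) stop("gtv is empty")
  ctv <- expand_mask(gtv, margins(ap_rl_mm, ap_rl_mm, ap_rl_mm, ap_rl_mm,
                                  cc_mm, cc_mm), name = "CTV")
  for (nd in node_masks) {
    stopifnot(inherits(nd, "roi_mask"))
    stop_if_geometry_differs(ctv, nd)
    ctv$voxels <- ctv$voxels | nd$voxels
  }
  ptv <- expand_mask(ctv, margins_isotropic(setup_mm), name = "PTV")
  if (!is.null(external)) {
    stop_if_geometry_differs(ctv, external)
    ctv$voxels <- ctv$voxels & external$voxels
    ptv$voxels <- ptv$voxels & external$voxels
  }
  list(ctv = ctv, ptv = ptv)
}
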