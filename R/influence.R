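#' Dose influence operator for an arc plan
#'
#' Precomputes, for every scoring voxel and control point, the pencil-beam
#' transfer term (exponential attenuation at radiological depth times
#' inverse-square fall-off) and the voxel's beam's-eye-view coordinates in
#' the collimator-rotated fluence frame. Dose is then linear in the fluence
#' weights: each beamlet's contribution is its transfer term times the
#' Gaussian-penumbra-blurred fluence interpolated at the voxel's BEV
#' position. The operator is stored in factored form (transfer terms + BEV
#' coordinates) rather than as an explicit sparse matrix; single columns can
#' be materialized with [influence_column()].
#'
#' @param plan an `arc_plan`.
#' @param density `voxel_grid` of relative electron density (couch included).
#' @param roi_bounding non-empty `roi_mask` restricting dose scoring
#'   (normally the body contour).
#' @param target optional `roi_mask` whose BEV projection sizes the fluence
#'   grid; defaults to `roi_bounding`.
#' @param field_margin_mm margin added around the target projection (mm).
#' @param step_mm ray-trace sampling step (mm).
#' @param fluence_grid optional list with `u` and `v` bin-centre vectors,
#'   overriding the automatic field sizing (used when a plan must be
#'   recomputed on the exact fluence grid it was optimized on).
#' @return An object of class `dose_influence`.
#' @export
influence_matrix <- function(plan, density, roi_bounding, target = NULL,
                             field_margin_mm = 12,
                             step_mm = min(density$spacing),
                             fluence_grid = NULL) {
  stopifnot(inherits(plan, "arc_plan"), inherits(density, "voxel_grid"),
            inherits(roi_bounding, "roi_mask"))
  stop_if_geometry_differs(density, roi_bounding)
  if (!any(roi_bounding$voxels)) stop("bounding ROI is empty")
  target <- target %||% roi_bounding
  geo <- arc_geometry(plan)
  m <- plan$machine

  pitch <- m$beamlet_width_mm
  if (is.null(fluence_grid)) {
    # fluence grid sized to cover the target's BEV projection at every angle
    tid <- which(target$voxels, arr.ind = TRUE)
    tpts <- voxel_centers_mm(target, tid)
    half_u <- 0; half_v <- 0
    for (c in seq_len(nrow(geo$src))) {
      vec <- sweep(tpts, 2, geo$src[c, ], "-")
      w <- as.numeric(vec %*% geo$ew[c, ])
      u <- as.numeric(vec %*% geo$eu[c, ]) * m$sad_mm / w
      v <- as.numeric(vec %*% geo$ev[c, ]) * m$sad_mm / w
      half_u <- max(half_u, abs(u)); half_v <- max(half_v, abs(v))
    }
    nu <- 2L * as.integer(ceiling((half_u + field_margin_mm) / pitch)) + 1L
    nv <- 2L * as.integer(ceiling((half_v + field_margin_mm) / pitch)) + 1L
    u_centers <- (seq_len(nu) - (nu + 1) / 2) * pitch
    v_centers <- (seq_len(nv) - (nv + 1) / 2) * pitch
  } else {
    u_centers <- fluence_grid$u
    v_centers <- fluence_grid$v
  }

  vox_idx <- which(as.logical(roi_bounding$voxels))
  tr <- cpp_build_transfer(as.numeric(density$values), dim(density$values),
                           density$spacing, density$origin,
                           as.integer(vox_idx - 1L), geo$src, geo$eu, geo$ev,
                           geo$ew, m$sad_mm, m$mu_water_per_cm, step_mm)
  structure(
    list(T = tr$T, U = tr$U, V = tr$V, vox_idx = vox_idx,
         dims = dim(density$values), spacing = density$spacing,
         origin = density$origin, n_cp = length(plan$control_points),
         u_centers = u_centers, v_centers = v_centers,
         machine = m, collimator_deg = plan$collimator_deg,
         isocenter_mm = plan$isocenter_mm),
    class = "dose_influence"
  )
}

#' @export
print.dose_influence <- function(x, ...) {
  cat(sprintf(
    "<dose_influence> %d voxels x %d control points, fluence grid %d x %d @ %g mm\n",
    length(x$vox_idx), x$n_cp, length(x$u_centers), length(x$v_centers),
    x$machine$beamlet_width_mm))
  invisible(x)
}

n_beamlets <- function(influence)
  c(nu = length(influence$u_centers), nv = length(influence$v_centers),
    ncp = influence$n_cp)

# separable Gaussian penumbra blur of a (nu x nv x ncp) fluence array,
# kernel truncated at 3 sigma, normalized to unit sum
blur_fluence <- function(fluence, influence) {
  sig <- influence$machine$penumbra_sigma_mm
  pitch <- influence$machine$beamlet_width_mm
  r <- as.integer(ceiling(3 * sig / pitch))
  if (r == 0) return(fluence)
  k <- stats::dnorm((-r:r) * pitch, sd = sig)
  k <- k / sum(k)
  d <- dim(fluence)
  out <- array(0, d)
  for (j in seq_along(k)) {       # along u
    sh <- j - r - 1
    su <- seq_len(d[1])
    keep <- su + sh >= 1 & su + sh <= d[1]
    out[su[keep], , ] <- out[su[keep], , ] + k[j] * fluence[su[keep] + sh, , ]
  }
  out2 <- array(0, d)
  for (j in seq_along(k)) {       # along v
    sh <- j - r - 1
    sv <- seq_len(d[2])
    keep <- sv + sh >= 1 & sv + sh <= d[2]
    out2[, sv[keep], ] <- out2[, sv[keep], ] + k[j] * out[, sv[keep] + sh, ]
  }
  out2
}

forward_dose_vector <- function(influence, weights) {
  nb <- n_beamlets(influence)
  w <- array(weights, nb)
  fl <- blur_fluence(w, influence)
  pitch <- influence$machine$beamlet_width_mm
  cpp_forward(influence$T, influence$U, influence$V, as.numeric(fl),
              nb[["nu"]], nb[["nv"]], influence$u_centers[1], pitch,
              influence$v_centers[1], pitch) *
    influence$machine$output_gy_per_mu
}

backproject_gradient <- function(influence, resid_vox) {
  nb <- n_beamlets(influence)
  pitch <- influence$machine$beamlet_width_mm
  g <- cpp_backproject(influence$T, influence$U, influence$V, resid_vox,
                       nb[["nu"]], nb[["nv"]], influence$u_centers[1], pitch,
                       influence$v_centers[1], pitch)
  blur_fluence(array(g, nb), influence) * influence$machine$output_gy_per_mu
}

#' Compute the dose distribution for a set of beamlet weights
#'
#' Dose is exactly linear in the weights (fluence in MU): it is the
#' influence operator applied to the penumbra-blurred fluence, scaled by the
#' machine output calibration. Voxels outside the bounding ROI used to build
#' the influence receive zero dose.
#'
#' @param plan the `arc_plan` (carries the machine model).
#' @param influence a `dose_influence` from [influence_matrix()].
#' @param weights non-negative fluence array (`nu x nv x n_cp`) or vector.
#' @return A `voxel_grid` of dose in Gy.
#' @export
compute_dose <- function(plan, influence, weights) {
  stopifnot(inherits(influence, "dose_influence"))
  if (any(weights < 0)) stop("negative beamlet weight")
  nb <- n_beamlets(influence)
  if (length(weights) != prod(nb))
    stop("weights not conformal with influence (expected ", prod(nb),
         " values)")
  dvec <- forward_dose_vector(influence, weights)
  vals <- numeric(prod(influence$dims))
  vals[influence$vox_idx] <- dvec
  voxel_grid(array(vals, influence$dims), influence$spacing, influence$origin)
}

#' Materialize one influence column (single beamlet, unit weight)
#'
#' @param influence a `dose_influence`.
#' @param cp control-point index.
#' @param iu,iv beamlet indices on the fluence grid.
#' @return A `voxel_grid` of dose per unit weight.
#' @export
influence_column <- function(influence, cp, iu, iv) {
  nb <- n_beamlets(influence)
  w <- array(0, nb)
  w[iu, iv, cp] <- 1
  dvec <- forward_dose_vector(influence, w)
  vals <- numeric(prod(influence$dims))
  vals[influence$vox_idx] <- dvec
  voxel_grid(array(vals, influence$dims), influence$spacing, influence$origin)
}

#' Calibrate the machine output scalar against a phantom
#'
#' Sets `output_gy_per_mu` so that one MU of central-axis fluence delivers
#' 1 cGy at the isocentre on average over the arc's control points —
#' i.e. the transfer term at the isocentre voxel, averaged over gantry
#' angles, maps to 0.01 Gy/MU.
#'
#' @param influence a `dose_influence` built with a provisional output.
#' @param gy_per_mu_at_iso desired Gy per MU at the isocentre (default 0.01).
#' @return The influence object with the machine output updated.
#' @export
calibrate_output <- function(influence, gy_per_mu_at_iso = 0.01) {
  iso_idx_arr <- round((influence$isocenter_mm - influence$origin) /
                         influence$spacing) + 1
  lin <- linear_index(influence$dims, matrix(iso_idx_arr, ncol = 3))
  row <- match(lin, influence$vox_idx)
  if (is.na(row)) stop("isocentre lies outside the bounding ROI")
  mean_T <- mean(influence$T[row, ])
  influence$machine$output_gy_per_mu <- gy_per_mu_at_iso / mean_T
  influence
}
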