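#' Convert optimized fluence into deliverable apertures
#'
#' One aperture per control point: for each leaf pair (a row of the fluence
#' grid along the leaf-travel direction), the open interval is the
#' contiguous span around the row maximum where fluence stays at or above a
#' configured fraction of that maximum; rows with negligible fluence close
#' completely. Control-point MU is proportional to the mean in-aperture
#' fluence; all MU are then rescaled by a single global factor so the
#' sequenced plan reproduces the optimized mean dose over `renorm_mask`
#' (when given), mirroring clinical plan renormalization.
#'
#' @param plan the `arc_plan` to fill in.
#' @param influence the `dose_influence` the weights refer to.
#' @param weights optimized fluence (`nu x nv x n_cp`).
#' @param threshold_fraction aperture threshold as a fraction of each row's
#'   maximum fluence.
#' @param renorm_mask optional `roi_mask` (normally the PTV) used for the
#'   global MU renormalization.
#' @return List with `plan` (control points carrying leaf positions and MU)
#'   and `fluence` (the sequenced fluence array implied by the apertures).
#' @export
sequence_leaves <- function(plan, influence, weights,
                            threshold_fraction = 0.5, renorm_mask = NULL) {
  nb <- n_beamlets(influence)
  w <- array(weights, nb)
  gmax <- max(w)
  if (gmax <= 0) stop("all-zero fluence at every control point; nothing to sequence")
  pitch <- influence$machine$beamlet_width_mm
  u <- influence$u_centers
  nu <- nb[["nu"]]; nv <- nb[["nv"]]; ncp <- nb[["ncp"]]
  seqfl <- array(0, nb)

  for (c in seq_len(ncp)) {
    left <- numeric(nv); right <- numeric(nv)
    open_vals <- c()
    open_bins <- matrix(FALSE, nu, nv)
    for (j in seq_len(nv)) {
      f <- w[, j, c]
      fmax <- max(f)
      if (fmax <= 1e-9 * gmax) { left[j] <- 0; right[j] <- 0; next }
      thr <- threshold_fraction * fmax
      pk <- which.max(f)
      il <- pk; while (il > 1 && f[il - 1] >= thr) il <- il - 1
      ir <- pk; while (ir < nu && f[ir + 1] >= thr) ir <- ir + 1
      left[j] <- u[il] - pitch / 2
      right[j] <- u[ir] + pitch / 2
      open_bins[il:ir, j] <- TRUE
      open_vals <- c(open_vals, f[il:ir])
    }
    mu_c <- if (length(open_vals)) mean(open_vals) else 0
    plan$control_points[[c]]$leaf_left_mm <- left
    plan$control_points[[c]]$leaf_right_mm <- right
    plan$control_points[[c]]$mu <- mu_c
    seqfl[, , c][open_bins] <- mu_c
  }

  alpha <- 1
  if (!is.null(renorm_mask)) {
    d_opt <- forward_dose_vector(influence, w)
    d_seq <- forward_dose_vector(influence, seqfl)
    sel <- influence$vox_idx %in% which(as.logical(renorm_mask$voxels))
    ms <- mean(d_seq[sel])
    if (ms > 0) alpha <- mean(d_opt[sel]) / ms
  }
  if (alpha != 1) {
    for (c in seq_len(ncp))
      plan$control_points[[c]]$mu <- plan$control_points[[c]]$mu * alpha
    seqfl <- seqfl * alpha
  }
  plan$fluence_grid <- list(u = u, v = influence$v_centers)
  list(plan = plan, fluence = seqfl)
}
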