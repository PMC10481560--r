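#' Conformity index of a plan
#'
#' `CI = TV_PIV^2 / (TV x PIV)` where `TV` is the target volume, `PIV` the
#' volume enclosed by the prescription isodose, and `TV_PIV` the target
#' volume covered by it (all in cc from voxel counts). `CI = 1` iff the
#' prescription isodose region coincides with the target voxel set. An
#' empty prescription isodose yields `CI = 0` with a warning.
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param target non-empty `roi_mask`.
#' @param prescription_gy prescription (Gy), positive.
#' @return CI in `[0, 1]`.
#' @export
conformity_index <- function(dose, target, prescription_gy) {
  stopifnot(inherits(dose, "voxel_grid"), inherits(target, "roi_mask"))
  stop_if_geometry_differs(dose, target)
  if (!any(target$voxels)) stop("empty target")
  if (prescription_gy <= 0) stop("prescription must be positive")
  piv <- dose$values >= prescription_gy
  n_piv <- sum(piv)
  if (n_piv == 0) {
    warning("prescription isodose volume is empty; CI defined as 0")
    return(0)
  }
  n_tv <- sum(target$voxels)
  n_cov <- sum(piv & target$voxels)
  n_cov^2 / (n_tv * n_piv)
}

#' Homogeneity index of a target dose
#'
#' `HI = (D2 - D98) / D_prescription`: 0 for a perfectly uniform target
#' dose, larger for more heterogeneous coverage. Invariant under joint
#' rescaling of dose and prescription.
#'
#' @param dvh target `dvh`.
#' @param prescription_gy prescription (Gy), positive.
#' @return Non-negative numeric.
#' @export
homogeneity_index <- function(dvh, prescription_gy) {
  if (prescription_gy <= 0) stop("prescription must be positive")
  (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / prescription_gy
}

#' Voxelwise sum of two dose grids
#'
#' Composite dose for organ-at-risk evaluation over the initial and boost
#' plans.
#'
#' @param dose_a,dose_b `voxel_grid`s on the same geometry.
#' @return A `voxel_grid`.
#' @export
plan_sum <- function(dose_a, dose_b) {
  stopifnot(inherits(dose_a, "voxel_grid"), inherits(dose_b, "voxel_grid"))
  stop_if_geometry_differs(dose_a, dose_b)
  out <- dose_a
  out$values <- dose_a$values + dose_b$values
  out
}

#' Summary metrics of a plan for one ROI
#'
#' @param dose `voxel_grid`.
#' @param mask `roi_mask`.
#' @param prescription_gy prescription for Dx-as-percent reporting.
#' @return Tibble with Dmean, Dmax, D2, D93, D98 (Gy and % of Rx).
#' @export
roi_dose_summary <- function(dose, mask, prescription_gy) {
  dvh <- cumulative_dvh(dose, mask)
  d <- dose$values[mask$voxels]
  tibble::tibble(
    roi = mask$name, mean_gy = mean(d), max_gy = max(d),
    d2_gy = dose_at_volume(dvh, 2), d93_gy = dose_at_volume(dvh, 93),
    d98_gy = dose_at_volume(dvh, 98),
    d2_pct = 100 * dose_at_volume(dvh, 2) / prescription_gy,
    d93_pct = 100 * dose_at_volume(dvh, 93) / prescription_gy,
    d98_pct = 100 * dose_at_volume(dvh, 98) / prescription_gy)
}
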