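#' Simplified photon beam model
#'
#' Parameters of the primary-photon pencil-beam kernel: exponential
#' attenuation in water-equivalent depth, Gaussian lateral penumbra,
#' inverse-square fall-off from a point source at the source-axis distance.
#' The defaults approximate a 10 MV beam; no buildup or scatter kernels are
#' modelled, so depth dose decreases monotonically from the surface.
#'
#' @param mu_water_per_cm linear attenuation coefficient (1/cm).
#' @param penumbra_sigma_mm lateral Gaussian blur sigma (mm).
#' @param sad_mm source-axis distance (mm).
#' @param beamlet_width_mm fluence-grid pitch (mm).
#' @param output_gy_per_mu calibration scalar (Gy per MU of fluence on the
#'   central axis); see [calibrate_output()].
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(mu_water_per_cm = 0.04, penumbra_sigma_mm = 3,
                       sad_mm = 1000, beamlet_width_mm = 5,
                       output_gy_per_mu = 0.01) {
  p <- list(mu_water_per_cm = mu_water_per_cm,
            penumbra_sigma_mm = penumbra_sigma_mm, sad_mm = sad_mm,
            beamlet_width_mm = beamlet_width_mm,
            output_gy_per_mu = output_gy_per_mu)
  if (any(vapply(p, function(x) !is.finite(x) || x <= 0, logical(1))))
    stop("all beam model parameters must be positive and finite")
  structure(p, class = "beam_model")
}

#' Build a single full-arc VMAT plan skeleton
#'
#' Control points are placed at uniform gantry spacing `360 / n_cp` starting
#' at 0 degrees, with zero monitor units and closed leaves; the optimizer and
#' leaf sequencer fill them in. Gantry 0 is anterior, angles increase toward
#' the patient's left (source at +RL for gantry 90).
#'
#' @param isocenter_mm machine isocentre (mm), normally the PTV centroid.
#' @param n_cp number of control points (>= 8).
#' @param collimator_deg collimator angle (degrees); applied as an in-plane
#'   rotation of the leaf-travel frame.
#' @param machine a [beam_model()].
#' @param prescription_gy prescribed dose (Gy).
#' @return An object of class `arc_plan`.
#' @export
build_arc <- function(isocenter_mm, n_cp = 72, collimator_deg = 355,
                      machine = beam_model(), prescription_gy = 45) {
  if (n_cp < 8) stop("n_cp must be at least 8")
  if (prescription_gy <= 0) stop("prescription must be positive")
  angles <- (seq_len(n_cp) - 1) * 360 / n_cp
  cps <- lapply(angles, function(a)
    list(gantry_deg = a, mu = 0,
         leaf_left_mm = numeric(0), leaf_right_mm = numeric(0)))
  structure(
    list(control_points = cps, collimator_deg = collimator_deg,
         isocenter_mm = as.numeric(isocenter_mm),
         prescription_gy = prescription_gy, machine = machine,
         fluence_grid = NULL),
    class = "arc_plan"
  )
}

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf(
    "<arc_plan> %d control points, collimator %g deg, Rx %g Gy, total MU %.1f\n",
    length(x$control_points), x$collimator_deg, x$prescription_gy,
    total_mu(x)))
  invisible(x)
}

plan_gantry_deg <- function(plan)
  vapply(plan$control_points, `[[`, numeric(1), "gantry_deg")

# Per-control-point beam frame: source position and BEV unit vectors with
# the collimator rotation applied to (u, v).
arc_geometry <- function(plan) {
  th <- plan_gantry_deg(plan) * pi / 180
  phi <- plan$collimator_deg * pi / 180
  sad <- plan$machine$sad_mm
  a <- cbind(sin(th), -cos(th), 0)              # iso -> source direction
  src <- sweep(sad * a, 2, plan$isocenter_mm, "+")
  ew <- -a                                      # central-axis direction
  eu0 <- cbind(cos(th), sin(th), 0)
  ev0 <- matrix(rep(c(0, 0, 1), each = length(th)), ncol = 3)
  eu <- cos(phi) * eu0 + sin(phi) * ev0
  ev <- -sin(phi) * eu0 + cos(phi) * ev0
  list(src = src, eu = eu, ev = ev, ew = ew)
}

#' Water-equivalent radiological depth along a ray
#'
#' Line integral of relative electron density from `source` to `target`, by
#' uniform-step sampling of the density grid; returned in cm of water.
#'
#' @param density `voxel_grid` of relative electron density.
#' @param source,target world points (mm).
#' @param step_mm sampling step (mm).
#' @return Non-negative numeric scalar (cm).
#' @export
radiological_depth <- function(density, source, target,
                               step_mm = min(density$spacing)) {
  stopifnot(all(is.finite(source)), all(is.finite(target)))
  cpp_ray_depth(as.numeric(density$values), dim(density$values),
                density$spacing, density$origin, as.numeric(source),
                matrix(as.numeric(target), ncol = 3), step_mm)[1]
}
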