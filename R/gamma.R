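#' Gamma-analysis acceptance criteria
#'
#' @param dose_diff_pct dose-difference criterion as percent of the global
#'   normalization (reference maximum).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param low_dose_cutoff_fraction reference voxels below this fraction of
#'   the reference maximum are excluded from analysis.
#' @param search_radius_dta search radius as a multiple of the DTA.
#' @param step_dta displacement sampling step as a fraction of the DTA.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff_pct = 3, dta_mm = 2,
                           low_dose_cutoff_fraction = 0.1,
                           search_radius_dta = 3, step_dta = 0.2) {
  stopifnot(dose_diff_pct > 0, dta_mm > 0, low_dose_cutoff_fraction >= 0,
            search_radius_dta > 0, step_dta > 0)
  structure(list(dose_diff_pct = dose_diff_pct, dta_mm = dta_mm,
                 low_dose_cutoff_fraction = low_dose_cutoff_fraction,
                 search_radius_dta = search_radius_dta,
                 step_dta = step_dta, normalization = "global"),
            class = "gamma_criteria")
}

gamma_offsets <- function(criteria, spacing) {
  dta <- criteria$dta_mm
  r <- criteria$search_radius_dta * dta
  st <- criteria$step_dta * dta
  ax <- seq(-r, r, by = st)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  d2 <- rowSums(g^2)
  keep <- d2 <= r^2 + 1e-9
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  list(offsets = g[ord, , drop = FALSE], r2_norm = d2[ord] / dta^2)
}

#' Gamma pass rate between two dose distributions
#'
#' For every reference voxel above the low-dose cutoff, the gamma index is
#' the minimum over candidate displacements (within the search radius,
#' sampled at a fraction of the DTA, evaluated dose trilinearly
#' interpolated) of `sqrt((dose diff / dose criterion)^2 +
#' (distance / DTA)^2)`, with the dose criterion taken globally as a
#' percentage of the reference maximum. A voxel passes when gamma <= 1.
#'
#' @param reference,evaluated `voxel_grid`s on the same geometry (resample
#'   the evaluated grid first if needed, see [resample_to()]).
#' @param criteria a [gamma_criteria()].
#' @return Pass rate in percent, with attributes `n_evaluated`,
#'   `mean_gamma`, and the per-voxel `gamma` grid.
#' @export
gamma_pass_rate <- function(reference, evaluated,
                            criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "voxel_grid"),
            inherits(evaluated, "voxel_grid"))
  stop_if_geometry_differs(reference, evaluated)
  rmax <- max(reference$values)
  if (rmax <= 0) stop("reference maximum must be positive")
  off <- gamma_offsets(criteria, reference$spacing)
  dd_abs <- criteria$dose_diff_pct / 100 * rmax
  cutoff <- criteria$low_dose_cutoff_fraction * rmax
  g <- cpp_gamma(as.numeric(reference$values), as.numeric(evaluated$values),
                 dim(reference$values), reference$spacing, dd_abs, cutoff,
                 off$offsets, off$r2_norm)
  analyzed <- !is.na(g)
  if (!any(analyzed)) stop("no reference voxel above the low-dose cutoff")
  rate <- 100 * sum(g[analyzed] <= 1) / sum(analyzed)
  structure(rate, n_evaluated = sum(analyzed),
            mean_gamma = mean(g[analyzed]),
            gamma = voxel_grid(array(g, dim(reference$values)),
                               reference$spacing, reference$origin))
}

#' Independent dose recomputation for self-QA
#'
#' Recomputes a plan's dose with independent numerical settings: the
#' ray-trace step halved and the scoring grid shifted by half a voxel, then
#' trilinearly resampled back onto the original geometry. Comparing the
#' result against the plan dose with [gamma_pass_rate()] probes the
#' numerical robustness of the dose computation.
#'
#' @param plan sequenced or optimized `arc_plan`.
#' @param density `voxel_grid` used for planning (couch included).
#' @param external body `roi_mask`.
#' @param weights the plan's fluence weights.
#' @param fluence_grid the fluence grid the weights were optimized on
#'   (list with `u`, `v`), normally `plan$fluence_grid`.
#' @return A `voxel_grid` of recomputed dose on the original geometry.
#' @export
recompute_dose_independent <- function(plan, density, external, weights,
                                       fluence_grid = plan$fluence_grid) {
  if (is.null(fluence_grid)) stop("fluence grid unknown; sequence the plan first")
  shift <- density$spacing / 2
  density_s <- density; density_s$origin <- density$origin + shift
  # score one voxel beyond the body so the resample back onto the original
  # grid has valid neighbours at the surface
  ext_s <- expand_mask(external, margins_isotropic(max(external$spacing)))
  ext_s$origin <- external$origin + shift
  infl <- influence_matrix(plan, density_s, ext_s,
                           step_mm = min(density$spacing) / 2,
                           fluence_grid = fluence_grid)
  infl$machine <- plan$machine  # keep the calibrated output
  dose_s <- compute_dose(plan, infl, weights)
  resample_to(dose_s, density)
}
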