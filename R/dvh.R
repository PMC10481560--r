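#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH: at every bin edge the curve holds
#' the fraction of the ROI's voxels receiving at least that dose, so it
#' starts at 1 at 0 Gy, is non-increasing, and reaches 0 beyond the maximum
#' dose.
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param mask non-empty `roi_mask` on the same grid.
#' @param bin_width_gy histogram bin width (Gy).
#' @return An object of class `dvh` with `bin_edges_gy`,
#'   `cumulative_volume_fraction`, `total_cc` and the ROI name.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_gy = 0.05) {
  stopifnot(inherits(dose, "voxel_grid"), inherits(mask, "roi_mask"))
  stop_if_geometry_differs(dose, mask)
  if (!any(mask$voxels)) stop("empty mask '", mask$name, "'")
  d <- dose$values[mask$voxels]
  dvh <- dvh_from_vector(d, voxel_volume_cc(mask), bin_width_gy)
  dvh$roi <- mask$name
  dvh
}

dvh_from_vector <- function(d, vox_cc, bin_width_gy = 0.05) {
  edges <- seq(0, max(d, 0) + 2 * bin_width_gy, by = bin_width_gy)
  # fraction of voxels with dose >= edge, via a reversed cumulative count
  cnt <- tabulate(findInterval(d, edges), nbins = length(edges))
  frac <- rev(cumsum(rev(cnt))) / length(d)
  structure(
    list(roi = NA_character_, bin_edges_gy = edges,
         cumulative_volume_fraction = frac,
         total_cc = length(d) * vox_cc),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s: %.2f cc, D50 = %.2f Gy, Dmax bin = %.2f Gy\n",
              x$roi, x$total_cc, dose_at_volume(x, 50),
              max(x$bin_edges_gy) - 2 * diff(x$bin_edges_gy[1:2])))
  invisible(x)
}

#' Tidy a DVH into a tibble
#' @param x a `dvh`.
#' @param ... unused.
#' @return Tibble with `dose_gy`, `volume_fraction`, `volume_cc`, `roi`.
#' @export
tidy.dvh <- function(x, ...) {
  tibble::tibble(dose_gy = x$bin_edges_gy,
                 volume_fraction = x$cumulative_volume_fraction,
                 volume_cc = x$cumulative_volume_fraction * x$total_cc,
                 roi = x$roi)
}

#' Dose received by at least x% of the volume (Dx)
#'
#' The largest dose whose cumulative volume fraction is still at least
#' `x_pct / 100`, with linear interpolation between bin edges.
#'
#' @param dvh a `dvh`.
#' @param x_pct volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, x_pct) {
  if (x_pct <= 0 || x_pct > 100) stop("x_pct must lie in (0, 100]")
  f <- dvh$cumulative_volume_fraction
  e <- dvh$bin_edges_gy
  q <- x_pct / 100
  k <- which(f >= q)
  if (!length(k)) return(0)
  i <- max(k)
  if (i == length(f) || f[i] == q) return(e[i])
  # f decreases from f[i] (>= q) to f[i+1] (< q) across the bin
  if (f[i] == f[i + 1]) return(e[i])
  e[i] + (f[i] - q) / (f[i] - f[i + 1]) * (e[i + 1] - e[i])
}

#' Volume receiving at least a given dose (Vx)
#'
#' @param dvh a `dvh`.
#' @param dose_gy dose threshold (Gy), non-negative.
#' @return List with `pct` (percent of the ROI volume) and `cc`.
#' @export
volume_at_dose <- function(dvh, dose_gy) {
  if (dose_gy < 0) stop("dose_gy must be >= 0")
  f <- dvh$cumulative_volume_fraction
  e <- dvh$bin_edges_gy
  if (dose_gy >= max(e)) return(list(pct = 0, cc = 0))
  frac <- stats::approx(e, f, xout = dose_gy, rule = 2)$y
  list(pct = 100 * frac, cc = frac * dvh$total_cc)
}
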