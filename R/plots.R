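#' Plot cumulative DVH curves
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param structs `structure_set`.
#' @param rois ROI names to plot (default: the canonical clinical ROIs
#'   present).
#' @return A ggplot object.
#' @export
plot_dvh <- function(dose, structs,
                     rois = intersect(canonical_roi_names()$required,
                                      names(structs$masks))) {
  rois <- setdiff(rois, "External")
  curves <- do.call(rbind, lapply(rois, function(nm)
    tidy.dvh(cumulative_dvh(dose, structs[[nm]]))))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$dose_gy,
                               y = 100 * .data$volume_fraction,
                               colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of dose over the anatomy
#'
#' @param dose `voxel_grid` of dose.
#' @param structs optional `structure_set` whose External contour frames
#'   the slice.
#' @param cc_mm craniocaudal position of the slice (mm); defaults to the
#'   grid centre.
#' @return A ggplot object.
#' @export
plot_dose_slice <- function(dose, structs = NULL, cc_mm = NULL) {
  d <- dim(dose$values)
  zc <- dose$origin[3] + (seq_len(d[3]) - 1) * dose$spacing[3]
  k <- if (is.null(cc_mm)) ceiling(d[3] / 2) else which.min(abs(zc - cc_mm))
  sl <- dose$values[, , k]
  df <- expand.grid(
    rl = dose$origin[1] + (seq_len(d[1]) - 1) * dose$spacing[1],
    ap = dose$origin[2] + (seq_len(d[2]) - 1) * dose$spacing[2])
  df$dose <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rl, y = .data$ap,
                                   fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Dose (Gy)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "RL (mm)", y = "AP (mm)") +
    ggplot2::theme_minimal()
}
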