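#' Total monitor units of a plan
#' @param plan an `arc_plan`.
#' @return Sum of control-point MU (>= 0).
#' @export
total_mu <- function(plan) {
  stopifnot(inherits(plan, "arc_plan"))
  sum(vapply(plan$control_points, `[[`, numeric(1), "mu"))
}

#' Modulation complexity score of a sequenced arc plan
#'
#' The VMAT modulation complexity score combines, per control point, the
#' aperture-area variability (AAV: summed leaf-pair openings normalized by
#' each pair's maximum opening over the whole arc) and the leaf-sequence
#' variability (LSV: per leaf bank, the mean of
#' `(pos_max - |adjacent-leaf position difference|) / pos_max` over open
#' pairs, the two banks multiplied). The score is the MU-weighted sum over
#' adjacent control-point pairs of the averaged AAV times the averaged LSV.
#' It lies in `[0, 1]`; 1 is a fully open, uniformly weighted arc and
#' values nearer 0 indicate more modulated (complex) delivery. Invariant
#' under uniform MU rescaling.
#'
#' @param plan sequenced `arc_plan` with leaf positions and MU.
#' @return MCS in `[0, 1]`.
#' @export
modulation_complexity <- function(plan) {
  stopifnot(inherits(plan, "arc_plan"))
  cps <- plan$control_points
  mu <- vapply(cps, `[[`, numeric(1), "mu")
  if (sum(mu) <= 0) stop("plan has zero total MU; sequence it first")
  n_pairs <- length(cps[[1]]$leaf_left_mm)
  if (n_pairs == 0) stop("plan has no leaf positions; sequence it first")
  openings <- vapply(cps, function(cp) cp$leaf_right_mm - cp$leaf_left_mm,
                     numeric(n_pairs))
  openings <- matrix(openings, nrow = n_pairs)
  pair_max <- apply(openings, 1, max)

  aav <- vapply(seq_along(cps), function(i) {
    denom <- sum(pair_max)
    if (denom <= 0) return(0)
    sum(openings[, i]) / denom
  }, numeric(1))

  lsv <- vapply(seq_along(cps), function(i) {
    open <- openings[, i] > 0
    if (sum(open) < 2) return(1)
    bank <- function(pos) {
      p <- pos[open]
      pos_max <- max(p) - min(p)
      if (pos_max <= 0) return(1)
      mean((pos_max - abs(diff(p))) / pos_max)
    }
    bank(cps[[i]]$leaf_left_mm) * bank(cps[[i]]$leaf_right_mm)
  }, numeric(1))

  i <- seq_len(length(cps) - 1)
  w_pair <- (mu[i] + mu[i + 1])
  w_pair <- w_pair / sum(w_pair)
  sum(0.5 * (aav[i] + aav[i + 1]) * 0.5 * (lsv[i] + lsv[i + 1]) * w_pair)
}
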