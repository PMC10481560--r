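#' Optimization objective
#'
#' One-sided quadratic penalty terms on the dose inside an ROI. Kinds:
#' `min_dose` (penalize below the level), `max_dose` (above), `max_dvh`
#' (above the level for the worst-excess fraction of voxels beyond the
#' allowed volume), `uniform` (symmetric about the level), and
#' `dose_falloff` (penalize dose above a per-voxel target that ramps
#' linearly from `high_gy` at the ROI's target-facing boundary down to
#' `low_gy` at `distance_mm` away).
#'
#' @param kind objective kind (see above).
#' @param roi ROI name the penalty applies to.
#' @param dose_gy dose level in Gy (not used by `dose_falloff`).
#' @param weight positive penalty weight.
#' @param volume_pct allowed volume (%) for `max_dvh`.
#' @param high_gy,low_gy,distance_mm fall-off parameters.
#' @param is_constraint flag marking goal-driven constraint objectives.
#' @return An object of class `plan_objective`.
#' @export
objective <- function(kind = c("min_dose", "max_dose", "max_dvh", "uniform",
                               "dose_falloff"),
                      roi, dose_gy = NULL, weight = 1, volume_pct = NULL,
                      high_gy = NULL, low_gy = NULL, distance_mm = NULL,
                      is_constraint = FALSE) {
  kind <- match.arg(kind)
  if (weight <= 0) stop("objective weight must be positive")
  if (kind == "dose_falloff") {
    if (is.null(high_gy) || is.null(low_gy) || is.null(distance_mm))
      stop("dose_falloff needs high_gy, low_gy and distance_mm")
    if (high_gy <= low_gy) stop("dose_falloff needs high_gy > low_gy")
    if (distance_mm <= 0) stop("dose_falloff needs distance_mm > 0")
    if (low_gy < 0) stop("dose levels must be >= 0")
  } else {
    if (is.null(dose_gy) || dose_gy < 0) stop("dose_gy must be >= 0")
    if (kind == "max_dvh" &&
        (is.null(volume_pct) || volume_pct <= 0 || volume_pct >= 100))
      stop("max_dvh needs volume_pct in (0, 100)")
  }
  structure(
    list(kind = kind, roi = roi, dose_gy = dose_gy, weight = weight,
         volume_pct = volume_pct, high_gy = high_gy, low_gy = low_gy,
         distance_mm = distance_mm, is_constraint = is_constraint),
    class = "plan_objective"
  )
}

#' Build the automated planner's objective list for one plan
#'
#' Target coverage and uniformity objectives on the planning target, a
#' near-maximum cap on the body implementing the D2 goal, and exactly one
#' dose fall-off objective per organ-at-risk helper structure
#' (`z_Bladder_opt`, `z_SmallBowel_opt`, `z_AnteriorShell`, and both
#' femoral heads). All dose levels scale with the prescription, so the same
#' construction serves the initial and the boost plan.
#'
#' @param structs structure set with the derived optimization ROIs present.
#' @param target planning target ROI name.
#' @param prescription_gy prescription (Gy).
#' @param goals optional list of [clinical_goal()]s; ROIs named there must
#'   exist (unknown ROIs raise an error). Organ-at-risk Vx goals are
#'   translated into max-DVH objectives on the target-subtracted helper
#'   ROIs, with dose levels scaled by this plan's share of the summed
#'   prescription and the allowed volume tightened by a headroom factor;
#'   zero-volume goals become maximum-dose caps.
#' @param config an [autoplan_config()] providing weights and fall-off
#'   defaults.
#' @param plan_fraction this plan's fraction of the total (plan-sum)
#'   prescription, used to scale absolute-dose goal levels.
#' @return List of `plan_objective`s.
#' @export
build_objectives <- function(structs, target = "PTV_initial",
                             prescription_gy = 45, goals = list(),
                             config = autoplan_config(),
                             plan_fraction = NULL) {
  need <- c(target, "z_Bladder_opt", "z_SmallBowel_opt", "z_AnteriorShell",
            "FemoralHead_L", "FemoralHead_R")
  for (r in need) if (!(r %in% names(structs$masks)))
    stop("derived ROI '", r, "' missing; run derive_optimization_rois first")
  for (g in goals) {
    rois <- resolve_goal_rois(g$roi)
    for (r in rois) if (!(r %in% names(structs$masks)) &&
                        !(r %in% c("PTV_initial", "PTV_boost")))
      stop("unknown ROI '", r, "' in clinical goals")
  }
  rx <- prescription_gy
  fo <- config$falloff
  obj <- list(
    objective("uniform", target, dose_gy = rx, weight = config$w_uniform),
    objective("min_dose", target, dose_gy = 0.985 * rx,
              weight = config$w_min_dose),
    objective("max_dose", target, dose_gy = 1.05 * rx,
              weight = config$w_max_dose)
  )
  # with no clinical goals there is nothing to protect: target objectives only
  if (length(goals) == 0) return(obj)
  obj <- c(obj, list(
    objective("max_dose", "External", dose_gy = 1.07 * rx,
              weight = config$w_body_max)))
  oars <- c("z_Bladder_opt", "z_SmallBowel_opt", "z_AnteriorShell",
            "FemoralHead_L", "FemoralHead_R")
  for (r in oars) {
    obj <- c(obj, list(objective("dose_falloff", r,
      high_gy = fo$high_fraction * rx, low_gy = fo$low_fraction * rx,
      distance_mm = fo$distance_mm, weight = config$w_falloff)))
  }

  # goal-derived organ-at-risk objectives
  if (is.null(plan_fraction))
    plan_fraction <- rx / sum(config$prescriptions_gy)
  opt_name <- c(Bladder = "z_Bladder_opt", SmallBowel = "z_SmallBowel_opt",
                FemoralHeads = NA, FemoralHead_L = "FemoralHead_L",
                FemoralHead_R = "FemoralHead_R")
  for (g in goals) {
    if (g$metric != "Vx" || !(g$comparator %in% c("<", "<=")) ||
        g$roi == "PTV") next
    rois <- if (g$roi == "FemoralHeads") c("FemoralHead_L", "FemoralHead_R")
            else opt_name[[g$roi]] %||% g$roi
    level <- g$parameter * plan_fraction
    for (r in rois) {
      vol_pct <- if (g$units == "cc")
        100 * g$threshold / volume_cc(structs[[r]]) else g$threshold
      vol_pct <- config$goal_headroom * vol_pct
      o <- if (vol_pct <= 0 || vol_pct >= 100) {
        if (vol_pct > 0) next
        # zero-volume goals are absolute caps: tighten the level (the other
        # plan's spill at the shared boundary is disproportionate to its
        # prescription share) and weight like a constraint
        objective("max_dose", r, dose_gy = config$goal_cap_headroom * level,
                  weight = config$w_goal_max, is_constraint = TRUE)
      } else {
        objective("max_dvh", r, dose_gy = level, volume_pct = vol_pct,
                  weight = config$w_goal_dvh)
      }
      obj <- c(obj, list(o))
    }
  }
  obj
}

# Bind objectives to the scoring geometry: per-objective voxel rows (into
# the influence's scoring vector) and per-voxel fall-off dose targets from
# the Euclidean distance to the planning target.
bind_objectives <- function(objectives, structs, influence, target) {
  if (length(objectives) == 0) stop("objective list is empty")
  dist_mm <- NULL
  tgt_mask <- structs[[target]]
  lapply(objectives, function(o) {
    m <- structs[[o$roi]]
    rows <- which(as.logical(m$voxels[influence$vox_idx]))
    b <- list(obj = o, rows = rows, n = max(1L, length(rows)))
    if (o$kind == "dose_falloff") {
      if (is.null(dist_mm)) {
        dist_mm <<- cpp_distance_mm(as.logical(tgt_mask$voxels),
                                    dim(tgt_mask$voxels), tgt_mask$spacing)
      }
      dvox <- dist_mm[influence$vox_idx][rows]
      ramp <- pmin(dvox / o$distance_mm, 1)
      b$falloff_target <- o$high_gy - (o$high_gy - o$low_gy) * ramp
    }
    b
  })
}

# value and per-voxel dose-gradient of the weighted penalty sum; doses are
# normalized by `rx` so weights are prescription-scale-free
penalty_eval <- function(bound, dose_vec, rx) {
  f <- 0
  grad <- numeric(length(dose_vec))
  for (b in bound) {
    o <- b$obj
    d <- dose_vec[b$rows]
    w <- o$weight / (b$n * rx^2)
    if (o$kind == "min_dose") {
      r <- pmin(d - o$dose_gy, 0)
    } else if (o$kind == "max_dose") {
      r <- pmax(d - o$dose_gy, 0)
    } else if (o$kind == "uniform") {
      r <- d - o$dose_gy
    } else if (o$kind == "dose_falloff") {
      r <- pmax(d - b$falloff_target, 0)
    } else if (o$kind == "max_dvh") {
      # penalize voxels above the level but below the dose at the allowed
      # volume: pushing them under the level restores the DVH goal
      r <- numeric(length(d))
      over <- d > o$dose_gy
      n_allow <- floor(o$volume_pct / 100 * length(d))
      if (sum(over) > n_allow) {
        dv <- sort(d, decreasing = TRUE)[n_allow + 1]
        sel <- over & d <= dv
        r[sel] <- d[sel] - o$dose_gy
      }
    }
    f <- f + w * sum(r^2)
    grad[b$rows] <- grad[b$rows] + 2 * w * r
  }
  list(value = f, grad = grad)
}
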