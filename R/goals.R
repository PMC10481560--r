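#' Clinical goal for plan evaluation
#'
#' One dose-volume criterion: a metric (`Dx`, `Vx`, `Dmax`, `Dmean`) on an
#' ROI compared against a threshold. Thresholds carry units: `%Rx` (percent
#' of the prescription, for target Dx goals), `Gy`, `%vol` (percent of the
#' ROI volume) or `cc`. The scope says which dose the goal is read from:
#' the initial plan, the boost plan, or the plan sum.
#'
#' @param roi ROI name; `"PTV"` resolves to the scope's planning target and
#'   `"FemoralHeads"` to the worst of the left and right femoral heads.
#' @param metric one of `"Dx"`, `"Vx"`, `"Dmax"`, `"Dmean"`.
#' @param parameter x of Dx (% volume) or Vx (Gy); ignored otherwise.
#' @param comparator one of `"<"`, `"<="`, `">"`, `">="`.
#' @param threshold numeric threshold.
#' @param units one of `"%Rx"`, `"Gy"`, `"%vol"`, `"cc"`.
#' @param scope one of `"initial"`, `"boost"`, `"plan_sum"`.
#' @return An object of class `clinical_goal`.
#' @export
clinical_goal <- function(roi, metric, parameter = NA_real_, comparator,
                          threshold, units, scope = "plan_sum") {
  metric <- match.arg(metric, c("Dx", "Vx", "Dmax", "Dmean"))
  comparator <- match.arg(comparator, c("<", "<=", ">", ">="))
  units <- match.arg(units, c("%Rx", "Gy", "%vol", "cc"))
  scope <- match.arg(scope, c("initial", "boost", "plan_sum"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (metric %in% c("Dx", "Vx") && !is.finite(parameter))
    stop(metric, " needs a finite parameter")
  if (metric %in% c("Dx", "Dmax", "Dmean") && units %in% c("%vol", "cc"))
    stop("dose metric '", metric, "' cannot carry volume units")
  if (metric == "Vx" && units %in% c("%Rx", "Gy"))
    stop("volume metric 'Vx' cannot carry dose units")
  structure(
    list(roi = roi, metric = metric, parameter = parameter,
         comparator = comparator, threshold = threshold, units = units,
         scope = scope),
    class = "clinical_goal"
  )
}

#' The packaged clinical-goal set
#'
#' Eleven goals: target coverage and near-maximum (D93 > 98%, D2 < 110% of
#' the prescription), small-bowel V35/V40/V45 in cc, bladder V40/V45/V50 and
#' femoral-head V40/V45/V50 in percent of organ volume. Organ-at-risk goals
#' are evaluated on the plan sum; target goals on the initial plan (and the
#' planner re-evaluates them for the boost plan at its own prescription).
#'
#' @return List of [clinical_goal()]s.
#' @export
default_goals <- function() {
  read_goals(system.file("extdata", "goals_default.json",
                         package = "arcplan"))
}

#' Read clinical goals from a JSON file
#'
#' @param path JSON file: an array of objects with fields `roi`, `metric`,
#'   `parameter`, `comparator`, `threshold`, `units`, `scope`.
#' @return List of [clinical_goal()]s.
#' @export
read_goals <- function(path) {
  if (!file.exists(path)) stop("goals file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(seq_along(raw), function(i) {
    g <- raw[[i]]
    tryCatch(
      clinical_goal(roi = g$roi, metric = g$metric,
                    parameter = g$parameter %||% NA_real_,
                    comparator = g$comparator, threshold = g$threshold,
                    units = g$units, scope = g$scope %||% "plan_sum"),
      error = function(e) stop("invalid goal #", i, " (roi '",
                               g$roi %||% "?", "'): ",
                               conditionMessage(e), call. = FALSE))
  })
}

#' Write clinical goals to JSON
#' @param goals list of [clinical_goal()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_goals <- function(goals, path) {
  jsonlite::write_json(lapply(goals, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

resolve_goal_rois <- function(roi, scope = "plan_sum") {
  if (roi == "PTV") {
    if (scope == "boost") "PTV_boost" else "PTV_initial"
  } else if (roi == "FemoralHeads") {
    c("FemoralHead_L", "FemoralHead_R")
  } else roi
}

goal_metric_value <- function(dose, mask, goal, rx) {
  dvh <- cumulative_dvh(dose, mask)
  switch(goal$metric,
    Dx = {
      v <- dose_at_volume(dvh, goal$parameter)
      if (goal$units == "%Rx") 100 * v / rx else v
    },
    Vx = {
      v <- volume_at_dose(dvh, goal$parameter)
      if (goal$units == "cc") v$cc else v$pct
    },
    Dmax = max(dose$values[mask$voxels]),
    Dmean = mean(dose$values[mask$voxels]))
}

#' Evaluate clinical goals against one or more dose distributions
#'
#' Each goal is read from the dose its scope names and compared with its
#' threshold. Volume goals are computed in both percent and cc regardless of
#' the goal's unit, so organ constraints stated in cc can be cross-read in
#' percent. A maximum-type organ-at-risk goal that fails on the full organ
#' but passes once the voxels shared with the planning target are removed is
#' reported as `"flagged"` rather than `"fail"` — exceeding such a goal
#' inside the target overlap is clinically tolerated.
#'
#' @param doses named list of `voxel_grid`s (`initial`, `boost`,
#'   `plan_sum`; only the scopes the goals use are required).
#' @param structs `structure_set`.
#' @param goals list of [clinical_goal()]s.
#' @param prescriptions_gy named numeric: prescription per scope.
#' @return Tibble (class `goal_report`): one row per evaluated goal with
#'   `achieved`, `achieved_pct`, `achieved_cc`, `status`; attribute
#'   `overall_pass`.
#' @export
evaluate_goals <- function(doses, structs, goals,
                           prescriptions_gy = c(initial = 45, boost = 5.4,
                                                plan_sum = 50.4)) {
  rows <- list()
  for (g in goals) {
    dose <- doses[[g$scope]]
    if (is.null(dose)) stop("no dose supplied for scope '", g$scope, "'")
    rx <- prescriptions_gy[[g$scope]]
    rois <- resolve_goal_rois(g$roi, g$scope)
    for (r in rois) {
      if (!(r %in% names(structs$masks))) stop("unresolvable ROI '", r, "'")
    }
    vals <- vapply(rois, function(r)
      goal_metric_value(dose, structs[[r]], g, rx), numeric(1))
    worst <- if (g$comparator %in% c("<", "<=")) max(vals) else min(vals)
    worst_roi <- rois[if (g$comparator %in% c("<", "<=")) which.max(vals)
                      else which.min(vals)]
    ok <- switch(g$comparator, "<" = worst < g$threshold,
                 "<=" = worst <= g$threshold, ">" = worst > g$threshold,
                 ">=" = worst >= g$threshold)
    status <- if (ok) "pass" else "fail"

    # overlap-tolerant flagging for maximum-type OAR goals
    if (!ok && g$comparator %in% c("<", "<=") && !(g$roi %in% c("PTV"))) {
      tgt <- if ("PTV_initial" %in% names(structs$masks))
        structs[["PTV_initial"]] else NULL
      if (!is.null(tgt)) {
        vals2 <- vapply(rois, function(r) {
          m <- structs[[r]]
          m2 <- boolean_op(m, tgt, "difference")
          if (!any(m2$voxels)) return(-Inf)
          goal_metric_value(dose, m2, g, rx)
        }, numeric(1))
        worst2 <- max(vals2)
        ok2 <- switch(g$comparator, "<" = worst2 < g$threshold,
                      "<=" = worst2 <= g$threshold)
        overlap <- any(vapply(rois, function(r)
          any(structs[[r]]$voxels & tgt$voxels), logical(1)))
        if (ok2 && overlap) status <- "flagged"
      }
    }

    pct <- cc <- NA_real_
    if (g$metric == "Vx") {
      dvh <- cumulative_dvh(dose, structs[[worst_roi]])
      v <- volume_at_dose(dvh, g$parameter)
      pct <- v$pct; cc <- v$cc
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      roi = g$roi, evaluated_roi = worst_roi, metric = g$metric,
      parameter = g$parameter, comparator = g$comparator,
      threshold = g$threshold, units = g$units, scope = g$scope,
      achieved = worst, achieved_pct = pct, achieved_cc = cc,
      status = status)
  }
  out <- do.call(rbind, rows)
  attr(out, "overall_pass") <- all(out$status != "fail")
  class(out) <- c("goal_report", class(out))
  out
}
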