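#' Configuration of the automated planning workflow
#'
#' Defaults encode the scripted workflow: two optimization passes, hotspot
#' extraction, three correction passes with an added hotspot objective, then
#' coverage-constraint escalation and a final optimization. The hotspot
#' threshold (1.05 x prescription) sits below the near-maximum goal
#' (D2 < 110%) with headroom; fall-off objectives ramp from the full
#' prescription at the target boundary to 30% at 20 mm.
#'
#' @param hotspot_threshold_fraction hotspot threshold as a fraction of the
#'   prescription; must exceed 1.
#' @param initial_opts,hotspot_opts number of warm-started optimization runs
#'   before and after hotspot extraction.
#' @param inner_iterations accepted iterations per optimization run.
#' @param escalation_factor multiplicative weight increase per escalation
#'   round of the target coverage objective.
#' @param max_escalations bound on escalation rounds.
#' @param d93_goal_pct target coverage goal: D93 as % of prescription.
#' @param falloff list with `high_fraction`, `low_fraction`, `distance_mm`.
#' @param w_uniform,w_min_dose,w_max_dose,w_body_max,w_falloff,w_hotspot
#'   penalty weights.
#' @param w_goal_dvh weight of the organ-at-risk objectives derived from
#'   Vx clinical goals.
#' @param w_goal_max weight of the absolute dose caps derived from
#'   zero-volume (VX <= 0) goals.
#' @param goal_headroom factor tightening goal-derived allowed volumes
#'   below their clinical limits, leaving room for the plan-sum
#'   contribution of the other plan.
#' @param goal_cap_headroom factor tightening the dose level of
#'   zero-volume caps, absorbing the other plan's boundary spill.
#' @param n_cp,collimator_deg arc geometry.
#' @param aperture_threshold leaf-sequencing threshold fraction.
#' @param couch list with `thickness_mm`, `density_rel`.
#' @param prescriptions_gy named vector with `initial` and `boost` dose.
#' @return An object of class `autoplan_config`.
#' @export
autoplan_config <- function(hotspot_threshold_fraction = 1.05,
                            initial_opts = 2, hotspot_opts = 3,
                            inner_iterations = 50, escalation_factor = 10,
                            max_escalations = 5, d93_goal_pct = 98,
                            falloff = list(high_fraction = 1.0,
                                           low_fraction = 0.3,
                                           distance_mm = 20),
                            w_uniform = 100, w_min_dose = 200,
                            w_max_dose = 100, w_body_max = 100,
                            w_falloff = 20, w_hotspot = 500,
                            w_goal_dvh = 60, w_goal_max = 3000,
                            goal_headroom = 0.75, goal_cap_headroom = 0.92,
                            n_cp = 72, collimator_deg = 355,
                            aperture_threshold = 0.5,
                            couch = list(thickness_mm = 50, density_rel = 0.3),
                            prescriptions_gy = c(initial = 45, boost = 5.4)) {
  if (hotspot_threshold_fraction <= 1)
    stop("hotspot_threshold_fraction must exceed 1")
  if (initial_opts < 1) stop("at least one optimization pass is required")
  stopifnot(inner_iterations >= 1, escalation_factor > 1, max_escalations >= 0)
  structure(
    list(hotspot_threshold_fraction = hotspot_threshold_fraction,
         initial_opts = initial_opts, hotspot_opts = hotspot_opts,
         inner_iterations = inner_iterations,
         escalation_factor = escalation_factor,
         max_escalations = max_escalations, d93_goal_pct = d93_goal_pct,
         falloff = falloff, w_uniform = w_uniform, w_min_dose = w_min_dose,
         w_max_dose = w_max_dose, w_body_max = w_body_max,
         w_falloff = w_falloff, w_hotspot = w_hotspot,
         w_goal_dvh = w_goal_dvh, w_goal_max = w_goal_max,
         goal_headroom = goal_headroom,
         goal_cap_headroom = goal_cap_headroom, n_cp = n_cp,
         collimator_deg = collimator_deg,
         aperture_threshold = aperture_threshold, couch = couch,
         prescriptions_gy = prescriptions_gy),
    class = "autoplan_config"
  )
}

#' Extract hotspot voxels from a dose distribution
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param prescription_gy prescription (Gy).
#' @param threshold_fraction fraction of the prescription above which a
#'   voxel counts as a hotspot; must exceed 1 (a threshold at or below the
#'   prescription would flag the whole target).
#' @param external optional body `roi_mask` restricting the search.
#' @return `roi_mask` named `z_Hotspot`.
#' @export
extract_hotspots <- function(dose, prescription_gy, threshold_fraction = 1.05,
                             external = NULL) {
  if (threshold_fraction <= 1)
    stop("threshold_fraction must exceed 1 (would flag the whole target)")
  v <- dose$values >= threshold_fraction * prescription_gy
  if (!is.null(external)) {
    stop_if_geometry_differs(dose, external)
    v <- v & external$voxels
  }
  roi_mask("z_Hotspot", v, dose$spacing, dose$origin)
}

#' One round of PTV coverage-constraint escalation
#'
#' While the target's D93 falls short of the coverage goal, the minimum-dose
#' objective on the target has its weight multiplied by the escalation
#' factor and is marked as a constraint. When a `reoptimize` callback is
#' supplied the loop re-optimizes and re-measures D93 each round (bounded by
#' `max_escalations`); without one, a single escalation round is applied.
#'
#' @param objectives list of `plan_objective`s.
#' @param d93_pct current D93 as % of prescription.
#' @param config an [autoplan_config()].
#' @param reoptimize optional function(objectives) returning the new D93
#'   (%) after re-optimization with the escalated objectives.
#' @return List with `objectives` and `rounds` used.
#' @export
escalate_ptv_constraints <- function(objectives, d93_pct, config,
                                     reoptimize = NULL) {
  rounds <- 0
  goal <- config$d93_goal_pct
  while (d93_pct < goal && rounds < config$max_escalations) {
    idx <- which(vapply(objectives, function(o)
      o$kind == "min_dose" && !startsWith(o$roi, "z_"), logical(1)))
    for (i in idx) {
      objectives[[i]]$weight <- objectives[[i]]$weight * config$escalation_factor
      objectives[[i]]$is_constraint <- TRUE
    }
    rounds <- rounds + 1
    if (is.null(reoptimize)) break
    d93_pct <- reoptimize(objectives)
  }
  list(objectives = objectives, rounds = rounds)
}

new_stage_log <- function() {
  tibble::tibble(stage = character(), plan = character(),
                 seconds = numeric(), detail = character())
}

log_stage <- function(log, stage, plan, t0, detail = "") {
  rbind(log, tibble::tibble(
    stage = stage, plan = plan,
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    detail = detail))
}

hotspot_cc <- function(dose_vec, influence, external_rows, threshold_gy) {
  sum(dose_vec[external_rows] >= threshold_gy) *
    prod(influence$spacing) / 1000
}

# optimize one plan (initial or boost) through the staged workflow;
# returns plan artifacts plus appended log rows
plan_one <- function(label, target, rx, density, structs, config, machine,
                     log, goals = list()) {
  t0 <- Sys.time()
  structs <- derive_optimization_rois(structs, target = target,
                                      anterior_mm = 30, gap_mm = 3)
  log <- log_stage(log, "roi_derivation", label, t0,
                   "z_Bladder_opt, z_SmallBowel_opt, z_AnteriorShell")

  t0 <- Sys.time()
  iso <- centroid_mm(structs[[target]])
  plan <- build_arc(iso, n_cp = config$n_cp,
                    collimator_deg = config$collimator_deg,
                    machine = machine, prescription_gy = rx)
  influence <- influence_matrix(plan, density, structs[["External"]],
                                target = structs[[target]])
  influence <- calibrate_output(influence)
  plan$machine <- influence$machine
  log <- log_stage(log, "beam_setup", label, t0,
                   sprintf("isocenter (%s) mm", paste(round(iso, 1),
                                                      collapse = ", ")))

  t0 <- Sys.time()
  objectives <- build_objectives(structs, target = target,
                                 prescription_gy = rx, goals = goals,
                                 config = config,
                                 plan_fraction = rx / sum(config$prescriptions_gy))
  bound <- bind_objectives(objectives, structs, influence, target)
  log <- log_stage(log, "objective_input", label, t0,
                   sprintf("%d objectives", length(objectives)))

  ext_rows <- seq_along(influence$vox_idx)
  tgt_rows <- which(as.logical(structs[[target]]$voxels[influence$vox_idx]))
  fit <- NULL
  for (k in seq_len(config$initial_opts)) {
    t0 <- Sys.time()
    fit <- optimize_fluence(influence, bound,
                            start_weights = fit$weights,
                            n_iter = config$inner_iterations, rx = rx)
    log <- log_stage(log, "optimization_pass", label, t0,
                     sprintf("objective %.4g", utils::tail(fit$trace, 1)))
  }

  hot_cc <- c()
  structs_cur <- structs
  if (config$hotspot_opts > 0) {
    t0 <- Sys.time()
    dose_now <- compute_dose(plan, influence, fit$weights)
    hs <- extract_hotspots(dose_now, rx, config$hotspot_threshold_fraction,
                           external = structs[["External"]])
    hot_cc <- sum(hs$voxels) * voxel_volume_cc(hs)
    if (any(hs$voxels)) {
      structs_cur <- set_add(structs, hs, derived = TRUE)
      objectives <- c(objectives, list(objective(
        "max_dose", "z_Hotspot", dose_gy = 1.02 * rx,
        weight = config$w_hotspot)))
      bound <- bind_objectives(objectives, structs_cur, influence, target)
    }
    log <- log_stage(log, "hotspot_extraction", label, t0,
                     sprintf("V%.0f%% = %.2f cc",
                             100 * config$hotspot_threshold_fraction, hot_cc))
    thr_gy <- config$hotspot_threshold_fraction * rx
    for (k in seq_len(config$hotspot_opts)) {
      t0 <- Sys.time()
      fit <- optimize_fluence(influence, bound, start_weights = fit$weights,
                              n_iter = config$inner_iterations, rx = rx)
      cc_k <- hotspot_cc(fit$dose_vec, influence, ext_rows, thr_gy)
      hot_cc <- c(hot_cc, cc_k)
      log <- log_stage(log, "hotspot_correction_pass", label, t0,
                       sprintf("V%.0f%% = %.2f cc",
                               100 * config$hotspot_threshold_fraction, cc_k))
    }
  }

  # coverage-constraint escalation, measured on the deliverable
  # (aperture-projected) dose and re-optimized each round
  t0 <- Sys.time()
  d93_now <- function(dv) {
    dvh <- dvh_from_vector(dv[tgt_rows], voxel_volume_cc(structs[[target]]))
    100 * dose_at_volume(dvh, 93) / rx
  }
  esc_env <- new.env()
  esc_env$fit <- fit
  esc_env$ap <- optimize_apertures(influence, bound, fit$weights, rx = rx,
                                   n_rounds = 3)
  esc <- escalate_ptv_constraints(objectives, d93_now(esc_env$ap$dose_vec),
    config,
    reoptimize = function(objs) {
      b2 <- bind_objectives(objs, structs_cur, influence, target)
      esc_env$fit <- optimize_fluence(influence, b2,
        start_weights = esc_env$fit$weights,
        n_iter = ceiling(config$inner_iterations / 2), rx = rx)
      esc_env$bound <- b2
      esc_env$ap <- optimize_apertures(influence, b2, esc_env$fit$weights,
                                       rx = rx, n_rounds = 3,
                                       segweight_iters = 8,
                                       init = esc_env$ap[c("il", "ir", "mu")])
      d93_now(esc_env$ap$dose_vec)
    })
  fit <- esc_env$fit
  objectives <- esc$objectives
  bound <- if (!is.null(esc_env$bound)) esc_env$bound else bound
  log <- log_stage(log, "ptv_constraint_escalation", label, t0,
                   sprintf("%d rounds, deliverable D93 = %.1f%%", esc$rounds,
                           d93_now(esc_env$ap$dose_vec)))

  # final optimization: aperture-constrained refinement of leaf edges and
  # segment weights, warm-started from the escalation state
  t0 <- Sys.time()
  ap <- optimize_apertures(influence, bound, fit$weights, rx = rx,
                           n_rounds = 8,
                           init = esc_env$ap[c("il", "ir", "mu")])
  log <- log_stage(log, "final_optimization", label, t0,
                   sprintf("aperture objective %.4g, D93 = %.1f%%",
                           ap$objective, d93_now(ap$dose_vec)))

  t0 <- Sys.time()
  sq <- sequence_leaves(plan, influence, ap$weights,
                        threshold_fraction = config$aperture_threshold,
                        renorm_mask = structs[[target]])
  plan <- sq$plan
  dose <- compute_dose(plan, influence, ap$weights)
  dose_seq <- compute_dose(plan, influence, sq$fluence)
  log <- log_stage(log, "leaf_sequencing", label, t0,
                   sprintf("total MU %.1f", total_mu(plan)))

  list(plan = plan, dose = dose, dose_sequenced = dose_seq,
       weights = ap$weights, structs = structs, hotspot_cc = hot_cc,
       escalation_rounds = esc$rounds, log = log)
}

#' Run the fully automated VMAT planning workflow
#'
#' Executes the scripted pipeline on a density grid and structure set: ROI
#' name check, density mapping, virtual couch insertion, optimization-ROI
#' derivation, isocentre placement at the target centroid, objective
#' construction with dose fall-off, two optimization passes, hotspot
#' extraction and three correction passes, coverage-constraint escalation,
#' a final optimization, and leaf sequencing — for the initial plan on
#' `PTV_initial` and the boost plan on `PTV_boost` — then evaluates the
#' clinical goals on the plans and their sum. Every stage is appended to a
#' timed log.
#'
#' @param density `voxel_grid` of relative electron density.
#' @param structs canonical `structure_set`.
#' @param goals list of [clinical_goal()]s (default: the packaged goal set).
#' @param config an [autoplan_config()].
#' @param machine a [beam_model()].
#' @return An object of class `autoplan_result`: sequenced `plan_initial` /
#'   `plan_boost`, dose grids (`dose_initial`, `dose_boost`, `dose_sum`,
#'   plus sequenced-aperture doses), `goal_report`, `hotspot_cc` per plan,
#'   and the stage `log`.
#' @export
run_autoplan <- function(density, structs, goals = default_goals(),
                         config = autoplan_config(), machine = beam_model()) {
  log <- new_stage_log()
  t0 <- Sys.time()
  chk <- check_roi_names(structs)
  if (length(chk$missing))
    stop("missing canonical ROI(s): ", paste(chk$missing, collapse = ", "))
  log <- log_stage(log, "roi_name_check", "global", t0,
                   if (chk$ok) "ok" else "extras tolerated")

  t0 <- Sys.time()
  # CT-number conversion collapses to the identity on relative electron
  # density; logged to keep the workflow record complete
  log <- log_stage(log, "density_mapping", "global", t0,
                   "relative electron density (water = 1)")

  t0 <- Sys.time()
  density <- insert_virtual_couch(density, structs[["External"]],
                                  thickness_mm = config$couch$thickness_mm,
                                  density_rel = config$couch$density_rel)
  log <- log_stage(log, "couch_insertion", "global", t0,
                   sprintf("%g mm slab, density %g",
                           config$couch$thickness_mm,
                           config$couch$density_rel))

  rx <- config$prescriptions_gy
  res_i <- plan_one("initial", "PTV_initial", rx[["initial"]], density,
                    structs, config, machine, log, goals = goals)
  log <- res_i$log
  res_b <- plan_one("boost", "PTV_boost", rx[["boost"]], density,
                    structs, config, machine, log, goals = goals)
  log <- res_b$log

  dose_sum <- plan_sum(res_i$dose, res_b$dose)
  t0 <- Sys.time()
  # target goals apply to both plans at their own prescriptions
  for (g in goals) {
    if (g$roi == "PTV" && g$scope == "initial") {
      g$scope <- "boost"
      goals <- c(goals, list(g))
    }
  }
  report <- evaluate_goals(
    doses = list(initial = res_i$dose, boost = res_b$dose,
                 plan_sum = dose_sum),
    structs = structs, goals = goals,
    prescriptions_gy = c(initial = rx[["initial"]], boost = rx[["boost"]],
                         plan_sum = sum(rx)))
  log <- log_stage(log, "goal_evaluation", "global", t0,
                   sprintf("%d/%d goals passed",
                           sum(report$status == "pass"), nrow(report)))

  structure(
    list(plan_initial = res_i$plan, plan_boost = res_b$plan,
         dose_initial = res_i$dose, dose_boost = res_b$dose,
         dose_sum = dose_sum,
         dose_initial_sequenced = res_i$dose_sequenced,
         dose_boost_sequenced = res_b$dose_sequenced,
         weights_initial = res_i$weights, weights_boost = res_b$weights,
         hotspot_cc = list(initial = res_i$hotspot_cc,
                           boost = res_b$hotspot_cc),
         escalation_rounds = c(initial = res_i$escalation_rounds,
                               boost = res_b$escalation_rounds),
         goal_report = report, log = log, config = config),
    class = "autoplan_result"
  )
}

#' @export
print.autoplan_result <- function(x, ...) {
  cat("<autoplan_result>\n")
  cat(sprintf("  stages logged: %d, total %.1f s\n", nrow(x$log),
              sum(x$log$seconds)))
  cat(sprintf("  goals passed: %d/%d (%d flagged)\n",
              sum(x$goal_report$status == "pass"), nrow(x$goal_report),
              sum(x$goal_report$status == "flagged")))
  invisible(x)
}
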