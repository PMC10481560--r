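#' Projected-gradient fluence optimization
#'
#' Minimizes the weighted sum of one-sided quadratic penalties over
#' non-negative fluence weights by projected gradient descent with
#' backtracking line search. Accepted iterates never increase the objective;
#' when no decrease can be found above the step-size floor the solver stops
#' at the incumbent (convergence). Warm-startable via `start_weights`.
#'
#' @param influence a `dose_influence`.
#' @param bound bound objectives from `bind_objectives()` (or a raw
#'   objective list together with `structs` and `target`).
#' @param start_weights starting fluence (array or vector); zeros by default.
#' @param n_iter maximum accepted iterations.
#' @param rx prescription (Gy) used to normalize penalties.
#' @param structs,target needed only when `bound` is a raw objective list.
#' @return List with `weights`, `dose_vec` (scoring-vector dose), `trace`
#'   (objective per accepted iterate, non-increasing), `converged`.
#' @export
optimize_fluence <- function(influence, bound, start_weights = NULL,
                             n_iter = 50, rx = 45, structs = NULL,
                             target = NULL) {
  if (length(bound) && inherits(bound[[1]], "plan_objective")) {
    if (is.null(structs)) stop("raw objectives need `structs` and `target`")
    bound <- bind_objectives(bound, structs, influence, target)
  }
  if (length(bound) == 0) stop("objective list is empty")
  nb <- n_beamlets(influence)
  w <- if (is.null(start_weights)) array(0, nb) else array(start_weights, nb)
  if (any(w < 0)) stop("start weights must be non-negative")

  d <- forward_dose_vector(influence, w)
  pe <- penalty_eval(bound, d, rx)
  f <- pe$value
  trace <- f
  if (!is.finite(f)) stop("non-finite objective at start")

  # initial step from a one-shot curvature probe along the gradient
  g <- backproject_gradient(influence, pe$grad)
  gn2 <- sum(g^2)
  step <- if (gn2 > 0) {
    dg <- forward_dose_vector(influence, g)
    denom <- 2 * penalty_curvature(bound, dg, rx)
    if (denom > 0) gn2 / denom else 1
  } else 1

  it <- 0
  while (it < n_iter) {
    if (gn2 <= 1e-30) break
    accepted <- FALSE
    s <- step
    for (bt in 1:30) {
      w_try <- pmax(w - s * g, 0)
      d_try <- forward_dose_vector(influence, w_try)
      pe_try <- penalty_eval(bound, d_try, rx)
      if (!is.finite(pe_try$value))
        stop("optimizer divergence: non-finite objective (step ", s, ")")
      if (pe_try$value < f) {
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) break  # step-size floor without decrease: converged
    w <- w_try
    f <- pe_try$value
    trace <- c(trace, f)
    g <- backproject_gradient(influence, pe_try$grad)
    gn2 <- sum(g^2)
    step <- s * 2
    it <- it + 1
    if (length(trace) > 2 &&
        (trace[length(trace) - 1] - f) < 1e-4 * max(f, 1e-12)) break
  }
  list(weights = w, dose_vec = forward_dose_vector(influence, w),
       trace = trace, converged = TRUE)
}

# quadratic curvature of the penalty along a dose direction (upper bound:
# treats every one-sided term as active)
penalty_curvature <- function(bound, ddir, rx) {
  acc <- 0
  for (b in bound) {
    w <- b$obj$weight / (b$n * rx^2)
    acc <- acc + w * sum(ddir[b$rows]^2)
  }
  acc
}
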