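#' Aperture-constrained (direct-aperture) plan optimization
#'
#' Projects an optimized fluence onto the deliverable single-aperture-per-
#' control-point parameterization and then optimizes the machine parameters
#' directly: alternating segment-weight optimization (projected gradient on
#' the per-control-point MU) and greedy leaf-edge refinement (single-bin
#' leaf moves accepted on their exact objective change, evaluated
#' incrementally on the voxels inside the moved bin's kernel support).
#' This mirrors the conversion-and-continue step of clinical optimizers:
#' the final plan dose is the dose of the deliverable apertures, so leaf
#' sequencing afterwards is lossless.
#'
#' @param influence a `dose_influence`.
#' @param bound bound objectives (from `bind_objectives()`); `max_dvh`
#'   objectives are honoured by the segment-weight steps but ignored by the
#'   leaf-move deltas.
#' @param fluence the optimized free fluence to project (array).
#' @param rx prescription (Gy).
#' @param init_threshold row-threshold fraction for the initial apertures
#'   (span from first to last bin above it).
#' @param n_rounds refinement rounds (one leaf sweep plus one segment-weight
#'   optimization each).
#' @param segweight_iters projected-gradient iterations per segment-weight
#'   optimization.
#' @param max_steps maximum bins a leaf edge may travel per sweep visit.
#' @param init optional warm start: a list with `il`, `ir`, `mu` from a
#'   previous aperture optimization, bypassing the threshold projection.
#' @return List with `weights` (deliverable fluence `A x mu`), `dose_vec`,
#'   `il`/`ir` (1-based open-interval bins per leaf pair and control point),
#'   `mu`, `objective`.
#' @export
optimize_apertures <- function(influence, bound, fluence, rx = 45,
                               init_threshold = 0.2, n_rounds = 8,
                               segweight_iters = 10, max_steps = 4,
                               init = NULL) {
  nb <- n_beamlets(influence)
  nu <- nb[["nu"]]; nv <- nb[["nv"]]; ncp <- nb[["ncp"]]
  w <- array(fluence, nb)
  gmax <- max(w)
  if (gmax <= 0) stop("all-zero fluence; nothing to project onto apertures")

  if (!is.null(init)) {
    il <- init$il; ir <- init$ir; mu <- init$mu
  } else {
    # initial apertures: first-to-last bin above the row threshold
    il <- matrix(0L, nv, ncp); ir <- matrix(0L, nv, ncp)
    mu <- numeric(ncp)
    for (cc in seq_len(ncp)) {
      vals <- c()
      for (j in seq_len(nv)) {
        f <- w[, j, cc]
        fmax <- max(f)
        if (fmax <= 1e-9 * gmax) next
        idx <- which(f >= init_threshold * fmax)
        il[j, cc] <- min(idx); ir[j, cc] <- max(idx)
        vals <- c(vals, f[min(idx):max(idx)])
      }
      mu[cc] <- if (length(vals)) mean(vals) else 0
    }
  }

  refine <- prepare_refine_data(influence, bound, rx)
  st <- segment_weight_opt(influence, bound, il, ir, mu, rx,
                           n_iter = segweight_iters)
  mu <- st$mu
  f <- st$value
  for (round in seq_len(n_rounds)) {
    sw <- cpp_refine_sweep(il, ir, mu, st$dose_vec, influence$T,
                           influence$U, influence$V, refine$ordU,
                           influence$u_centers, influence$v_centers,
                           influence$machine$beamlet_width_mm,
                           influence$machine$penumbra_sigma_mm,
                           influence$machine$output_gy_per_mu,
                           refine$memb_mask, refine$obj_kind, refine$obj_w,
                           refine$obj_level, refine$fall_col, refine$fall_t,
                           as.integer(max_steps))
    il <- sw$il; ir <- sw$ir
    st <- segment_weight_opt(influence, bound, il, ir, mu, rx,
                             n_iter = segweight_iters)
    mu <- st$mu
    improved <- f - st$value
    f <- st$value
    if (sw$n_accepted == 0 && improved <= 1e-8 * max(f, 1e-12)) break
  }
  list(weights = aperture_fluence(il, ir, mu, nu),
       dose_vec = st$dose_vec, il = il, ir = ir, mu = mu, objective = f)
}

aperture_fluence <- function(il, ir, mu, nu) {
  nv <- nrow(il); ncp <- ncol(il)
  w <- array(0, c(nu, nv, ncp))
  for (cc in seq_len(ncp)) {
    if (mu[cc] <= 0) next
    for (j in seq_len(nv)) {
      if (il[j, cc] > 0) w[il[j, cc]:ir[j, cc], j, cc] <- mu[cc]
    }
  }
  w
}

segment_weight_opt <- function(influence, bound, il, ir, mu, rx,
                               n_iter = 15) {
  nu <- length(influence$u_centers)
  ncp <- length(mu)
  shapes <- aperture_fluence(il, ir, rep(1, ncp), nu)
  mkw <- function(mu) sweep(shapes, 3, mu, "*")
  d <- forward_dose_vector(influence, mkw(mu))
  pe <- penalty_eval(bound, d, rx)
  f <- pe$value
  step <- 1
  for (it in seq_len(n_iter)) {
    gfl <- backproject_gradient(influence, pe$grad)
    gmu <- vapply(seq_len(ncp), function(cc) sum(gfl[, , cc] * shapes[, , cc]),
                  numeric(1))
    accepted <- FALSE
    for (bt in 1:25) {
      mut <- pmax(mu - step * gmu, 0)
      dt <- forward_dose_vector(influence, mkw(mut))
      pet <- penalty_eval(bound, dt, rx)
      if (pet$value < f) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    mu <- mut; f <- pet$value; pe <- pet; d <- dt
    step <- step * 2
  }
  list(mu = mu, dose_vec = d, value = f)
}

# pack objective data for the C++ leaf-refinement kernel: per-voxel
# membership bitmask, per-objective kind/weight/level, per-voxel fall-off
# dose targets
prepare_refine_data <- function(influence, bound, rx) {
  n <- length(influence$vox_idx)
  kinds <- c(min_dose = 0L, max_dose = 1L, uniform = 2L, dose_falloff = 3L)
  keep <- vapply(bound, function(b) b$obj$kind %in% names(kinds), logical(1))
  bound <- bound[keep]
  if (length(bound) > 31) stop("too many objectives for the refinement mask")
  memb <- integer(n)
  obj_kind <- integer(0); obj_w <- numeric(0); obj_level <- numeric(0)
  fall_col <- integer(0)
  fall_t <- NULL
  for (k in seq_along(bound)) {
    b <- bound[[k]]
    memb[b$rows] <- bitwOr(memb[b$rows], bitwShiftL(1L, k - 1L))
    obj_kind <- c(obj_kind, kinds[[b$obj$kind]])
    obj_w <- c(obj_w, b$obj$weight / (b$n * rx^2))
    obj_level <- c(obj_level, b$obj$dose_gy %||% 0)
    if (b$obj$kind == "dose_falloff") {
      col <- numeric(n)
      col[b$rows] <- b$falloff_target
      fall_t <- cbind(fall_t, col)
      fall_col <- c(fall_col, ncol(fall_t) - 1L)
    } else {
      fall_col <- c(fall_col, 0L)
    }
  }
  if (is.null(fall_t)) fall_t <- matrix(0, n, 1)
  ordU <- matrix(0L, n, influence$n_cp)
  for (cc in seq_len(influence$n_cp))
    ordU[, cc] <- order(influence$U[, cc]) - 1L
  list(memb_mask = memb, obj_kind = obj_kind, obj_w = obj_w,
       obj_level = obj_level, fall_col = fall_col, fall_t = fall_t,
       ordU = ordU)
}
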