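# shared fixtures, memoized across test files (helpers are sourced once per
# test run)
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# coarse (5 mm) phantom: same anatomy, ~8x fewer voxels; fast unit tests
coarse_spec <- function(...) phantom_spec(spacing_mm = c(5, 5, 5), ...)

coarse_phantom <- function() memo("coarse", generate_phantom(coarse_spec()))

# the packaged study phantom at full resolution
default_phantom <- function() memo("default", generate_phantom(phantom_spec()))

# uniform water cube grid: n^3 voxels at `sp` mm, density 1
water_grid <- function(n = 20, sp = 5) {
  voxel_grid(array(1, c(n, n, n)), rep(sp, 3),
             origin = rep(-(n - 1) * sp / 2, 3))
}

full_mask <- function(grid, name = "External") {
  roi_mask(name, array(TRUE, dim(grid$values)), grid$spacing, grid$origin)
}

sphere_mask <- function(grid, center, radius_mm, name = "roi") {
  pts <- voxel_centers_mm(grid)
  d2 <- rowSums(sweep(pts, 2, center)^2)
  roi_mask(name, array(d2 <= radius_mm^2, dim(grid$values)),
           grid$spacing, grid$origin)
}

# smooth positive 3D field for gamma tests
smooth_field <- function(n, seed) {
  set.seed(seed)
  ax <- seq(-1, 1, length.out = n[1])
  ay <- seq(-1, 1, length.out = n[2])
  az <- seq(-1, 1, length.out = n[3])
  f <- outer(outer(exp(-ax^2 / 0.4), exp(-ay^2 / 0.5)), exp(-az^2 / 0.6))
  array(40 * f + stats::rnorm(prod(n), 0, 0.1), n)
}

# brute-force octant-anisotropic expansion oracle: voxel is set iff some
# source voxel lies within the direction-dependent scaled distance
expand_oracle <- function(mask, m) {
  d <- dim(mask$voxels)
  src <- which(mask$voxels, arr.ind = TRUE)
  src_mm <- voxel_centers_mm(mask, src)
  all_mm <- voxel_centers_mm(mask)
  neg <- c(m$right_mm, m$anterior_mm, m$caudal_mm)
  pos <- c(m$left_mm, m$posterior_mm, m$cranial_mm)
  out <- logical(nrow(all_mm))
  for (k in seq_len(nrow(src_mm))) {
    delta <- sweep(all_mm, 2, src_mm[k, ])
    s <- 0
    for (a in 1:3) {
      mm <- ifelse(delta[, a] < 0, neg[a], pos[a])
      term <- ifelse(delta[, a] == 0, 0,
                     ifelse(mm > 0, (delta[, a] / mm)^2, Inf))
      s <- s + term
    }
    out <- out | (s <= 1)
  }
  roi_mask(mask$name, array(out, d), mask$spacing, mask$origin)
}

# exhaustive gamma oracle over the same candidate displacement set as the
# implementation, with an independent R trilinear interpolator
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria()) {
  rmax <- max(reference$values)
  dd <- criteria$dose_diff_pct / 100 * rmax
  cutoff <- criteria$low_dose_cutoff_fraction * rmax
  dta <- criteria$dta_mm
  r <- criteria$search_radius_dta * dta
  st <- criteria$step_dta * dta
  ax <- seq(-r, r, by = st)
  offs <- as.matrix(expand.grid(ax, ax, ax))
  offs <- offs[rowSums(offs^2) <= r^2 + 1e-9, , drop = FALSE]
  d <- dim(reference$values)
  interp <- function(g) {  # trilinear at fractional voxel coords
    if (any(g < 0) || any(g > d - 1)) return(NA_real_)
    j <- pmin(floor(g), d - 2); j <- pmax(j, 0)
    f <- g - j
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
           (if (cc) f[3] else 1 - f[3])
      acc <- acc + w * evaluated$values[j[1] + a + 1, j[2] + b + 1,
                                       j[3] + cc + 1]
    }
    acc
  }
  n_pass <- 0L; n_tot <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    rd <- reference$values[x, y, z]
    if (rd < cutoff) next
    n_tot <- n_tot + 1L
    best <- Inf
    for (k in seq_len(nrow(offs))) {
      g <- c(x - 1, y - 1, z - 1) + offs[k, ] / reference$spacing
      e <- interp(g)
      if (is.na(e)) next
      g2 <- ((e - rd) / dd)^2 + sum(offs[k, ]^2) / dta^2
      if (g2 < best) best <- g2
    }
    if (sqrt(best) <= 1) n_pass <- n_pass + 1L
  }
  100 * n_pass / n_tot
}

# exact Wilcoxon oracle: enumerate all 2^n sign assignments
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_lo <- mean(ws <= w_obs + 1e-9)
  p_hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
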