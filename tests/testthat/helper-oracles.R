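# Independent oracles used across the suite.  These deliberately avoid the
# package's traversal/geometry code paths: the sampling oracle walks the
# rasterized volume in tiny steps, and the root-finding oracle solves the
# sphere crossing numerically.

# Dense brute-force gap measurement along a ray through a label volume:
# sample the labels every `min(spacing)/10` mm and locate the
# condyle-exit / fossa-entry transitions.  Returns NA when either crossing
# is missing.
brute_force_gap <- function(volume, origin, direction, t_max = 50) {
  step <- min(volume$spacing) / 10
  ts <- seq(0, t_max, by = step)
  d <- dim(volume$voxels)
  labs <- vapply(ts, function(t) {
    idx <- round((origin + t * direction - volume$origin) / volume$spacing)
    if (any(idx < 0) || any(idx >= d)) return(NA_integer_)
    volume$voxels[idx[1] + 1, idx[2] + 1, idx[3] + 1]
  }, integer(1))
  in_grid <- !is.na(labs)
  labs <- labs[in_grid]; ts <- ts[in_grid]
  if (!length(labs) || labs[1] != 1L) return(NA_real_)
  exit_i <- which(labs != 1L)[1]
  if (is.na(exit_i)) return(NA_real_)
  fossa_i <- which(labs == 2L & seq_along(labs) >= exit_i)[1]
  if (is.na(fossa_i)) return(NA_real_)
  ts[fossa_i] - ts[exit_i]
}

# Numerical root-finding oracle for the fossa inner-sphere crossing:
# solves |d + t u| = R_inner by bisection, then applies the same cap test
# as the closed form.
numeric_gap <- function(spec, direction) {
  u <- direction / sqrt(sum(direction^2))
  d <- spec$displacement_mm
  Ri <- spec$fossa_inner_radius_mm
  fdist <- function(t) sqrt(sum((d + t * u)^2)) - Ri
  if (fdist(0) >= 0) return(NA_real_)       # origin outside the inner sphere
  t_hi <- 2 * (Ri + sqrt(sum(d^2)))
  root <- uniroot(fdist, c(0, t_hi), tol = 1e-12)$root
  q <- d + root * u
  polar <- acos(min(1, max(-1, q[3] / sqrt(sum(q^2)))))
  if (polar > spec$fossa_coverage_deg * pi / 180) return(NA_real_)
  root - spec$condyle_radius_mm
}

# Analytic gap evaluated only where the fossa entry sits at least
# `margin_deg` inside the cap; rays nearer the rim are boundary cases whose
# voxel-limit gap is discontinuous and are excluded from pointwise
# rasterization comparisons.
analytic_gap_interior <- function(spec, direction, margin_deg) {
  g <- analytic_gap(spec, direction)
  if (is.na(g)) return(NA_real_)
  q <- spec$displacement_mm + (g + spec$condyle_radius_mm) * direction
  polar <- acos(min(1, max(-1, q[3] / sqrt(sum(q^2))))) * 180 / pi
  if (polar > spec$fossa_coverage_deg - margin_deg) return(NA_real_)
  g
}

# cap-edge angular jitter of a rasterization: half a voxel diagonal seen
# from the fossa center
cap_margin_deg <- function(spec) {
  asin(sqrt(3) / 2 * spec$spacing_mm / spec$fossa_inner_radius_mm) * 180 / pi
}

# small fast direction set shared by several tests
test_directions <- function(n = 50) build_direction_set(n)
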