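## Analytic sphere phantoms: a condyle ball seated under a spherical-cap
## fossa shell, with closed-form ray gaps.  These stand in for clinical
## condyle/fossa segmentations (which are not publicly available) and are
## labelled synthetic throughout; they trade anatomical realism for exact
## geometric ground truth.

#' Specify a condyle/fossa sphere phantom
#'
#' The fossa is a spherical shell cap centered at the world origin, opening
#' inferiorly (the shell occupies polar angles up to `fossa_coverage_deg`
#' from the superior axis); the condyle is a ball whose center sits at
#' `displacement_mm` relative to the fossa center.  Zero displacement is a
#' perfectly seated joint with a uniform gap of
#' `fossa_inner_radius_mm - condyle_radius_mm`.
#'
#' @param condyle_radius_mm ball radius, default 5.
#' @param fossa_inner_radius_mm shell inner radius, default 7.
#' @param fossa_thickness_mm shell thickness, default 2.
#' @param fossa_coverage_deg polar half-angle of the shell cap, default 80.
#' @param displacement_mm length-3 offset of the condyle center from the
#'   fossa center (mm); must not make the solids overlap.
#' @param spacing_mm isotropic voxel size for rasterization, default 0.4.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(condyle_radius_mm = 5,
                         fossa_inner_radius_mm = 7,
                         fossa_thickness_mm = 2,
                         fossa_coverage_deg = 80,
                         displacement_mm = c(0, 0, 0),
                         spacing_mm = 0.4) {
  stopifnot(condyle_radius_mm > 0, fossa_inner_radius_mm > condyle_radius_mm,
            fossa_thickness_mm > 0, fossa_coverage_deg > 0,
            fossa_coverage_deg <= 90, spacing_mm > 0,
            length(displacement_mm) == 3L)
  spec <- structure(list(condyle_radius_mm = condyle_radius_mm,
                         fossa_inner_radius_mm = fossa_inner_radius_mm,
                         fossa_thickness_mm = fossa_thickness_mm,
                         fossa_coverage_deg = fossa_coverage_deg,
                         displacement_mm = as.numeric(displacement_mm),
                         spacing_mm = spacing_mm),
                    class = "phantom_spec")
  if (phantom_overlaps(spec))
    stop("condyle and fossa solids overlap at displacement (",
         paste(signif(displacement_mm, 3), collapse = ", "), ") mm")
  spec
}

# TRUE when the condyle ball intersects the fossa shell: nearest shell
# point to the condyle center, constrained to the cap, lies within the
# condyle radius.
phantom_overlaps <- function(spec) {
  d <- spec$displacement_mm
  dn <- sqrt(sum(d^2))
  Ri <- spec$fossa_inner_radius_mm
  rc <- spec$condyle_radius_mm
  cov <- spec$fossa_coverage_deg * pi / 180
  if (dn >= Ri) return(TRUE)        # condyle center outside the inner sphere
  polar <- if (dn == 0) 0 else acos(min(1, max(-1, d[3] / dn)))
  if (polar <= cov || dn == 0) {
    # nearest inner-sphere point along d is inside the cap
    (Ri - dn) < rc
  } else {
    # nearest cap point is on the rim circle
    d_xy <- sqrt(d[1]^2 + d[2]^2)
    min_d2 <- dn^2 + Ri^2 - 2 * Ri * (d_xy * sin(cov) + d[3] * cos(cov))
    sqrt(max(0, min_d2)) < rc
  }
}

#' Closed-form condyle-to-fossa gap along a ray direction
#'
#' From the condyle center along the unit direction `u`, the condyle
#' surface is crossed at `t = condyle_radius`; the fossa inner sphere is
#' crossed where `|d + t u| = R_inner` (`d` = displacement of the condyle
#' center from the fossa center), the positive root of a quadratic.  The
#' gap is the difference, or `NA` (`no_fossa`) when the crossing point
#' falls outside the shell's polar cap.
#'
#' @param spec a [phantom_spec].
#' @param direction unit 3-vector (superior component typically >= 0).
#' @return Gap in mm, or `NA_real_` when the ray misses the fossa cap.
#' @export
analytic_gap <- function(spec, direction) {
  u <- as.numeric(direction)
  u <- u / sqrt(sum(u^2))
  d <- spec$displacement_mm
  Ri <- spec$fossa_inner_radius_mm
  du <- sum(d * u)
  disc <- du^2 - sum(d^2) + Ri^2
  if (disc < 0) return(NA_real_)
  t_fossa <- -du + sqrt(disc)
  q <- d + t_fossa * u              # fossa entry relative to the fossa center
  polar <- acos(min(1, max(-1, q[3] / sqrt(sum(q^2)))))
  if (polar > spec$fossa_coverage_deg * pi / 180) return(NA_real_)
  t_fossa - spec$condyle_radius_mm
}

#' Rasterize a phantom into a label volume
#'
#' A voxel is labeled condyle iff its center lies inside the condyle ball
#' and fossa iff its center lies inside the shell cap (voxel-center point
#' membership, no partial volumes); deterministic.
#'
#' @param spec a [phantom_spec].
#' @param margin_mm padding around the solids, default 1.
#' @return A [label_volume] with the fossa center at the world origin.
#' @export
rasterize_phantom <- function(spec, margin_mm = 1) {
  rc <- spec$condyle_radius_mm
  Ri <- spec$fossa_inner_radius_mm
  Ro <- Ri + spec$fossa_thickness_mm
  d <- spec$displacement_mm
  sp <- spec$spacing_mm
  lo <- pmin(-Ro, d - rc) - margin_mm
  hi <- pmax(Ro, d + rc) + margin_mm
  nv <- ceiling((hi - lo) / sp) + 1L
  xs <- lo[1] + (seq_len(nv[1]) - 1) * sp
  ys <- lo[2] + (seq_len(nv[2]) - 1) * sp
  zs <- lo[3] + (seq_len(nv[3]) - 1) * sp
  # squared distances to the fossa center (origin) and the condyle center
  fx2 <- xs^2; fy2 <- ys^2; fz2 <- zs^2
  cx2 <- (xs - d[1])^2; cy2 <- (ys - d[2])^2; cz2 <- (zs - d[3])^2
  r2_fossa <- outer(outer(fx2, fy2, `+`), fz2, `+`)
  r2_cond <- outer(outer(cx2, cy2, `+`), cz2, `+`)
  condyle <- r2_cond <= rc^2
  # polar angle about the superior (+z) axis at the fossa center
  zg <- aperm(array(zs, dim = c(nv[3], nv[1], nv[2])), c(2, 3, 1))
  rg <- sqrt(r2_fossa)
  cos_polar <- ifelse(rg > 0, zg / rg, 1)
  fossa <- r2_fossa >= Ri^2 & r2_fossa <= Ro^2 &
    cos_polar >= cos(spec$fossa_coverage_deg * pi / 180)
  if (any(condyle & fossa))
    stop("rasterized condyle and fossa overlap; invalid phantom spec")
  vox <- array(0L, dim = nv)
  vox[condyle] <- LABEL_CONDYLE
  vox[fossa] <- LABEL_FOSSA
  label_volume(vox, spacing = rep(sp, 3), origin = lo, superior_axis = 3L)
}

#' Generate a labeled synthetic phantom dataset
#'
#' Draws per-joint displacement magnitudes from two disjoint ranges — small
#' displacements for correctly seated joints, large for incorrectly seated
#' ones (the clinical notion that an off-center condyle is incorrectly
#' seated) — with random directions and a ±10% jitter on both radii.
#' Incorrect-class displacement directions are confined to a cone of
#' `incorrect_cone_deg` about the inferior axis (the condyle sagging out
#' of the fossa); wider cones can drive the displaced condyle into the
#' fossa cap rim at the jitter extremes.
#'
#' @param n_correct,n_incorrect class counts (defaults 85 and 35).
#' @param correct_disp_mm,incorrect_disp_mm displacement-magnitude ranges
#'   (mm) for the two classes; must be disjoint (defaults 0–0.5, 1.5–3.5).
#' @param seed RNG seed; the dataset is reproducible from it.
#' @param spacing_mm voxel size passed to the phantom specs, default 0.4.
#' @param radius_jitter relative jitter on both radii, default 0.1.
#' @param incorrect_cone_deg half-angle of the inferior displacement cone
#'   for the incorrect class, default 30.
#' @return A `synthetic_dataset`: list with `records` (each holding
#'   `joint_id`, `side`, `spec`, `label`, `provenance = "synthetic"`),
#'   `n_correct`, `n_incorrect`, `seed`.
#' @export
make_dataset <- function(n_correct = 85L, n_incorrect = 35L,
                         correct_disp_mm = c(0, 0.5),
                         incorrect_disp_mm = c(1.5, 3.5),
                         seed = 0L, spacing_mm = 0.4,
                         radius_jitter = 0.1,
                         incorrect_cone_deg = 30) {
  stopifnot(n_correct >= 0, n_incorrect >= 0)
  if (max(correct_disp_mm) > min(incorrect_disp_mm))
    stop("displacement ranges overlap: ground-truth labels would be ambiguous")
  n <- n_correct + n_incorrect
  labels <- c(rep("correct", n_correct), rep("incorrect", n_incorrect))
  records <- with_seed(derive_seed(seed, "phantoms"), {
    lapply(seq_len(n), function(i) {
      lab <- labels[i]
      mag <- if (lab == "correct")
        runif(1, correct_disp_mm[1], correct_disp_mm[2])
      else runif(1, incorrect_disp_mm[1], incorrect_disp_mm[2])
      if (lab == "correct") {
        # uniform direction on the full sphere
        v <- rnorm(3)
        u <- v / sqrt(sum(v^2))
      } else {
        # uniform within a cone about the inferior (-z) axis
        cos_max <- cos(incorrect_cone_deg * pi / 180)
        cz <- runif(1, cos_max, 1)
        phi <- runif(1, 0, 2 * pi)
        s <- sqrt(1 - cz^2)
        u <- c(s * cos(phi), s * sin(phi), -cz)
      }
      jit <- runif(2, 1 - radius_jitter, 1 + radius_jitter)
      sp <- phantom_spec(condyle_radius_mm = 5 * jit[1],
                         fossa_inner_radius_mm = 7 * jit[2],
                         fossa_thickness_mm = 2,
                         displacement_mm = mag * u,
                         spacing_mm = spacing_mm)
      list(joint_id = sprintf("synth_%03d", i),
           side = if (i %% 2 == 0) "left" else "right",
           spec = sp, label = lab, provenance = "synthetic")
    })
  })
  structure(list(records = records, n_correct = as.integer(n_correct),
                 n_incorrect = as.integer(n_incorrect),
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d joints (%d correct / %d incorrect), seed %d\n",
              length(x$records), x$n_correct, x$n_incorrect, x$seed))
  invisible(x)
}

#' Rasterize every phantom of a dataset
#'
#' @param dataset a `synthetic_dataset`.
#' @return Named list of [label_volume]s keyed by joint id.
#' @export
dataset_volumes <- function(dataset) {
  vols <- lapply(dataset$records, function(r) rasterize_phantom(r$spec))
  names(vols) <- vapply(dataset$records, `[[`, character(1), "joint_id")
  vols
}

#' Ground-truth labels of a dataset as a named vector
#' @param dataset a `synthetic_dataset`.
#' @export
dataset_labels <- function(dataset) {
  labs <- vapply(dataset$records, `[[`, character(1), "label")
  names(labs) <- vapply(dataset$records, `[[`, character(1), "joint_id")
  labs
}
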