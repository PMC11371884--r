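## Training-time augmentation: contralateral mirroring and per-epoch random
## rigid perturbation of the ray origin/orientation.

#' Augmentation configuration
#'
#' Bounds for the per-epoch random rigid perturbation of the hemisphere
#' (translation within +/- `max_translation_mm` in every axis, rotation
#' within +/- `max_rotation_deg` about every axis, both uniform) and the
#' mirroring switch.  The defaults (+/- 2 mm, +/- 10 degrees) emulate
#' residual uncertainty in the condyle centroid and slight head tilt
#' during scanning.
#'
#' @param max_translation_mm nonnegative scalar, default 2.
#' @param max_rotation_deg nonnegative scalar, default 10.
#' @param mirror add mirrored copies of training joints (default `TRUE`).
#' @param rng_seed master seed for the perturbation streams.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(max_translation_mm = 2,
                                max_rotation_deg = 10,
                                mirror = TRUE,
                                rng_seed = 0L) {
  stopifnot(max_translation_mm >= 0, max_rotation_deg >= 0)
  structure(list(max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 mirror = isTRUE(mirror),
                 rng_seed = as.integer(rng_seed)),
            class = "augmentation_config")
}

#' Mirror a condyle/fossa volume to simulate the contralateral joint
#'
#' Flips the voxel grid along the left-right axis; with the origin kept
#' fixed this realizes the reflection of the world geometry through the
#' volume's own mid-sagittal plane.  Labels are preserved and mirroring is
#' an involution (mirroring twice restores the original exactly).
#'
#' @param volume a [label_volume].
#' @param lr_axis the left-right array axis (default 1).
#' @return The mirrored [label_volume].
#' @export
mirror_pair <- function(volume, lr_axis = 1L) {
  stopifnot(inherits(volume, "label_volume"))
  lr_axis <- as.integer(lr_axis)
  if (!lr_axis %in% 1:3) stop("'lr_axis' must be 1, 2 or 3")
  if (lr_axis == volume$superior_axis)
    stop("left-right axis cannot equal the superior axis")
  d <- dim(volume$voxels)
  rev_idx <- function(a) if (a == lr_axis) rev(seq_len(d[a])) else seq_len(d[a])
  out <- volume
  out$voxels <- volume$voxels[rev_idx(1), rev_idx(2), rev_idx(3), drop = FALSE]
  out
}

#' Mirror a direction set about the mid-sagittal plane
#'
#' Negates the left-right component of every direction; used to check the
#' mirror-symmetry invariant (mirrored volume + mirrored directions must
#' reproduce the original feature vector).
#'
#' @param ds a `direction_set`.
#' @param lr_axis the left-right axis (default 1).
#' @export
mirror_direction_set <- function(ds, lr_axis = 1L) {
  stopifnot(inherits(ds, "direction_set"))
  out <- ds
  out$directions[, lr_axis] <- -out$directions[, lr_axis]
  out
}

#' Sample the per-epoch rigid perturbation for one joint
#'
#' Each translation component is drawn from
#' Uniform(-max_translation_mm, +max_translation_mm) and each Euler angle
#' from Uniform(-max_rotation_deg, +max_rotation_deg); the stream is seeded
#' deterministically by (rng_seed, epoch, joint_id), so a given joint sees
#' a fresh perturbation every epoch yet the whole schedule replays exactly
#' under the same master seed.
#'
#' @param cfg an [augmentation_config].
#' @param epoch integer epoch number.
#' @param joint_id joint identifier string.
#' @return A [rigid_perturbation].
#' @export
sample_perturbation <- function(cfg, epoch, joint_id) {
  stopifnot(inherits(cfg, "augmentation_config"))
  seed <- derive_seed(cfg$rng_seed, epoch, joint_id)
  draws <- with_seed(seed, runif(6, -1, 1))
  rigid_perturbation(translation = draws[1:3] * cfg$max_translation_mm,
                     rotation = draws[4:6] * cfg$max_rotation_deg)
}
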