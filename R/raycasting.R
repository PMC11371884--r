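## Ray casting through label volumes: condyle-exit / fossa-entry crossings
## and per-joint gap feature vectors.

RAY_STATUS <- c("ok", "no_fossa", "no_condyle_exit", "out_of_volume")

#' Cast a single ray through a label volume
#'
#' Traverses voxels front-to-back from `origin` along `direction` using
#' incremental grid traversal with exact face-crossing parameters (labels
#' are categorical; no interpolation).  The condyle exit is the first
#' condyle-to-non-condyle transition, the fossa entry the first subsequent
#' transition into the fossa label; both are located at the shared voxel
#' face, sub-voxel along the ray.
#'
#' @param volume a [label_volume].
#' @param origin world point (mm) inside the volume bounds.
#' @param direction unit 3-vector.
#' @return A `ray_hit`: list with `status` (one of `"ok"`, `"no_fossa"`,
#'   `"no_condyle_exit"`, `"out_of_volume"`), and for `"ok"` rays
#'   `condyle_exit`, `fossa_entry` (world points, mm) and `gap_mm`.
#' @export
cast_ray <- function(volume, origin, direction) {
  stopifnot(inherits(volume, "label_volume"))
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) stop("zero or non-finite ray direction")
  if (abs(nrm - 1) > 1e-6) stop("'direction' must be unit norm")
  res <- .cast_rays_cpp(as.vector(volume$voxels), dim(volume$voxels),
                        volume$spacing, volume$origin,
                        as.numeric(origin), matrix(direction, nrow = 1))
  status <- RAY_STATUS[res$status[1] + 1L]
  hit <- list(status = status)
  if (status == "ok") {
    hit$condyle_exit <- origin + res$t_exit[1] * direction
    hit$fossa_entry <- origin + res$t_fossa[1] * direction
    hit$gap_mm <- res$gap[1]
  }
  structure(hit, class = "ray_hit")
}

#' Impute gap distances for rays that missed the fossa
#'
#' Rays that never enter the fossa get a stand-in distance bounded by the
#' minimum and maximum of the gaps that were computed: the midpoint
#' (deterministic, used at prediction time) or a seeded uniform draw from
#' `[min, max]` (stochastic regularization during training).
#'
#' @param distances numeric vector of gaps; entries at `!ok_mask` are ignored.
#' @param ok_mask logical vector, `TRUE` where the ray produced a gap.
#' @param policy `"midpoint"` or `"uniform"`.
#' @param rng_seed integer seed for the uniform draws.
#' @return Numeric vector with missing entries filled in.
#' @export
impute <- function(distances, ok_mask, policy = c("midpoint", "uniform"),
                   rng_seed = 0L) {
  policy <- match.arg(policy)
  if (!any(ok_mask)) stop("cannot impute: zero computed ray distances")
  lo <- min(distances[ok_mask])
  hi <- max(distances[ok_mask])
  out <- distances
  miss <- which(!ok_mask)
  if (length(miss)) {
    if (policy == "midpoint") {
      out[miss] <- (lo + hi) / 2
    } else {
      out[miss] <- with_seed(rng_seed, runif(length(miss), lo, hi))
    }
  }
  out
}

#' Extract the per-joint ray-gap feature vector
#'
#' Places the ray origin at the condyle centroid (optionally rigidly
#' perturbed), casts one ray per direction, and imputes rays that missed
#' the fossa.  The imputation bounds are the min/max of the gaps computed
#' in this extraction (after any perturbation).
#'
#' @param volume a [label_volume] with a nonempty condyle.
#' @param ds a `direction_set`.
#' @param perturbation optional [rigid_perturbation] (`NULL` = identity).
#' @param imputation `"midpoint"` or `"uniform"`.
#' @param rng_seed seed for uniform imputation draws.
#' @param joint_id identifier carried into the result.
#' @param centroid optional precomputed condyle centroid (world mm); pass
#'   it when extracting repeatedly from the same volume.
#' @return A `ray_features`: list with `joint_id`, `distances` (length N,
#'   mm), `imputed` (logical), `n_imputed`, `status` (per-ray), `origin`.
#' @export
extract_features <- function(volume, ds, perturbation = NULL,
                             imputation = c("midpoint", "uniform"),
                             rng_seed = 0L, joint_id = "joint",
                             centroid = NULL) {
  imputation <- match.arg(imputation)
  stopifnot(inherits(volume, "label_volume"), inherits(ds, "direction_set"))
  if (is.null(centroid)) centroid <- condyle_centroid(volume)
  # the unperturbed centroid must lie inside the condyle mask
  cidx <- round(world_to_voxel(volume, centroid))
  inside <- all(cidx >= 0) && all(cidx < dim(volume$voxels))
  if (!inside || volume$voxels[matrix(cidx + 1, nrow = 1)] != LABEL_CONDYLE)
    stop("centroid not inside condyle")
  dirs <- ds$directions
  origin <- centroid
  if (!is.null(perturbation)) {
    pt <- perturb(ds, centroid, perturbation)
    dirs <- pt$directions$directions
    origin <- pt$origin
  }
  res <- .cast_rays_cpp(volume$voxels, dim(volume$voxels),
                        volume$spacing, volume$origin,
                        origin, dirs)
  ok <- res$status == 0L
  if (!any(ok)) stop("no fossa coverage: all ", ds$n, " rays missed")
  distances <- impute(ifelse(ok, res$gap, NA_real_), ok,
                      policy = imputation, rng_seed = rng_seed)
  structure(list(joint_id = joint_id,
                 distances = distances,
                 imputed = !ok,
                 n_imputed = sum(!ok),
                 status = RAY_STATUS[res$status + 1L],
                 origin = origin),
            class = "ray_features")
}

#' @export
print.ray_features <- function(x, ...) {
  cat(sprintf("ray_features '%s': %d rays, %d imputed, gap %.2f-%.2f mm\n",
              x$joint_id, length(x$distances), x$n_imputed,
              min(x$distances), max(x$distances)))
  invisible(x)
}

#' Per-ray debug table for one extraction
#'
#' @param features a `ray_features`.
#' @param ds the `direction_set` used.
#' @return data.frame with direction components, status, gap and imputed flag.
#' @export
ray_debug_table <- function(features, ds) {
  d <- ds$directions
  data.frame(ray = seq_along(features$distances) - 1L,
             dx = d[, 1], dy = d[, 2], dz = d[, 3],
             status = features$status,
             gap_mm = features$distances,
             imputed = features$imputed)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic stream seed derived from a master seed and context values
# (epoch number, joint id, ...); stays below 2^31
derive_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(x) else as.numeric(x)
  }))
  h <- as.numeric(master) %% 2147483629
  for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483629) + 1) %% 2147483629
  as.integer(h)
}
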