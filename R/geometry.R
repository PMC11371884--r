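## Hemisphere direction sets, condyle centroids and rigid perturbations.

#' Build a quasi-uniform direction set on the superior hemisphere
#'
#' Directions are the ray directions cast from the condyle centroid toward
#' the glenoid fossa.  The default construction is a spherical Fibonacci
#' lattice restricted to the superior hemisphere: superior components
#' `z_i = 1 - i/n` (uniform in z, hence uniform in area) with azimuths
#' advancing by the golden angle.  It realizes any requested count exactly —
#' including the default 198 matching the classifier input width — and always
#' contains the superior pole, so `n = 1` degenerates to the superior axis.
#' A clipped subdivided-icosahedron alternative (`"clipped_icosphere"`) is
#' provided for tessellation-fidelity experiments; it can only realize the
#' vertex counts its subdivision levels admit.
#'
#' @param n number of directions (default 198).
#' @param construction `"fibonacci_hemisphere"` (default) or
#'   `"clipped_icosphere"`.
#' @param superior_axis array/world axis pointing superior (default 3).
#' @param reference_radius_mm radius of the reference hemisphere vertices
#'   (default 1 mm).  Carried for provenance; rays are parameterized by
#'   direction only, so it never affects gap measurements.
#' @return A `direction_set`: list with `directions` (n x 3 unit rows),
#'   `n`, `construction`, `superior_axis`, `reference_radius_mm`.
#' @export
build_direction_set <- function(n = 198L,
                                construction = c("fibonacci_hemisphere",
                                                 "clipped_icosphere"),
                                superior_axis = 3L,
                                reference_radius_mm = 1) {
  construction <- match.arg(construction)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (construction == "fibonacci_hemisphere") {
    i <- seq_len(n) - 1
    z <- 1 - i / n                      # in (0, 1]; i = 0 is the pole
    r <- sqrt(pmax(0, 1 - z^2))
    golden <- pi * (3 - sqrt(5))
    phi <- i * golden
    dirs <- cbind(r * cos(phi), r * sin(phi), z)
  } else {
    dirs <- clipped_icosphere_directions(n)
  }
  # place the superior component on the requested axis
  if (superior_axis != 3L) {
    perm <- switch(superior_axis, c(3L, 2L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
    dirs <- dirs[, perm, drop = FALSE]
  }
  dimnames(dirs) <- NULL
  structure(list(directions = dirs, n = n, construction = construction,
                 superior_axis = as.integer(superior_axis),
                 reference_radius_mm = reference_radius_mm),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("direction_set: %d unit vectors (%s), superior axis %d\n",
              x$n, x$construction, x$superior_axis))
  invisible(x)
}

# Superior-half vertices of a recursively bisected icosahedron.  Vertex
# counts before clipping are 10 * 4^s + 2; after clipping to z >= 0 the
# achievable counts depend on the orientation (pole-vertex-up here).
clipped_icosphere_directions <- function(n) {
  counts <- integer(0)
  for (s in 0:5) {
    v <- icosphere_vertices(s)
    keep <- v[v[, 3] >= -1e-9, , drop = FALSE]
    counts <- c(counts, nrow(keep))
    if (nrow(keep) == n) return(keep[order(-keep[, 3], atan2(keep[, 2], keep[, 1])), ,
                                     drop = FALSE])
  }
  stop("clipped_icosphere cannot realize n = ", n,
       "; achievable counts: ", paste(counts, collapse = ", "))
}

icosphere_vertices <- function(subdivisions) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # rotate so a vertex sits at the north pole (z axis)
  pole <- v[2, ]
  axis <- c(-pole[2], pole[1], 0)
  axis <- axis / sqrt(sum(axis^2))
  ang <- acos(pole[3])
  R <- axis_angle_matrix(axis, ang)
  v <- v %*% t(R)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- verts[a, ] + verts[b, ]
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  v
}

axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(a)
}

#' Centroid of the condyle mask in world coordinates
#'
#' Mean of the world coordinates of all condyle-labeled voxel centers, the
#' anchor point from which the hemisphere of rays is cast.
#'
#' @param volume a [label_volume] with a nonempty condyle label.
#' @return World point (mm), numeric length 3.
#' @export
condyle_centroid <- function(volume) {
  idx <- which(volume$voxels == LABEL_CONDYLE, arr.ind = TRUE)
  if (!nrow(idx)) stop("no condyle voxels")
  voxel_to_world(volume, unname(colMeans(idx)) - 1)   # arr.ind is 1-based
}

#' Define a rigid perturbation of the ray origin and orientation
#'
#' @param translation numeric length 3, mm.
#' @param rotation numeric length 3, Euler angles in degrees, applied in
#'   fixed order X then Y then Z.
#' @param max_translation_mm,max_rotation_deg optional bounds; components
#'   exceeding them raise an error.
#' @return A `rigid_perturbation`.
#' @export
rigid_perturbation <- function(translation = c(0, 0, 0),
                               rotation = c(0, 0, 0),
                               max_translation_mm = Inf,
                               max_rotation_deg = Inf) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  stopifnot(length(translation) == 3L, length(rotation) == 3L)
  if (any(abs(translation) > max_translation_mm))
    stop("translation exceeds bound of ", max_translation_mm, " mm")
  if (any(abs(rotation) > max_rotation_deg))
    stop("rotation exceeds bound of ", max_rotation_deg, " degrees")
  structure(list(translation = translation, rotation = rotation),
            class = "rigid_perturbation")
}

# Composed rotation matrix for Euler angles (degrees), fixed order X.Y.Z:
# R = Rz %*% Ry %*% Rx (X applied first).
euler_matrix <- function(rotation_deg) {
  th <- rotation_deg * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid perturbation to a direction set and ray origin
#'
#' Rotates every direction by the composed Euler rotation (X then Y then Z,
#' degrees) and translates the origin; unit norms are preserved.
#'
#' @param ds a `direction_set` from [build_direction_set].
#' @param origin world point (mm), the ray origin.
#' @param p a [rigid_perturbation].
#' @return list with elements `directions` (perturbed `direction_set`) and
#'   `origin` (translated point).
#' @export
perturb <- function(ds, origin, p) {
  stopifnot(inherits(ds, "direction_set"), inherits(p, "rigid_perturbation"))
  R <- euler_matrix(p$rotation)
  out <- ds
  out$directions <- ds$directions %*% t(R)
  list(directions = out, origin = origin + p$translation)
}

#' Export a direction set to CSV (n rows, columns x, y, z)
#'
#' @param ds a `direction_set`.
#' @param path output path.
#' @export
write_direction_set <- function(ds, path) {
  d <- ds$directions
  data.table::fwrite(data.table::data.table(x = d[, 1], y = d[, 2], z = d[, 3]),
                     path)
  invisible(path)
}
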