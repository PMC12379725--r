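# Analytic geometry: shapes, ray-surface intersections and point containment.
# All lengths are in metres. Rays are (origin, unit direction); intersection
# routines return distances t > tol so that a photon sitting on a surface does
# not immediately re-intersect it.

#' Analytic shapes for media and boundaries
#'
#' `cylinder()` describes an infinite circular cylinder by a point on its
#' axis, a unit axis direction and a radius. `slab()` describes a laterally
#' infinite plane-parallel layer by its unit normal, the offset of its first
#' face along that normal, and its thickness.
#'
#' @param axis_point Point on the cylinder axis (metres, length 3).
#' @param axis_dir Unit vector along the axis.
#' @param radius Cylinder radius in metres (> 0).
#' @return A shape object (`cylinder` or `slab`).
#' @export
cylinder <- function(axis_point, axis_dir, radius) {
  if (!is_unit3(axis_dir)) stop_invalid("`axis_dir` must be a unit 3-vector")
  if (!is.finite(radius) || radius <= 0) stop_invalid("`radius` must be > 0")
  structure(list(axis_point = as.numeric(axis_point),
                 axis_dir = as.numeric(axis_dir), radius = radius),
            class = c("cylinder", "shape"))
}

#' @rdname cylinder
#' @param normal Unit normal of the slab faces.
#' @param plane_offset Signed offset of the first face: the slab occupies
#'   `plane_offset <= x . normal <= plane_offset + thickness`.
#' @param thickness Slab thickness in metres (> 0).
#' @export
slab <- function(normal, plane_offset, thickness) {
  if (!is_unit3(normal)) stop_invalid("`normal` must be a unit 3-vector")
  if (!is.finite(thickness) || thickness <= 0) {
    stop_invalid("`thickness` must be > 0")
  }
  structure(list(normal = as.numeric(normal), plane_offset = plane_offset,
                 thickness = thickness),
            class = c("slab", "shape"))
}

#' Ray-cylinder intersection distances
#'
#' All distances `t > tol` at which `origin + t * direction` lies on the
#' infinite cylinder surface, in ascending order. The tolerance excludes the
#' surface the photon currently sits on.
#'
#' @param origin Ray origin (metres, length 3).
#' @param direction Unit direction.
#' @param cyl A [cylinder()].
#' @param tol Minimum accepted distance (default 1e-12 m).
#' @return Numeric vector of 0, 1 or 2 distances.
#' @export
ray_cylinder_intersect <- function(origin, direction, cyl, tol = 1e-12) {
  t2 <- ray_cylinder_t(matrix(origin, 1), matrix(direction, 1), cyl, tol)
  sort(t2[is.finite(t2)])
}

# Vectorized core: O, D are n x 3; returns n x 2 matrix of distances
# (ascending per row, Inf where absent).
#' @noRd
ray_cylinder_t <- function(O, D, cyl, tol = 1e-12) {
  n <- nrow(O)
  a <- row3(cyl$axis_point, n)
  u <- cyl$axis_dir
  w <- O - a
  wu <- drop(w %*% u)
  du <- drop(D %*% u)
  wp <- w - outer(wu, u)
  dp <- D - outer(du, u)
  A <- rowSums(dp * dp)
  B <- 2 * rowSums(wp * dp)
  C <- rowSums(wp * wp) - cyl$radius^2
  disc <- B * B - 4 * A * C
  out <- matrix(Inf, n, 2)
  ok <- disc >= 0 & A > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-B[ok] - sq) / (2 * A[ok])
    t2 <- (-B[ok] + sq) / (2 * A[ok])
    t1[t1 <= tol] <- Inf
    t2[t2 <= tol] <- Inf
    out[ok, 1] <- pmin(t1, t2)
    out[ok, 2] <- pmax(t1, t2)
  }
  out
}

#' Ray-plane intersection distance
#'
#' Forward distance to the plane `x . normal = offset`, or `NULL` when the ray
#' is parallel to the plane or the hit lies behind the origin.
#'
#' @inheritParams ray_cylinder_intersect
#' @param plane A list with `normal` (unit vector) and `offset`.
#' @return A single distance, or `NULL`.
#' @export
ray_plane_intersect <- function(origin, direction, plane, tol = 1e-12) {
  t <- ray_plane_t(matrix(origin, 1), matrix(direction, 1),
                   plane$normal, plane$offset, tol)
  if (is.finite(t)) t else NULL
}

#' @noRd
ray_plane_t <- function(O, D, normal, offset, tol = 1e-12) {
  dn <- drop(D %*% normal)
  t <- (offset - drop(O %*% normal)) / dn
  t[!is.finite(t) | t <= tol] <- Inf
  t
}

# squared radial distance from the cylinder axis, vectorized
#' @noRd
cyl_radial2 <- function(P, cyl) {
  n <- nrow(P)
  w <- P - row3(cyl$axis_point, n)
  wu <- drop(w %*% cyl$axis_dir)
  rowSums(w * w) - wu * wu
}

#' @noRd
point_in_shape <- function(P, shape) {
  if (inherits(shape, "cylinder")) {
    cyl_radial2(P, shape) <= shape$radius^2
  } else {
    s <- drop(P %*% shape$normal)
    s >= shape$plane_offset & s <= shape$plane_offset + shape$thickness
  }
}

# outward unit normal of a shape surface at points P (n x 3)
#' @noRd
shape_normal_at <- function(P, shape) {
  if (inherits(shape, "cylinder")) {
    n <- nrow(P)
    w <- P - row3(shape$axis_point, n)
    wu <- drop(w %*% shape$axis_dir)
    normalize_rows(w - outer(wu, shape$axis_dir))
  } else {
    n <- nrow(P)
    s <- drop(P %*% shape$normal)
    mid <- shape$plane_offset + shape$thickness / 2
    sign_out <- ifelse(s >= mid, 1, -1)
    outer(sign_out, shape$normal)
  }
}

#' Simulation boundary constructors
#'
#' The boundary closes the simulation world; photons reaching it are recorded
#' as escaped. A cylindrical boundary has finite length (two end caps), a
#' spherical one a radius, and a box is axis-aligned with corner coordinates.
#'
#' @param axis_point,axis_dir,radius As in [cylinder()].
#' @param length Cylinder length in metres (caps at `+/- length/2` along the
#'   axis from `axis_point`).
#' @return A boundary object.
#' @export
boundary_cylinder <- function(axis_point, axis_dir, radius, length) {
  if (!is_unit3(axis_dir)) stop_invalid("`axis_dir` must be a unit 3-vector")
  structure(list(kind = "cylinder", axis_point = as.numeric(axis_point),
                 axis_dir = as.numeric(axis_dir), radius = radius,
                 length = length),
            class = "sim_boundary")
}

#' @rdname boundary_cylinder
#' @param center Sphere/box center (box: lower corner) in metres.
#' @export
boundary_sphere <- function(center, radius) {
  structure(list(kind = "sphere", center = as.numeric(center), radius = radius),
            class = "sim_boundary")
}

#' @rdname boundary_cylinder
#' @param lower,upper Opposite corners of the axis-aligned box (metres).
#' @export
boundary_box <- function(lower, upper) {
  structure(list(kind = "box", lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "sim_boundary")
}

#' @noRd
in_boundary <- function(P, b) {
  switch(b$kind,
    cylinder = {
      ax <- drop((P - row3(b$axis_point, nrow(P))) %*% b$axis_dir)
      cyl_radial2(P, b) <= b$radius^2 & abs(ax) <= b$length / 2
    },
    sphere = {
      w <- P - row3(b$center, nrow(P))
      rowSums(w * w) <= b$radius^2
    },
    box = {
      lo <- row3(b$lower, nrow(P)); up <- row3(b$upper, nrow(P))
      rowSums(P >= lo & P <= up) == 3
    })
}

# forward exit distance from inside the boundary (vectorized)
#' @noRd
ray_boundary_t <- function(O, D, b, tol = 1e-12) {
  n <- nrow(O)
  switch(b$kind,
    cylinder = {
      tl <- ray_cylinder_t(O, D, cylinder(b$axis_point, b$axis_dir, b$radius),
                           tol)
      t_lat <- tl[, 1]
      hw <- b$length / 2
      a0 <- b$axis_point
      tc1 <- ray_plane_t(O, D, b$axis_dir, sum(a0 * b$axis_dir) + hw, tol)
      tc2 <- ray_plane_t(O, D, b$axis_dir, sum(a0 * b$axis_dir) - hw, tol)
      pmin(t_lat, tc1, tc2)
    },
    sphere = {
      w <- O - row3(b$center, n)
      bq <- 2 * rowSums(w * D)
      cq <- rowSums(w * w) - b$radius^2
      disc <- bq * bq - 4 * cq
      tt <- (-bq + sqrt(pmax(disc, 0))) / 2
      tt[tt <= tol | disc < 0] <- Inf
      tt
    },
    box = {
      tmin <- rep(Inf, n)
      for (ax in 1:3) {
        e <- c(0, 0, 0); e[ax] <- 1
        for (off in c(b$lower[ax], b$upper[ax])) {
          tmin <- pmin(tmin, ray_plane_t(O, D, e, off, tol))
        }
      }
      tmin
    })
}
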