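# Scene description: media with analytic shapes and optical properties, flow
# fields, light source and detector, plus the geometric queries that the
# transport loop relies on.

#' Flow field attached to a medium
#'
#' A flow field combines a deterministic velocity function with an isotropic
#' Brownian speed. The Brownian component is added to the deterministic flow
#' only where the velocity enters the physics: at scattering events, when the
#' Doppler shift is evaluated.
#'
#' @param velocity_fn Function mapping an `n x 3` position matrix (metres) to
#'   an `n x 3` velocity matrix (m/s).
#' @param brownian_speed Magnitude of the isotropic Brownian velocity
#'   component in m/s (default 0).
#' @param particle_diameter,temperature Optional bookkeeping fields (metres,
#'   kelvin) so that a Stokes-Einstein-based rule for `brownian_speed` can be
#'   plugged in later.
#' @param spec Optional serializable description of the field (used by the
#'   scene reader/writer for the built-in profiles).
#' @return A `flow_field` object.
#' @export
flow_field <- function(velocity_fn, brownian_speed = 0,
                       particle_diameter = NA_real_, temperature = 293.15,
                       spec = NULL) {
  stopifnot(is.function(velocity_fn))
  if (!is.finite(brownian_speed) || brownian_speed < 0) {
    stop_invalid("`brownian_speed` must be >= 0")
  }
  structure(list(velocity_fn = velocity_fn, brownian_speed = brownian_speed,
                 particle_diameter = particle_diameter,
                 temperature = temperature, spec = spec),
            class = "flow_field")
}

#' Laminar (Poiseuille) flow in a cylindrical tube
#'
#' Parabolic no-slip profile `v(rho) = 2 vbar (1 - (rho/R)^2)` along the tube
#' axis, where `vbar = volume_rate / (pi R^2)` is the cross-sectional mean
#' velocity; zero outside the tube radius.
#'
#' @param volume_rate Volume flow rate in m^3/s (>= 0).
#' @param tube The lumen [cylinder()].
#' @param flow_dir `+1` to flow along the axis direction, `-1` against it.
#' @param brownian_speed Isotropic Brownian speed in m/s added at scattering
#'   events (default 0).
#' @return A [flow_field()].
#' @examples
#' tube <- cylinder(c(0, 0, 0), c(1, 0, 0), 0.475e-3)
#' ff <- poiseuille_flow(1e-6 / 60, tube) # 1 mL/min
#' ff$velocity_fn(matrix(0, 1, 3))        # centerline velocity
#' @export
poiseuille_flow <- function(volume_rate, tube, flow_dir = 1,
                            brownian_speed = 0) {
  stopifnot(inherits(tube, "cylinder"))
  if (!is.finite(volume_rate) || volume_rate < 0) {
    stop_invalid("`volume_rate` must be >= 0 (m^3/s)")
  }
  if (!flow_dir %in% c(-1, 1)) stop_invalid("`flow_dir` must be +1 or -1")
  R <- tube$radius
  vbar <- volume_rate / (pi * R^2)
  axis <- flow_dir * tube$axis_dir
  fn <- function(P) {
    rho2 <- cyl_radial2(P, tube)
    speed <- 2 * vbar * pmax(1 - rho2 / R^2, 0)
    outer(speed, axis)
  }
  flow_field(fn, brownian_speed = brownian_speed,
             spec = list(type = "poiseuille", volume_rate_m3_s = volume_rate,
                         flow_dir = flow_dir))
}

#' Sample isotropic Brownian velocity vectors
#'
#' Draws unit vectors uniformly over the sphere, scaled by the field's
#' Brownian speed. Every sample has norm exactly `brownian_speed`.
#'
#' @param field A [flow_field()].
#' @param n_samples Number of samples.
#' @return An `n_samples x 3` matrix of velocities (m/s).
#' @export
brownian_velocity <- function(field, n_samples) {
  stopifnot(inherits(field, "flow_field"))
  brownian_from_uniforms(field$brownian_speed,
                         stats::runif(n_samples), stats::runif(n_samples))
}

# deterministic kernel: two uniforms -> isotropic direction * speed
#' @noRd
brownian_from_uniforms <- function(speed, uA, uB) {
  n <- length(uA)
  if (speed == 0) return(matrix(0, n, 3))
  cz <- 2 * uA - 1
  sz <- sqrt(pmax(1 - cz^2, 0))
  b <- 2 * pi * uB
  speed * cbind(sz * cos(b), sz * sin(b), cz)
}

#' Light source description
#'
#' @param kind One of `"point"` (isotropic emitter), `"pencil"` (zero-width
#'   collimated beam) or `"gaussian"` (Gaussian intensity spot with finite
#'   numerical aperture).
#' @param position Source position in metres.
#' @param direction Unit propagation direction (ignored for `"point"`).
#' @param wavelength Vacuum wavelength in metres.
#' @param spot_diameter_1e Diameter at which the *intensity* falls to 1/e of
#'   its peak (metres; `"gaussian"` only).
#' @param na Numerical aperture setting the angular spread of a `"gaussian"`
#'   source (`0 <= na < 1`).
#' @param polarization Unit polarization vector perpendicular to `direction`.
#'   Default: the projection of the y axis onto the plane perpendicular to
#'   `direction` (i.e. polarization in the y-z plane for a beam along z).
#' @return A `source_spec` object.
#' @export
source_spec <- function(kind = c("pencil", "gaussian", "point"),
                        position, direction = c(0, 0, 1),
                        wavelength = 633e-9,
                        spot_diameter_1e = 0, na = 0,
                        polarization = NULL) {
  kind <- match.arg(kind)
  if (!is_unit3(direction)) stop_invalid("`direction` must be a unit 3-vector")
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop_invalid("`wavelength` must be > 0")
  }
  if (na < 0 || na >= 1) stop_invalid("`na` must lie in [0, 1)")
  if (is.null(polarization)) {
    y <- c(0, 1, 0)
    pr <- y - sum(y * direction) * direction
    if (sqrt(sum(pr^2)) < 1e-9) {
      z <- c(0, 0, 1)
      pr <- z - sum(z * direction) * direction
    }
    polarization <- pr / sqrt(sum(pr^2))
  }
  if (!is_unit3(polarization) ||
      abs(sum(polarization * direction)) > 1e-12) {
    stop_invalid("`polarization` must be a unit vector perpendicular to `direction`")
  }
  structure(list(kind = kind, position = as.numeric(position),
                 direction = as.numeric(direction), wavelength = wavelength,
                 spot_diameter_1e = spot_diameter_1e, na = na,
                 polarization = as.numeric(polarization)),
            class = "source_spec")
}

#' Detector description
#'
#' A circular disk detector. Photons whose propagation step crosses the
#' detector plane moving along its normal, within `diameter / 2` of the
#' center, are recorded.
#'
#' @param center Disk center in metres.
#' @param normal Unit plane normal; photons are counted when crossing with
#'   `k . normal > 0`.
#' @param diameter Disk diameter in metres (> 0).
#' @param save_fields Character subset of
#'   `c("position", "direction", "polarization", "weight", "doppler",
#'   "n_scatter")` to keep in the records.
#' @param selection Optional predicate taking the records data frame and
#'   returning a logical vector (e.g. minimum scatter count).
#' @return A `detector_spec` object.
#' @export
detector_spec <- function(center, normal = c(0, 0, 1), diameter,
                          save_fields = c("position", "direction",
                                          "polarization", "weight", "doppler",
                                          "n_scatter"),
                          selection = NULL) {
  if (!is_unit3(normal)) stop_invalid("`normal` must be a unit 3-vector")
  if (!is.finite(diameter) || diameter <= 0) {
    stop_invalid("`diameter` must be > 0")
  }
  save_fields <- match.arg(save_fields, several.ok = TRUE)
  structure(list(center = as.numeric(center), normal = as.numeric(normal),
                 diameter = diameter, save_fields = save_fields,
                 selection = selection),
            class = "detector_spec")
}

#' Medium description
#'
#' @param shape A [cylinder()] or [slab()].
#' @param n Refractive index (>= 1).
#' @param mus,mua Scattering and absorption coefficients in mm^-1 (the
#'   conventional unit at the configuration boundary; they are converted to
#'   SI once, here).
#' @param flow Optional [flow_field()].
#' @param sampler Optional [build_scatter_sampler()] result; required at run
#'   time for media with `mus > 0`.
#' @param phase Optional serializable description of the phase function
#'   (e.g. `list(type = "mie", diameter = ..., ...)`), used by the scene
#'   writer and to rebuild `sampler` on read.
#' @return A `medium_spec` object.
#' @export
medium_spec <- function(shape, n, mus = 0, mua = 0, flow = NULL,
                        sampler = NULL, phase = NULL) {
  stopifnot(inherits(shape, "shape"))
  if (!is.finite(n) || n < 1) stop_invalid("refractive index must be >= 1")
  if (mus < 0 || mua < 0) stop_invalid("`mus` and `mua` must be >= 0")
  if (!is.null(flow)) stopifnot(inherits(flow, "flow_field"))
  if (!is.null(sampler)) stopifnot(inherits(sampler, "scatter_sampler"))
  n <- as.numeric(n)
  mus <- as.numeric(mus)
  mua <- as.numeric(mua)
  structure(list(shape = shape, n = n, mus = mus, mua = mua,
                 mus_si = per_mm(mus), mua_si = per_mm(mua),
                 flow = flow, sampler = sampler, phase = phase),
            class = "medium_spec")
}

#' Assemble a simulation scene
#'
#' Media must be listed cylinders first, ordered outermost to innermost, then
#' slabs. Nesting of the cylinders inside the simulation boundary is verified
#' by sampling points on each cylinder surface.
#'
#' @param boundary A [boundary_cylinder()], [boundary_sphere()] or
#'   [boundary_box()].
#' @param media List of [medium_spec()] objects.
#' @param source A [source_spec()].
#' @param detector A [detector_spec()].
#' @param ambient_n Refractive index outside all media (default 1, air).
#' @param check_nesting Number of surface sample points used to verify that
#'   nested cylinders do not cross (default 10000; 0 disables the check).
#' @return A `scene` object.
#' @export
scene <- function(boundary, media, source, detector, ambient_n = 1,
                  check_nesting = 10000) {
  stopifnot(inherits(boundary, "sim_boundary"),
            inherits(source, "source_spec"),
            inherits(detector, "detector_spec"))
  stopifnot(all(vapply(media, inherits, logical(1), "medium_spec")))
  is_cyl <- vapply(media, function(m) inherits(m$shape, "cylinder"),
                   logical(1))
  if (is.unsorted(rev(is_cyl))) {
    stop_invalid("media must be listed cylinders first, then slabs")
  }
  cyls <- which(is_cyl)
  if (check_nesting > 0 && length(cyls) > 1) {
    for (i in seq_along(cyls)[-1]) {
      inner <- media[[cyls[i]]]$shape
      outer_ <- media[[cyls[i - 1]]]$shape
      P <- cylinder_surface_points(inner, boundary, check_nesting)
      if (nrow(P) > 0 && !all(point_in_shape(P, outer_))) {
        stop_invalid("cylinder %d is not nested inside cylinder %d within the boundary",
                     i, i - 1)
      }
    }
  }
  structure(list(boundary = boundary, media = media, source = source,
                 detector = detector, ambient_n = ambient_n),
            class = "scene")
}

# deterministic grid of points on a cylinder's lateral surface, clipped to the
# boundary region
#' @noRd
cylinder_surface_points <- function(cyl, boundary, n_points) {
  u <- cyl$axis_dir
  # any transverse frame
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  half_len <- switch(boundary$kind,
                     cylinder = boundary$length / 2 + boundary$radius,
                     sphere = boundary$radius,
                     box = sum(abs(boundary$upper - boundary$lower)))
  n_ax <- max(10, floor(sqrt(n_points)))
  n_az <- ceiling(n_points / n_ax)
  ax <- seq(-half_len, half_len, length.out = n_ax)
  az <- seq(0, 2 * pi, length.out = n_az + 1)[seq_len(n_az)]
  grid <- expand.grid(ax = ax, az = az)
  P <- row3(cyl$axis_point, nrow(grid)) +
    outer(grid$ax, u) +
    cyl$radius * (outer(cos(grid$az), e1) + outer(sin(grid$az), e2))
  P[in_boundary(P, boundary), , drop = FALSE]
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene>", length(x$media), "media,",
      sprintf("boundary: %s\n", x$boundary$kind))
  for (i in seq_along(x$media)) {
    m <- x$media[[i]]
    cat(sprintf("  [%d] %s n=%.3f mus=%.3g mm-1 mua=%.3g mm-1%s%s\n", i,
                class(m$shape)[1], m$n, m$mus, m$mua,
                if (!is.null(m$flow)) " +flow" else "",
                if (!is.null(m$sampler)) " +sampler" else ""))
  }
  invisible(x)
}

#' Locate the medium containing each position
#'
#' The innermost cylinder containing a point wins; otherwise the first
#' containing slab; otherwise the ambient medium (index 0).
#'
#' @param sc A [scene()].
#' @param position Either a length-3 vector or an `n x 3` matrix of positions
#'   (metres), all inside the simulation boundary.
#' @return Integer vector of medium indices (0 = ambient).
#' @export
locate_medium <- function(sc, position) {
  P <- if (is.matrix(position)) position else matrix(position, 1)
  if (!all(in_boundary(P, sc$boundary))) {
    stop_invalid("position outside the simulation boundary")
  }
  idx <- integer(nrow(P))
  for (i in seq_along(sc$media)) {
    m <- sc$media[[i]]
    inside <- point_in_shape(P, m$shape)
    if (inherits(m$shape, "cylinder")) {
      idx[inside] <- i            # later (inner) cylinders overwrite
    } else {
      idx[inside & idx == 0] <- i # slabs never override a cylinder
    }
  }
  idx
}

#' Launch a batch of photons from a source
#'
#' Photons start with weight 1, Doppler shift 0 and polarization
#' perpendicular to their propagation direction. `"gaussian"` sources draw
#' radial offsets so that intensity falls to 1/e at `spot_diameter_1e / 2`
#' and angular deviations with a 1/e intensity half-angle of `asin(na)`.
#'
#' @param source A [source_spec()].
#' @param N Number of photons (>= 1).
#' @return A `photon_batch` object (see [photon_batch()]).
#' @export
emit_photons <- function(source, N) {
  stopifnot(inherits(source, "source_spec"), N >= 1)
  k0 <- source$direction
  p0 <- source$polarization
  r <- row3(source$position, N)
  if (source$kind == "pencil") {
    k <- row3(k0, N)
    p <- row3(p0, N)
  } else if (source$kind == "point") {
    u <- matrix(stats::runif(2 * N), N, 2)
    cz <- 2 * u[, 1] - 1
    sz <- sqrt(pmax(1 - cz^2, 0))
    b <- 2 * pi * u[, 2]
    k <- cbind(sz * cos(b), sz * sin(b), cz)
    p <- project_polarization(row3(p0, N), k)
  } else { # gaussian
    e1 <- p0
    e2 <- c(k0[2] * e1[3] - k0[3] * e1[2],
            k0[3] * e1[1] - k0[1] * e1[3],
            k0[1] * e1[2] - k0[2] * e1[1])
    u <- matrix(stats::runif(4 * N), N, 4)
    w0 <- source$spot_diameter_1e / 2
    rad <- w0 * sqrt(-log1p(-u[, 1]))
    psi <- 2 * pi * u[, 2]
    r <- r + rad * (outer(cos(psi), e1) + outer(sin(psi), e2))
    th0 <- asin(source$na)
    td <- th0 * sqrt(-log1p(-u[, 3]))
    pd <- 2 * pi * u[, 4]
    k <- outer(cos(td), k0) +
      sin(td) * (outer(cos(pd), e1) + outer(sin(pd), e2))
    k <- normalize_rows(k)
    p <- project_polarization(row3(p0, N), k)
  }
  photon_batch(r = r, k = k, p = p)
}

# project a polarization matrix perpendicular to direction rows, renormalized
#' @noRd
project_polarization <- function(p, k) {
  pr <- p - dot_rows(p, k) * k
  nr <- norm_rows(pr)
  deg <- nr < 1e-9
  if (any(deg)) {
    # direction parallel to requested polarization: fall back to any
    # perpendicular vector
    kd <- k[deg, , drop = FALSE]
    alt <- cbind(-kd[, 2], kd[, 1], 0)
    bad <- norm_rows(alt) < 1e-9
    alt[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    pr[deg, ] <- alt
    nr[deg] <- norm_rows(pr[deg, , drop = FALSE])
  }
  pr / nr
}
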