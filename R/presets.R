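# The packaged reference geometry and scene (de)serialization.

#' Reference through-transmission flow-tube scene
#'
#' The packaged default geometry: a Gaussian source (170 um 1/e intensity
#' diameter, NA 2.5e-3) in air, 1 mm from a soda-lime glass tube (outer
#' diameter 1.35 mm, inner diameter 0.95 mm, n = 1.52) whose lumen holds
#' water (n = 1.33) with suspended polystyrene beads; a 0.5 mm glass plate
#' 1.8 mm behind the tube surface; and a 1 mm diameter disk detector 0.7 mm
#' behind the plate, centered on the beam. The simulation boundary is a
#' cylinder of radius 13.175 mm and length 5 mm, coaxial with the tube.
#' Coordinates: beam along +z, tube axis and flow along +x, detector plane
#' perpendicular to z.
#'
#' @param mus Lumen scattering coefficient in mm^-1.
#' @param bead_diameter Polystyrene bead diameter in metres (default 1 um).
#' @param flow_rate Volume flow rate in mL/min (0 disables the flow field,
#'   giving a fully static scene).
#' @param mua Lumen absorption coefficient in mm^-1 (default 0).
#' @param brownian_speed Isotropic Brownian speed in m/s added at scattering
#'   events when a flow field is present (default 0.002).
#' @param n_particle,n_medium Bead and water refractive indices at 633 nm.
#' @param wavelength Vacuum wavelength in metres.
#' @param K,n_phi_nodes Phase-function and sampler resolution passed to
#'   [mie_phase_functions()] and [build_scatter_sampler()].
#' @param sampler Optional pre-built [build_scatter_sampler()] result; when
#'   supplied, the Mie computation is skipped.
#' @return A [scene()].
#' @examples
#' sc <- reference_scene(mus = 1, K = 361, n_phi_nodes = 120)
#' locate_medium(sc, c(0, 0, 0)) # lumen
#' @export
reference_scene <- function(mus = 1, bead_diameter = 1e-6, flow_rate = 0,
                            mua = 0, brownian_speed = 0.002,
                            n_particle = 1.586, n_medium = 1.33,
                            wavelength = 633e-9, K = 1801, n_phi_nodes = 360,
                            sampler = NULL) {
  tube_outer <- cylinder(c(0, 0, 0), c(1, 0, 0), 1.35e-3 / 2)
  lumen_cyl <- cylinder(c(0, 0, 0), c(1, 0, 0), 0.95e-3 / 2)
  plate <- slab(c(0, 0, 1), 1.35e-3 / 2 + 1.8e-3, 0.5e-3)

  phase <- NULL
  if (mus > 0 && is.null(sampler)) {
    tab <- mie_phase_functions(bead_diameter, n_particle, n_medium,
                               wavelength, K = K)
    sampler <- build_scatter_sampler(tab, n_phi_nodes = n_phi_nodes)
    phase <- list(type = "mie", diameter = bead_diameter,
                  n_particle = n_particle, n_medium = n_medium,
                  wavelength = wavelength, K = K, n_phi_nodes = n_phi_nodes)
  }
  flow <- NULL
  if (flow_rate > 0) {
    flow <- poiseuille_flow(flow_rate * 1e-6 / 60, lumen_cyl,
                            flow_dir = 1, brownian_speed = brownian_speed)
  }

  media <- list(
    medium_spec(tube_outer, n = 1.52),
    medium_spec(lumen_cyl, n = n_medium, mus = mus, mua = mua, flow = flow,
                sampler = if (mus > 0) sampler else NULL, phase = phase),
    medium_spec(plate, n = 1.52))

  src <- source_spec("gaussian",
                     position = c(0, 0, -(1.35e-3 / 2 + 1e-3)),
                     direction = c(0, 0, 1), wavelength = wavelength,
                     spot_diameter_1e = 170e-6, na = 2.5e-3)
  det <- detector_spec(center = c(0, 0, 1.35e-3 / 2 + 1.8e-3 + 0.5e-3 + 0.7e-3),
                       normal = c(0, 0, 1), diameter = 1e-3)
  bnd <- boundary_cylinder(c(0, 0, 0), c(1, 0, 0), 13.175e-3, 5e-3)
  scene(bnd, media, src, det, ambient_n = 1, check_nesting = 10000)
}

#' Write or read a scene as a JSON configuration
#'
#' Scenes are serialized as structured JSON with explicit unit suffixes on
#' every dimensional key (`*_m` for metres, `*_mm1` for mm^-1;
#' `wavelength_nm` is also accepted on input). Flow fields and phase
#' functions are stored via their generating parameters (Poiseuille profile,
#' Mie spec, or an inline phase table), so a round trip reproduces the scene
#' exactly.
#'
#' @param sc A [scene()]. Custom `velocity_fn` flow fields without a `spec`
#'   cannot be serialized.
#' @param path File path of the JSON configuration.
#' @return `write_scene` returns `path` invisibly; `read_scene` the scene.
#' @export
write_scene <- function(sc, path) {
  ser_shape <- function(sh) {
    if (inherits(sh, "cylinder")) {
      list(type = "cylinder", axis_point_m = sh$axis_point,
           axis_dir = sh$axis_dir, radius_m = sh$radius)
    } else {
      list(type = "slab", normal = sh$normal, plane_offset_m = sh$plane_offset,
           thickness_m = sh$thickness)
    }
  }
  ser_medium <- function(m) {
    out <- list(shape = ser_shape(m$shape), n = m$n, mus_mm1 = m$mus,
                mua_mm1 = m$mua)
    if (!is.null(m$flow)) {
      if (is.null(m$flow$spec)) {
        stop_invalid("cannot serialize a custom flow field without a `spec`")
      }
      out$flow <- c(m$flow$spec,
                    list(brownian_speed_m_s = m$flow$brownian_speed))
    }
    if (!is.null(m$phase)) {
      out$phase <- m$phase
    } else if (!is.null(m$sampler)) {
      stop_invalid("cannot serialize a sampler without a `phase` description")
    }
    out
  }
  b <- sc$boundary
  bnd <- switch(b$kind,
    cylinder = list(kind = "cylinder", axis_point_m = b$axis_point,
                    axis_dir = b$axis_dir, radius_m = b$radius,
                    length_m = b$length),
    sphere = list(kind = "sphere", center_m = b$center, radius_m = b$radius),
    box = list(kind = "box", lower_m = b$lower, upper_m = b$upper))
  cfg <- list(
    boundary = bnd,
    ambient_n = sc$ambient_n,
    media = lapply(sc$media, ser_medium),
    source = list(kind = sc$source$kind, position_m = sc$source$position,
                  direction = sc$source$direction,
                  wavelength_m = sc$source$wavelength,
                  spot_diameter_1e_m = sc$source$spot_diameter_1e,
                  na = sc$source$na, polarization = sc$source$polarization),
    detector = list(center_m = sc$detector$center,
                    normal = sc$detector$normal,
                    diameter_m = sc$detector$diameter,
                    save_fields = sc$detector$save_fields))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop_invalid("scene config: missing required field `%s` in %s",
                   field, where)
    }
    x[[field]]
  }
  de_shape <- function(s) {
    if (need(s, "type", "shape") == "cylinder") {
      cylinder(need(s, "axis_point_m", "cylinder"),
               need(s, "axis_dir", "cylinder"),
               need(s, "radius_m", "cylinder"))
    } else {
      slab(need(s, "normal", "slab"), need(s, "plane_offset_m", "slab"),
           need(s, "thickness_m", "slab"))
    }
  }
  de_medium <- function(m) {
    sh <- de_shape(need(m, "shape", "medium"))
    flow <- NULL
    if (!is.null(m$flow)) {
      if (need(m$flow, "type", "flow") != "poiseuille") {
        stop_invalid("scene config: unknown flow type `%s`", m$flow$type)
      }
      if (!inherits(sh, "cylinder")) {
        stop_invalid("poiseuille flow requires a cylindrical medium")
      }
      bs <- m$flow$brownian_speed_m_s
      flow <- poiseuille_flow(need(m$flow, "volume_rate_m3_s", "flow"), sh,
                              flow_dir = need(m$flow, "flow_dir", "flow"),
                              brownian_speed = if (is.null(bs)) 0 else bs)
    }
    sampler <- NULL
    phase <- m$phase
    if (!is.null(phase)) {
      if (phase$type == "mie") {
        tab <- mie_phase_functions(phase$diameter, phase$n_particle,
                                   phase$n_medium, phase$wavelength,
                                   K = phase$K)
        sampler <- build_scatter_sampler(tab, n_phi_nodes = phase$n_phi_nodes)
      } else if (phase$type == "table") {
        tab <- phase_table(phase$theta, phase$Ps, phase$Pp)
        sampler <- build_scatter_sampler(tab, n_phi_nodes = phase$n_phi_nodes)
        phase <- lapply(phase, identity) # keep as-is for re-serialization
      } else {
        stop_invalid("scene config: unknown phase type `%s`", phase$type)
      }
    }
    medium_spec(sh, n = need(m, "n", "medium"),
                mus = if (is.null(m$mus_mm1)) 0 else m$mus_mm1,
                mua = if (is.null(m$mua_mm1)) 0 else m$mua_mm1,
                flow = flow, sampler = sampler, phase = phase)
  }
  b <- need(cfg, "boundary", "config")
  bnd <- switch(need(b, "kind", "boundary"),
    cylinder = boundary_cylinder(b$axis_point_m, b$axis_dir, b$radius_m,
                                 b$length_m),
    sphere = boundary_sphere(b$center_m, b$radius_m),
    box = boundary_box(b$lower_m, b$upper_m),
    stop_invalid("scene config: unknown boundary kind `%s`", b$kind))
  s <- need(cfg, "source", "config")
  wl <- if (!is.null(s$wavelength_m)) s$wavelength_m else
    if (!is.null(s$wavelength_nm)) s$wavelength_nm * 1e-9 else
      stop_invalid("scene config: missing required field `wavelength_m` in source")
  src <- source_spec(need(s, "kind", "source"),
                     position = need(s, "position_m", "source"),
                     direction = need(s, "direction", "source"),
                     wavelength = wl,
                     spot_diameter_1e = if (is.null(s$spot_diameter_1e_m)) 0
                                        else s$spot_diameter_1e_m,
                     na = if (is.null(s$na)) 0 else s$na,
                     polarization = s$polarization)
  d <- need(cfg, "detector", "config")
  det <- detector_spec(center = need(d, "center_m", "detector"),
                       normal = need(d, "normal", "detector"),
                       diameter = need(d, "diameter_m", "detector"),
                       save_fields = if (is.null(d$save_fields))
                         c("position", "direction", "polarization", "weight",
                           "doppler", "n_scatter") else d$save_fields)
  an <- cfg$ambient_n
  scene(bnd, lapply(need(cfg, "media", "config"), de_medium), src, det,
        ambient_n = if (is.null(an)) 1 else an)
}

#' Write or read detector records
#'
#' Records use a fixed columnar schema (`x, y, z, kx, ky, kz, px, py, pz,
#' weight, fD_Hz, n_scat`, subset to the detector's `save_fields`). `"csv"`
#' writes headered text; `"feather"` writes an Apache Arrow binary container
#' with the identical schema (requires the `arrow` package).
#'
#' @param records Data frame of detector records.
#' @param path Output path.
#' @param format `"csv"` or `"feather"`.
#' @return `write_records` returns `path` invisibly; `read_records` the data
#'   frame.
#' @export
write_records <- function(records, path, format = c("csv", "feather")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_invalid("the `arrow` package is required for feather output")
    }
    arrow::write_feather(records, path)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, format = c("csv", "feather")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_invalid("the `arrow` package is required for feather input")
    }
    as.data.frame(arrow::read_feather(path))
  }
}

#' Write a run manifest as JSON
#'
#' @param manifest The `manifest` element of a [run_simulation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
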