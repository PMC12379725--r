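# Elementary photon-transport operations. All of them are expressed over
# arrays of photons with no cross-photon data dependence, so the batched main
# loop in simulate.R and a naive per-photon loop produce identical results
# given the same per-photon random numbers.

# photon status codes
ST_ALIVE <- 0L
ST_DETECTED <- 1L
ST_ESCAPED <- 2L
ST_ABSORBED <- 3L
ST_STALLED <- 4L

#' Photon batch container
#'
#' Per-photon state for `N` photons: position `r`, direction `k`,
#' polarization `p` (all `N x 3`), weight `w` in `(0, 1]`, cumulative Doppler
#' shift `fD` (Hz), remaining sampled path length `d_pending` (m, `NA` when a
#' fresh path must be drawn), current medium index (`0` = ambient),
#' scattering-event count and a status code.
#'
#' @param r,k,p `N x 3` matrices (metres / unit vectors). `k` and `p` must be
#'   unit-norm with `p` perpendicular to `k`.
#' @param w,fD,d_pending,medium,n_scat,status Optional per-photon vectors;
#'   defaults describe freshly launched photons.
#' @return A `photon_batch` object.
#' @export
photon_batch <- function(r, k, p,
                         w = rep(1, nrow(r)),
                         fD = rep(0, nrow(r)),
                         d_pending = rep(NA_real_, nrow(r)),
                         medium = rep(NA_integer_, nrow(r)),
                         n_scat = rep(0L, nrow(r)),
                         status = rep(ST_ALIVE, nrow(r))) {
  stopifnot(is.matrix(r), ncol(r) == 3, identical(dim(r), dim(k)),
            identical(dim(r), dim(p)))
  if (any(abs(norm_rows(k) - 1) > 1e-9) || any(abs(norm_rows(p) - 1) > 1e-9)) {
    stop_invalid("`k` and `p` must be unit vectors")
  }
  if (any(abs(dot_rows(k, p)) > 1e-9)) {
    stop_invalid("`p` must be perpendicular to `k`")
  }
  structure(list(r = r, k = k, p = p, w = w, fD = fD, d_pending = d_pending,
                 medium = medium, n_scat = n_scat, status = status),
            class = "photon_batch")
}

#' @export
print.photon_batch <- function(x, ...) {
  cat(sprintf("<photon_batch> %d photons: %d alive, %d detected, %d escaped, %d absorbed\n",
              length(x$w), sum(x$status == ST_ALIVE),
              sum(x$status == ST_DETECTED), sum(x$status == ST_ESCAPED),
              sum(x$status == ST_ABSORBED)))
  invisible(x)
}

#' Sample free path lengths from the scattering coefficient
#'
#' Inverse-CDF sampling of the exponential free-path distribution:
#' `d = -log(1 - u) / mus`. A uniform variate of exactly 1 would map to an
#' infinite path; such draws are replaced by a fresh uniform rather than
#' clamped, so infinity is never propagated. For `mus = 0` the path is
#' effectively infinite and the photon runs until it hits a surface or the
#' boundary.
#'
#' @param mus Scattering coefficient in mm^-1 (> 0).
#' @param u Uniform variates in `[0, 1)`.
#' @return Path lengths in metres.
#' @examples
#' sample_path_length(1, 1 - exp(-1)) # 1 mm
#' @export
sample_path_length <- function(mus, u) {
  if (any(mus < 0)) stop_invalid("`mus` must be >= 0")
  while (any(u >= 1)) u[u >= 1] <- stats::runif(sum(u >= 1))
  mus_v <- rep_len(per_mm(mus), length(u))
  ifelse(mus_v > 0, -log1p(-u) / mus_v, Inf)
}

#' Weight attenuation by the Lambert-Beer law
#'
#' @param batch A [photon_batch()].
#' @param mua Absorption coefficient in mm^-1 (scalar or per photon).
#' @param distance Travelled distance in metres (scalar or per photon).
#' @return The batch with `w` multiplied by `exp(-mua * distance)`.
#' @export
apply_absorption <- function(batch, mua, distance) {
  if (any(mua < 0) || any(distance < 0)) {
    stop_invalid("`mua` and `distance` must be >= 0")
  }
  batch$w <- batch$w * exp(-per_mm(mua) * distance)
  batch
}

#' Russian roulette configuration
#'
#' Photons whose weight drops below `w_min` survive a roulette draw with
#' probability `survival_prob` (defaulting to `w_min` itself) and are
#' otherwise terminated. In the default mode a survivor's weight is set to
#' `w_revive`; this scheme is not weight-conserving in expectation, so a
#' `conserving` mode is offered in which survivors carry `w / survival_prob`.
#'
#' @param w_min Roulette threshold weight in `(0, 1)` (default 0.1).
#' @param w_revive Survivor weight in default mode (default 0.5).
#' @param survival_prob Survival probability in `(0, 1]` (default `w_min`).
#' @param conserving Use the unbiased `w / survival_prob` revival rule.
#' @return A `roulette_config` object.
#' @export
roulette_config <- function(w_min = 0.1, w_revive = 0.5,
                            survival_prob = w_min, conserving = FALSE) {
  if (w_min < 0 || w_min >= 1) stop_invalid("`w_min` must lie in [0, 1)")
  if (w_min == 0 && survival_prob == 0) survival_prob <- 1 # roulette disabled
  if (survival_prob <= 0 || survival_prob > 1) {
    stop_invalid("`survival_prob` must lie in (0, 1]")
  }
  structure(list(w_min = w_min, w_revive = w_revive,
                 survival_prob = survival_prob, conserving = conserving),
            class = "roulette_config")
}

#' Russian roulette on low-weight photons
#'
#' @param batch A [photon_batch()].
#' @param cfg A [roulette_config()]. A `w_min` of 0 disables roulette.
#' @param u Optional uniform variates, one per photon (drawn internally if
#'   missing); only entries for photons with `w < w_min` are consulted.
#' @return The batch: survivors revived, casualties marked absorbed.
#' @export
russian_roulette <- function(batch, cfg = roulette_config(), u = NULL) {
  cand <- batch$status == ST_ALIVE & batch$w < cfg$w_min
  if (!any(cand)) return(batch)
  if (is.null(u)) {
    u <- rep(NA_real_, length(batch$w))
    u[cand] <- stats::runif(sum(cand))
  }
  survive <- cand & u <= cfg$survival_prob
  die <- cand & !survive
  if (cfg$conserving) {
    batch$w[survive] <- batch$w[survive] / cfg$survival_prob
  } else {
    batch$w[survive] <- cfg$w_revive
  }
  batch$status[die] <- ST_ABSORBED
  batch
}

#' Fresnel reflectivity for polarized photons
#'
#' Reflectivity `R = Rs cos^2(psi) + Rp sin^2(psi)`, where `psi` is the angle
#' between the photon polarization and the s-polarized direction
#' (`normal x k`, normalized). Total internal reflection gives `R = 1`;
#' within `1e-12` of normal incidence the polarization-independent closed
#' form `((n1 - n2) / (n1 + n2))^2` is used.
#'
#' @param k Direction unit vector(s): length-3 vector or `n x 3` matrix.
#' @param normal Interface unit normal(s) pointing into the incidence medium
#'   (`k . normal < 0`).
#' @param p Polarization unit vector(s), perpendicular to `k`.
#' @param n1,n2 Refractive indices of the incidence and far media.
#' @return Reflectivity values in `[0, 1]`.
#' @export
fresnel_reflectivity <- function(k, normal, p, n1, n2) {
  if (!is.matrix(k)) k <- matrix(k, 1)
  if (!is.matrix(normal)) normal <- matrix(normal, nrow(k), 3, byrow = TRUE)
  if (!is.matrix(p)) p <- matrix(p, nrow(k), 3, byrow = TRUE)
  c1 <- pmin(abs(dot_rows(k, normal)), 1)
  sin2_i <- 1 - c1^2
  eta <- n1 / n2
  sin2_t <- eta^2 * sin2_i
  tir <- sin2_t > 1
  c2 <- sqrt(pmax(1 - sin2_t, 0))
  Rs <- ((n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2))^2
  Rp <- ((n1 * c2 - n2 * c1) / (n1 * c2 + n2 * c1))^2
  s <- cross_rows(normal, k)
  sn <- norm_rows(s)
  near_normal <- sn < 1e-12
  cos2_psi <- rep(0.5, nrow(k))
  ok <- !near_normal
  if (any(ok)) {
    s_ok <- s[ok, , drop = FALSE] / sn[ok]
    cos2_psi[ok] <- pmin(dot_rows(p[ok, , drop = FALSE], s_ok)^2, 1)
  }
  R <- Rs * cos2_psi + Rp * (1 - cos2_psi)
  R[near_normal] <- ((n1 - n2) / (n1 + n2))^2
  R[tir] <- 1
  pmin(pmax(R, 0), 1)
}

# Vectorized reflection/refraction kernel. `normal` rows point into the
# incidence medium (k . normal < 0). Returns updated k, p and the logical
# `reflected`. Polarization is re-decomposed into s/p components and
# reassembled perpendicular to the new direction; no Fresnel amplitude
# re-weighting is applied because the binary reflect/transmit draw already
# accounts for R.
#' @noRd
interface_kernel <- function(k, p, normal, n1, n2, u) {
  R <- fresnel_reflectivity(k, normal, p, n1, n2)
  reflected <- u <= R

  c1 <- -dot_rows(k, normal)
  s <- cross_rows(normal, k)
  sn <- norm_rows(s)
  near_normal <- sn < 1e-12
  shat <- s
  shat[!near_normal, ] <- s[!near_normal, , drop = FALSE] / sn[!near_normal]

  E_s <- dot_rows(p, shat)
  h_in <- cross_rows(shat, k)
  E_h <- dot_rows(p, h_in)

  k_new <- k
  p_new <- p
  if (any(reflected)) {
    i <- reflected
    kr <- k[i, , drop = FALSE] -
      2 * dot_rows(k[i, , drop = FALSE], normal[i, , drop = FALSE]) *
      normal[i, , drop = FALSE]
    k_new[i, ] <- kr
    pr <- E_s[i] * shat[i, , drop = FALSE] +
      E_h[i] * cross_rows(shat[i, , drop = FALSE], kr)
    nn <- near_normal[i]
    pr[nn, ] <- p[i, , drop = FALSE][nn, , drop = FALSE]
    p_new[i, ] <- normalize_rows(pr)
  }
  if (any(!reflected)) {
    i <- !reflected
    eta <- (n1 / n2)[i]
    c2 <- sqrt(pmax(1 - eta^2 * (1 - c1[i]^2), 0))
    kt <- eta * k[i, , drop = FALSE] +
      (eta * c1[i] - c2) * normal[i, , drop = FALSE]
    kt <- normalize_rows(kt)
    k_new[i, ] <- kt
    pt <- E_s[i] * shat[i, , drop = FALSE] +
      E_h[i] * cross_rows(shat[i, , drop = FALSE], kt)
    nn <- near_normal[i]
    pt[nn, ] <- p[i, , drop = FALSE][nn, , drop = FALSE]
    p_new[i, ] <- normalize_rows(pt)
  }
  list(k = k_new, p = p_new, reflected = reflected, R = R)
}

#' Reflect or refract photons at a material interface
#'
#' For each photon a uniform variate is compared with its Fresnel
#' reflectivity: photons with `u <= R` are mirror-reflected, the rest cross
#' the interface following Snell's law in vector form. In both cases the
#' polarization is decomposed into components perpendicular and parallel to
#' the plane of incidence and reassembled perpendicular to the new direction.
#' Transmitted photons must have their path length resampled in the new
#' medium (the main loop does this by clearing `d_pending`).
#'
#' @param batch A [photon_batch()] whose photons sit on an interface.
#' @param normal `n x 3` matrix of unit normals pointing into the incidence
#'   medium.
#' @param n1,n2 Refractive indices (scalar or per photon).
#' @param u Optional uniform variates (drawn internally if missing).
#' @return The updated batch plus an attribute `"reflected"` (logical).
#' @export
reflect_or_refract <- function(batch, normal, n1, n2, u = NULL) {
  n <- nrow(batch$k)
  if (is.null(u)) u <- stats::runif(n)
  res <- interface_kernel(batch$k, batch$p, normal,
                          rep_len(n1, n), rep_len(n2, n), u)
  batch$k <- res$k
  batch$p <- res$p
  batch$d_pending[!res$reflected] <- NA_real_
  attr(batch, "reflected") <- res$reflected
  batch
}

# Scattering kernel: given incident k, p and sampled angles, returns the new
# direction and polarization. The azimuth phi is measured in the plane
# perpendicular to k such that phi = 0 puts the scattering plane
# perpendicular to the current polarization (the perpendicular/`Ps` case) and
# phi = pi/2 puts the polarization in the scattering plane (`Pp`), matching
# the cos^2/sin^2 weighting the azimuth was sampled from. The scattered
# polarization is the renormalized resultant of the incident s/p components
# scaled by the field amplitudes |S1(theta)| and |S2(theta)|.
#' @noRd
scatter_kernel <- function(k, p, theta, phi, sampler) {
  e1 <- cross_rows(k, p)                 # phi = 0 axis (perpendicular case)
  st <- sin(theta)
  ct <- cos(theta)
  trans <- cos(phi) * e1 + sin(phi) * p
  k_out <- ct * k + st * trans
  k_out <- normalize_rows(k_out)

  # amplitudes at theta (linear interpolation on the stored grid)
  gt <- sampler$amp_theta
  ii <- findInterval(theta, gt, all.inside = TRUE)
  wfr <- (theta - gt[ii]) / (gt[ii + 1] - gt[ii])
  a_s <- sampler$amp_s[ii] * (1 - wfr) + sampler$amp_s[ii + 1] * wfr
  a_p <- sampler$amp_p[ii] * (1 - wfr) + sampler$amp_p[ii + 1] * wfr

  s <- cross_rows(k, k_out)
  sn <- norm_rows(s)
  deg <- sn < 1e-9                        # forward/backward: plane undefined
  shat <- s
  shat[!deg, ] <- s[!deg, , drop = FALSE] / sn[!deg]
  E_s <- dot_rows(p, shat)
  h_in <- cross_rows(shat, k)
  E_h <- dot_rows(p, h_in)
  p_out <- a_s * E_s * shat + a_p * E_h * cross_rows(shat, k_out)
  if (any(deg)) {
    pd <- p[deg, , drop = FALSE] -
      dot_rows(p[deg, , drop = FALSE], k_out[deg, , drop = FALSE]) *
      k_out[deg, , drop = FALSE]
    p_out[deg, ] <- pd
  }
  nr <- norm_rows(p_out)
  tiny <- nr < 1e-12
  if (any(tiny)) {
    # fully crossed polarization: rebuild any perpendicular vector
    p_out[tiny, ] <- project_polarization(
      matrix(c(0, 1, 0), sum(tiny), 3, byrow = TRUE),
      k_out[tiny, , drop = FALSE])
    nr[tiny] <- 1
  }
  p_out <- p_out / nr
  # guard against accumulated loss of orthogonality
  p_out <- p_out - dot_rows(p_out, k_out) * k_out
  p_out <- normalize_rows(p_out)
  list(k = k_out, p = p_out)
}

#' Scatter photons and update their Doppler shifts
#'
#' Draws scattering angles from the medium's sampler, rotates direction and
#' polarization, and, when a flow field is present, increments the cumulative
#' Doppler shift by `-v . q` with momentum transfer
#' `q = (n / lambda) (k_in - k_out)` and `v` the deterministic flow at the
#' scattering site plus an isotropic Brownian sample.
#'
#' @param batch A [photon_batch()] whose photons are at scatter sites.
#' @param sampler A [build_scatter_sampler()] result.
#' @param flow Optional [flow_field()] (`NULL` for a static medium).
#' @param n_medium Refractive index of the scattering medium.
#' @param wavelength Vacuum wavelength in metres.
#' @param u Optional `n x 4` matrix of uniforms (azimuth, angle, two for the
#'   Brownian direction); drawn internally if missing.
#' @return The updated batch (`k`, `p`, `fD`, `n_scat`; `d_pending` cleared).
#' @export
scatter_photons <- function(batch, sampler, flow = NULL, n_medium = 1.33,
                            wavelength = 633e-9, u = NULL) {
  n <- nrow(batch$k)
  if (is.null(u)) u <- matrix(stats::runif(4 * n), n, 4)
  ang <- sample_angles(sampler, u[, 1], u[, 2])
  res <- scatter_kernel(batch$k, batch$p, ang$theta, ang$phi, sampler)
  if (!is.null(flow)) {
    v <- flow$velocity_fn(batch$r)
    if (flow$brownian_speed > 0) {
      v <- v + brownian_from_uniforms(flow$brownian_speed, u[, 3], u[, 4])
    }
    q <- (n_medium / wavelength) * (batch$k - res$k)
    batch$fD <- batch$fD - dot_rows(v, q)
  }
  batch$k <- res$k
  batch$p <- res$p
  batch$n_scat <- batch$n_scat + 1L
  batch$d_pending <- rep(NA_real_, n)
  batch
}

#' Extract detector records from photons on the detector plane
#'
#' Photons within `diameter / 2` of the detector center are marked detected;
#' the returned data frame keeps the columns selected by the detector's
#' `save_fields` and applies its `selection` predicate.
#'
#' @param batch A [photon_batch()] whose photons lie on the detector plane.
#' @param detector A [detector_spec()].
#' @return A list with `records` (data frame) and `hit` (logical per photon).
#' @export
detect_photons <- function(batch, detector) {
  n <- nrow(batch$r)
  d <- batch$r - row3(detector$center, n)
  d_ax <- dot_rows(d, row3(detector$normal, n))
  rad2 <- rowSums(d * d) - d_ax^2
  hit <- rad2 <= (detector$diameter / 2)^2
  records <- records_from_batch(batch, which(hit))
  if (!is.null(detector$selection)) {
    records <- records[detector$selection(records), , drop = FALSE]
  }
  keep <- c(
    if ("position" %in% detector$save_fields) c("x", "y", "z"),
    if ("direction" %in% detector$save_fields) c("kx", "ky", "kz"),
    if ("polarization" %in% detector$save_fields) c("px", "py", "pz"),
    if ("weight" %in% detector$save_fields) "weight",
    if ("doppler" %in% detector$save_fields) "fD_Hz",
    if ("n_scatter" %in% detector$save_fields) "n_scat")
  list(records = records[, keep, drop = FALSE], hit = hit)
}

#' @noRd
records_from_batch <- function(batch, idx) {
  data.frame(x = batch$r[idx, 1], y = batch$r[idx, 2], z = batch$r[idx, 3],
             kx = batch$k[idx, 1], ky = batch$k[idx, 2], kz = batch$k[idx, 3],
             px = batch$p[idx, 1], py = batch$p[idx, 2], pz = batch$p[idx, 3],
             weight = batch$w[idx], fD_Hz = batch$fD[idx],
             n_scat = batch$n_scat[idx])
}
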