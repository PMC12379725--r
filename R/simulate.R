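# Batched Monte Carlo main loop: sample path -> propagate to the nearest of
# (material interface, scatter site, detector plane, simulation boundary) ->
# absorb -> handle the event -> roulette, until every photon of the batch is
# detected, escaped or absorbed.
#
# Random number protocol: at the start of every iteration a fixed block of 7
# uniforms per alive photon is drawn (columns: path length, interface draw,
# scattering azimuth, scattering angle, two Brownian-direction uniforms,
# roulette draw), whether or not each is consumed. This makes the stream a
# pure function of (seed, iteration, photon index), so a per-photon reference
# loop sharing the stream reproduces the batched trajectories exactly.

# locate_medium without the boundary error: out-of-boundary -> ambient
#' @noRd
locate_medium_safe <- function(sc, P) {
  idx <- integer(nrow(P))
  inb <- in_boundary(P, sc$boundary)
  if (any(inb)) {
    idx[inb] <- locate_medium(sc, P[inb, , drop = FALSE])
  }
  idx
}

# flat list of material surfaces: cylinders contribute one surface, slabs two
#' @noRd
scene_surfaces <- function(sc) {
  surfs <- list()
  for (i in seq_along(sc$media)) {
    sh <- sc$media[[i]]$shape
    if (inherits(sh, "cylinder")) {
      surfs[[length(surfs) + 1]] <- list(type = "cyl", shape = sh, medium = i)
    } else {
      surfs[[length(surfs) + 1]] <- list(type = "plane", normal = sh$normal,
                                         offset = sh$plane_offset, medium = i)
      surfs[[length(surfs) + 1]] <- list(type = "plane", normal = sh$normal,
                                         offset = sh$plane_offset + sh$thickness,
                                         medium = i)
    }
  }
  surfs
}

#' Advance photons one propagation step
#'
#' Moves each alive photon to the nearest of: the closest intersected
#' material interface, the endpoint of its sampled path (a scatter site), the
#' detector plane, or the simulation boundary. Escaped photons are marked;
#' `d_pending` is decremented by the travelled distance.
#'
#' @param batch A [photon_batch()] with `d_pending` sampled (alive photons).
#' @param sc A [scene()].
#' @param tol Minimum surface distance accepted, excluding the surface a
#'   photon currently sits on (metres).
#' @return A list: `batch` (moved), `event` (per alive photon, one of
#'   `"interface"`, `"scatter_site"`, `"det_plane"`, `"boundary_escape"`,
#'   `"stuck"`), `alive_idx`, `dist` travelled, and `surf_id` of the hit
#'   surface (0 when none).
#' @export
propagate_step <- function(batch, sc, tol = 1e-10) {
  a <- which(batch$status == ST_ALIVE)
  n <- length(a)
  if (n == 0) {
    return(list(batch = batch, event = character(0), alive_idx = integer(0),
                dist = numeric(0), surf_id = integer(0)))
  }
  O <- batch$r[a, , drop = FALSE]
  D <- batch$k[a, , drop = FALSE]
  surfs <- scene_surfaces(sc)

  t_surf <- rep(Inf, n)
  surf_id <- integer(n)
  for (s in seq_along(surfs)) {
    sf <- surfs[[s]]
    ts <- if (sf$type == "cyl") {
      ray_cylinder_t(O, D, sf$shape, tol)[, 1]
    } else {
      ray_plane_t(O, D, sf$normal, sf$offset, tol)
    }
    upd <- ts < t_surf
    t_surf[upd] <- ts[upd]
    surf_id[upd] <- s
  }
  t_bnd <- ray_boundary_t(O, D, sc$boundary, tol)
  det <- sc$detector
  dn <- drop(D %*% det$normal)
  t_det <- ray_plane_t(O, D, det$normal, sum(det$center * det$normal), tol)
  t_det[dn <= 0] <- Inf
  d_p <- batch$d_pending[a]

  t_ev <- pmin(t_surf, t_bnd, t_det, d_p)
  ev <- rep("scatter_site", n)
  ev[t_bnd == t_ev] <- "boundary_escape"
  ev[t_det == t_ev] <- "det_plane"
  ev[t_surf == t_ev] <- "interface"
  ev[!is.finite(t_ev)] <- "stuck"

  fin <- is.finite(t_ev)
  batch$r[a[fin], ] <- O[fin, , drop = FALSE] + t_ev[fin] * D[fin, , drop = FALSE]
  batch$d_pending[a[fin]] <- d_p[fin] - t_ev[fin]
  batch$status[a[ev == "boundary_escape"]] <- ST_ESCAPED
  dist <- ifelse(fin, t_ev, 0)
  list(batch = batch, event = ev, alive_idx = a, dist = dist,
       surf_id = surf_id)
}

# Run one emitted batch to completion. Returns the final batch plus tallies.
#' @noRd
transport_batch <- function(sc, batch, cfg = roulette_config(),
                            max_iter = 2000, tol = 1e-10) {
  media <- sc$media
  n_vec <- c(sc$ambient_n, vapply(media, `[[`, numeric(1), "n"))
  mus_vec <- c(0, vapply(media, `[[`, numeric(1), "mus_si"))
  mua_vec <- c(0, vapply(media, `[[`, numeric(1), "mua_si"))
  surfs <- scene_surfaces(sc)
  det <- sc$detector
  det_off <- sum(det$center * det$normal)
  lam <- sc$source$wavelength
  det_r2 <- (det$diameter / 2)^2

  absorbed_medium_w <- 0
  roulette_w <- 0
  n_steps <- 0
  iter <- 0

  repeat {
    a <- which(batch$status == ST_ALIVE)
    n <- length(a)
    if (n == 0 || iter >= max_iter) break
    iter <- iter + 1
    n_steps <- n_steps + n
    U <- matrix(stats::runif(7 * n), n, 7)

    # fresh path lengths where needed
    mus_a <- mus_vec[batch$medium[a] + 1L]
    need <- is.na(batch$d_pending[a])
    if (any(need)) {
      batch$d_pending[a[need]] <-
        ifelse(mus_a[need] > 0, -log1p(-U[need, 1]) / mus_a[need], Inf)
    }

    O <- batch$r[a, , drop = FALSE]
    D <- batch$k[a, , drop = FALSE]
    t_surf <- rep(Inf, n)
    surf_id <- integer(n)
    for (s in seq_along(surfs)) {
      sf <- surfs[[s]]
      ts <- if (sf$type == "cyl") {
        ray_cylinder_t(O, D, sf$shape, tol)[, 1]
      } else {
        ray_plane_t(O, D, sf$normal, sf$offset, tol)
      }
      upd <- ts < t_surf
      t_surf[upd] <- ts[upd]
      surf_id[upd] <- s
    }
    t_bnd <- ray_boundary_t(O, D, sc$boundary, tol)
    dn <- drop(D %*% det$normal)
    t_det <- ray_plane_t(O, D, det$normal, det_off, tol)
    t_det[dn <= 0] <- Inf
    d_p <- batch$d_pending[a]

    t_ev <- pmin(t_surf, t_bnd, t_det, d_p)
    ev <- rep(4L, n)                      # 1 iface, 2 det, 3 bnd, 4 scatter
    ev[t_bnd == t_ev] <- 3L
    ev[t_det == t_ev] <- 2L
    ev[t_surf == t_ev] <- 1L
    stuck <- !is.finite(t_ev)
    ev[stuck] <- 5L

    fin <- !stuck
    batch$r[a[fin], ] <- O[fin, , drop = FALSE] +
      t_ev[fin] * D[fin, , drop = FALSE]
    batch$d_pending[a] <- d_p - ifelse(fin, t_ev, 0)

    # Lambert-Beer absorption over the travelled segment
    mua_a <- mua_vec[batch$medium[a] + 1L]
    decay <- exp(-mua_a * ifelse(fin, t_ev, 0))
    w_old <- batch$w[a]
    batch$w[a] <- w_old * decay
    absorbed_medium_w <- absorbed_medium_w + sum(w_old - batch$w[a])

    batch$status[a[ev == 5L]] <- ST_STALLED
    batch$status[a[ev == 3L]] <- ST_ESCAPED

    # detector plane crossings
    i_det <- which(ev == 2L)
    if (length(i_det)) {
      idx <- a[i_det]
      dvec <- batch$r[idx, , drop = FALSE] - row3(det$center, length(idx))
      dax <- drop(dvec %*% det$normal)
      hit <- rowSums(dvec * dvec) - dax^2 <= det_r2
      batch$status[idx[hit]] <- ST_DETECTED
    }

    # material interfaces
    i_if <- which(ev == 1L)
    if (length(i_if)) {
      idx <- a[i_if]
      P <- batch$r[idx, , drop = FALSE]
      K <- batch$k[idx, , drop = FALSE]
      nrm <- matrix(0, length(idx), 3)
      for (s in unique(surf_id[i_if])) {
        rows <- which(surf_id[i_if] == s)
        sf <- surfs[[s]]
        g <- if (sf$type == "cyl") {
          shape_normal_at(P[rows, , drop = FALSE], sf$shape)
        } else {
          matrix(sf$normal, length(rows), 3, byrow = TRUE)
        }
        flip <- dot_rows(K[rows, , drop = FALSE], g) > 0
        g[flip, ] <- -g[flip, , drop = FALSE]
        nrm[rows, ] <- g
      }
      n1 <- n_vec[batch$medium[idx] + 1L]
      other <- locate_medium_safe(sc, P + 1e-9 * K)
      n2 <- n_vec[other + 1L]
      res <- interface_kernel(K, batch$p[idx, , drop = FALSE], nrm, n1, n2,
                              U[i_if, 2])
      batch$k[idx, ] <- res$k
      batch$p[idx, ] <- res$p
      tr <- !res$reflected
      batch$medium[idx[tr]] <- other[tr]
      batch$d_pending[idx[tr]] <- NA_real_
    }

    # scattering with polarization and Doppler updates
    i_sc <- which(ev == 4L)
    if (length(i_sc)) {
      for (m in unique(batch$medium[a[i_sc]])) {
        rows <- i_sc[batch$medium[a[i_sc]] == m]
        idx <- a[rows]
        med <- media[[m]]
        if (is.null(med$sampler)) {
          stop_invalid("medium %d scatters (mus > 0) but has no sampler", m)
        }
        ang <- sample_angles(med$sampler, U[rows, 3], U[rows, 4])
        res <- scatter_kernel(batch$k[idx, , drop = FALSE],
                              batch$p[idx, , drop = FALSE],
                              ang$theta, ang$phi, med$sampler)
        if (!is.null(med$flow)) {
          v <- med$flow$velocity_fn(batch$r[idx, , drop = FALSE])
          if (med$flow$brownian_speed > 0) {
            v <- v + brownian_from_uniforms(med$flow$brownian_speed,
                                            U[rows, 5], U[rows, 6])
          }
          q <- (med$n / lam) * (batch$k[idx, , drop = FALSE] - res$k)
          batch$fD[idx] <- batch$fD[idx] - dot_rows(v, q)
        }
        batch$k[idx, ] <- res$k
        batch$p[idx, ] <- res$p
        batch$n_scat[idx] <- batch$n_scat[idx] + 1L
        batch$d_pending[idx] <- NA_real_
      }
    }

    # Russian roulette on still-alive low-weight photons
    if (cfg$w_min > 0) {
      cand <- which(batch$status[a] == ST_ALIVE & batch$w[a] < cfg$w_min)
      if (length(cand)) {
        idx <- a[cand]
        survive <- U[cand, 7] <= cfg$survival_prob
        if (cfg$conserving) {
          batch$w[idx[survive]] <- batch$w[idx[survive]] / cfg$survival_prob
        } else {
          batch$w[idx[survive]] <- cfg$w_revive
        }
        roulette_w <- roulette_w + sum(batch$w[idx[!survive]])
        batch$status[idx[!survive]] <- ST_ABSORBED
      }
    }
  }

  list(batch = batch, absorbed_medium_w = absorbed_medium_w,
       roulette_w = roulette_w, n_steps = n_steps, n_iter = iter)
}

#' Run a Monte Carlo simulation
#'
#' Launches photon batches from the scene's source and propagates them until
#' a stop criterion is met: a target number of detected photons or a cap on
#' launched photons. Identical `seed` and configuration give identical
#' detector records.
#'
#' @param sc A [scene()]; every medium with `mus > 0` must carry a sampler.
#' @param stop A list with `n_detected` (target) and/or `n_launched` (cap).
#' @param seed Integer seed for the run (`NULL` leaves the RNG state alone).
#' @param cfg A [roulette_config()].
#' @param batch_size Photons launched per batch (default 20000).
#' @param max_iter Iteration cap per batch; photons still alive afterwards
#'   are tallied as stalled (default 2000).
#' @param tol Surface tolerance in metres used by the stepper.
#' @return A `doppler_run` list: `records` (data frame of detected photons,
#'   columns filtered by the detector's `save_fields` and `selection`) and
#'   `manifest` (seed, parameters and launched / detected / escaped /
#'   absorbed counts and weights).
#' @examples
#' \donttest{
#' sc <- reference_scene(mus = 1)
#' run <- run_simulation(sc, stop = list(n_detected = 500), seed = 1)
#' run$manifest$n_detected
#' }
#' @export
run_simulation <- function(sc, stop = list(n_detected = 10000), seed = NULL,
                           cfg = roulette_config(), batch_size = 20000,
                           max_iter = 2000, tol = 1e-10) {
  stopifnot(inherits(sc, "scene"))
  target <- stop$n_detected
  cap <- stop$n_launched
  if (is.null(target) && is.null(cap)) {
    stop_invalid("`stop` must give `n_detected` and/or `n_launched`")
  }
  if (!is.null(target) && target <= 0) stop_invalid("stop criterion must be positive")
  if (!is.null(cap) && cap <= 0) stop_invalid("stop criterion must be positive")
  for (i in seq_along(sc$media)) {
    m <- sc$media[[i]]
    if (m$mus > 0 && is.null(m$sampler)) {
      stop_invalid("medium %d has mus > 0 but no scatter sampler", i)
    }
  }
  if (!is.null(seed)) set.seed(seed)

  tal <- list(launched_n = 0, launched_w = 0, detected_n = 0, detected_w = 0,
              escaped_n = 0, escaped_w = 0, roulette_n = 0, roulette_w = 0,
              absorbed_medium_w = 0, stalled_n = 0, stalled_w = 0,
              n_steps = 0, n_batches = 0)
  rec_list <- list()

  repeat {
    n_batch <- batch_size
    if (!is.null(cap)) n_batch <- min(n_batch, cap - tal$launched_n)
    if (n_batch <= 0) break
    batch <- emit_photons(sc$source, n_batch)
    batch$medium <- locate_medium(sc, batch$r)
    res <- transport_batch(sc, batch, cfg, max_iter, tol)
    b <- res$batch

    det <- b$status == ST_DETECTED
    esc <- b$status == ST_ESCAPED
    abs_ <- b$status == ST_ABSORBED
    stl <- b$status %in% c(ST_STALLED, ST_ALIVE)
    tal$launched_n <- tal$launched_n + n_batch
    tal$launched_w <- tal$launched_w + n_batch
    tal$detected_n <- tal$detected_n + sum(det)
    tal$detected_w <- tal$detected_w + sum(b$w[det])
    tal$escaped_n <- tal$escaped_n + sum(esc)
    tal$escaped_w <- tal$escaped_w + sum(b$w[esc])
    tal$roulette_n <- tal$roulette_n + sum(abs_)
    tal$roulette_w <- tal$roulette_w + res$roulette_w
    tal$absorbed_medium_w <- tal$absorbed_medium_w + res$absorbed_medium_w
    tal$stalled_n <- tal$stalled_n + sum(stl)
    tal$stalled_w <- tal$stalled_w + sum(b$w[stl])
    tal$n_steps <- tal$n_steps + res$n_steps
    tal$n_batches <- tal$n_batches + 1

    if (any(det)) {
      rec_list[[length(rec_list) + 1]] <- records_from_batch(b, which(det))
    }
    if (!is.null(target) && tal$detected_n >= target) break
    if (!is.null(cap) && tal$launched_n >= cap) break
  }

  records <- if (length(rec_list)) do.call(rbind, rec_list) else
    records_from_batch(photon_batch(matrix(0, 0, 3), matrix(0, 0, 3),
                                    matrix(0, 0, 3)), integer(0))
  # the last batch may overshoot an n_detected target; keep exactly the
  # requested number of records (tallies still describe the full run)
  if (!is.null(target) && nrow(records) > target) {
    records <- records[seq_len(target), , drop = FALSE]
  }
  if (nrow(records) == 0) {
    warning("no photons detected before the stop criterion; returning partial results")
  }
  detector <- sc$detector
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
  records <- records[, keep, drop = FALSE]

  manifest <- c(list(seed = seed, wavelength = sc$source$wavelength,
                     stop = stop, batch_size = batch_size,
                     max_iter = max_iter, tol = tol,
                     roulette = unclass(cfg),
                     n_media = length(sc$media),
                     mus_mm1 = vapply(sc$media, `[[`, numeric(1), "mus"),
                     mua_mm1 = vapply(sc$media, `[[`, numeric(1), "mua"),
                     package_version =
                       as.character(utils::packageVersion("dopplerMC"))),
                tal)
  names(manifest)[names(manifest) == "detected_n"] <- "n_detected"
  names(manifest)[names(manifest) == "launched_n"] <- "n_launched"
  structure(list(records = records, manifest = manifest),
            class = "doppler_run")
}

#' @export
print.doppler_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<doppler_run> launched %d, detected %d (w = %.4g), escaped %d, roulette-absorbed %d\n",
              m$n_launched, m$n_detected, m$detected_w, m$escaped_n,
              m$roulette_n))
  invisible(x)
}
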