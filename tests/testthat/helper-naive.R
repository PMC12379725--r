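# Naive per-photon reference implementation of the transport loop. It
# processes one photon at a time (1-row matrices throughout) but shares the
# random-number protocol of the batched engine: per round, a 7-column uniform
# block for the alive photons in index order. Trajectories must match the
# batched engine exactly.

naive_transport <- function(sc, batch, cfg = roulette_config(),
                            max_iter = 2000, tol = 1e-10) {
  surfs <- dopplerMC:::scene_surfaces(sc)
  media <- sc$media
  n_vec <- c(sc$ambient_n, vapply(media, `[[`, numeric(1), "n"))
  mus_vec <- c(0, vapply(media, `[[`, numeric(1), "mus_si"))
  mua_vec <- c(0, vapply(media, `[[`, numeric(1), "mua_si"))
  det <- sc$detector
  det_off <- sum(det$center * det$normal)
  det_r2 <- (det$diameter / 2)^2
  lam <- sc$source$wavelength
  ST_ALIVE <- 0L; ST_DETECTED <- 1L; ST_ESCAPED <- 2L
  ST_ABSORBED <- 3L; ST_STALLED <- 4L

  iter <- 0
  repeat {
    a <- which(batch$status == ST_ALIVE)
    if (length(a) == 0 || iter >= max_iter) break
    iter <- iter + 1
    U <- matrix(stats::runif(7 * length(a)), length(a), 7)

    for (pos in seq_along(a)) {
      i <- a[pos]
      u <- U[pos, ]
      mus <- mus_vec[batch$medium[i] + 1L]
      if (is.na(batch$d_pending[i])) {
        batch$d_pending[i] <- if (mus > 0) -log1p(-u[1]) / mus else Inf
      }
      O <- batch$r[i, , drop = FALSE]
      D <- batch$k[i, , drop = FALSE]

      t_surf <- Inf
      surf_hit <- 0L
      for (s in seq_along(surfs)) {
        sf <- surfs[[s]]
        ts <- if (sf$type == "cyl") {
          dopplerMC:::ray_cylinder_t(O, D, sf$shape, tol)[, 1]
        } else {
          dopplerMC:::ray_plane_t(O, D, sf$normal, sf$offset, tol)
        }
        if (ts < t_surf) {
          t_surf <- ts
          surf_hit <- s
        }
      }
      t_bnd <- dopplerMC:::ray_boundary_t(O, D, sc$boundary, tol)
      dn <- sum(D * det$normal)
      t_det <- dopplerMC:::ray_plane_t(O, D, det$normal, det_off, tol)
      if (dn <= 0) t_det <- Inf
      d_p <- batch$d_pending[i]

      t_ev <- min(t_surf, t_bnd, t_det, d_p)
      ev <- 4L
      if (t_bnd == t_ev) ev <- 3L
      if (t_det == t_ev) ev <- 2L
      if (t_surf == t_ev) ev <- 1L
      if (!is.finite(t_ev)) ev <- 5L

      if (is.finite(t_ev)) {
        batch$r[i, ] <- O + t_ev * D
        batch$d_pending[i] <- d_p - t_ev
      }
      mua <- mua_vec[batch$medium[i] + 1L]
      batch$w[i] <- batch$w[i] * exp(-mua * (if (is.finite(t_ev)) t_ev else 0))

      if (ev == 5L) batch$status[i] <- ST_STALLED
      if (ev == 3L) batch$status[i] <- ST_ESCAPED
      if (ev == 2L) {
        dv <- batch$r[i, ] - det$center
        dax <- sum(dv * det$normal)
        if (sum(dv * dv) - dax^2 <= det_r2) batch$status[i] <- ST_DETECTED
      }
      if (ev == 1L) {
        P <- batch$r[i, , drop = FALSE]
        K <- batch$k[i, , drop = FALSE]
        sf <- surfs[[surf_hit]]
        g <- if (sf$type == "cyl") {
          dopplerMC:::shape_normal_at(P, sf$shape)
        } else {
          matrix(sf$normal, 1, 3)
        }
        if (sum(K * g) > 0) g <- -g
        n1 <- n_vec[batch$medium[i] + 1L]
        other <- dopplerMC:::locate_medium_safe(sc, P + 1e-9 * K)
        n2 <- n_vec[other + 1L]
        res <- dopplerMC:::interface_kernel(K, batch$p[i, , drop = FALSE],
                                            g, n1, n2, u[2])
        batch$k[i, ] <- res$k
        batch$p[i, ] <- res$p
        if (!res$reflected) {
          batch$medium[i] <- other
          batch$d_pending[i] <- NA_real_
        }
      }
      if (ev == 4L) {
        med <- media[[batch$medium[i]]]
        ang <- sample_angles(med$sampler, u[3], u[4])
        res <- dopplerMC:::scatter_kernel(batch$k[i, , drop = FALSE],
                                          batch$p[i, , drop = FALSE],
                                          ang$theta, ang$phi, med$sampler)
        if (!is.null(med$flow)) {
          v <- med$flow$velocity_fn(batch$r[i, , drop = FALSE])
          if (med$flow$brownian_speed > 0) {
            v <- v + dopplerMC:::brownian_from_uniforms(
              med$flow$brownian_speed, u[5], u[6])
          }
          q <- (med$n / lam) * (batch$k[i, , drop = FALSE] - res$k)
          batch$fD[i] <- batch$fD[i] - sum(v * q)
        }
        batch$k[i, ] <- res$k
        batch$p[i, ] <- res$p
        batch$n_scat[i] <- batch$n_scat[i] + 1L
        batch$d_pending[i] <- NA_real_
      }
      if (cfg$w_min > 0 && batch$status[i] == ST_ALIVE &&
          batch$w[i] < cfg$w_min) {
        if (u[7] <= cfg$survival_prob) {
          batch$w[i] <- if (cfg$conserving) {
            batch$w[i] / cfg$survival_prob
          } else {
            cfg$w_revive
          }
        } else {
          batch$status[i] <- ST_ABSORBED
        }
      }
    }
  }
  batch
}
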