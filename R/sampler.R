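# Inverse-CDF samplers for the polarization-resolved phase function.
#
# The scattering azimuth phi (measured from the photon polarization direction
# in the plane perpendicular to propagation) has marginal density proportional
# to the integral of P(theta, phi) sin(theta) over theta; because
# P(theta, phi) = cos^2(phi) Ps + sin^2(phi) Pp this reduces to
# cos^2(phi) As + sin^2(phi) Ap with As, Ap the solid-angle weighted integrals
# of the two tables. The conditional theta distribution at each azimuth node
# is inverted once onto a dense uniform u-grid, giving a matrix that can be
# interpolated bilinearly at sampling time; monotone piecewise-cubic
# interpolation of the exactly integrated CDF is used for the inversion, so
# every inverse CDF is nondecreasing by construction. The sin(theta)
# solid-angle Jacobian is always included when forming densities: omitting it
# would bias sampling on the sphere.

#' Build inverse-CDF samplers for scattering angles
#'
#' Converts a polarization-resolved phase function table into samplers for the
#' scattering azimuth `phi` (relative to the photon polarization direction)
#' and the conditional scattering angle `theta` given `phi`.
#'
#' @param table A [phase_table] object.
#' @param n_phi_nodes Number of azimuth nodes for the conditional theta
#'   inverse CDFs (between 100 and 1000; default 360).
#' @param n_u Resolution of the uniform quantile grid each conditional inverse
#'   CDF is tabulated on (default 8193).
#' @return A `scatter_sampler` object with elements `azimuth_icdf` (a
#'   monotone function `[0,1] -> [0, 2*pi)`), `theta_icdf` (an
#'   `n_u x n_phi_nodes` matrix of theta quantiles), `phi_nodes`, `u_grid`,
#'   `g` (anisotropy of the unpolarized table, by quadrature) and `norm`
#'   (the solid-angle integral of the unnormalized table).
#' @examples
#' tab <- mie_phase_functions(1e-6, 1.586, 1.33, 633e-9, K = 361)
#' smp <- build_scatter_sampler(tab, n_phi_nodes = 120)
#' sample_angles(smp, 0.3, 0.7)
#' @export
build_scatter_sampler <- function(table, n_phi_nodes = 360, n_u = 8193) {
  stopifnot(inherits(table, "phase_table"))
  if (n_phi_nodes < 100 || n_phi_nodes > 1000) {
    stop_invalid("`n_phi_nodes` must lie in [100, 1000]")
  }
  theta <- table$theta
  st <- sin(theta)
  As <- trapz(theta, table$Ps * st)
  Ap <- trapz(theta, table$Pp * st)
  if (As + Ap <= 0) stop_invalid("phase function table is identically zero")

  # azimuth marginal: cos^2(phi) As + sin^2(phi) Ap, on a fine grid
  phi_fine <- seq(0, 2 * pi, length.out = 4 * n_phi_nodes + 1)
  pdf_phi <- cos(phi_fine)^2 * As + sin(phi_fine)^2 * Ap
  cdf_phi <- cumtrapz(phi_fine, pdf_phi)
  cdf_phi <- cdf_phi / cdf_phi[length(cdf_phi)]
  keep <- c(TRUE, diff(cdf_phi) > 0)
  azimuth_icdf <- stats::splinefun(cdf_phi[keep], phi_fine[keep],
                                   method = "monoH.FC")

  # conditional theta inverse CDFs, one column per azimuth node
  phi_nodes <- seq(0, 2 * pi, length.out = n_phi_nodes + 1)[seq_len(n_phi_nodes)]
  u_grid <- seq(0, 1, length.out = n_u)
  theta_icdf <- matrix(0, nrow = n_u, ncol = n_phi_nodes)
  for (j in seq_len(n_phi_nodes)) {
    pdf_t <- combined_phase(table, phi_nodes[j]) * st
    cdf_t <- cumtrapz(theta, pdf_t)
    cdf_t <- cdf_t / cdf_t[length(cdf_t)]
    keep <- c(TRUE, diff(cdf_t) > 0)
    fn <- stats::splinefun(cdf_t[keep], theta[keep], method = "monoH.FC")
    theta_icdf[, j] <- pmin(pmax(fn(u_grid), 0), pi)
  }
  theta_icdf[1, ] <- 0
  theta_icdf[n_u, ] <- pi

  g <- trapz(theta, (table$Ps + table$Pp) * st * cos(theta)) / (As + Ap)

  structure(list(azimuth_icdf = azimuth_icdf,
                 theta_icdf = theta_icdf,
                 phi_nodes = phi_nodes,
                 n_phi_nodes = n_phi_nodes,
                 u_grid = u_grid,
                 g = g,
                 norm = pi * (As + Ap),
                 # scattered-field amplitude tables for polarization updates
                 amp_theta = theta,
                 amp_s = sqrt(table$Ps),
                 amp_p = sqrt(table$Pp)),
            class = "scatter_sampler")
}

#' @export
print.scatter_sampler <- function(x, ...) {
  cat(sprintf("<scatter_sampler> %d azimuth nodes, %d quantile nodes, g = %.4f\n",
              x$n_phi_nodes, length(x$u_grid), x$g))
  invisible(x)
}

#' Draw scattering angles from a sampler
#'
#' Deterministically maps a pair of uniform variates to a scattering azimuth
#' and angle: `phi = azimuth_icdf(u1)` and `theta` interpolated bilinearly in
#' the conditional inverse-CDF table at (`phi`, `u2`).
#'
#' @param sampler A [build_scatter_sampler()] result.
#' @param u1,u2 Uniform variates in `[0, 1]` (vectorized; recycled to a common
#'   length).
#' @return A list with numeric vectors `theta` and `phi` (radians).
#' @export
sample_angles <- function(sampler, u1, u2) {
  stopifnot(inherits(sampler, "scatter_sampler"))
  n <- max(length(u1), length(u2))
  u1 <- rep_len(pmin(pmax(u1, 0), 1), n)
  u2 <- rep_len(pmin(pmax(u2, 0), 1), n)

  phi <- sampler$azimuth_icdf(u1)
  phi <- pmin(pmax(phi, 0), 2 * pi * (1 - 1e-15)) # wrap top end onto [0, 2pi)

  np <- sampler$n_phi_nodes
  dphi <- 2 * pi / np
  jf <- phi / dphi
  j0 <- pmin(floor(jf), np - 1)          # 0-based node index
  wj <- jf - j0
  j1 <- (j0 + 1) %% np                   # wraps 2*pi back to node 0

  nu <- length(sampler$u_grid)
  uf <- u2 * (nu - 1)
  i0 <- pmin(floor(uf), nu - 2)          # 0-based quantile index
  wi <- uf - i0

  M <- sampler$theta_icdf
  idx <- function(i, j) M[cbind(i + 1L, j + 1L)]
  th0 <- idx(i0, j0) * (1 - wi) + idx(i0 + 1, j0) * wi
  th1 <- idx(i0, j1) * (1 - wi) + idx(i0 + 1, j1) * wi
  theta <- th0 * (1 - wj) + th1 * wj
  list(theta = theta, phi = phi)
}
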