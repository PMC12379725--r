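# Mie theory for homogeneous spheres: scattering coefficients a_n, b_n by the
# Bohren & Huffman recurrences (logarithmic derivative downward, Riccati-Bessel
# functions upward), amplitude functions S1/S2 via the pi_n/tau_n angular
# recurrences, and the derived quantities Q_sca, C_sca and the asymmetry g.

# Mie expansion coefficients for relative index m and size parameter x.
#' @noRd
mie_coefficients <- function(m, x) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  # logarithmic derivative D_n(mx) by downward recurrence
  nmx <- max(nmax, ceiling(abs(m * x))) + 16
  mx <- m * x
  D <- numeric(nmx + 1)
  for (i in nmx:1) {
    D[i] <- i / mx - 1 / (D[i + 1] + i / mx)
  }
  D <- D[2:(nmax + 1)]

  a <- complex(nmax)
  b <- complex(nmax)
  # Riccati-Bessel psi_n(x), chi_n(x), upward from orders 0 and 1
  psi_nm1 <- sin(x)
  chi_nm1 <- cos(x)
  psi_n <- sin(x) / x - cos(x)
  chi_n <- cos(x) / x + sin(x)
  for (k in seq_len(nmax)) {
    if (k > 1) {
      psi_np1 <- (2 * k - 1) / x * psi_n - psi_nm1
      chi_np1 <- (2 * k - 1) / x * chi_n - chi_nm1
      psi_nm1 <- psi_n; psi_n <- psi_np1
      chi_nm1 <- chi_n; chi_n <- chi_np1
    }
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    Dk <- D[k]
    a[k] <- ((Dk / m + k / x) * psi_n - psi_nm1) /
            ((Dk / m + k / x) * xi_n - xi_nm1)
    b[k] <- ((Dk * m + k / x) * psi_n - psi_nm1) /
            ((Dk * m + k / x) * xi_n - xi_nm1)
  }
  list(a = a, b = b, nmax = nmax)
}

# Amplitude functions S1, S2 at the cosines mu of the scattering angle.
#' @noRd
mie_amplitudes <- function(coef, mu) {
  a <- coef$a
  b <- coef$b
  nmax <- coef$nmax
  S1 <- complex(length(mu))
  S2 <- complex(length(mu))
  pi_nm1 <- numeric(length(mu))
  pi_n <- rep(1, length(mu))
  for (k in seq_len(nmax)) {
    tau_n <- k * mu * pi_n - (k + 1) * pi_nm1
    f <- (2 * k + 1) / (k * (k + 1))
    S1 <- S1 + f * (a[k] * pi_n + b[k] * tau_n)
    S2 <- S2 + f * (a[k] * tau_n + b[k] * pi_n)
    pi_np1 <- ((2 * k + 1) * mu * pi_n - (k + 1) * pi_nm1) / k
    pi_nm1 <- pi_n
    pi_n <- pi_np1
  }
  list(S1 = S1, S2 = S2)
}

#' Polarization-resolved Mie phase functions for a spherical particle
#'
#' Computes the two phase functions of a homogeneous sphere for polarization
#' perpendicular (`Ps`, from \eqn{|S_1(\theta)|^2}) and parallel (`Pp`, from
#' \eqn{|S_2(\theta)|^2}) to the scattering plane, on a regular grid of
#' scattering angles covering \eqn{[0, \pi]}. The tables are stored
#' unnormalized; normalization to a probability density happens once, in
#' [build_scatter_sampler()].
#'
#' @param diameter Particle diameter in metres.
#' @param n_particle Real refractive index of the particle.
#' @param n_medium Real refractive index of the host medium.
#' @param wavelength Vacuum wavelength in metres.
#' @param K Number of angular grid points (default 1801, i.e. 0.1 degree).
#'
#' @return An object of class `phase_table`: a list with `theta` (radians,
#'   length `K`), `Ps`, `Pp`, and `meta` carrying `diameter`, `wavelength`,
#'   `n_particle`, `n_medium`, the size parameter `x`, scattering efficiency
#'   `Qsca`, scattering cross-section `Csca` (m^2) and anisotropy `g`.
#' @examples
#' tab <- mie_phase_functions(1e-6, 1.586, 1.33, 633e-9)
#' tab$meta$g
#' @export
mie_phase_functions <- function(diameter, n_particle, n_medium, wavelength,
                                K = 1801) {
  if (!is.finite(diameter) || diameter <= 0) {
    stop_invalid("`diameter` must be a positive finite number (metres)")
  }
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop_invalid("`wavelength` must be a positive finite number (metres)")
  }
  if (!is.finite(n_particle) || n_particle <= 0 ||
      !is.finite(n_medium) || n_medium <= 0) {
    stop_invalid("refractive indices must be real, finite and positive")
  }
  if (K < 181) stop_invalid("`K` must be at least 181 angular nodes")

  x <- pi * diameter * n_medium / wavelength
  if (!is.finite(x) || x <= 0) stop_invalid("size parameter must be positive")
  m <- n_particle / n_medium
  coef <- mie_coefficients(m, x)
  theta <- seq(0, pi, length.out = K)
  amp <- mie_amplitudes(coef, cos(theta))
  Ps <- Mod(amp$S1)^2
  Pp <- Mod(amp$S2)^2

  n <- seq_len(coef$nmax)
  a <- coef$a
  b <- coef$b
  Qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  nm <- n[-coef$nmax]
  g <- (4 / x^2) / Qsca *
    (sum(nm * (nm + 2) / (nm + 1) *
           Re(a[nm] * Conj(a[nm + 1]) + b[nm] * Conj(b[nm + 1]))) +
     sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b))))
  Csca <- Qsca * pi * (diameter / 2)^2

  phase_table(theta, Ps, Pp,
              meta = list(diameter = diameter, wavelength = wavelength,
                          n_particle = n_particle, n_medium = n_medium,
                          x = x, Qsca = Qsca, Csca = Csca, g = g))
}

#' Construct a polarization-resolved phase function table
#'
#' @param theta Scattering angles in radians, strictly increasing from 0 to
#'   `pi`.
#' @param Ps,Pp Nonnegative phase function values for the perpendicular and
#'   parallel polarization states (arbitrary common scale, per solid angle).
#' @param meta Optional named list of metadata (particle diameter, wavelength,
#'   refractive indices, anisotropy, ...).
#' @return A `phase_table` object.
#' @export
phase_table <- function(theta, Ps, Pp, meta = list()) {
  if (length(theta) < 2 || any(diff(theta) <= 0)) {
    stop_invalid("`theta` must be strictly increasing")
  }
  if (abs(theta[1]) > 1e-12 || abs(theta[length(theta)] - pi) > 1e-9) {
    stop_invalid("`theta` must span [0, pi]")
  }
  if (length(Ps) != length(theta) || length(Pp) != length(theta)) {
    stop_invalid("`Ps` and `Pp` must match `theta` in length")
  }
  if (any(!is.finite(Ps)) || any(!is.finite(Pp)) ||
      any(Ps < 0) || any(Pp < 0)) {
    stop_invalid("phase function values must be finite and nonnegative")
  }
  structure(list(theta = theta, Ps = Ps, Pp = Pp, meta = meta),
            class = "phase_table")
}

#' @export
print.phase_table <- function(x, ...) {
  cat("<phase_table>", length(x$theta), "angles on [0, pi]\n")
  if (!is.null(x$meta$diameter)) {
    cat(sprintf("  d = %.3g um, lambda = %.4g nm, n_p/n_med = %.4g/%.4g\n",
                x$meta$diameter * 1e6, x$meta$wavelength * 1e9,
                x$meta$n_particle, x$meta$n_medium))
  }
  if (!is.null(x$meta$g)) {
    cat(sprintf("  Qsca = %.5g, Csca = %.5g m^2, g = %.5g\n",
                x$meta$Qsca, x$meta$Csca, x$meta$g))
  }
  invisible(x)
}

#' Scattering coefficient of a monodisperse sphere suspension
#'
#' Converts a particle volume fraction into a scattering coefficient under the
#' independent-scattering approximation:
#' \eqn{\mu_s = (\phi_v / V_{sphere}) \, C_{sca}} with
#' \eqn{V_{sphere} = (\pi/6) d^3}. The relation is exactly linear in
#' `phi_v`.
#'
#' @inheritParams mie_phase_functions
#' @param phi_v Particle volume fraction (dimensionless, e.g. 0.00028 for
#'   0.028 \% v/v). Must lie in `[0, 0.05)`; above a few percent the
#'   independent-scattering assumption breaks down.
#' @return Scattering coefficient in mm^-1.
#' @examples
#' # 1.0 um polystyrene in water at 633 nm, 0.028 % v/v
#' mus_from_concentration(1e-6, 1.586, 1.33, 633e-9, 0.00028)
#' @export
mus_from_concentration <- function(diameter, n_particle, n_medium, wavelength,
                                   phi_v) {
  if (!is.numeric(phi_v) || any(!is.finite(phi_v)) || any(phi_v < 0)) {
    stop_invalid("`phi_v` must be a nonnegative volume fraction")
  }
  if (any(phi_v >= 0.05)) {
    stop_invalid("`phi_v` >= 5 %% v/v is outside the independent-scattering regime")
  }
  tab <- mie_phase_functions(diameter, n_particle, n_medium, wavelength,
                             K = 181)
  v_bead <- pi / 6 * diameter^3
  mus_m <- phi_v / v_bead * tab$meta$Csca # m^-1
  mus_m / 1e3                             # mm^-1
}

#' Volume fraction required for a target scattering coefficient
#'
#' Exact inverse of [mus_from_concentration()].
#'
#' @inheritParams mus_from_concentration
#' @param target_mus Target scattering coefficient in mm^-1.
#' @return Particle volume fraction (dimensionless).
#' @examples
#' concentration_for_mus(3e-6, 1.586, 1.33, 633e-9, 1.0) * 100 # % v/v
#' @export
concentration_for_mus <- function(diameter, n_particle, n_medium, wavelength,
                                  target_mus) {
  if (!is.numeric(target_mus) || any(!is.finite(target_mus)) ||
      any(target_mus < 0)) {
    stop_invalid("`target_mus` must be nonnegative (mm^-1)")
  }
  tab <- mie_phase_functions(diameter, n_particle, n_medium, wavelength,
                             K = 181)
  v_bead <- pi / 6 * diameter^3
  target_mus * 1e3 * v_bead / tab$meta$Csca
}

#' Phase function for a given scattering azimuth
#'
#' For scattering azimuth `phi` measured from the photon polarization
#' direction, the one-dimensional phase function over the scattering angle is
#' the linear combination
#' \eqn{P(\theta,\phi) = \cos^2(\phi) P_s(\theta) + \sin^2(\phi) P_p(\theta)}.
#'
#' @param table A [phase_table] object.
#' @param phi Scattering azimuth in radians (wrapped modulo `2*pi`).
#' @return Numeric vector of phase function values over `table$theta`.
#' @export
combined_phase <- function(table, phi) {
  stopifnot(inherits(table, "phase_table"))
  phi <- phi %% (2 * pi)
  cos(phi)^2 * table$Ps + sin(phi)^2 * table$Pp
}

#' Write or read a phase function table as delimited text
#'
#' The on-disk format is three whitespace-delimited columns
#' (`theta_rad`, `P_s`, `P_p`) preceded by `#`-prefixed header lines carrying
#' the metadata as `# key: value` pairs. The round trip is loss-free at full
#' double precision.
#'
#' @param table A [phase_table] object.
#' @param path File path.
#' @return `write_phase_table` returns `path` invisibly; `read_phase_table`
#'   returns a [phase_table].
#' @export
write_phase_table <- function(table, path) {
  stopifnot(inherits(table, "phase_table"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(table$meta)) {
    writeLines(sprintf("# %s: %.17g", key, table$meta[[key]]), con)
  }
  writeLines("# columns: theta_rad P_s P_p", con)
  utils::write.table(
    data.frame(theta = sprintf("%.17g", table$theta),
               Ps = sprintf("%.17g", table$Ps),
               Pp = sprintf("%.17g", table$Pp)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_table
#' @export
read_phase_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  hdr <- hdr[!grepl("^# columns:", hdr)]
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([^:]+): (.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("theta", "Ps", "Pp"))
  phase_table(dat$theta, dat$Ps, dat$Pp, meta = meta)
}
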