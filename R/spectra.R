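# From detected photon records to Doppler power spectra.
#
# The detector is split into strips perpendicular to the flow axis (the
# Doppler shift depends strongly on the position along the flow), the Doppler
# shifts within each strip are histogrammed, and the power spectrum is built
# from the interference of all photon pairs whose Doppler shifts differ by
# each difference frequency. Writing the pair weight as
# w_i w_j (p_i . p_j)^2 with polarizations projected onto the detector plane,
# the pair sum factorizes over histogram bins through the second-moment
# accumulators Ixx, Iyy, Ixy, turning an O(photons^2) sum into O(bins^2).

#' Strip-wise Doppler histograms of detector records
#'
#' Partitions the detector into `n_strips` equal-width bands along the flow
#' axis and histograms the photon Doppler shifts within each strip,
#' accumulating the weight-scaled polarization second moments
#' `Ixx = sum(w px'^2)`, `Iyy = sum(w py'^2)` and `Ixy = sum(w px' py')`,
#' where `(px', py')` are the polarization components projected onto the
#' detector plane (x' along the flow axis).
#'
#' @param records Data frame with columns `x, y, z, px, py, pz, weight,
#'   fD_Hz` (as produced by [run_simulation()]).
#' @param detector The [detector_spec()] the records were collected on.
#' @param flow_axis Direction of the flow (projected onto the detector
#'   plane; default +x).
#' @param n_strips Number of detector strips (>= 1; default 3).
#' @param n_bins Number of Doppler-shift bins (default 2048).
#' @param f_max Half-width of the symmetric bin range in Hz; default the
#'   99.9th percentile of `|fD|` (shifts beyond it are clamped into the edge
#'   bins so that weight is conserved).
#' @return A list of `doppler_histogram` objects, one per strip, sharing
#'   `bin_edges`. Photons outside the detector radius are excluded; their
#'   count is stored in each histogram's `meta$n_excluded`.
#' @export
bin_doppler <- function(records, detector, flow_axis = c(1, 0, 0),
                        n_strips = 3, n_bins = 2048, f_max = NULL) {
  need <- c("x", "y", "z", "px", "py", "pz", "weight", "fD_Hz")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_invalid("records lack column(s) %s; include the matching save_fields when simulating",
                 paste(miss, collapse = ", "))
  }
  if (n_strips < 1) stop_invalid("`n_strips` must be >= 1")
  nrm <- detector$normal
  u <- flow_axis - sum(flow_axis * nrm) * nrm
  if (sqrt(sum(u^2)) < 1e-12) {
    stop_invalid("`flow_axis` is perpendicular to the detector plane")
  }
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])

  P <- cbind(records$x, records$y, records$z) -
    row3(detector$center, nrow(records))
  su <- drop(P %*% u)
  sv <- drop(P %*% v)
  R <- detector$diameter / 2
  inside <- su^2 + sv^2 <= R^2 * (1 + 1e-12)
  n_excluded <- sum(!inside)
  rec <- records[inside, , drop = FALSE]
  su <- su[inside]

  if (is.null(f_max)) {
    f_max <- stats::quantile(abs(rec$fD_Hz), 0.999, names = FALSE)
    if (!is.finite(f_max) || f_max <= 0) f_max <- 1
  }
  edges <- seq(-f_max, f_max, length.out = n_bins + 1)
  fb <- findInterval(rec$fD_Hz, edges, rightmost.closed = TRUE,
                     all.inside = TRUE)

  strip_edges <- seq(-R, R, length.out = n_strips + 1)
  sb <- findInterval(su, strip_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)

  pol <- cbind(rec$px, rec$py, rec$pz)
  pu <- drop(pol %*% u)
  pv <- drop(pol %*% v)
  w <- rec$weight

  lapply(seq_len(n_strips), function(s) {
    i <- sb == s
    f <- factor(fb[i], levels = seq_len(n_bins))
    structure(list(
      strip_index = s,
      bin_edges = edges,
      bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
      Ixx = as.numeric(tapply(w[i] * pu[i]^2, f, sum, default = 0)),
      Iyy = as.numeric(tapply(w[i] * pv[i]^2, f, sum, default = 0)),
      Ixy = as.numeric(tapply(w[i] * pu[i] * pv[i], f, sum, default = 0)),
      n_photons = as.integer(table(f)),
      meta = list(n_strips = n_strips, n_excluded = n_excluded,
                  f_max = f_max)),
      class = "doppler_histogram")
  })
}

# sum_m x[m] * y[m + k] for k = 0 .. n-1
#' @noRd
lag_products <- function(x, y) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x[seq_len(n - k)] * y[seq_len(n - k) + k])
  }, numeric(1))
}

#' Doppler power spectrum from strip histograms
#'
#' Per strip, the power at difference frequency `k * df` is
#' `P(k) = sum_m [Ixx(m) Ixx(m+k) + Iyy(m) Iyy(m+k) + 2 Ixy(m) Ixy(m+k)]`
#' over all bin pairs separated by `k`; the strip spectra are summed and
#' divided by the number of strips. The `k = 0` self-term is retained in
#' `power[1]` (and duplicated in `meta$dc_power`) so that width summaries
#' can exclude it.
#'
#' @param histograms List of [bin_doppler()] histograms with identical bin
#'   edges.
#' @return A `power_spectrum` object: `freq` (Hz, nonnegative multiples of
#'   the bin width), `power` (arbitrary units, >= 0) and `meta`.
#' @export
power_spectrum <- function(histograms) {
  if (inherits(histograms, "doppler_histogram")) histograms <- list(histograms)
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    if (!isTRUE(all.equal(h$bin_edges, edges, tolerance = 1e-12))) {
      stop_invalid("histograms do not share bin edges")
    }
  }
  n_bins <- length(edges) - 1
  df <- edges[2] - edges[1]
  total <- numeric(n_bins)
  for (h in histograms) {
    total <- total + lag_products(h$Ixx, h$Ixx) +
      lag_products(h$Iyy, h$Iyy) + 2 * lag_products(h$Ixy, h$Ixy)
  }
  total <- total / length(histograms)
  structure(list(freq = (0:(n_bins - 1)) * df,
                 power = pmax(total, 0),
                 meta = list(n_strips = length(histograms), n_bins = n_bins,
                             bin_width = df, dc_power = total[1],
                             normalized = FALSE, noise = NULL)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df = %.4g Hz, total power %.4g%s\n",
              length(x$freq), x$freq[2] - x$freq[1], sum(x$power),
              if (isTRUE(x$meta$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Spectral width summary
#'
#' The frequency below which a fraction `q` of the spectral power lies,
#' excluding the DC bin by default.
#'
#' @param ps A [power_spectrum()].
#' @param q Power fraction (default 0.9).
#' @param exclude_dc Drop the zero-frequency self-term first (default TRUE).
#' @return Frequency in Hz.
#' @export
spectral_width <- function(ps, q = 0.9, exclude_dc = TRUE) {
  stopifnot(inherits(ps, "power_spectrum"))
  f <- ps$freq
  p <- ps$power
  if (exclude_dc) {
    f <- f[-1]
    p <- p[-1]
  }
  if (sum(p) <= 0) return(0)
  cum <- cumsum(p) / sum(p)
  f[which(cum >= q)[1]]
}

#' Normalize a simulated spectrum to a measured one
#'
#' The simulated spectrum is divided by the frequency-weighted sum of its
#' values and multiplied by the frequency-weighted sum of the measured
#' spectrum, after interpolation onto the measured frequency grid. After the
#' operation the two frequency-weighted sums agree to within 1e-9 relative.
#'
#' @param sim,meas [power_spectrum()] objects.
#' @return The rescaled simulated spectrum, on `meas$freq`.
#' @export
normalize_to_measurement <- function(sim, meas) {
  stopifnot(inherits(sim, "power_spectrum"), inherits(meas, "power_spectrum"))
  p <- stats::approx(sim$freq, sim$power, xout = meas$freq, rule = 1)$y
  p[is.na(p)] <- 0
  s_sim <- sum(meas$freq * p)
  if (s_sim <= 0) stop_invalid("degenerate spectrum: frequency-weighted sum is zero")
  s_meas <- sum(meas$freq * meas$power)
  out <- sim
  out$freq <- meas$freq
  out$power <- p * s_meas / s_sim
  out$meta$normalized <- TRUE
  out$meta$n_bins <- length(out$freq)
  out
}

#' Add a noise floor to a simulated spectrum
#'
#' Spectrum values below `noise_mean` are replaced by white-noise draws with
#' the given mean and standard deviation (clipped at zero); values above the
#' baseline are left untouched.
#'
#' @param sim A [power_spectrum()].
#' @param noise_mean,noise_std Baseline mean and standard deviation
#'   (`noise_std >= 0`).
#' @return The spectrum with the noise floor applied.
#' @export
add_noise_floor <- function(sim, noise_mean, noise_std) {
  stopifnot(inherits(sim, "power_spectrum"))
  if (noise_std < 0) stop_invalid("`noise_std` must be >= 0")
  below <- sim$power < noise_mean
  sim$power[below] <- pmax(stats::rnorm(sum(below), noise_mean, noise_std), 0)
  sim$meta$noise <- list(mean = noise_mean, sd = noise_std,
                         n_replaced = sum(below))
  sim
}

#' Estimate the noise baseline of a measured spectrum
#'
#' Mean and standard deviation of the top fraction of the frequency axis,
#' assumed signal-free.
#'
#' @param meas A [power_spectrum()].
#' @param top_fraction Fraction of the highest frequencies used (default
#'   0.1).
#' @return A list with `mean` and `sd`.
#' @export
estimate_noise_floor <- function(meas, top_fraction = 0.1) {
  stopifnot(inherits(meas, "power_spectrum"))
  n <- length(meas$power)
  i <- seq.int(ceiling(n * (1 - top_fraction)) + 1, n)
  list(mean = mean(meas$power[i]), sd = stats::sd(meas$power[i]))
}

#' Write or read a power spectrum as delimited text
#'
#' Two whitespace-delimited columns (`freq_Hz`, `power`) with `#`-prefixed
#' metadata header lines.
#'
#' @param ps A [power_spectrum()].
#' @param path File path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` a
#'   [power_spectrum()].
#' @export
write_spectrum <- function(ps, path) {
  stopifnot(inherits(ps, "power_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- ps$meta
  for (key in c("n_strips", "n_bins", "bin_width", "dc_power")) {
    if (!is.null(m[[key]])) {
      writeLines(sprintf("# %s: %.17g", key, m[[key]]), con)
    }
  }
  writeLines(sprintf("# normalized: %s", isTRUE(m$normalized)), con)
  writeLines("# columns: freq_Hz power", con)
  utils::write.table(
    data.frame(f = sprintf("%.17g", ps$freq), p = sprintf("%.17g", ps$power)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (h in grep("^# [a-z_]+: ", lines, value = TRUE)) {
    m <- regmatches(h, regexec("^# ([a-z_]+): (.*)$", h))[[1]]
    if (m[2] == "columns") next
    meta[[m[2]]] <- if (m[2] == "normalized") as.logical(m[3]) else
      as.numeric(m[3])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("freq", "power"))
  structure(list(freq = dat$freq, power = dat$power, meta = meta),
            class = "power_spectrum")
}
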