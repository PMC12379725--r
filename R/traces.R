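# Detector time traces: synthesis from Doppler histograms and the segmented
# FFT-averaging processing used for measured signals.

#' Measured (or synthetic) detector time trace
#'
#' @param samples Numeric vector of detector readings (a.u.) at uniform
#'   sampling; at least 256 samples.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param gain Amplifier gain applied to the signal (bookkeeping only).
#' @param zero_flow_reference Optional companion `measured_trace` recorded at
#'   zero flow, processed identically and subtracted.
#' @return A `measured_trace` object.
#' @export
measured_trace <- function(samples, sampling_rate, gain = 1,
                           zero_flow_reference = NULL) {
  if (length(samples) < 256) {
    stop_invalid("a trace needs at least 256 samples")
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop_invalid("`sampling_rate` must be > 0")
  }
  if (!is.null(zero_flow_reference)) {
    stopifnot(inherits(zero_flow_reference, "measured_trace"))
  }
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 gain = gain, zero_flow_reference = zero_flow_reference),
            class = "measured_trace")
}

#' @export
print.measured_trace <- function(x, ...) {
  cat(sprintf("<measured_trace> %d samples at %.4g Hz%s\n",
              length(x$samples), x$sampling_rate,
              if (!is.null(x$zero_flow_reference)) " (+ zero-flow reference)"
              else ""))
  invisible(x)
}

#' Power spectrum of a detector time trace
#'
#' The trace is cut into `n_segments` segments of equal length (a rectangular
#' window; any remainder samples are dropped), the magnitude-squared FFT of
#' each segment is taken, and the segment spectra are averaged. When the
#' trace carries a zero-flow reference it is processed identically and
#' subtracted, with the result clamped at zero.
#'
#' @param trace A [measured_trace()].
#' @param n_segments Number of segments (default 128).
#' @return A [power_spectrum()] on the one-sided frequency grid set by the
#'   sampling rate and segment length.
#' @export
process_measured_trace <- function(trace, n_segments = 128) {
  stopifnot(inherits(trace, "measured_trace"))
  L <- floor(length(trace$samples) / n_segments)
  if (L < 2) stop_invalid("segment length below 2 samples; trace too short")
  avg <- function(samples) {
    m <- matrix(samples[seq_len(L * n_segments)], nrow = L)
    rowMeans(Mod(stats::mvfft(m))^2)
  }
  p <- avg(trace$samples)
  if (!is.null(trace$zero_flow_reference)) {
    ref <- trace$zero_flow_reference
    if (floor(length(ref$samples) / n_segments) != L) {
      stop_invalid("zero-flow reference has a different segment length")
    }
    p <- p - avg(ref$samples)
  }
  nf <- floor(L / 2) + 1
  structure(list(freq = (0:(nf - 1)) * trace$sampling_rate / L,
                 power = pmax(p[seq_len(nf)], 0),
                 meta = list(n_segments = n_segments, segment_length = L,
                             sampling_rate = trace$sampling_rate,
                             normalized = FALSE,
                             zero_flow_subtracted =
                               !is.null(trace$zero_flow_reference))),
            class = "power_spectrum")
}

#' Synthesize a detector time trace from a Doppler histogram
#'
#' Builds a photocurrent as the intensity of a sum of phasors, one per
#' occupied Doppler bin: `I(t) = |sum_j a_j exp(i (2 pi f_j t + phi_j))|^2`
#' with amplitudes `a_j = sqrt(bin weight)` and independent random phases.
#' This provides synthetic "measured" traces whose processed spectrum can be
#' compared with the pairwise-interference spectrum of the same records.
#'
#' @param histogram A [bin_doppler()] histogram.
#' @param duration Trace duration in seconds.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the largest
#'   occupied `|fD|` (aliasing guard).
#' @return A [measured_trace()].
#' @export
synth_detector_trace <- function(histogram, duration, sampling_rate) {
  stopifnot(inherits(histogram, "doppler_histogram"))
  wbin <- histogram$Ixx + histogram$Iyy
  occ <- which(wbin > 0)
  if (!length(occ)) stop_invalid("histogram holds no weight")
  f <- histogram$bin_centers[occ]
  if (sampling_rate <= 2 * max(abs(f))) {
    stop_invalid("sampling_rate must exceed twice the largest |fD| (%.4g Hz)",
                 max(abs(f)))
  }
  a <- sqrt(wbin[occ])
  phase <- stats::runif(length(occ), 0, 2 * pi)
  t <- seq(0, duration, by = 1 / sampling_rate)
  field <- exp(1i * (outer(t, 2 * pi * f) +
                       matrix(phase, length(t), length(occ), byrow = TRUE)))
  intensity <- Mod(drop(field %*% a))^2
  measured_trace(intensity, sampling_rate)
}

#' Write or read a detector time trace as delimited text
#'
#' Two whitespace-delimited columns (`time_s`, `value`) with a `#`-prefixed
#' header carrying the sampling rate and gain.
#'
#' @param trace A [measured_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   [measured_trace()] (without any zero-flow reference).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "measured_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %.17g", trace$sampling_rate), con)
  writeLines(sprintf("# gain: %.17g", trace$gain), con)
  writeLines("# columns: time_s value", con)
  t <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  utils::write.table(
    data.frame(t = sprintf("%.17g", t),
               v = sprintf("%.17g", trace$samples)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  rate <- NA_real_
  gain <- 1
  for (h in grep("^#", lines, value = TRUE)) {
    m <- regmatches(h, regexec("^# ([a-z_]+): (.*)$", h))[[1]]
    if (length(m) == 3 && m[2] == "sampling_rate") rate <- as.numeric(m[3])
    if (length(m) == 3 && m[2] == "gain") gain <- as.numeric(m[3])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("time", "value"))
  if (!is.finite(rate)) {
    dt <- mean(diff(dat$time))
    if (!is.finite(dt) || dt <= 0) {
      stop_invalid("trace file carries no sampling rate and no usable time column")
    }
    rate <- 1 / dt
  }
  measured_trace(dat$value, rate, gain = gain)
}
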