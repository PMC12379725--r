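# Doppler binning and the strip-wise pairwise-interference power spectrum.

toy_detector <- function() detector_spec(c(0, 0, 3.675e-3), c(0, 0, 1), 1e-3)

# records with Doppler shifts placed exactly at bin centers so the binned
# computation has no discretization error against the pairwise oracle
centered_records <- function(n = 100, n_bins = 32, f_max = 1e3, seed = 71) {
  set.seed(seed)
  edges <- seq(-f_max, f_max, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  rad <- 0.5e-3 * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  pol <- runif(n, 0, 2 * pi)
  data.frame(x = rad * cos(ang), y = rad * sin(ang), z = 3.675e-3,
             kx = 0, ky = 0, kz = 1,
             px = cos(pol), py = sin(pol), pz = 0,
             weight = runif(n, 0.2, 1),
             fD_Hz = sample(centers, n, replace = TRUE), n_scat = 1L)
}

test_that("binning conserves projected weight and validates input", {
  rec <- centered_records()
  h <- bin_doppler(rec, toy_detector(), n_strips = 1, n_bins = 32,
                   f_max = 1e3)
  expect_length(h, 1)
  expect_equal(sum(h[[1]]$Ixx + h[[1]]$Iyy),
               sum(rec$weight * (rec$px^2 + rec$py^2)))
  expect_identical(sum(h[[1]]$n_photons), nrow(rec))
  expect_error(bin_doppler(rec[, -which(names(rec) == "fD_Hz")],
                           toy_detector()), "fD_Hz")
  expect_error(bin_doppler(rec, toy_detector(), flow_axis = c(0, 0, 1)),
               "perpendicular")
})

test_that("identical Doppler shifts occupy a single bin", {
  rec <- centered_records()
  rec$fD_Hz <- 250
  h <- bin_doppler(rec, toy_detector(), n_strips = 1, n_bins = 32,
                   f_max = 1e3)[[1]]
  expect_identical(sum(h$n_photons > 0), 1L)
})

test_that("photons outside the detector radius are excluded and counted", {
  rec <- centered_records()
  rec$x[1:5] <- 0.7e-3
  h <- bin_doppler(rec, toy_detector(), n_strips = 1, n_bins = 16,
                   f_max = 1e3)[[1]]
  expect_identical(h$meta$n_excluded, 5L)
  expect_identical(sum(h$n_photons), nrow(rec) - 5L)
})

test_that("strip assignment matches a brute-force coordinate comparison", {
  rec <- centered_records(n = 1000)
  n_strips <- 5
  hs <- bin_doppler(rec, toy_detector(), n_strips = n_strips, n_bins = 16,
                    f_max = 1e3)
  R <- 0.5e-3
  brute <- pmin(pmax(findInterval(rec$x, seq(-R, R, length.out = n_strips + 1),
                                  rightmost.closed = TRUE), 1), n_strips)
  for (s in seq_len(n_strips)) {
    expect_identical(sum(hs[[s]]$n_photons), sum(brute == s))
  }
})

test_that("degenerate spectra reduce to spikes", {
  rec <- centered_records()
  # all photons identical shift and polarization: single spike at zero
  rec$fD_Hz <- 0
  rec$px <- 0
  rec$py <- 1
  ps <- power_spectrum(bin_doppler(rec, toy_detector(), n_strips = 1,
                                   n_bins = 32, f_max = 1e3))
  expect_true(all(ps$power[-1] == 0))
  expect_gt(ps$power[1], 0)
  # two co-polarized populations at 0 and f0: spikes at 0 and f0 only
  f0 <- 500
  rec2 <- centered_records(n = 60)
  rec2$px <- 0
  rec2$py <- 1
  rec2$weight <- 1
  rec2$fD_Hz <- rep(c(0, f0), 30)
  nb <- 40
  ps2 <- power_spectrum(bin_doppler(rec2, toy_detector(), n_strips = 1,
                                    n_bins = nb, f_max = 1e3))
  occupied <- which(ps2$power > 0)
  k0 <- round(f0 / ps2$meta$bin_width)
  expect_setequal(occupied, c(1, k0 + 1))
})

test_that("the binned spectrum equals the O(N^2) pairwise oracle", {
  rec <- centered_records(n = 100, n_bins = 32)
  ps <- power_spectrum(bin_doppler(rec, toy_detector(), n_strips = 1,
                                   n_bins = 32, f_max = 1e3))
  oracle <- pairwise_oracle(rec, n_bins = 32, f_max = 1e3, by = "bin")
  expect_equal(ps$power, oracle, tolerance = 1e-10)
})

test_that("refining the bins shrinks the gap to the |fD|-difference oracle", {
  set.seed(72)
  rec <- centered_records(n = 80)
  rec$fD_Hz <- runif(80, -900, 900) # arbitrary shifts, off the bin centers
  gap <- vapply(c(64, 128), function(nb) {
    ps <- power_spectrum(bin_doppler(rec, toy_detector(), n_strips = 1,
                                     n_bins = nb, f_max = 1e3))
    oracle <- pairwise_oracle(rec, n_bins = nb, f_max = 1e3, by = "freq")
    # compare integrated spectra: a one-bin misassignment then contributes
    # one bin width, which shrinks as the bins refine
    df <- ps$meta$bin_width
    sum(abs(cumsum(ps$power[-1]) - cumsum(oracle[-1]))) * df /
      sum(oracle[-1])
  }, numeric(1))
  expect_lt(gap[2], 0.75 * gap[1])
})

test_that("mismatched bin edges are rejected", {
  rec <- centered_records()
  h1 <- bin_doppler(rec, toy_detector(), n_strips = 1, n_bins = 32,
                    f_max = 1e3)[[1]]
  h2 <- bin_doppler(rec, toy_detector(), n_strips = 1, n_bins = 32,
                    f_max = 2e3)[[1]]
  expect_error(power_spectrum(list(h1, h2)), "bin edges")
})

test_that("normalization equalizes frequency-weighted sums and is scale-invariant", {
  rec <- centered_records()
  ps <- power_spectrum(bin_doppler(rec, toy_detector(), n_strips = 1,
                                   n_bins = 32, f_max = 1e3))
  expect_equal(normalize_to_measurement(ps, ps)$power, ps$power,
               tolerance = 1e-12)
  meas <- ps
  meas$power <- meas$power * 3.7 + 0.01
  scaled <- ps
  scaled$power <- ps$power * 123.4
  n1 <- normalize_to_measurement(ps, meas)
  n2 <- normalize_to_measurement(scaled, meas)
  expect_equal(n1$power, n2$power, tolerance = 1e-12)
  expect_equal(sum(n1$freq * n1$power), sum(meas$freq * meas$power),
               tolerance = 1e-9)
  degenerate <- ps
  degenerate$power[] <- 0
  expect_error(normalize_to_measurement(degenerate, meas), "degenerate")
})

test_that("the noise floor replaces only sub-baseline values", {
  ps <- structure(list(freq = 0:999, power = rep(c(0, 10), 500),
                       meta = list(normalized = FALSE)),
                  class = "power_spectrum")
  # zero spread: sub-baseline values set exactly to the mean
  out <- add_noise_floor(ps, 1, 0)
  expect_true(all(out$power[ps$power == 0] == 1))
  expect_true(all(out$power[ps$power == 10] == 10))
  # spectrum entirely above the baseline: unchanged
  hi <- ps
  hi$power <- hi$power + 20
  expect_identical(add_noise_floor(hi, 1, 0.5)$power, hi$power)
  # sampling statistics of the replaced region
  set.seed(73)
  out <- add_noise_floor(ps, 5, 0.5)
  repl <- out$power[ps$power == 0]
  expect_lt(abs(mean(repl) - 5), 3 * 0.5 / sqrt(length(repl)))
})

test_that("noise-floor estimation reads the top frequency decile", {
  ps <- structure(list(freq = 0:999, power = c(rep(100, 900), rep(2, 100)),
                       meta = list()), class = "power_spectrum")
  nf <- estimate_noise_floor(ps)
  expect_equal(nf$mean, 2)
  expect_equal(nf$sd, 0)
})

test_that("spectral width summaries exclude the DC term by default", {
  ps <- structure(list(freq = c(0, 10, 20, 30),
                       power = c(1000, 5, 4, 1),
                       meta = list()), class = "power_spectrum")
  expect_equal(spectral_width(ps, 0.95), 30)
  expect_equal(spectral_width(ps, 0.9), 20)
  expect_equal(spectral_width(ps, 0.5), 10)
  expect_equal(spectral_width(ps, 0.9, exclude_dc = FALSE), 0)
})

test_that("strip spectra converge at three strips at low scattering", {
  run <- run_mus1_flow(15)
  det <- toy_detector()
  mk <- function(ns) {
    power_spectrum(bin_doppler(run$records, det, n_strips = ns,
                               n_bins = 64))
  }
  ps1 <- mk(1)
  ps3 <- mk(3)
  ps9 <- mk(9)
  # refining 3 -> 9 strips changes the spectrum far less than 1 -> 3, and
  # the width summary is converged at three strips (to within its bin
  # quantization)
  expect_lt(rel_l1(ps3, ps9), rel_l1(ps1, ps3) / 3)
  expect_lt(abs(spectral_width(ps3) - spectral_width(ps9)),
            max(0.1 * spectral_width(ps3), 1.5 * ps3$meta$bin_width))
  # the 1-strip spectrum is much broader than the 3-strip spectrum
  expect_gt(spectral_width(ps1), 1.25 * spectral_width(ps3))
})

test_that("strip count barely matters at high scattering", {
  run <- run_mus9_flow15()
  det <- toy_detector()
  ps1 <- power_spectrum(bin_doppler(run$records, det, n_strips = 1,
                                    n_bins = 256))
  ps3 <- power_spectrum(bin_doppler(run$records, det, n_strips = 3,
                                    n_bins = 256))
  expect_lt(rel_l1(ps1, ps3), 0.05)
})

test_that("spectral width grows with flow rate", {
  widths <- vapply(c(1, 5, 15), function(rate) {
    run <- run_mus1_flow(rate)
    ps <- power_spectrum(bin_doppler(run$records, toy_detector(),
                                     n_strips = 3, n_bins = 256))
    spectral_width(ps)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("a dominant zero-shift peak imprints a drop at the histogram half-width", {
  # ballistic-heavy population at fD = 0 plus a weak broad component over
  # [-W, W]: the beat spectrum must fall off sharply just above W
  set.seed(74)
  W <- 20e3
  n_bal <- 300
  n_br <- 150
  rad <- 0.5e-3 * sqrt(runif(n_bal + n_br))
  ang <- runif(n_bal + n_br, 0, 2 * pi)
  rec <- data.frame(x = rad * cos(ang), y = rad * sin(ang), z = 3.675e-3,
                    kx = 0, ky = 0, kz = 1, px = 0, py = 1, pz = 0,
                    weight = c(rep(1, n_bal), rep(0.3, n_br)),
                    fD_Hz = c(rep(0, n_bal), runif(n_br, -W, W)),
                    n_scat = c(rep(0L, n_bal), rep(1L, n_br)))
  ps <- power_spectrum(bin_doppler(rec, toy_detector(), n_strips = 1,
                                   n_bins = 256, f_max = 2 * W))
  below <- ps$freq > 0.7 * W & ps$freq < 0.95 * W
  above <- ps$freq > 1.05 * W & ps$freq < 1.3 * W
  expect_gt(mean(ps$power[below]), 5 * mean(ps$power[above]))
})

test_that("spectra round-trip through delimited text", {
  rec <- centered_records()
  ps <- power_spectrum(bin_doppler(rec, toy_detector(), n_strips = 3,
                                   n_bins = 64, f_max = 1e3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(ps, path)
  ps2 <- read_spectrum(path)
  expect_identical(ps2$freq, ps$freq)
  expect_identical(ps2$power, ps$power)
  expect_identical(ps2$meta$n_strips, 3)
  expect_false(ps2$meta$normalized)
})
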