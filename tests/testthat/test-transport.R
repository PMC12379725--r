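# Elementary transport operations: path sampling, absorption, roulette,
# Fresnel/Snell, scattering with Doppler updates, detection.

test_that("path lengths follow the exponential free-path law", {
  expect_identical(sample_path_length(1, 0), 0)
  expect_equal(sample_path_length(1, 1 - exp(-1)), 1e-3, tolerance = 1e-12)
  expect_identical(sample_path_length(0, 0.5), Inf)
  set.seed(51)
  d <- sample_path_length(5, runif(1e6))
  se <- sd(d) / sqrt(1e6)
  expect_lt(abs(mean(d) - 0.2e-3), 3 * se)
  # u = 1 resamples instead of producing infinity
  set.seed(52)
  expect_true(is.finite(sample_path_length(1, 1)))
  expect_error(sample_path_length(-1, 0.5), ">= 0")
})

test_that("absorption follows the Lambert-Beer law and is additive", {
  b <- photon_batch(matrix(0, 3, 3), row3(c(0, 0, 1), 3), row3(c(0, 1, 0), 3))
  expect_identical(apply_absorption(b, 0, 1e-3)$w, b$w)
  b1 <- apply_absorption(b, 1, 1e-3)
  expect_equal(b1$w, rep(exp(-1), 3))
  # two segments equal one combined segment exactly
  b2 <- apply_absorption(apply_absorption(b, 2, 0.3e-3), 2, 0.7e-3)
  b3 <- apply_absorption(b, 2, 1e-3)
  expect_equal(b2$w, b3$w, tolerance = 1e-14)
})

test_that("russian roulette kills, revives and conserves as configured", {
  n <- 1e5
  mk <- function(w) {
    photon_batch(matrix(0, n, 3), row3(c(0, 0, 1), n), row3(c(0, 1, 0), n),
                 w = rep(w, n))
  }
  # photons above threshold are untouched
  safe <- russian_roulette(mk(0.5), roulette_config())
  expect_true(all(safe$w == 0.5) && all(safe$status == 0L))
  # defaults: survival probability 0.1, survivors revived to 0.5
  set.seed(53)
  out <- russian_roulette(mk(0.05), roulette_config())
  surv <- out$status == 0L
  expect_lt(abs(mean(surv) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(out$w[surv] == 0.5))
  expect_true(all(out$status[!surv] == 3L))
  # conserving mode preserves expected total weight
  set.seed(54)
  out <- russian_roulette(mk(0.05), roulette_config(conserving = TRUE))
  w_after <- sum(out$w[out$status == 0L])
  se <- sqrt(n * 0.1 * 0.9) * 0.5
  expect_lt(abs(w_after - 0.05 * n), 3 * se)
})

test_that("fresnel reflectivity matches the closed forms", {
  # normal incidence air -> glass, polarization-independent
  R0 <- ((1 - 1.52) / (1 + 1.52))^2
  expect_equal(fresnel_reflectivity(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0),
                                    1, 1.52), R0, tolerance = 1e-12)
  expect_equal(fresnel_reflectivity(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                                    1, 1.52), R0, tolerance = 1e-12)
  expect_equal(R0, 0.0426, tolerance = 1e-3)
  # beyond the critical angle (glass -> air at 45 deg): total reflection
  k45 <- c(sin(pi / 4), 0, cos(pi / 4))
  expect_identical(
    fresnel_reflectivity(k45, c(0, 0, -1), c(0, 1, 0), 1.52, 1), 1)
  # p-polarized at Brewster angle: null
  thB <- atan(1.52)
  kB <- c(sin(thB), 0, cos(thB))
  pB <- c(cos(thB), 0, -sin(thB)) # in the plane of incidence
  expect_lt(fresnel_reflectivity(kB, c(0, 0, -1), pB, 1, 1.52), 1e-12)
  # s-polarized reflectivity at an oblique angle vs the scalar formula
  th <- 0.6
  k <- c(sin(th), 0, cos(th))
  tht <- asin(sin(th) / 1.52)
  Rs <- ((cos(th) - 1.52 * cos(tht)) / (cos(th) + 1.52 * cos(tht)))^2
  expect_equal(fresnel_reflectivity(k, c(0, 0, -1), c(0, 1, 0), 1, 1.52),
               Rs, tolerance = 1e-12)
})

test_that("snell refraction and mirror reflection update directions correctly", {
  mk <- function(k, p) photon_batch(matrix(0, 1, 3), matrix(k, 1),
                                    matrix(p, 1))
  nrm <- matrix(c(0, 0, -1), 1)
  # normal-incidence transmission leaves the direction unchanged
  b <- reflect_or_refract(mk(c(0, 0, 1), c(0, 1, 0)), nrm, 1, 1.52, u = 0.9)
  expect_false(attr(b, "reflected"))
  expect_equal(b$k, matrix(c(0, 0, 1), 1))
  expect_true(is.na(b$d_pending))
  # 45 degrees air -> glass: refraction angle asin(sin(45)/1.52)
  k45 <- c(sin(pi / 4), 0, cos(pi / 4))
  b <- reflect_or_refract(mk(k45, c(0, 1, 0)), nrm, 1, 1.52, u = 0.9)
  ang <- acos(b$k[1, 3])
  expect_equal(ang * 180 / pi, 27.72, tolerance = 1e-3)
  expect_batch_invariants(b$k, b$p)
  # reflection: angle in = angle out, normal component flips sign only
  b <- reflect_or_refract(mk(k45, c(0, 1, 0)), nrm, 1, 1.52, u = 0)
  expect_true(attr(b, "reflected"))
  expect_equal(b$k, matrix(c(sin(pi / 4), 0, -cos(pi / 4)), 1))
  expect_batch_invariants(b$k, b$p)
})

test_that("scattering in a static medium never touches the Doppler shift", {
  smp <- iso_sampler()
  n <- 500
  set.seed(55)
  b <- photon_batch(matrix(0, n, 3), row3(c(0, 0, 1), n), row3(c(0, 1, 0), n))
  out <- scatter_photons(b, smp, flow = NULL)
  expect_identical(out$fD, rep(0, n))
  expect_identical(out$n_scat, rep(1L, n))
  expect_batch_invariants(out$k, out$p)
})

test_that("forward scattering produces zero momentum transfer", {
  smp <- iso_sampler()
  flow <- flow_field(function(P) cbind(1, 0, 0)[rep(1, nrow(P)), , drop = FALSE],
                     brownian_speed = 0)
  b <- photon_batch(matrix(0, 1, 3), matrix(c(0, 0, 1), 1),
                    matrix(c(0, 1, 0), 1))
  out <- scatter_photons(b, smp, flow = flow, u = matrix(c(0.3, 0, 0.5, 0.5), 1))
  expect_identical(out$fD, 0) # theta = 0 -> q = 0 regardless of v
})

test_that("the Doppler increment equals -v . q with q = (n/lambda)(k_in - k_out)", {
  smp <- iso_sampler()
  # flow 0.1 m/s along +x, k: +z -> +x via theta = pi/2, phi = pi
  flow <- flow_field(function(P) {
    matrix(c(0.1, 0, 0), nrow(P), 3, byrow = TRUE)
  }, brownian_speed = 0)
  b <- photon_batch(matrix(0, 1, 3), matrix(c(0, 0, 1), 1),
                    matrix(c(0, 1, 0), 1))
  out <- scatter_photons(b, smp, flow = flow, n_medium = 1.33,
                         wavelength = 633e-9,
                         u = matrix(c(0.5, 0.5, 0.5, 0.5), 1))
  # isotropic sampler: u = 0.5 gives theta = pi/2 and phi = pi, i.e.
  # k_out = +x in the (k x p, p) azimuth frame
  expect_equal(out$k, matrix(c(1, 0, 0), 1), tolerance = 1e-6)
  expect_equal(out$fD, 1.33 / 633e-9 * 0.1, tolerance = 1e-4)
  # scatter-event invariants: theta between directions, |q| = (2n/lambda) sin(theta/2)
  theta <- acos(sum(b$k[1, ] * out$k[1, ]))
  q <- 1.33 / 633e-9 * (b$k[1, ] - out$k[1, ])
  expect_equal(sqrt(sum(q^2)), 2 * 1.33 / 633e-9 * sin(theta / 2),
               tolerance = 1e-9)
})

test_that("brownian motion contributes to the Doppler shift at scattering", {
  smp <- iso_sampler()
  flow <- flow_field(function(P) matrix(0, nrow(P), 3), brownian_speed = 0.002)
  n <- 2000
  set.seed(56)
  b <- photon_batch(matrix(0, n, 3), row3(c(0, 0, 1), n), row3(c(0, 1, 0), n))
  out <- scatter_photons(b, smp, flow = flow)
  expect_gt(sd(out$fD), 0) # zero mean flow, nonzero spread from Brownian
  expect_lt(abs(mean(out$fD)), 3 * sd(out$fD) / sqrt(n))
})

test_that("detection respects the disk radius, save_fields and selection", {
  det <- detector_spec(c(0, 0, 1e-3), c(0, 0, 1), 1e-3)
  n <- 200
  set.seed(57)
  r <- cbind(runif(n, -0.7e-3, 0.7e-3), runif(n, -0.7e-3, 0.7e-3), 1e-3)
  b <- photon_batch(r, row3(c(0, 0, 1), n), row3(c(0, 1, 0), n),
                    n_scat = sample(0:3, n, replace = TRUE))
  res <- detect_photons(b, det)
  expect_identical(res$hit, sqrt(r[, 1]^2 + r[, 2]^2) <= 0.5e-3)
  # radial boundary: epsilon outside is rejected
  b1 <- photon_batch(matrix(c(0.5e-3 + 1e-9, 0, 1e-3), 1),
                     matrix(c(0, 0, 1), 1), matrix(c(0, 1, 0), 1))
  expect_false(detect_photons(b1, det)$hit)
  b2 <- photon_batch(matrix(c(0.5e-3 - 1e-9, 0, 1e-3), 1),
                     matrix(c(0, 0, 1), 1), matrix(c(0, 1, 0), 1))
  expect_true(detect_photons(b2, det)$hit)
  # selection predicate equals a brute-force filter
  det_sel <- detector_spec(c(0, 0, 1e-3), c(0, 0, 1), 1e-3,
                           selection = function(d) d$n_scat >= 1)
  res_sel <- detect_photons(b, det_sel)
  expect_identical(nrow(res_sel$records), sum(res$hit & b$n_scat >= 1))
  # save_fields filtering
  det_min <- detector_spec(c(0, 0, 1e-3), c(0, 0, 1), 1e-3,
                           save_fields = c("weight", "doppler"))
  expect_named(detect_photons(b, det_min)$records, c("weight", "fD_Hz"))
})

test_that("propagate_step tags interfaces, scatter sites and escapes", {
  sc <- scene_mus1()
  mk <- function(r, k, d = NA_real_, medium = 0L) {
    b <- photon_batch(matrix(r, 1), matrix(k, 1), matrix(c(0, 1, 0), 1),
                      d_pending = d, medium = medium)
    b
  }
  # ambient photon aimed at the tube lands exactly on the outer wall
  b <- mk(c(0, 0, -1.675e-3), c(0, 0, 1), d = Inf)
  res <- propagate_step(b, sc)
  expect_identical(res$event, "interface")
  expect_lt(abs(sqrt(sum(res$batch$r[1, 2:3]^2)) - 0.675e-3), 1e-9)
  # path shorter than any surface: scatter site at r + d k
  b <- mk(c(0, 0, 0), c(0, 0, 1), d = 0.1e-3, medium = 2L)
  res <- propagate_step(b, sc)
  expect_identical(res$event, "scatter_site")
  expect_equal(res$batch$r[1, ], c(0, 0, 0.1e-3))
  expect_identical(res$batch$d_pending, 0)
  # aimed outward with nothing in the way: boundary escape
  b <- mk(c(0, 0, -1.675e-3), c(0, 0, -1), d = Inf)
  res <- propagate_step(b, sc)
  expect_identical(res$event, "boundary_escape")
  expect_identical(res$batch$status, 2L)
})
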