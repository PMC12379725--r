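# Shared fixtures: cached Mie tables, samplers and simulation runs, so the
# expensive pieces are computed once per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) {
    assign(name, builder(), envir = .cache)
  }
  get(name, envir = .cache)
}

mie_1um <- function() cached("mie_1um", function() {
  mie_phase_functions(1e-6, 1.586, 1.33, 633e-9)
})
mie_15um <- function() cached("mie_15um", function() {
  mie_phase_functions(1.5e-6, 1.586, 1.33, 633e-9)
})
mie_3um <- function() cached("mie_3um", function() {
  mie_phase_functions(3e-6, 1.586, 1.33, 633e-9)
})

sampler_1um <- function() cached("sampler_1um", function() {
  build_scatter_sampler(mie_1um())
})
sampler_3um <- function() cached("sampler_3um", function() {
  build_scatter_sampler(mie_3um())
})

# isotropic polarization-independent table
iso_table <- function() cached("iso_table", function() {
  th <- seq(0, pi, length.out = 721)
  phase_table(th, rep(1, 721), rep(1, 721))
})
iso_sampler <- function() cached("iso_sampler", function() {
  build_scatter_sampler(iso_table(), n_phi_nodes = 180)
})

ref_detector <- function() detector_spec(c(0, 0, 3.675e-3), c(0, 0, 1), 1e-3)

# reference scenes sharing the cached 1 um sampler
scene_mus1 <- function(flow_rate = 0) {
  reference_scene(mus = 1, flow_rate = flow_rate, sampler = sampler_1um())
}

run_mus0 <- function() cached("run_mus0", function() {
  run_simulation(reference_scene(mus = 0),
                 stop = list(n_launched = 20000), seed = 105)
})
run_mus1_static <- function() cached("run_mus1_static", function() {
  run_simulation(scene_mus1(), stop = list(n_detected = 10000), seed = 101)
})
run_mus1_flow <- function(rate) {
  name <- paste0("run_mus1_flow", rate)
  seed <- c(`1` = 103, `5` = 104, `15` = 102)[[as.character(rate)]]
  cached(name, function() {
    run_simulation(scene_mus1(flow_rate = rate),
                   stop = list(n_detected = 20000), seed = seed)
  })
}
run_mus5_static <- function() cached("run_mus5_static", function() {
  run_simulation(reference_scene(mus = 5, sampler = sampler_1um()),
                 stop = list(n_detected = 10000), seed = 108)
})
run_mus9_flow15 <- function() cached("run_mus9_flow15", function() {
  run_simulation(reference_scene(mus = 9.11, bead_diameter = 3e-6,
                                 flow_rate = 15, sampler = sampler_3um()),
                 stop = list(n_detected = 5000), seed = 107)
})

# O(photons^2) pairwise-interference oracle: ordered photon pairs (i, j),
# including i = j, accumulated at the signed bin difference of their Doppler
# shifts (`by = "bin"`) or at the nearest frequency bin of |fD_i - fD_j|
# (`by = "freq"`). Polarizations are projected onto the detector plane.
pairwise_oracle <- function(records, n_bins, f_max, by = c("bin", "freq")) {
  by <- match.arg(by)
  edges <- seq(-f_max, f_max, length.out = n_bins + 1)
  df <- edges[2] - edges[1]
  bin_of <- findInterval(records$fD_Hz, edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  n <- nrow(records)
  P <- numeric(n_bins)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      wij <- records$weight[i] * records$weight[j] *
        (records$px[i] * records$px[j] + records$py[i] * records$py[j])^2
      k <- if (by == "bin") {
        bin_of[j] - bin_of[i]
      } else {
        round(abs(records$fD_Hz[i] - records$fD_Hz[j]) / df)
      }
      if (by == "bin" && k < 0) next
      if (by == "freq" && (i > j)) next
      if (k < n_bins) P[k + 1] <- P[k + 1] + wij
    }
  }
  P
}

# relative L1 distance between two spectra over the band occupied by `a`,
# after normalizing each to unit power there (the absolute scale of a
# strip-wise spectrum depends on the strip count; only the shape is
# comparable, as with measurement-normalized spectra)
rel_l1 <- function(a, b, floor_frac = 1e-4) {
  stopifnot(isTRUE(all.equal(a$freq, b$freq)))
  band <- a$power > floor_frac * max(a$power)
  band[1] <- FALSE # exclude the DC self-term
  pa <- a$power[band] / sum(a$power[band])
  pb <- b$power[band] / sum(b$power[band])
  sum(abs(pa - pb))
}

expect_batch_invariants <- function(k, p, tol = 1e-9) {
  expect_lt(max(abs(sqrt(rowSums(k^2)) - 1)), tol)
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), tol)
  expect_lt(max(abs(rowSums(k * p))), tol)
}
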