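test_that("double-gamma response starts at zero and peaks near the peak delay", {
  tg <- seq(0, 32, by = 0.01)
  h <- hrf(tg)
  expect_equal(h[1], 0, tolerance = 1e-8)
  expect_equal(max(h), 1)
  expect_equal(tg[which.max(h)], 5, tolerance = 0.5 / 5)
  # single positive lobe followed by an undershoot
  expect_lt(min(h[tg > 10 & tg < 25]), 0)
})

test_that("periodic design fills the run with whole stimulation cycles", {
  d <- make_periodic_design(10, 1, n_volumes = 200, tr = 2.52)
  expect_length(d$onsets, 50)
  expect_equal(unique(diff(d$onsets)), 10)
  expect_length(make_periodic_design(10, 1, n_volumes = 4, tr = 2.52)$onsets, 1)
})

test_that("pseudo-randomised task design honours count, ISI range and seed", {
  d <- make_task_design(seed = 3)
  expect_length(d$onsets, 40)
  isis <- diff(d$onsets)
  expect_true(all(isis >= 15 & isis <= 25))
  expect_equal(d$n_volumes * d$tr, 1033.2)
  expect_identical(make_task_design(seed = 3)$onsets, d$onsets)
  expect_false(identical(make_task_design(seed = 4)$onsets, d$onsets))
  expect_error(make_task_design(n_stimuli = 100, n_volumes = 100),
               "infeasible")
})

test_that("ROI ramp is 1 at the centre, 0 beyond the radius, monotone between", {
  ph <- tiny_phantom()
  w <- make_roi_ramp(ph, ph$seed_sensory, 6)
  d <- geodesic_from(ph, ph$seed_sensory)
  expect_equal(w[ph$seed_sensory], 1)
  expect_true(all(w[d >= 6] == 0))
  mid <- which.min(abs(d - 3))
  expect_equal(w[mid], 1 - d[mid] / 6, tolerance = 1e-12)
  o <- order(d)
  expect_true(all(diff(w[o]) <= 1e-12))
})

test_that("background noise has the configured temporal autocorrelation", {
  ph <- tiny_phantom()
  zero <- simulate_background(ph, noise_model(sigma = 0, drift_amplitude = 0),
                              n_volumes = 20)
  expect_true(all(zero$data == 0))
  lag1 <- function(ts) {
    mask <- which(ts$phantom$voxel_tissue != "background")
    m <- matrix(ts$data, prod(dim(ts$data)[1:3]), dim(ts$data)[4])[mask, ]
    mean(apply(m, 1, function(x) stats::cor(x[-1], x[-length(x)])))
  }
  white <- simulate_background(ph, noise_model(ar_coeff = 0, drift_amplitude = 0,
                                               spatial_fwhm_mm = 0, seed = 5),
                               n_volumes = 400)
  expect_lt(abs(lag1(white)), 3 / sqrt(400))
  ar <- simulate_background(ph, noise_model(ar_coeff = 0.4, drift_amplitude = 0,
                                            spatial_fwhm_mm = 0, seed = 5),
                            n_volumes = 400)
  expect_equal(lag1(ar), 0.4, tolerance = 0.05 / 0.4)
  # per-voxel standard deviation is calibrated to sigma
  mask <- which(ph$voxel_tissue != "background")
  m <- matrix(ar$data, prod(dim(ar$data)[1:3]), 400)[mask, ]
  expect_equal(mean(apply(m, 1, stats::sd)), 1, tolerance = 0.05)
  # the background compartment stays silent
  bg <- which(ph$voxel_tissue == "background")
  mb <- matrix(ar$data, prod(dim(ar$data)[1:3]), 400)[bg, ]
  expect_true(all(mb == 0))
})

test_that("signal injection is additive and confined to the weighted region", {
  ph <- tiny_phantom()
  ts0 <- simulate_background(ph, noise_model(seed = 2), n_volumes = 40)
  design <- make_periodic_design(10, 1, 40, 2.52)
  w <- make_roi_ramp(ph, ph$seed_sensory, 6)
  ts1 <- inject_hrf_signal(ts0, design, w, amplitude = 2)
  expect_identical(inject_hrf_signal(ts0, design, w, amplitude = 0), ts0)
  diffd <- ts1$data - ts0$data
  w_vox <- map_surface_to_volume(w, ph)
  reg <- event_regressor(design)
  expected <- array(outer(2 * as.numeric(w_vox), reg), dim(ts0$data))
  expect_equal(diffd, expected, tolerance = 1e-12)
  zero_w <- which(as.numeric(w_vox) == 0)[1]
  expect_equal(matrix(diffd, prod(dim(diffd)[1:3]))[zero_w, ],
               rep(0, 40))
  expect_equal(ts1$ground_truth$amplitude, 2 * w_vox)
})

test_that("connectivity signals carry the designed carrier and correlations", {
  sig <- make_connectivity_signals(seed = 9)
  for (s in list(sig$s1, sig$s2c, sig$s2u)) {
    expect_equal(mean(s), 0, tolerance = 1e-10)
  }
  # dominant discrete frequency of s1 is the 0.05 Hz bin
  n <- 210; tr <- 2.52
  spec <- Mod(stats::fft(sig$s1))^2
  freqs <- (seq_len(n) - 1) / (n * tr)
  half <- 2:floor(n / 2)
  peak <- freqs[half][which.max(spec[half])]
  expect_lt(abs(peak - 0.05), 1 / (n * tr))
  # no noise: the shared carrier makes the pair perfectly correlated
  clean <- make_connectivity_signals(noise_fraction = 0, seed = 9)
  expect_equal(stats::cor(clean$s1, clean$s2c), 1, tolerance = 1e-10)
  # pinning yields exact designed sample correlations
  pinned <- make_connectivity_signals(seed = 9, rho_cc = 0.86, rho_uu = 0.042)
  expect_equal(stats::cor(pinned$s1, pinned$s2c), 0.86, tolerance = 1e-10)
  expect_equal(stats::cor(pinned$s1, pinned$s2u), 0.042, tolerance = 1e-10)
  expect_error(make_connectivity_signals(f0 = 0.3, tr = 2.52), "Nyquist")
})

test_that("amplitude scaling reaches the target correlation minimally", {
  set.seed(31)
  n <- 210
  pure <- sin(2 * pi * 0.05 * (0:(n - 1)) * 2.52)
  bg <- as.numeric(stats::arima.sim(list(ar = 0.3), n))
  out <- scale_and_insert(bg, pure, target_r = 0.95)
  expect_gte(out$achieved_r, 0.95)
  expect_equal(out$combined, bg + out$amplitude * pure)
  # one schedule step below the returned amplitude misses the target
  below <- stats::cor(bg + (out$amplitude / 1.1) * pure, pure)
  expect_lt(below, 0.95)
  # correlation grows monotonically along the amplitude grid
  grid <- out$amplitude * 1.1^(-5:5)
  rs <- vapply(grid, function(a) stats::cor(bg + a * pure, pure), numeric(1))
  expect_true(all(diff(rs) > 0))
  # zero background: any amplitude is perfect
  expect_equal(scale_and_insert(numeric(n), pure)$achieved_r, 1)
})

test_that("connectivity cohort calibration holds per subject and is reproducible", {
  ph <- tiny_phantom()
  coh <- simulate_connectivity_cohort(ph, n_subjects = 3, n_volumes = 210,
                                      seed = 6)
  a <- cohort_achieved(coh)
  expect_true(all(a$r_pure >= 0.95))
  expect_true(all(a$r_cc >= 0.80 & a$r_cc <= 0.84))
  expect_true(all(abs(a$r_cu) >= 0.02 & abs(a$r_cu) <= 0.06))
  coh2 <- simulate_connectivity_cohort(ph, n_subjects = 3, n_volumes = 210,
                                       seed = 6)
  expect_identical(cohort_achieved(coh2), a)
  expect_identical(coh2$subjects[[2]]$ts$data, coh$subjects[[2]]$ts$data)
})
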