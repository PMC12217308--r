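test_that("Morlet power peaks at the carrier and vanishes for zero signal", {
  ds <- sine_dataset(freq = 10, fs = 100, n_trials = 1, phases = 0)
  pw <- morlet_power(ds, freqs = 2:30)
  mid <- which.min(abs(pw$times - 3))
  expect_equal(pw$freqs[which.max(pw$power[1, 1, , mid])], 10)
  # unit-amplitude carrier gives ~unit power under the bank's normalization
  expect_equal(pw$power[1, 1, which(pw$freqs == 10), mid], 1, tolerance = 0.02)

  zero <- ds
  zero$voltages[] <- 0
  pz <- morlet_power(zero, freqs = 2:30)
  expect_equal(max(abs(pz$power)), 0)
})

test_that("FFT convolution matches a direct time-domain oracle within 1%", {
  fs <- 100
  ds <- sine_dataset(freq = 10, fs = fs, n_trials = 1, phases = 0)
  pw <- morlet_power(ds, freqs = c(8, 10, 12))
  # independent oracle: explicit time-domain convolution at one sample
  tt <- epoch_times(ds$epoch_def)
  x <- ds$voltages[1, 1, ]
  i0 <- which.min(abs(tt - 3))
  for (f in c(8, 10, 12)) {
    sigma_t <- 6 / (2 * pi * f)
    h <- floor(3 * sigma_t * fs)
    tw <- (-h:h) / fs
    w <- exp(-tw^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tw) *
      2 / (sigma_t * sqrt(2 * pi) * fs)
    acc <- sum(x[i0 - (-h:h)] * w)     # convolution sum at t0
    expect_equal(pw$power[1, 1, which(pw$freqs == f), which.min(abs(pw$times - 3))],
                 Mod(acc)^2, tolerance = 0.01)
  }
})

test_that("power of a stationary sinusoid is flat away from the edges", {
  ds <- sine_dataset(freq = 12, fs = 100, n_trials = 1, phases = 0)
  pw <- morlet_power(ds, freqs = c(12))
  central <- pw$times > 0.5 & pw$times < 6.5
  p <- pw$power[1, 1, 1, central]
  expect_lt(stats::sd(p) / mean(p), 0.02)
})

test_that("frequency bounds are enforced with informative errors", {
  ds <- sine_dataset(fs = 100, n_trials = 1, phases = 0)
  expect_error(morlet_power(ds, freqs = c(10, 50)), "Nyquist")
  short <- sine_dataset(fs = 100, n_trials = 1, phases = 0,
                        epochs = mini_epochs(100))
  expect_error(morlet_power(short, freqs = c(1, 10)), "1 Hz")
})

test_that("phase recovers imposed phase shifts and stays in (-pi, pi]", {
  ds <- sine_dataset(freq = 10, fs = 100, n_trials = 2, phases = c(0, 0))
  ph <- morlet_phase(ds, freqs = c(10))
  expect_equal(max(abs(ph$phase[, 1, , ] - ph$phase[, 2, , ])), 0)

  ds2 <- sine_dataset(freq = 10, fs = 100, n_trials = 1, phases = c(0, pi / 2))
  ph2 <- morlet_phase(ds2, freqs = c(10))
  central <- ph2$times > 1 & ph2$times < 6
  dphi <- ph2$phase[1, 1, 1, central] - ph2$phase[1, 2, 1, central]
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(abs(dphi)), pi / 2, tolerance = 0.05)

  rnd <- random_dataset(n_trials = 3, n_ch = 2, fs = 100, epochs = std_epochs(100))
  ph3 <- morlet_phase(rnd, freqs = c(5, 10))
  expect_true(all(ph3$phase > -pi & ph3$phase <= pi))
})

test_that("bootstrap z-score is scale-invariant, seeded, and near zero under the null", {
  ds <- random_dataset(n_trials = 30, n_ch = 2, fs = 100, epochs = std_epochs(100))
  pw <- morlet_power(ds, freqs = seq(10, 38, by = 2),
                     windows = list(c(-0.5, 0), c(2, 5)))
  z1 <- baseline_bootstrap_zscore(pw, n_boot = 200, seed = 7)
  z2 <- baseline_bootstrap_zscore(pw, n_boot = 200, seed = 7)
  expect_identical(z1$z_power, z2$z_power)

  scaled <- pw
  scaled$power <- pw$power * 3.7
  z3 <- baseline_bootstrap_zscore(scaled, n_boot = 200, seed = 7)
  expect_equal(z3$z_power, z1$z_power, tolerance = 1e-9)

  # task points are draws from the baseline process: the z distribution is
  # centred relative to its own spread (the bootstrap-mean convention
  # inflates the scale by ~sqrt(m), so centring is assessed relative to it)
  task <- z1$times >= 2
  zt <- z1$z_power[, , , task]
  expect_gt(length(zt), 1e4)
  expect_lt(abs(mean(zt)), 0.2 * stats::sd(zt))
  zraw <- baseline_bootstrap_zscore(pw, n_boot = 200, seed = 7,
                                    sd_source = "raw")$z_power[, , , task]
  expect_lt(abs(mean(zraw)), 0.2 * stats::sd(zraw))
  expect_lt(abs(mean(zraw)), 0.3)
})

test_that("z is affine in task power with one shared null per cell", {
  ds <- random_dataset(n_trials = 3, n_ch = 1, fs = 100, epochs = std_epochs(100))
  pw <- morlet_power(ds, freqs = c(20), windows = list(c(-0.5, 0), c(2, 5)))
  t1 <- which(pw$times >= 2)[1:3]
  pw$power[1, 1, 1, t1[1]] <- 0
  pw$power[1, 1, 1, t1[2]] <- 1
  z <- baseline_bootstrap_zscore(pw, n_boot = 300, seed = 4)
  sigma <- 1 / (z$z_power[1, 1, 1, t1[2]] - z$z_power[1, 1, 1, t1[1]])
  mu <- -z$z_power[1, 1, 1, t1[1]] * sigma
  # a task point placed at null mean + 5 null SDs scores z = 5
  pw$power[1, 1, 1, t1[3]] <- mu + 5 * sigma
  z5 <- baseline_bootstrap_zscore(pw, n_boot = 300, seed = 4)
  expect_equal(z5$z_power[1, 1, 1, t1[3]], 5, tolerance = 1e-8)
})

test_that("degenerate baselines raise errors naming the offending cell", {
  ds <- sine_dataset(freq = 10, fs = 100, n_trials = 2, phases = c(0, 0))
  ds$voltages[] <- 0                    # constant zero power everywhere
  pw <- morlet_power(ds, freqs = c(10), windows = list(c(-0.5, 0), c(2, 5)))
  expect_error(baseline_bootstrap_zscore(pw, n_boot = 50, seed = 1),
               "trial 1.*frequency 10")
})

test_that("raw-baseline SD variant is available behind a flag", {
  ds <- random_dataset(n_trials = 4, n_ch = 2, fs = 100, epochs = std_epochs(100))
  pw <- morlet_power(ds, freqs = c(10, 20), windows = list(c(-0.5, 0), c(2, 5)))
  za <- baseline_bootstrap_zscore(pw, n_boot = 100, seed = 1)
  zb <- baseline_bootstrap_zscore(pw, n_boot = 100, seed = 1, sd_source = "raw")
  # raw-sample SD is ~sqrt(m) larger than the bootstrap-mean SD
  expect_gt(mean(abs(za$z_power)) / mean(abs(zb$z_power)), 3)
})
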