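test_that("feature vectorization respects grid size, order, and averaging", {
  ep <- epoch_definition(sampling_rate = 10)  # maintenance [2,5) -> 30 samples
  times <- epoch_times(ep)
  keep <- times >= -0.5 & times < 5
  nt <- sum(times >= 2 & times < 5)
  freqs <- 1:4
  ch <- channel_info(c("e1", "e2", "h1"), c("EC", "EC", "HIPP"), "L")
  tr <- trial_info(1:2, "S01", c(6L, 8L), TRUE)
  z <- array(0, c(2, 3, length(freqs), sum(keep)))
  # distinguishable pattern: z = 100*f + t_index for channel e1, +2 for e2
  tsel <- which(times[keep] >= 2)
  for (f in seq_along(freqs)) for (ti in seq_along(tsel)) {
    z[, 1, f, tsel[ti]] <- 100 * f + ti
    z[, 2, f, tsel[ti]] <- 100 * f + ti + 2
  }
  tfr <- toy_tfr(z, freqs, times[keep], ep, ch, tr)
  fm <- vectorize_features(tfr, "EC", freq_band = c(1, 4))
  expect_equal(ncol(fm$X), 4 * nt)
  # frequency-major flattening: column (f-1)*nt + t; channel average adds 1
  expect_equal(fm$X[1, (3 - 1) * nt + 5], 100 * 3 + 5 + 1)
  # decimation: block means, F = nf * floor(nt / k)
  fm3 <- vectorize_features(tfr, "EC", freq_band = c(1, 4), decimation = 3)
  expect_equal(ncol(fm3$X), 4 * (nt %/% 3))
  expect_equal(fm3$X[1, 1], mean(100 * 1 + (1:3) + 1))
  # single-channel region is the identity
  fmh <- vectorize_features(tfr, "HIPP", freq_band = c(1, 4))
  expect_equal(fmh$X[1, ], as.vector(t(z[1, 3, , tsel])))
  expect_error(vectorize_features(tfr, "LTC"), "no channels")
  expect_error(vectorize_features(tfr, "EC", window = c(6, 7)), "window")
})

test_that("native-resolution maintenance grid yields the canonical 120000 features", {
  ep <- epoch_definition(sampling_rate = 1000)
  times <- seq(2, 5 - 1e-9, by = 1e-3)
  z <- array(0, c(2, 1, 40, length(times)))
  tfr <- toy_tfr(z, 1:40, times, ep,
                 channel_info("e1", "EC", "L"),
                 trial_info(1:2, "S01", c(6L, 8L), TRUE))
  fm <- vectorize_features(tfr, "EC", freq_band = c(1, 40))
  expect_identical(ncol(fm$X), 120000L)
  fm30 <- vectorize_features(tfr, "EC", freq_band = c(1, 40), decimation = 30)
  expect_identical(ncol(fm30$X), 4000L)
})

test_that("stratified splits have the stated sizes and are disjoint", {
  y <- rep(c(4L, 6L), each = 10)
  sp <- split_trials(y, 0.7, seed = 3)
  expect_length(sp$train, 14)
  expect_length(sp$test, 6)
  expect_equal(sum(y[sp$train] == 4), 7)
  expect_length(intersect(sp$train, sp$test), 0)
  # every trial lands in test about 30% of the time
  hits <- rowSums(vapply(1:100, function(s)
    seq_along(y) %in% split_trials(y, 0.7, s)$test, logical(length(y))))
  expect_true(all(hits > 10 & hits < 55))   # binomial(100, .3) bounds
  expect_error(split_trials(c(4L, 6L, 6L), 0.7, 1), "at least 2")
})

test_that("noise-free separable classes decode perfectly", {
  fm <- toy_features(n_per_class = 20, F = 20, effect = 10, noise = 0.01)
  res <- single_region_decode(fm, decoding_config(n_repeats = 5, n_perm = 0, seed = 2))
  expect_equal(res$mean_acc, 1)
  expect_true(all(res$accuracies == 1))
})

test_that("PCA is fit on training rows only and K meets the variance rule", {
  fm <- toy_features(n_per_class = 25, F = 30, effect = 1.5, seed = 4)
  sp <- split_trials(fm$y, 0.7, seed = 11)
  fit <- wmload:::fit_pca_svm(fm$X, fm$y, sp$train, 0.99, 1)
  ref <- stats::prcomp(fm$X[sp$train, ], center = TRUE)
  expect_equal(unname(abs(diag(crossprod(fit$rotation,
                                         ref$rotation[, seq_len(fit$K)])))),
               rep(1, fit$K), tolerance = 1e-8)
  v <- ref$sdev^2
  cum <- cumsum(v) / sum(v)
  expect_gte(cum[fit$K], 0.99)
  expect_lt(cum[fit$K - 1], 0.99)
  # a leaky fit (PCA on all rows) yields measurably different loadings
  leaky <- stats::prcomp(fm$X, center = TRUE)
  expect_gt(max(abs(abs(diag(crossprod(fit$rotation,
                                       leaky$rotation[, seq_len(fit$K)]))) - 1)),
            1e-6)
})

test_that("permutation null is centred at chance with a sane threshold", {
  fm <- toy_features(n_per_class = 50, F = 10, effect = 0, seed = 9)
  cfg <- decoding_config(n_repeats = 5, n_perm = 100, seed = 5)
  null <- permutation_null(fm, cfg)
  expect_lt(abs(mean(null$null_accuracies) - 0.5), 0.04)
  expect_gte(null$threshold95, stats::median(null$null_accuracies))
  expect_true(null$threshold95 <= 1 && null$threshold95 >= 0)
})

test_that("identity transfer reproduces single-region accuracy exactly", {
  fmA <- toy_features(n_per_class = 20, F = 12, effect = 0.8, seed = 6, region = "EC")
  fmB <- fmA; fmB$region <- "HIPP"
  cfg <- decoding_config(n_repeats = 6, n_perm = 0, seed = 13)
  xr <- cross_region_decode(list(EC = fmA, HIPP = fmB), cfg)
  single <- single_region_decode(fmA, cfg)
  expect_equal(unname(xr$acc_matrix["EC", "EC"]), single$mean_acc)
  # copied features transfer identically
  expect_equal(unname(xr$acc_matrix["EC", "HIPP"]),
               unname(xr$acc_matrix["EC", "EC"]))
  # mismatched trials are refused
  fmC <- fmB; fmC$trial_index <- rev(fmC$trial_index)
  expect_error(cross_region_decode(list(EC = fmA, HIPP = fmC), cfg), "mismatch")
})

test_that("per-trial residualization matches the closed-form regression", {
  set.seed(21)
  n <- 10; F <- 50
  fx <- toy_features(n_per_class = n / 2, F = F, effect = 0, seed = 31)
  fy <- toy_features(n_per_class = n / 2, F = F, effect = 0, seed = 32)
  res <- residualize(fy, fx)
  for (i in c(1, 4, n)) {
    fit <- stats::lm(fy$X[i, ] ~ fx$X[i, ])
    expect_equal(unname(res$X[i, ]), unname(stats::residuals(fit)), tolerance = 1e-10)
    expect_lt(abs(mean(res$X[i, ])), 1e-12)
    expect_lt(abs(stats::cor(res$X[i, ], fx$X[i, ])), 1e-10)
  }
  # self-regression gives zero residuals; exact affine maps too
  self <- residualize(fy, fy)
  expect_lt(max(abs(self$X)), 1e-10)
  aff <- fy; aff$X <- 2 * fx$X + 3
  expect_lt(max(abs(residualize(aff, fx)$X)), 1e-10)
  # constant regressor rows are refused
  const <- fx; const$X[2, ] <- 7
  expect_error(residualize(fy, const), "trial 2")
})

test_that("residual decoding removes shared signal and spares private signal", {
  set.seed(77)
  n_per <- 30; F <- 40
  y <- rep(c(6L, 8L), each = n_per)
  gain <- ifelse(y == 8L, 2, 1) * exp(rnorm(2 * n_per, 0, 0.2))
  pattern <- c(rep(1, 8), rep(0, F - 8))
  mkfm <- function(X, region) structure(
    list(X = X, y = y, region = region,
         trial_index = paste0("S01:", seq_along(y)),
         subjects = rep("S01", length(y)), freqs = seq_len(F), times = 1),
    class = "wm_features")
  noise <- function() matrix(rnorm(2 * n_per * F, sd = 0.3), ncol = F)
  fm_y <- mkfm(outer(gain, pattern) + noise(), "HIPP")
  fm_shared <- mkfm(outer(gain, pattern) + noise(), "EC")      # carries the signal
  fm_indep <- mkfm(noise(), "LTC")                             # carries nothing
  cfg <- decoding_config(n_repeats = 6, n_perm = 30, seed = 19)
  rr_shared <- residual_decode(fm_y, fm_shared, cfg)
  rr_indep <- residual_decode(fm_y, fm_indep, cfg)
  expect_gt(rr_shared$original_acc$mean_acc, 0.8)
  # removing the carrier region drops accuracy into the null band
  expect_lt(rr_shared$residual_acc$mean_acc, rr_shared$residual_acc$threshold95)
  expect_lt(rr_shared$delta_acc, -0.2)
  # an unrelated regressor changes little
  expect_gt(rr_indep$delta_acc, -0.1)
})

test_that("balanced decoding subsamples to the minimum class count", {
  fm <- toy_features(n_per_class = 30, F = 10, effect = 1, seed = 3)
  unbal <- fm
  keep <- c(seq_len(30), 30 + seq_len(18))    # 30 vs 18
  unbal$X <- fm$X[keep, ]; unbal$y <- fm$y[keep]
  unbal$trial_index <- fm$trial_index[keep]; unbal$subjects <- fm$subjects[keep]
  cfg <- decoding_config(n_repeats = 4, n_perm = 0, n_balance_resamples = 3, seed = 8)
  bal <- balanced_decode(unbal, cfg)
  expect_equal(bal$n_per_class, 18)
  expect_length(bal$per_resample, 3)
  expect_true(is.finite(bal$sd_between_resamples))
  # already balanced: identical to the plain run under the same seed
  bal2 <- balanced_decode(fm, cfg)
  plain <- single_region_decode(fm, cfg)
  expect_equal(bal2$per_resample[[1]]$accuracies, plain$accuracies)
  expect_equal(bal2$sd_between_resamples, 0)
})

test_that("performance grouping splits at the median with ties going high", {
  beh <- data.frame(subject_id = sprintf("S%02d", 1:5),
                    acc_load8 = c(0.9, 0.8, 0.85, 0.85, 0.7))
  g <- performance_group_split(beh)
  expect_setequal(g$high, c("S01", "S03", "S04"))
  expect_setequal(g$low, c("S02", "S05"))
  expect_error(performance_group_split(
    data.frame(subject_id = c("a", "b"), acc_load8 = c(0.8, 0.8))), "median")
})

test_that("decoding requires a two-class contrast and enough repeats", {
  fm <- toy_features()
  fm3 <- fm; fm3$y[1:5] <- 4L
  expect_error(single_region_decode(fm3, decoding_config()), "two load classes")
  expect_error(single_region_decode(fm, decoding_config(n_repeats = 1)), "n_repeats")
})
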