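# builds a wm_phase object directly from a [trials x channels x freqs x times]
# phase array
toy_phase <- function(ph, freqs = 1, times = 0, hemis = NULL) {
  n_ch <- dim(ph)[2]
  structure(list(phase = ph, freqs = freqs, times = times,
                 channels = channel_info(sprintf("c%d", seq_len(n_ch)),
                                         rep_len(c("EC", "HIPP", "LTC"), n_ch),
                                         if (is.null(hemis)) rep("L", n_ch) else hemis),
                 trials = NULL, epoch_def = std_epochs()),
            class = "wm_phase")
}

test_that("pairing keeps within-hemisphere cross-region pairs only", {
  ch <- channel_info(c("e1", "e2", "h1", "l1"),
                     c("EC", "EC", "HIPP", "LTC"), c("L", "R", "L", "R"))
  pr <- region_pairs(ch)
  expect_setequal(paste(pr$channel_a, pr$channel_b),
                  c("e1 h1", "e2 l1"))
  expect_setequal(pr$pair_type, c("EC-HIPP", "EC-LTC"))
})

test_that("PLV is exactly 1 for constant phase differences and symmetric", {
  n <- 50
  base <- stats::runif(n, -pi, pi)
  ph <- array(0, c(n, 2, 2, 3))
  ph[, 1, , ] <- base
  ph[, 2, , ] <- ((base + 0.7 + pi) %% (2 * pi)) - pi
  phase <- toy_phase(ph, freqs = c(5, 10), times = c(0, 1, 2))
  pairs <- region_pairs(phase$channels)
  pm <- plv_map(phase, pairs)
  expect_equal(max(abs(pm$plv - 1)), 0, tolerance = 1e-12)
  # swapping channel roles leaves PLV unchanged
  pairs_swapped <- pairs
  pairs_swapped[, c("channel_a", "channel_b")] <- pairs[, c("channel_b", "channel_a")]
  expect_equal(plv_map(phase, pairs_swapped)$plv, pm$plv)
  # a trial-constant offset on one channel changes nothing
  ph2 <- ph
  ph2[, 2, , ] <- ((ph2[, 2, , ] + 1.1 + pi) %% (2 * pi)) - pi
  expect_equal(plv_map(toy_phase(ph2, c(5, 10), c(0, 1, 2)), pairs)$plv, pm$plv,
               tolerance = 1e-12)
  expect_error(plv_map(phase, pairs, trials = 1), "2 trials")
})

test_that("independent uniform phases give near-Rayleigh PLV levels", {
  n <- 200
  ph <- array(withr::with_seed(12, stats::runif(n * 2 * 4 * 50, -pi, pi)),
              c(n, 2, 4, 50))
  pm <- plv_map(toy_phase(ph, freqs = 1:4, times = seq_len(50)),
                region_pairs(toy_phase(ph)$channels))
  expect_lt(mean(pm$plv), 0.15)
  expect_equal(mean(pm$plv), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.3)
})

test_that("aggregation is the grand mean over pairs, band and window", {
  ph <- array(0, c(5, 3, 4, 10))
  phase <- toy_phase(ph, freqs = 1:4, times = seq(2, 2.9, by = 0.1))
  pairs <- region_pairs(phase$channels)     # EC-HIPP, EC-LTC, HIPP-LTC
  pm <- plv_map(phase, pairs)
  pm$plv[] <- 0.4
  agg <- aggregate_plv(pm, window = c(2, 3), band = c(1, 4), subject_id = "S01", load = 4)
  expect_equal(agg$plv_scalar, rep(0.4, 3))
  # two values average to their mean, and equal the brute-force grand mean
  pm$plv[] <- stats::runif(length(pm$plv))
  agg2 <- aggregate_plv(pm, window = c(2, 3), band = c(2, 3))
  rows <- which(pm$pair_table$pair_type == "EC-HIPP")
  expect_equal(agg2$plv_scalar[agg2$region_pair == "EC-HIPP"],
               mean(pm$plv[rows, 2:3, ]))
  one <- pm$pair_table$pair_type == "EC-LTC"
  expect_equal(agg2$plv_scalar[agg2$region_pair == "EC-LTC"],
               mean(pm$plv[one, 2:3, ]))
})

test_that("repeated-measures ANOVA matches a hand-rolled sums-of-squares oracle", {
  tab <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3),
                    region_pair = "EC-HIPP",
                    load = rep(c(4, 6, 8), 3),
                    plv_scalar = c(0.20, 0.25, 0.33,
                                   0.18, 0.28, 0.30,
                                   0.22, 0.24, 0.35))
  a <- plv_load_anova(tab, "EC-HIPP")
  # oracle: classical one-way within-subject decomposition
  m <- matrix(tab$plv_scalar, nrow = 3, byrow = TRUE)
  grand <- mean(m)
  ss_load <- 3 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_load - ss_subj
  F_oracle <- (ss_load / 2) / (ss_err / 4)
  expect_equal(a$F, F_oracle, tolerance = 1e-8)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 4)
  expect_equal(a$p, stats::pf(F_oracle, 2, 4, lower.tail = FALSE), tolerance = 1e-8)
  expect_true(a$epsilon_gg >= 0.5 - 1e-8 && a$epsilon_gg <= 1 + 1e-8)
  expect_equal(nrow(a$posthoc), 3)
  expect_true(all(a$posthoc$p_holm >= a$posthoc$p_raw - 1e-12))
})

test_that("a load-flat PLV table yields no load effect", {
  # subject offsets plus measurement noise, no load structure
  withr::with_seed(20, {
    base <- rep(stats::runif(4, 0.2, 0.35), each = 3)
    tab <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 3),
                      region_pair = "EC-HIPP",
                      load = rep(c(4, 6, 8), 4),
                      plv_scalar = base + stats::rnorm(12, 0, 0.02))
  })
  a <- plv_load_anova(tab, "EC-HIPP")
  expect_gt(a$p, 0.1)
  expect_lt(a$F, 4)
  expect_error(plv_load_anova(tab[-1, ], "EC-HIPP"), "missing")
})

test_that("EC residualization removes exactly-linear dependence", {
  set.seed(5)
  subj <- rep(sprintf("s%d", 1:5), each = 3)
  load <- rep(c(4, 6, 8), 5)
  eh <- stats::runif(15, 0.2, 0.6)
  el <- stats::runif(15, 0.2, 0.6)
  tab <- rbind(
    data.frame(subject_id = subj, region_pair = "EC-HIPP", load = load, plv_scalar = eh),
    data.frame(subject_id = subj, region_pair = "EC-LTC", load = load, plv_scalar = el),
    data.frame(subject_id = subj, region_pair = "HIPP-LTC", load = load,
               plv_scalar = 0.1 + 0.5 * eh + 0.3 * el))
  res <- ec_residualized_plv(tab)
  expect_lt(max(abs(res$plv_scalar)), 1e-10)
  # collinear regressors are refused
  bad <- tab
  bad$plv_scalar[bad$region_pair == "EC-LTC"] <-
    bad$plv_scalar[bad$region_pair == "EC-HIPP"]
  expect_error(ec_residualized_plv(bad), "collinear")
})

test_that("residualizing on unrelated EC pairs preserves the load effect", {
  set.seed(8)
  subj <- rep(sprintf("s%d", 1:6), each = 3)
  load <- rep(c(4, 6, 8), 6)
  hl <- 0.2 + 0.05 * (load - 4) / 2 + stats::rnorm(18, 0, 0.01)
  tab <- rbind(
    data.frame(subject_id = subj, region_pair = "EC-HIPP", load = load,
               plv_scalar = stats::runif(18, 0.2, 0.4)),
    data.frame(subject_id = subj, region_pair = "EC-LTC", load = load,
               plv_scalar = stats::runif(18, 0.2, 0.4)),
    data.frame(subject_id = subj, region_pair = "HIPP-LTC", load = load,
               plv_scalar = hl))
  raw <- plv_load_anova(tab, "HIPP-LTC")
  res <- plv_load_anova(ec_residualized_plv(tab), "HIPP-LTC")
  expect_lt(raw$p, 0.01)
  expect_lt(res$p, 0.05)   # effect survives residualization on unrelated pairs
})
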