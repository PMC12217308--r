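#' Decoding configuration
#'
#' Bundles the classifier pipeline settings: 70/30 stratified splits, PCA
#' retaining the smallest number of components explaining at least 99% of
#' the training-set variance, a linear SVM with cost 1, 100 cross-validation
#' repeats and a 100-shuffle permutation null.
#'
#' @param train_frac Fraction of each class assigned to training (0-1).
#' @param n_repeats Number of cross-validation repeats.
#' @param var_keep Cumulative explained-variance threshold for PCA.
#' @param cost Linear SVM cost parameter.
#' @param n_perm Number of label permutations for the null (0 skips it).
#' @param decimation Time block-averaging factor applied before flattening
#'   features (1 = native resolution).
#' @param balance_trials Whether [balanced_decode()] should subsample
#'   classes to the minimum class count.
#' @param n_balance_resamples Resamples for the balanced control.
#' @param seed Master seed; repeats, permutations and resamples derive
#'   their seeds from it.
#' @return An object of class `wm_decode_config`.
#' @export
decoding_config <- function(train_frac = 0.7, n_repeats = 100, var_keep = 0.99,
                            cost = 1, n_perm = 100, decimation = 1,
                            balance_trials = FALSE, n_balance_resamples = 10,
                            seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1, var_keep > 0, var_keep <= 1,
            cost > 0, decimation >= 1, n_repeats >= 1, n_perm >= 0)
  structure(list(train_frac = train_frac, n_repeats = n_repeats,
                 var_keep = var_keep, cost = cost, n_perm = n_perm,
                 decimation = as.integer(decimation),
                 balance_trials = balance_trials,
                 n_balance_resamples = n_balance_resamples, seed = seed),
            class = "wm_decode_config")
}

#' Build a trial-by-feature matrix from z-scored power
#'
#' Averages z-power over a region's channels, restricts to a frequency band
#' and time window, optionally block-averages along time, and flattens to
#' one row per trial with frequency as the slower feature index. At the
#' native 1 ms resolution the 1-40 Hz x 3 s maintenance grid yields
#' 40 x 3000 = 120000 features per trial.
#'
#' @param tfr A `wm_tfr` from [baseline_bootstrap_zscore()].
#' @param region Region whose channels are averaged.
#' @param freq_band `c(low, high)` Hz, inclusive (default 1-40).
#' @param window `c(start, end)` s; default the maintenance epoch.
#' @param decimation Time block size for block-mean decimation (trailing
#'   samples that do not fill a block are dropped).
#' @return An object of class `wm_features`: `X` (trials x features), `y`
#'   (loads), `region`, `trial_index` (subject:trial keys), `subjects`,
#'   `freqs`, `times` (block centres).
#' @export
vectorize_features <- function(tfr, region, freq_band = c(1, 40),
                               window = NULL, decimation = 1) {
  stopifnot(inherits(tfr, "wm_tfr"))
  region <- match.arg(region, REGIONS)
  sel_ch <- which(tfr$channels$region == region)
  if (length(sel_ch) == 0) stop("no channels in region ", region)
  if (is.null(window)) window <- unlist(tfr$epoch_def$maintenance)
  sel_t <- which(tfr$times >= window[1] & tfr$times < window[2])
  if (length(sel_t) == 0)
    stop("window [", window[1], ", ", window[2], ") is outside the available times")
  n_expected <- round((window[2] - window[1]) * tfr$epoch_def$sampling_rate)
  if (length(sel_t) < n_expected)
    stop("window [", window[1], ", ", window[2],
         ") is only partially covered by the available times")
  sel_f <- which(tfr$freqs >= freq_band[1] & tfr$freqs <= freq_band[2])
  if (length(sel_f) == 0) stop("no frequencies inside the requested band")

  z <- tfr$z_power[, sel_ch, sel_f, sel_t, drop = FALSE]
  d <- dim(z)
  # region average over channels
  zm <- if (d[2] == 1) array(z, d[c(1, 3, 4)]) else
    colMeans(aperm(z, c(2, 1, 3, 4)))
  decimation <- as.integer(decimation)
  n_blocks <- length(sel_t) %/% decimation
  if (n_blocks == 0) stop("decimation factor exceeds the number of time samples")
  if (decimation > 1) {
    zm <- zm[, , seq_len(n_blocks * decimation), drop = FALSE]
    dim(zm) <- c(d[1], length(sel_f), decimation, n_blocks)
    zm <- colMeans(aperm(zm, c(3, 1, 2, 4)))
  }
  times <- colMeans(matrix(tfr$times[sel_t][seq_len(n_blocks * decimation)],
                           nrow = decimation))
  # flatten with frequency as the slower index: column = (f - 1) * n_blocks + t
  X <- matrix(aperm(zm, c(1, 3, 2)), nrow = d[1])
  structure(list(X = X, y = tfr$trials$load, region = region,
                 trial_index = paste(tfr$trials$subject_id, tfr$trials$trial_id, sep = ":"),
                 subjects = tfr$trials$subject_id,
                 freqs = tfr$freqs[sel_f], times = times),
            class = "wm_features")
}

#' Restrict a feature matrix to a load contrast
#'
#' @param fm A `wm_features`.
#' @param loads Integer vector of loads to keep, e.g. `c(6, 8)`.
#' @return A `wm_features` with only the selected trials.
#' @export
filter_loads <- function(fm, loads) {
  keep <- fm$y %in% loads
  fm$X <- fm$X[keep, , drop = FALSE]
  fm$y <- fm$y[keep]
  fm$trial_index <- fm$trial_index[keep]
  fm$subjects <- fm$subjects[keep]
  fm
}

#' Stratified train/test split
#'
#' Assigns `floor(train_frac * n)` trials of each class to training and the
#' remainder to testing; train and test are disjoint and preserve row order.
#'
#' @param y Class labels.
#' @param train_frac Training fraction per class.
#' @param seed RNG seed.
#' @return List with integer vectors `train` and `test`.
#' @export
split_trials <- function(y, train_frac = 0.7, seed = 1) {
  classes <- unique(y)
  counts <- table(y)
  if (any(counts < 2)) stop("every class needs at least 2 trials to split")
  train <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, floor(train_frac * length(idx)))
    }))
  })
  list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
}

# PCA (training rows only) + linear SVM fit; returns transfer-ready model.
# Scores are divided by one global factor (their pooled training RMS) so the
# unit-cost margin is expressed on the data's own scale; the same factor is
# applied to every projected test set.
fit_pca_svm <- function(X, y, train, var_keep, cost) {
  pr <- stats::prcomp(X[train, , drop = FALSE], center = TRUE, scale. = FALSE)
  v <- pr$sdev^2
  cum <- cumsum(v) / sum(v)
  K <- which(cum >= var_keep)[1]
  Ztr <- pr$x[, seq_len(K), drop = FALSE]
  s <- sqrt(mean(Ztr^2))
  if (s == 0) s <- 1
  model <- e1071::svm(x = Ztr / s, y = factor(y[train]), kernel = "linear",
                      cost = cost, scale = FALSE)
  list(model = model, center = pr$center, scale = s,
       rotation = pr$rotation[, seq_len(K), drop = FALSE], K = K)
}

predict_acc <- function(fit, X, y, test) {
  Zte <- sweep(X[test, , drop = FALSE], 2, fit$center) %*% fit$rotation / fit$scale
  pred <- stats::predict(fit$model, Zte)
  mean(pred == factor(y[test], levels = fit$model$levels))
}

#' Single-regional load decoding
#'
#' Repeated stratified 70/30 splits; per repeat, PCA is fit on the training
#' rows only (components to >= `var_keep` cumulative variance), test rows
#' are projected through the same transform, and a linear SVM (cost
#' `cfg$cost`) is trained and scored. Significance is assessed against a
#' label-permutation null ([permutation_null()]): mean accuracy strictly
#' above the null's 95th percentile counts as significant.
#'
#' @param fm A `wm_features` with exactly two load classes.
#' @param cfg A [decoding_config()].
#' @return An object of class `wm_decoding`: `accuracies` (one per repeat),
#'   `mean_acc`, `sd_acc`, `n_components_per_repeat`, `null_accuracies`,
#'   `threshold95`, `significant`.
#' @export
single_region_decode <- function(fm, cfg = decoding_config()) {
  stopifnot(inherits(fm, "wm_features"))
  if (length(unique(fm$y)) != 2)
    stop("decoding requires exactly two load classes; use filter_loads()")
  if (cfg$n_repeats < 2) stop("n_repeats must be >= 2")
  roots <- derive_seeds(cfg$seed, 2)
  rep_seeds <- derive_seeds(roots[1], cfg$n_repeats)
  acc <- numeric(cfg$n_repeats)
  K <- integer(cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    sp <- split_trials(fm$y, cfg$train_frac, rep_seeds[r])
    fit <- fit_pca_svm(fm$X, fm$y, sp$train, cfg$var_keep, cfg$cost)
    acc[r] <- predict_acc(fit, fm$X, fm$y, sp$test)
    K[r] <- fit$K
  }
  nullres <- if (cfg$n_perm > 0) permutation_null(fm, cfg, seed = roots[2]) else
    list(null_accuracies = numeric(0), threshold95 = NA_real_)
  mean_acc <- mean(acc)
  structure(list(region = fm$region, contrast = sort(unique(fm$y)),
                 accuracies = acc, mean_acc = mean_acc, sd_acc = stats::sd(acc),
                 n_components_per_repeat = K,
                 null_accuracies = nullres$null_accuracies,
                 threshold95 = nullres$threshold95,
                 significant = isTRUE(mean_acc > nullres$threshold95)),
            class = "wm_decoding")
}

#' @export
print.wm_decoding <- function(x, ...) {
  cat(sprintf("<wm_decoding> %s load %s vs %s: %.1f +/- %.1f%% (n=%d repeats)\n",
              x$region, x$contrast[1], x$contrast[2],
              100 * x$mean_acc, 100 * x$sd_acc, length(x$accuracies)))
  if (!is.na(x$threshold95))
    cat(sprintf("  permutation 95%% threshold %.1f%% -> %s\n", 100 * x$threshold95,
                if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Label-permutation null distribution
#'
#' Shuffles the label-to-trial assignment `n_perm` times and reruns the full
#' split + PCA + SVM pipeline once per permutation; the 95th percentile
#' (linear interpolation) of the null accuracies is the significance
#' threshold.
#'
#' @param fm A two-class `wm_features`.
#' @param cfg A [decoding_config()].
#' @param seed Optional seed (defaults to a stream derived from `cfg$seed`).
#' @return List with `null_accuracies` and `threshold95`.
#' @export
permutation_null <- function(fm, cfg = decoding_config(), seed = NULL) {
  if (length(unique(fm$y)) != 2) stop("permutation null requires two classes")
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 2)[2]
  perm_seeds <- derive_seeds(seed, 2 * cfg$n_perm)
  null_acc <- numeric(cfg$n_perm)
  for (p in seq_len(cfg$n_perm)) {
    y_perm <- with_seed(perm_seeds[p], sample(fm$y))
    sp <- split_trials(y_perm, cfg$train_frac, perm_seeds[cfg$n_perm + p])
    fit <- fit_pca_svm(fm$X, y_perm, sp$train, cfg$var_keep, cfg$cost)
    null_acc[p] <- predict_acc(fit, fm$X, y_perm, sp$test)
  }
  list(null_accuracies = null_acc,
       threshold95 = stats::quantile(null_acc, 0.95, type = 7, names = FALSE))
}

#' Cross-regional decoding generalization
#'
#' Per repeat, one stratified split is shared across regions. For each
#' training region the PCA + SVM pipeline is fit on its training rows; the
#' other regions' features for the *same held-out trials* are projected
#' through that fitted PCA and scored. A region's generalization is the
#' mean of its two transfer accuracies.
#'
#' @param fms Named list of `wm_features` (one per region) over identical
#'   trials (same `trial_index` and labels).
#' @param cfg A [decoding_config()].
#' @return An object of class `wm_crossregion`: `acc_matrix` (train x test
#'   mean accuracies), `generalization`, and the per-repeat array `acc_reps`.
#' @export
cross_region_decode <- function(fms, cfg = decoding_config()) {
  regions <- names(fms)
  stopifnot(length(fms) >= 2, !is.null(regions))
  ref <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(fm$trial_index, ref$trial_index) || !identical(fm$y, ref$y))
      stop("trial_index mismatch across regions: feature matrices must describe identical trials")
  }
  if (length(unique(ref$y)) != 2) stop("decoding requires exactly two load classes")
  rep_seeds <- derive_seeds(derive_seeds(cfg$seed, 2)[1], cfg$n_repeats)
  n_r <- length(regions)
  acc <- array(NA_real_, c(n_r, n_r, cfg$n_repeats),
               dimnames = list(train = regions, test = regions, NULL))
  for (r in seq_len(cfg$n_repeats)) {
    sp <- split_trials(ref$y, cfg$train_frac, rep_seeds[r])
    for (a in regions) {
      fit <- fit_pca_svm(fms[[a]]$X, ref$y, sp$train, cfg$var_keep, cfg$cost)
      for (b in regions)
        acc[a, b, r] <- predict_acc(fit, fms[[b]]$X, ref$y, sp$test)
    }
  }
  acc_matrix <- apply(acc, c(1, 2), mean)
  gen <- vapply(regions, function(a)
    mean(acc_matrix[a, setdiff(regions, a)]), 0)
  structure(list(acc_matrix = acc_matrix, generalization = gen, acc_reps = acc),
            class = "wm_crossregion")
}

#' @export
print.wm_crossregion <- function(x, ...) {
  cat("<wm_crossregion> mean accuracies (rows = train region):\n")
  print(round(100 * x$acc_matrix, 1))
  cat("generalization:", paste(sprintf("%s=%.1f%%", names(x$generalization),
                                       100 * x$generalization), collapse = " "), "\n")
  invisible(x)
}

#' Per-trial residualization of one region's features on another's
#'
#' For each trial, the target region's feature vector is regressed on the
#' regressor region's feature vector (scalar intercept and slope across the
#' feature positions, ordinary least squares); the residuals replace the
#' features. Within each trial the residuals have zero mean and zero
#' correlation with the regressor.
#'
#' @param fm_y Target `wm_features` (dependent).
#' @param fm_x Regressor `wm_features` (independent), same trials and
#'   feature dimension.
#' @return A `wm_features` whose rows are the per-trial residuals.
#' @export
residualize <- function(fm_y, fm_x) {
  if (!identical(fm_y$trial_index, fm_x$trial_index))
    stop("trial_index mismatch between target and regressor features")
  if (ncol(fm_y$X) != ncol(fm_x$X)) stop("feature dimensions differ")
  X <- fm_x$X; Y <- fm_y$X
  cx <- X - rowMeans(X)
  cy <- Y - rowMeans(Y)
  vx <- rowSums(cx^2)
  if (any(vx == 0))
    stop("regressor features constant within trial ", which(vx == 0)[1],
         ": slope undefined")
  beta1 <- rowSums(cx * cy) / vx
  out <- fm_y
  out$X <- cy - beta1 * cx
  out$residualized_on <- fm_x$region
  out
}

#' Residual-based decoding
#'
#' Decodes the target region before and after removing (per trial) the
#' component linearly shared with the regressor region. Both arms use the
#' same configuration seed, hence identical splits.
#'
#' @inheritParams residualize
#' @param cfg A [decoding_config()].
#' @return An object of class `wm_residual`: `original_acc`, `residual_acc`
#'   (both `wm_decoding`) and `delta_acc` (residual mean - original mean).
#' @export
residual_decode <- function(fm_y, fm_x, cfg = decoding_config()) {
  original <- single_region_decode(fm_y, cfg)
  residual <- single_region_decode(residualize(fm_y, fm_x), cfg)
  structure(list(target = fm_y$region, regressor = fm_x$region,
                 original_acc = original, residual_acc = residual,
                 delta_acc = residual$mean_acc - original$mean_acc),
            class = "wm_residual")
}

#' @export
print.wm_residual <- function(x, ...) {
  cat(sprintf("<wm_residual> %s | %s-residual: %.1f%% -> %.1f%% (delta %.1f%%)\n",
              x$target, x$regressor, 100 * x$original_acc$mean_acc,
              100 * x$residual_acc$mean_acc, 100 * x$delta_acc))
  invisible(x)
}

#' Balanced-trial-count control decoding
#'
#' Subsamples every class to the minimum class count and reruns the decode,
#' repeating with distinct subsampling seeds; reports per-resample and
#' pooled results. With already-balanced classes each resample reduces to
#' the unbalanced run.
#'
#' @param fm A two-class `wm_features`.
#' @param cfg A [decoding_config()]; `n_balance_resamples` controls the
#'   number of resamples.
#' @return An object of class `wm_balanced`: `per_resample` (list of
#'   `wm_decoding`), `mean_acc`, `sd_between_resamples`, `n_per_class`.
#' @export
balanced_decode <- function(fm, cfg = decoding_config()) {
  counts <- table(fm$y)
  n_min <- min(counts)
  if (n_min < 2) stop("minimum class count must be >= 2")
  sub_seeds <- derive_seeds(cfg$seed, cfg$n_balance_resamples)
  balanced_already <- all(counts == n_min)
  res <- lapply(seq_len(cfg$n_balance_resamples), function(i) {
    keep <- if (balanced_already) seq_along(fm$y) else
      sort(with_seed(sub_seeds[i], {
        unlist(lapply(unique(fm$y), function(cl)
          sample(which(fm$y == cl), n_min)))
      }))
    sub <- fm
    sub$X <- fm$X[keep, , drop = FALSE]
    sub$y <- fm$y[keep]
    sub$trial_index <- fm$trial_index[keep]
    sub$subjects <- fm$subjects[keep]
    single_region_decode(sub, cfg)
  })
  means <- vapply(res, `[[`, 0, "mean_acc")
  structure(list(per_resample = res, mean_acc = mean(means),
                 sd_between_resamples = stats::sd(means), n_per_class = n_min),
            class = "wm_balanced")
}

#' Median split of subjects by load-8 behavioural accuracy
#'
#' @param behavior Data frame with columns `subject_id` and `acc_load8`
#'   (proportion correct at load 8); ties at the median go to the high group.
#' @return List with character vectors `high` and `low`.
#' @export
performance_group_split <- function(behavior) {
  stopifnot(all(c("subject_id", "acc_load8") %in% names(behavior)))
  if (length(unique(behavior$acc_load8)) == 1)
    stop("all subjects have identical load-8 accuracy: median split undefined")
  med <- stats::median(behavior$acc_load8)
  list(high = behavior$subject_id[behavior$acc_load8 >= med],
       low = behavior$subject_id[behavior$acc_load8 < med])
}

#' Decoding by behavioural performance group
#'
#' Splits subjects at the median load-8 accuracy, pools trials within each
#' group, runs single-regional decoding per region and group (and
#' cross-regional generalization per group), and compares the two groups'
#' cross-validated accuracies with a permutation t test.
#'
#' @param fms Named list of two-class `wm_features` (one per region) over
#'   identical trials, carrying subject labels.
#' @param behavior Data frame with `subject_id` and `acc_load8`.
#' @param cfg A [decoding_config()].
#' @param n_perm_t Permutations for the group-comparison t tests.
#' @return An object of class `wm_groups`: `groups`, per-group `single` and
#'   `cross` results, and per-region `comparison` (permutation t tests on
#'   the accuracy vectors).
#' @export
performance_group_decode <- function(fms, behavior, cfg = decoding_config(),
                                     n_perm_t = 2000) {
  groups <- performance_group_split(behavior)
  if (length(groups$high) < 2 || length(groups$low) < 2)
    stop("each performance group needs at least 2 subjects")
  subset_group <- function(fm, subj) {
    keep <- fm$subjects %in% subj
    fm$X <- fm$X[keep, , drop = FALSE]
    fm$y <- fm$y[keep]
    fm$trial_index <- fm$trial_index[keep]
    fm$subjects <- fm$subjects[keep]
    fm
  }
  out <- list(groups = groups)
  for (g in c("high", "low")) {
    fms_g <- lapply(fms, subset_group, subj = groups[[g]])
    out[[g]] <- list(single = lapply(fms_g, single_region_decode, cfg = cfg),
                     cross = cross_region_decode(fms_g, cfg))
  }
  out$comparison <- lapply(stats::setNames(names(fms), names(fms)), function(r)
    permutation_t_test(out$high$single[[r]]$accuracies,
                       out$low$single[[r]]$accuracies,
                       n_perm = n_perm_t, seed = cfg$seed))
  class(out) <- "wm_groups"
  out
}
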