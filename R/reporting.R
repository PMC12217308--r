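#' Extract region feature matrices from a study
#'
#' The standard preprocessing chain feeding every decoding analysis:
#' correct-trial selection, common average reference, six-cycle Morlet
#' power, bootstrap baseline z-scoring, and region-averaged maintenance
#' features, pooled across subjects (trials are samples).
#'
#' @param study A [wm_study()].
#' @param regions Regions to extract (default all three).
#' @param freqs Frequencies (Hz) for the Morlet decomposition (default
#'   1-40, the decoding band).
#' @param n_cycles Morlet cycles.
#' @param baseline_window Baseline for z-scoring, default `[-0.5, 0)` s.
#' @param n_boot Bootstrap draws for the z-score null.
#' @param window Feature window, default the maintenance epoch.
#' @param decimation Time block-mean factor before flattening.
#' @param correct_only Restrict to correct trials.
#' @param car Apply common average reference.
#' @param seed Seed for the bootstrap resampling (per-subject streams).
#' @return Named list of [vectorize_features()] outputs, one per region,
#'   sharing `trial_index` and labels.
#' @export
extract_features <- function(study, regions = REGIONS, freqs = 1:40,
                             n_cycles = 6, baseline_window = c(-0.5, 0),
                             n_boot = 1000, window = NULL, decimation = 1,
                             correct_only = TRUE, car = TRUE, seed = 1) {
  stopifnot(inherits(study, "wm_study"))
  seeds <- derive_seeds(seed, length(study$subjects))
  parts <- vector("list", length(study$subjects))
  for (s in seq_along(study$subjects)) {
    ds <- study$subjects[[s]]
    if (correct_only) ds <- correct_trials(ds)
    if (car) ds <- common_average_reference(ds)
    win <- if (is.null(window)) unlist(ds$epoch_def$maintenance) else window
    tfr <- baseline_bootstrap_zscore(
      morlet_power(ds, freqs = freqs, n_cycles = n_cycles,
                   windows = list(baseline_window, win)),
      baseline_window, n_boot = n_boot, seed = seeds[s])
    parts[[s]] <- lapply(stats::setNames(regions, regions), function(r)
      vectorize_features(tfr, r, freq_band = range(freqs), window = win,
                         decimation = decimation))
    tfr <- NULL
    gc(FALSE)
  }
  lapply(stats::setNames(regions, regions), function(r) {
    fms <- lapply(parts, `[[`, r)
    out <- fms[[1]]
    out$X <- do.call(rbind, lapply(fms, `[[`, "X"))
    out$y <- unlist(lapply(fms, `[[`, "y"))
    out$trial_index <- unlist(lapply(fms, `[[`, "trial_index"))
    out$subjects <- unlist(lapply(fms, `[[`, "subjects"))
    out
  })
}

#' Experiment configuration
#'
#' Settings for [run_experiment()]. The defaults mirror the package's
#' reference simulation scale (1-40 Hz features, 300-draw bootstrap,
#' 15-sample time decimation, 20 cross-validation repeats, 100-shuffle
#' nulls); raise `n_repeats`/`n_boot`/`decimation = 1` for full-scale runs.
#'
#' @param freqs Morlet frequencies for decoding features.
#' @param n_cycles Morlet cycles.
#' @param baseline_window Baseline for z-scoring.
#' @param n_boot Bootstrap draws.
#' @param decimation Feature time decimation.
#' @param decode A [decoding_config()].
#' @param contrasts List of load pairs to decode.
#' @param residual_pairs List of `c(target, regressor)` region pairs for
#'   residual decoding (run on the second contrast).
#' @param plv_band Band for the PLV analyses.
#' @param run_groups Run the performance-group comparison (needs >= 2
#'   subjects per group).
#' @param n_perm_t Permutations for group comparisons.
#' @param seed Master seed.
#' @return An object of class `wm_experiment_config`.
#' @export
experiment_config <- function(freqs = 1:40, n_cycles = 6,
                              baseline_window = c(-0.5, 0), n_boot = 300,
                              decimation = 15,
                              decode = decoding_config(n_repeats = 20, n_perm = 100),
                              contrasts = list(c(4, 6), c(6, 8)),
                              residual_pairs = list(c("HIPP", "EC"), c("LTC", "EC"),
                                                    c("HIPP", "LTC"), c("LTC", "HIPP")),
                              plv_band = c(1, 40), run_groups = TRUE,
                              n_perm_t = 2000, seed = 1) {
  structure(list(freqs = freqs, n_cycles = n_cycles,
                 baseline_window = baseline_window, n_boot = n_boot,
                 decimation = decimation, decode = decode,
                 contrasts = contrasts, residual_pairs = residual_pairs,
                 plv_band = plv_band, run_groups = run_groups,
                 n_perm_t = n_perm_t, seed = seed),
            class = "wm_experiment_config")
}

cache_get <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Run the end-to-end load analysis
#'
#' Orchestrates, on one study: behavioural summary, feature extraction,
#' single-regional decoding per contrast, cross-regional generalization,
#' residual-based decoding, contrast delta accuracies, the PLV load ANOVAs
#' (raw for all three pairs and hub-residualized HIPP-LTC), and the
#' performance-group comparison. Deterministic given the study and
#' configuration seeds; optional stage caching never changes results.
#'
#' @param study A [wm_study()].
#' @param config An [experiment_config()].
#' @param cache_dir Optional directory for stage caching.
#' @return An object of class `wm_report`.
#' @export
run_experiment <- function(study, config = experiment_config(), cache_dir = NULL) {
  stopifnot(inherits(study, "wm_study"), inherits(config, "wm_experiment_config"))
  key <- function(stage) paste0(stage, "-", rlang::hash(list(stage, config,
                                                             study$config, config$seed)))
  behavior <- behavioral_summary(study)
  fms <- cache_get(cache_dir, key("features"), function()
    extract_features(study, freqs = config$freqs, n_cycles = config$n_cycles,
                     baseline_window = config$baseline_window,
                     n_boot = config$n_boot, decimation = config$decimation,
                     seed = config$seed))
  cname <- function(ct) paste0(ct[1], "v", ct[2])
  single <- list(); cross <- list()
  for (ct in config$contrasts) {
    fms_ct <- lapply(fms, filter_loads, loads = ct)
    single[[cname(ct)]] <- cache_get(cache_dir, key(paste0("single-", cname(ct))),
      function() lapply(fms_ct, single_region_decode, cfg = config$decode))
    cross[[cname(ct)]] <- cache_get(cache_dir, key(paste0("cross-", cname(ct))),
      function() cross_region_decode(fms_ct, config$decode))
  }
  res_ct <- config$contrasts[[length(config$contrasts)]]
  fms_res <- lapply(fms, filter_loads, loads = res_ct)
  residual <- cache_get(cache_dir, key("residual"), function()
    lapply(config$residual_pairs, function(pr)
      residual_decode(fms_res[[pr[1]]], fms_res[[pr[2]]], config$decode)))
  names(residual) <- vapply(config$residual_pairs, function(pr)
    paste0(pr[1], "_", pr[2], "res"), "")

  plv_tab <- cache_get(cache_dir, key("plv"), function()
    plv_table(study, band = config$plv_band))
  plv_anova <- lapply(stats::setNames(sort(unique(plv_tab$region_pair)),
                                      sort(unique(plv_tab$region_pair))),
                      function(tp) plv_load_anova(plv_tab, tp))
  plv_resid_tab <- ec_residualized_plv(plv_tab)
  plv_resid_anova <- plv_load_anova(plv_resid_tab, "HIPP-LTC")

  groups <- NULL
  if (config$run_groups) {
    beh <- behavior$by_subject[c("subject_id", "acc_load8")]
    groups <- tryCatch(
      performance_group_decode(lapply(fms, filter_loads, loads = res_ct),
                               beh, config$decode, config$n_perm_t),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "wm_groups_skipped"))
  }
  report <- structure(list(schema_version = "1.0",
                           behavior = behavior, single = single, cross = cross,
                           residual = residual, plv_table = plv_tab,
                           plv_anova = plv_anova,
                           plv_residualized_anova = plv_resid_anova,
                           groups = groups,
                           config = config, seed = config$seed),
                      class = "wm_report")
  report$delta <- tryCatch(delta_accuracy_table(report), error = function(e) NULL)
  report
}

#' Per-repeat accuracy differences between the two load contrasts
#'
#' Pairs cross-validation repeats by index (repeats share split seeds
#' across contrasts) and tabulates `acc(6v8) - acc(4v6)` per region.
#'
#' @param report A `wm_report` holding both contrasts.
#' @return Tidy data frame `(region, repeat_idx, delta)` with a
#'   `summary` attribute (mean and SD per region).
#' @export
delta_accuracy_table <- function(report) {
  if (length(report$single) < 2) stop("both contrasts are required")
  lo <- report$single[[1]]; hi <- report$single[[2]]
  out <- do.call(rbind, lapply(names(hi), function(r) {
    a <- lo[[r]]$accuracies; b <- hi[[r]]$accuracies
    if (length(a) != length(b)) stop("unequal repeat counts between contrasts")
    data.frame(region = r, repeat_idx = seq_along(a), delta = b - a,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(out, out$region), function(g)
    data.frame(region = g$region[1], mean_delta = mean(g$delta),
               sd_delta = stats::sd(g$delta))))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

#' Write a report's tidy tables and JSON summary
#'
#' Emits `report.json` plus one CSV per result family under
#' `out_dir/tables/`; figures, if wanted, are rendered from these CSVs.
#' Byte-identical across reruns with the same seeds.
#'
#' @param report A `wm_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  tdir <- file.path(out_dir, "tables")
  dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
  acc <- do.call(rbind, lapply(names(report$single), function(ct)
    do.call(rbind, lapply(names(report$single[[ct]]), function(r) {
      d <- report$single[[ct]][[r]]
      data.frame(contrast = ct, region = r, repeat_idx = seq_along(d$accuracies),
                 accuracy = d$accuracies, n_components = d$n_components_per_repeat)
    }))))
  utils::write.csv(acc, file.path(tdir, "single_accuracies.csv"), row.names = FALSE)
  nulls <- do.call(rbind, lapply(names(report$single), function(ct)
    do.call(rbind, lapply(names(report$single[[ct]]), function(r) {
      d <- report$single[[ct]][[r]]
      if (length(d$null_accuracies) == 0) return(NULL)
      data.frame(contrast = ct, region = r, perm = seq_along(d$null_accuracies),
                 accuracy = d$null_accuracies)
    }))))
  if (!is.null(nulls))
    utils::write.csv(nulls, file.path(tdir, "null_accuracies.csv"), row.names = FALSE)
  xr <- do.call(rbind, lapply(names(report$cross), function(ct) {
    m <- report$cross[[ct]]$acc_matrix
    data.frame(contrast = ct, train = rep(rownames(m), ncol(m)),
               test = rep(colnames(m), each = nrow(m)), accuracy = as.vector(m))
  }))
  utils::write.csv(xr, file.path(tdir, "cross_region.csv"), row.names = FALSE)
  resid <- do.call(rbind, lapply(names(report$residual), function(nm) {
    d <- report$residual[[nm]]
    data.frame(analysis = nm, target = d$target, regressor = d$regressor,
               original = d$original_acc$mean_acc,
               residual = d$residual_acc$mean_acc, delta = d$delta_acc)
  }))
  utils::write.csv(resid, file.path(tdir, "residual_decoding.csv"), row.names = FALSE)
  utils::write.csv(report$plv_table, file.path(tdir, "plv_table.csv"), row.names = FALSE)
  if (!is.null(report$delta))
    utils::write.csv(report$delta, file.path(tdir, "delta_accuracy.csv"), row.names = FALSE)
  utils::write.csv(report$behavior$by_load, file.path(tdir, "behavior_by_load.csv"),
                   row.names = FALSE)
  anova_brief <- function(a)
    list(F = a$F, df = c(a$df1, a$df2), p = a$p, epsilon_gg = a$epsilon_gg,
         p_gg = a$p_gg, means = as.list(a$means))
  summary <- list(
    schema_version = report$schema_version, seed = report$seed,
    single = lapply(report$single, function(ct) lapply(ct, function(d)
      list(mean_acc = d$mean_acc, sd_acc = d$sd_acc,
           threshold95 = d$threshold95, significant = d$significant))),
    generalization = lapply(report$cross, function(x) as.list(x$generalization)),
    residual_delta = lapply(report$residual, function(d) d$delta_acc),
    plv_anova = lapply(report$plv_anova, anova_brief),
    plv_residualized_anova = anova_brief(report$plv_residualized_anova),
    behavior = report$behavior$group)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.wm_report <- function(x, ...) {
  cat("<wm_report> schema", x$schema_version, "seed", x$seed, "\n")
  for (ct in names(x$single)) {
    cat(" ", ct, ": ")
    cat(paste(sprintf("%s=%.1f%%%s", names(x$single[[ct]]),
                      100 * vapply(x$single[[ct]], `[[`, 0, "mean_acc"),
                      ifelse(vapply(x$single[[ct]], `[[`, TRUE, "significant"), "*", "")),
              collapse = "  "), "\n")
  }
  for (ct in names(x$cross))
    cat("  generalization ", ct, ": ",
        paste(sprintf("%s=%.1f%%", names(x$cross[[ct]]$generalization),
                      100 * x$cross[[ct]]$generalization), collapse = "  "), "\n", sep = "")
  invisible(x)
}
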