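#' Within-hemisphere cross-region channel pairs
#'
#' Builds the pair table over which PLV is computed: every pair of channels
#' from different regions recorded in the same hemisphere; cross-hemisphere
#' pairs are excluded.
#'
#' @param channels Channel table from [channel_info()].
#' @return Data frame with `channel_a`, `channel_b`, `region_a`, `region_b`,
#'   `hemisphere` and the canonical `pair_type` (regions in alphabetical
#'   order, e.g. `"EC-HIPP"`).
#' @export
region_pairs <- function(channels) {
  idx <- utils::combn(nrow(channels), 2)
  a <- idx[1, ]; b <- idx[2, ]
  keep <- channels$hemisphere[a] == channels$hemisphere[b] &
    channels$region[a] != channels$region[b]
  a <- a[keep]; b <- b[keep]
  ra <- channels$region[a]; rb <- channels$region[b]
  data.frame(channel_a = channels$channel_id[a],
             channel_b = channels$channel_id[b],
             region_a = ra, region_b = rb,
             hemisphere = channels$hemisphere[a],
             pair_type = paste(pmin(ra, rb), pmax(ra, rb), sep = "-"),
             stringsAsFactors = FALSE)
}

#' Phase-locking value map
#'
#' For each channel pair and time-frequency point, the modulus of the
#' trial-averaged unit phasor of the phase difference:
#' `PLV(t,f) = |mean_n exp(i(phi_a - phi_b))|`, in `[0, 1]`.
#'
#' @param phase A `wm_phase` from [morlet_phase()].
#' @param pairs Pair table from [region_pairs()] (any subset of its rows).
#' @param trials Optional logical/integer selection of trials (default all).
#' @return An object of class `wm_plvmap`: `plv` `[pairs x freqs x times]`,
#'   `pair_table`, `n_trials`, `freqs`, `times`.
#' @export
plv_map <- function(phase, pairs, trials = NULL) {
  stopifnot(inherits(phase, "wm_phase"))
  if (is.null(trials)) trials <- seq_len(dim(phase$phase)[1])
  if (is.logical(trials)) trials <- which(trials)
  if (length(trials) < 2)
    stop("PLV needs at least 2 trials (a single trial gives PLV = 1 degenerately)")
  ids <- phase$channels$channel_id
  ia <- match(pairs$channel_a, ids)
  ib <- match(pairs$channel_b, ids)
  if (anyNA(ia) || anyNA(ib)) stop("pair table references unknown channels")
  d <- dim(phase$phase)
  plv <- array(NA_real_, c(nrow(pairs), d[3], d[4]))
  for (p in seq_len(nrow(pairs))) {
    for (k in seq_len(d[3])) {      # per frequency, to bound temporaries
      dphi <- phase$phase[trials, ia[p], k, ] - phase$phase[trials, ib[p], k, ]
      plv[p, k, ] <- Mod(colMeans(exp(1i * dphi)))
    }
  }
  structure(list(plv = plv, pair_table = pairs, n_trials = length(trials),
                 freqs = phase$freqs, times = phase$times,
                 epoch_def = phase$epoch_def),
            class = "wm_plvmap")
}

#' Aggregate a PLV map to one scalar per region pair
#'
#' Grand mean over all channel pairs of each region-pair type, frequencies
#' in `band` and times in `window` — one row per pair type.
#'
#' @param plvmap A `wm_plvmap`.
#' @param window `c(start, end)` s; default the maintenance epoch.
#' @param band `c(low, high)` Hz, inclusive.
#' @param subject_id Subject label for the output rows.
#' @param load Load label for the output rows.
#' @return Data frame rows `(subject_id, region_pair, load, plv_scalar,
#'   n_pairs)`.
#' @export
aggregate_plv <- function(plvmap, window = NULL, band = c(1, 40),
                          subject_id = NA_character_, load = NA_integer_) {
  stopifnot(inherits(plvmap, "wm_plvmap"))
  if (is.null(window)) window <- unlist(plvmap$epoch_def$maintenance)
  sel_t <- plvmap$times >= window[1] & plvmap$times < window[2]
  sel_f <- plvmap$freqs >= band[1] & plvmap$freqs <= band[2]
  if (!any(sel_t) || !any(sel_f)) stop("window/band outside the PLV map axes")
  types <- sort(unique(plvmap$pair_table$pair_type))
  out <- do.call(rbind, lapply(types, function(tp) {
    rows <- which(plvmap$pair_table$pair_type == tp)
    data.frame(subject_id = subject_id, region_pair = tp, load = load,
               plv_scalar = mean(plvmap$plv[rows, sel_f, sel_t]),
               n_pairs = length(rows), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Subject x region-pair x load PLV table
#'
#' Runs the full connectivity pipeline on a study: common average
#' reference, Morlet phase (1-40 Hz, six cycles) over the maintenance
#' window, Eq.-style PLV across each subject's correct trials of each load,
#' aggregated to one scalar per subject x pair type x load. Subjects with
#' no qualifying pairs are omitted with a warning.
#'
#' @param study A [wm_study()].
#' @param band `c(low, high)` Hz for phase extraction and aggregation.
#' @param window `c(start, end)` s; default the maintenance epoch.
#' @param loads Loads to tabulate.
#' @param correct_only Restrict to correct trials (default `TRUE`).
#' @param n_cycles Morlet cycles.
#' @param car Apply common average reference first (default `TRUE`).
#' @return Data frame with `subject_id`, `region_pair`, `load`,
#'   `plv_scalar`, `n_pairs`, `n_trials`.
#' @export
plv_table <- function(study, band = c(1, 40), window = NULL, loads = LOADS,
                      correct_only = TRUE, n_cycles = 6, car = TRUE) {
  stopifnot(inherits(study, "wm_study"))
  freqs <- seq(ceiling(band[1]), floor(band[2]))
  out <- list()
  for (nm in names(study$subjects)) {
    ds <- study$subjects[[nm]]
    if (correct_only) ds <- correct_trials(ds)
    if (car) ds <- common_average_reference(ds)
    win <- if (is.null(window)) unlist(ds$epoch_def$maintenance) else window
    pairs <- region_pairs(ds$channels)
    if (nrow(pairs) == 0) {
      warning("subject ", nm, " has no within-hemisphere cross-region pairs; omitted")
      next
    }
    phase <- morlet_phase(ds, freqs = freqs, n_cycles = n_cycles, windows = win)
    for (L in loads) {
      sel <- ds$trials$load == L
      pm <- plv_map(phase, pairs, sel)
      rows <- aggregate_plv(pm, window = win, band = band,
                            subject_id = nm, load = L)
      rows$n_trials <- pm$n_trials
      out[[length(out) + 1]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Repeated-measures load ANOVA on PLV
#'
#' One-way repeated-measures ANOVA (load as the within-subject factor) on
#' the scalar PLV of one region pair, with Greenhouse-Geisser-corrected p
#' reported alongside and Holm-corrected paired t tests as post hocs.
#'
#' @param table PLV table from [plv_table()] (or the same columns).
#' @param pair_type Region pair to analyse, e.g. `"EC-HIPP"`; `NULL` is
#'   allowed when `table` holds a single pair type.
#' @return List with `F`, `df1`, `df2`, `p`, `epsilon_gg`, `p_gg`,
#'   `means` (per load), and `posthoc` (pairwise Holm-corrected paired t).
#' @export
plv_load_anova <- function(table, pair_type = NULL) {
  if (!is.null(pair_type)) table <- table[table$region_pair == pair_type, ]
  if (nrow(table) == 0) stop("no rows for pair type ", pair_type)
  loads <- sort(unique(table$load))
  subjects <- unique(table$subject_id)
  for (s in subjects) for (L in loads)
    if (sum(table$subject_id == s & table$load == L) != 1)
      stop("missing or duplicated PLV cell: subject ", s, ", load ", L)
  df <- data.frame(plv = table$plv_scalar,
                   load = factor(table$load),
                   subject = factor(table$subject_id))
  fit <- stats::aov(plv ~ load + Error(subject / load), data = df)
  tab <- summary(fit)[["Error: subject:load"]][[1]]
  F_val <- tab["load", "F value"]
  df1 <- tab["load", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["load", "Pr(>F)"]
  # Greenhouse-Geisser sphericity correction from the subject x load matrix
  wide <- tapply(df$plv, list(df$subject, df$load), mean)
  k <- ncol(wide)
  S <- stats::cov(wide)
  C <- diag(k) - 1 / k
  CSC <- C %*% S %*% C
  eps <- sum(diag(CSC))^2 / ((k - 1) * sum(CSC^2))
  p_gg <- stats::pf(F_val, df1 * eps, df2 * eps, lower.tail = FALSE)
  combos <- utils::combn(loads, 2)
  ph <- data.frame(load_a = combos[1, ], load_b = combos[2, ])
  ph$t <- NA_real_; ph$p_raw <- NA_real_
  for (i in seq_len(nrow(ph))) {
    va <- wide[, as.character(ph$load_a[i])]
    vb <- wide[, as.character(ph$load_b[i])]
    tt <- stats::t.test(va, vb, paired = TRUE)
    ph$t[i] <- unname(tt$statistic); ph$p_raw[i] <- tt$p.value
  }
  ph$p_holm <- stats::p.adjust(ph$p_raw, method = "holm")
  list(pair_type = if (is.null(pair_type)) unique(table$region_pair) else pair_type,
       F = F_val, df1 = df1, df2 = df2, p = p,
       epsilon_gg = eps, p_gg = p_gg,
       means = tapply(df$plv, df$load, mean), posthoc = ph)
}

#' Hub-residualized PLV for the hippocampus-LTC pair
#'
#' Regresses, across the subject x load rows, the HIPP-LTC scalar PLV on
#' the two EC-involving scalar PLVs (OLS with intercept; or on their mean
#' with `regressors = "mean"`) and returns the HIPP-LTC rows with the
#' residuals as `plv_scalar`, ready for [plv_load_anova()].
#'
#' @param table PLV table containing `EC-HIPP`, `EC-LTC` and `HIPP-LTC`
#'   rows for every subject x load.
#' @param regressors `"both"` (default, two-regressor OLS) or `"mean"`
#'   (single regressor, the mean of the two EC PLVs).
#' @return A PLV table for `HIPP-LTC` with residualized `plv_scalar`.
#' @export
ec_residualized_plv <- function(table, regressors = c("both", "mean")) {
  regressors <- match.arg(regressors)
  need <- c("EC-HIPP", "EC-LTC", "HIPP-LTC")
  if (!all(need %in% table$region_pair))
    stop("table must contain rows for ", paste(need, collapse = ", "))
  get <- function(tp) {
    x <- table[table$region_pair == tp, c("subject_id", "load", "plv_scalar")]
    names(x)[3] <- tp
    x
  }
  wide <- Reduce(function(a, b) merge(a, b, by = c("subject_id", "load")),
                 lapply(need, get))
  if (anyNA(wide)) stop("missing subject x load cells in the PLV table")
  X <- if (regressors == "both")
    cbind(1, wide[["EC-HIPP"]], wide[["EC-LTC"]]) else
    cbind(1, (wide[["EC-HIPP"]] + wide[["EC-LTC"]]) / 2)
  if (qr(X)$rank < ncol(X))
    stop("EC PLV regressors are constant or collinear: residualization undefined")
  y <- wide[["HIPP-LTC"]]
  res <- stats::lsfit(X, y, intercept = FALSE)$residuals
  out <- wide[c("subject_id", "load")]
  out$region_pair <- "HIPP-LTC"
  out$plv_scalar <- res
  out[c("subject_id", "region_pair", "load", "plv_scalar")]
}
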