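#' Pashler's working-memory capacity estimate
#'
#' `K_P = (hit_rate - fa_rate) * N / (1 - fa_rate)`, the standard capacity
#' estimator for whole-display probe tasks.
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates in `[0, 1]`
#'   (`fa_rate < 1`); vectorized.
#' @param N Set size (number of letters presented).
#' @return Numeric `K_P` values.
#' @export
pashler_k <- function(hit_rate, fa_rate, N) {
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1, na.rm = TRUE),
            all(fa_rate >= 0 & fa_rate <= 1, na.rm = TRUE))
  if (any(fa_rate == 1, na.rm = TRUE))
    stop("false-alarm rate of 1 leaves K_P undefined")
  (hit_rate - fa_rate) * N / (1 - fa_rate)
}

t_statistic <- function(a, b, paired, flavor) {
  if (paired) {
    d <- a - b
    s <- stats::sd(d)
    if (s == 0) return(if (mean(d) == 0) 0 else sign(mean(d)) * Inf)
    return(mean(d) / (s / sqrt(length(d))))
  }
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (flavor == "welch") {
    se <- sqrt(va / na + vb / nb)
  } else {
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    se <- sp * sqrt(1 / na + 1 / nb)
  }
  if (se == 0) return(if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf)
  (mean(a) - mean(b)) / se
}

#' Permutation t test
#'
#' Computes a Welch (default) or Student t statistic and references it to a
#' null built by label exchanges: random reassignment of the pooled values
#' preserving group sizes (unpaired) or random sign flips of the paired
#' differences (paired). Two-sided p with add-one smoothing,
#' `p = (1 + #\{|t*| >= |t|\}) / (n_perm + 1)`. With `exact = TRUE` all
#' reassignments (or sign patterns) are enumerated and `p` is the exact
#' proportion.
#'
#' @param a,b Numeric samples (equal length if `paired`).
#' @param n_perm Number of random permutations.
#' @param paired Paired test via sign flips of `a - b`.
#' @param seed RNG seed.
#' @param flavor `"welch"` (default) or `"student"` pooled-variance t.
#' @param exact Enumerate all label exchanges instead of sampling.
#' @return List with `t`, `p`, `n_perm`, `paired`, `flavor`.
#' @export
permutation_t_test <- function(a, b, n_perm = 10000, paired = FALSE, seed = 1,
                               flavor = c("welch", "student"), exact = FALSE) {
  flavor <- match.arg(flavor)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")
  if (!paired && stats::var(a) == 0 && stats::var(b) == 0 &&
      stats::var(c(a, b)) == 0)
    stop("zero variance in both samples: t statistic undefined")
  t_obs <- t_statistic(a, b, paired, flavor)
  tol <- 1e-12
  if (exact) {
    if (paired) {
      n <- length(a)
      if (n > 20) stop("exact paired enumeration limited to n <= 20")
      d <- a - b
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      t_null <- apply(signs, 1, function(s) t_statistic(d * s, numeric(n), TRUE, flavor))
    } else {
      pool <- c(a, b)
      na <- length(a)
      combos <- utils::combn(length(pool), na)
      t_null <- apply(combos, 2, function(idx)
        t_statistic(pool[idx], pool[-idx], FALSE, flavor))
    }
    p <- mean(abs(t_null) >= abs(t_obs) - tol)
    n_used <- length(t_null)
  } else {
    t_null <- with_seed(seed, {
      if (paired) {
        d <- a - b
        n <- length(d)
        vapply(seq_len(n_perm), function(i)
          t_statistic(d * sample(c(-1, 1), n, replace = TRUE), numeric(n),
                      TRUE, flavor), 0)
      } else {
        pool <- c(a, b)
        na <- length(a)
        vapply(seq_len(n_perm), function(i) {
          idx <- sample.int(length(pool), na)
          t_statistic(pool[idx], pool[-idx], FALSE, flavor)
        }, 0)
      }
    })
    p <- (1 + sum(abs(t_null) >= abs(t_obs) - tol)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(t = t_obs, p = p, n_perm = n_used, paired = paired, flavor = flavor)
}

#' Behavioural summary with capacity estimates
#'
#' Computes, per subject and load, hit and false-alarm rates from probe
#' membership and responses, Pashler's `K_P`, the subject's `K_max`
#' (maximum `K_P` across loads) and overall accuracy, plus group-level
#' medians. Loads for which a subject lacks "in" or "out" probes get `NA`
#' rates (flagged with a warning).
#'
#' @param trials Trial table (or `wm_study`) with columns `subject_id`,
#'   `load`, `correct`, `probe_in`, `response_in`.
#' @return An object of class `wm_behavior`: `by_load` (subject x load
#'   rates and `K_P`), `by_subject` (`K_max`, `accuracy_pct`, `acc_load8`),
#'   and `group` (medians / means across subjects).
#' @export
behavioral_summary <- function(trials) {
  if (inherits(trials, "wm_study"))
    trials <- do.call(rbind, lapply(trials$subjects, `[[`, "trials"))
  req <- c("subject_id", "load", "correct", "probe_in", "response_in")
  if (!all(req %in% names(trials)))
    stop("trial table lacks column(s): ", paste(setdiff(req, names(trials)), collapse = ", "))
  by_load <- do.call(rbind, lapply(split(trials, trials[c("subject_id", "load")]),
                                   function(g) {
    if (nrow(g) == 0) return(NULL)
    n_in <- sum(g$probe_in); n_out <- sum(!g$probe_in)
    hit <- if (n_in > 0) mean(g$response_in[g$probe_in]) else NA_real_
    fa <- if (n_out > 0) mean(g$response_in[!g$probe_in]) else NA_real_
    data.frame(subject_id = g$subject_id[1], load = g$load[1], n_trials = nrow(g),
               hit_rate = hit, fa_rate = fa,
               K_P = if (!is.na(hit) && !is.na(fa) && fa < 1)
                 pashler_k(hit, fa, g$load[1]) else NA_real_,
               accuracy = mean(g$correct))
  }))
  rownames(by_load) <- NULL
  if (anyNA(by_load$hit_rate) || anyNA(by_load$fa_rate))
    warning("some subject x load cells lack 'in' or 'out' probes; rates flagged NA")
  by_subject <- do.call(rbind, lapply(split(trials, trials$subject_id), function(g) {
    bl <- by_load[by_load$subject_id == g$subject_id[1], ]
    l8 <- g[g$load == 8, ]
    data.frame(subject_id = g$subject_id[1],
               K_max = if (all(is.na(bl$K_P))) NA_real_ else max(bl$K_P, na.rm = TRUE),
               accuracy_pct = 100 * mean(g$correct),
               acc_load8 = if (nrow(l8) > 0) mean(l8$correct) else NA_real_)
  }))
  rownames(by_subject) <- NULL
  group <- list(median_K_max = stats::median(by_subject$K_max, na.rm = TRUE),
                mean_accuracy_pct = mean(by_subject$accuracy_pct),
                sd_accuracy_pct = stats::sd(by_subject$accuracy_pct),
                median_accuracy_pct = stats::median(by_subject$accuracy_pct))
  structure(list(by_load = by_load, by_subject = by_subject, group = group),
            class = "wm_behavior")
}

#' @export
print.wm_behavior <- function(x, ...) {
  cat(sprintf("<wm_behavior> %d subjects; accuracy %.2f +/- %.2f%%, median K_max %.2f\n",
              nrow(x$by_subject), x$group$mean_accuracy_pct,
              x$group$sd_accuracy_pct, x$group$median_K_max))
  invisible(x)
}
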