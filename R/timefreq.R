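# Complex Morlet filter bank, FFT-domain. Wavelets are Gaussian-windowed
# complex exponentials with sigma_t = n_cycles / (2*pi*f), truncated at
# +/- 3 sigma_t, scaled so a unit-amplitude sinusoid at the carrier yields
# unit power at the peak.
morlet_bank <- function(freqs, n_cycles, fs, n_samples, nfft) {
  lapply(freqs, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    h <- floor(3 * sigma_t * fs)
    len <- 2L * h + 1L
    if (len > n_samples)
      stop("wavelet at ", f, " Hz (", len, " samples) is longer than the epoch (",
           n_samples, " samples)")
    tw <- (-h:h) / fs
    w <- exp(-tw^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tw)
    w <- w * 2 / (sigma_t * sqrt(2 * pi) * fs)
    list(f = f, half = h, W = stats::fft(c(w, complex(nfft - len))))
  })
}

# Morlet coefficients for all (trial, channel, freq, kept time); `output`
# selects what is materialized (power/phase avoid holding the full complex
# tensor in memory)
morlet_transform <- function(dataset, freqs, n_cycles = 6, windows = NULL,
                             output = c("complex", "power", "phase")) {
  output <- match.arg(output)
  stopifnot(inherits(dataset, "wm_dataset"))
  fs <- dataset$epoch_def$sampling_rate
  if (any(freqs <= 0)) stop("frequencies must be positive")
  if (any(freqs >= fs / 2))
    stop("frequency ", max(freqs), " Hz is at or above the Nyquist limit (", fs / 2, " Hz)")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly increasing")
  times <- epoch_times(dataset$epoch_def)
  n_t <- length(times)
  d <- dim(dataset$voltages)
  keep <- if (is.null(windows)) rep(TRUE, n_t) else {
    if (!is.list(windows)) windows <- list(windows)
    Reduce(`|`, lapply(windows, function(w) times >= w[1] & times < w[2]))
  }
  if (!any(keep)) stop("no samples fall inside the requested window(s)")
  kept_times <- times[keep]

  max_h <- floor(3 * (n_cycles / (2 * pi * min(freqs))) * fs)
  nfft <- stats::nextn(n_t + 2L * max_h + 1L, 2)
  bank <- morlet_bank(freqs, n_cycles, fs, n_t, nfft)
  for (k in seq_along(bank)) bank[[k]]$W <- bank[[k]]$W / nfft

  # batch all trial x channel signals as columns of one matrix
  sig <- matrix(aperm(dataset$voltages, c(3, 1, 2)), nrow = n_t)
  sig <- rbind(sig, matrix(0, nfft - n_t, ncol(sig)))
  X <- stats::mvfft(sig)
  sig <- NULL

  out <- if (output == "complex")
    array(0i, c(d[1], d[2], length(freqs), sum(keep))) else
    array(0, c(d[1], d[2], length(freqs), sum(keep)))
  for (k in seq_along(bank)) {
    b <- bank[[k]]
    Y <- stats::mvfft(X * b$W, inverse = TRUE)
    Y <- Y[(b$half + 1L):(b$half + n_t), , drop = FALSE][keep, , drop = FALSE]
    if (output == "power") Y <- Re(Y)^2 + Im(Y)^2
    else if (output == "phase") {
      Y <- Arg(Y)
      Y[Y <= -pi] <- pi
    }
    out[, , k, ] <- aperm(array(Y, c(sum(keep), d[1], d[2])), c(2, 3, 1))
    if (k %% 8L == 0L) gc(FALSE)   # large complex temporaries per band
  }
  edge_valid <- vapply(bank, function(b) {
    lo <- times[1] + b$half / fs
    hi <- times[n_t] - b$half / fs
    kept_times >= lo & kept_times <= hi
  }, logical(length(kept_times)))
  list(coef = out, freqs = freqs, times = kept_times,
       edge_valid = t(edge_valid),   # freqs x times, TRUE = untouched by padding
       channels = dataset$channels, trials = dataset$trials,
       epoch_def = dataset$epoch_def)
}

#' Morlet wavelet power
#'
#' Convolves every trial and channel with six-cycle complex Morlet wavelets
#' (zero-padded FFT convolution) and returns squared-magnitude power at the
#' native sample resolution.
#'
#' @param dataset A [recording_dataset()].
#' @param freqs Strictly increasing frequencies (Hz), below Nyquist;
#'   default 1-100 Hz in 1 Hz steps (capped below Nyquist).
#' @param n_cycles Wavelet width in cycles (default 6).
#' @param windows Optional list of `c(start, end)` time intervals (s) to
#'   retain, e.g. baseline + maintenance, to bound memory; `NULL` keeps all.
#' @return An object of class `wm_rawpower`: `power`
#'   `[trials x channels x freqs x times]`, with `freqs`, `times`, metadata,
#'   and an `edge_valid` `[freqs x times]` mask flagging samples further
#'   than half a wavelet from the epoch edges.
#' @export
morlet_power <- function(dataset, freqs = NULL, n_cycles = 6, windows = NULL) {
  fs <- dataset$epoch_def$sampling_rate
  if (is.null(freqs)) freqs <- seq(1, min(100, ceiling(fs / 2) - 1))
  tf <- morlet_transform(dataset, freqs, n_cycles, windows, output = "power")
  tf$power <- tf$coef
  tf$coef <- NULL
  class(tf) <- "wm_rawpower"
  tf
}

#' Morlet wavelet phase
#'
#' @inheritParams morlet_power
#' @param freqs Frequencies (Hz); default 1-40 Hz in 1 Hz steps.
#' @return An object of class `wm_phase` with `phase`
#'   `[trials x channels x freqs x times]` in `(-pi, pi]`.
#' @export
morlet_phase <- function(dataset, freqs = 1:40, n_cycles = 6, windows = NULL) {
  tf <- morlet_transform(dataset, freqs, n_cycles, windows, output = "phase")
  tf$phase <- tf$coef
  tf$coef <- NULL
  class(tf) <- "wm_phase"
  tf
}

#' Bootstrap baseline z-scoring of Morlet power
#'
#' For every (trial, channel, frequency) cell a null distribution is built
#' from the cell's own pre-stimulus baseline power: `n_boot` bootstrap
#' draws, each resampling as many points (with replacement) as the baseline
#' holds and averaging them — a bootstrap of the baseline mean. Power at
#' each time point is then z-scored against the mean and SD of that null.
#' One resampling-weight matrix is drawn per call (seeded) and applied to
#' every cell's own baseline vector, which keeps each cell's null correct
#' while making the computation a single matrix product.
#'
#' @param power A `wm_rawpower` from [morlet_power()]; its times must cover
#'   `baseline_window`.
#' @param baseline_window `c(start, end)` seconds; default the last 500 ms
#'   of fixation, `[-0.5, 0)`.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed RNG seed for the resampling.
#' @param sd_source `"bootstrap"` (SD of the bootstrap-mean null, default)
#'   or `"raw"` (SD of the raw baseline samples).
#' @return An object of class `wm_tfr` with `z_power`
#'   `[trials x channels x freqs x times]` plus axes and metadata.
#' @export
baseline_bootstrap_zscore <- function(power, baseline_window = c(-0.5, 0),
                                      n_boot = 1000, seed = 1,
                                      sd_source = c("bootstrap", "raw")) {
  stopifnot(inherits(power, "wm_rawpower"))
  sd_source <- match.arg(sd_source)
  b_idx <- which(power$times >= baseline_window[1] & power$times < baseline_window[2])
  m <- length(b_idx)
  if (m < 2) stop("baseline window holds fewer than 2 samples of `power$times`")
  d <- dim(power$power)
  n_cells <- d[1] * d[2] * d[3]
  P <- matrix(power$power, nrow = n_cells)        # cells x times (time is slowest dim)
  power$power <- NULL   # drop the local reference; P is the working copy
  B <- P[, b_idx, drop = FALSE]
  mu_b <- rowMeans(B)
  ss <- rowSums(B^2) - m * mu_b^2
  degenerate <- which(ss <= 0 | ss / pmax(mu_b^2, .Machine$double.xmin) < 1e-24)
  if (length(degenerate) > 0) {
    ind <- arrayInd(degenerate[1], d[1:3])
    stop("zero baseline variance for trial ", ind[1], ", channel ", ind[2],
         " ('", power$channels$channel_id[ind[2]], "'), frequency ",
         power$freqs[ind[3]], " Hz: z-score undefined")
  }
  if (sd_source == "bootstrap") {
    W <- with_seed(seed, {
      t(vapply(seq_len(n_boot),
               function(i) tabulate(sample.int(m, m, replace = TRUE), m),
               integer(m))) / m
    })
    tW <- t(W)                                    # m x n_boot
    mu <- numeric(n_cells); sd <- numeric(n_cells)
    chunk <- max(1L, floor(2e7 / n_boot))
    for (i0 in seq(1L, n_cells, by = chunk)) {
      i1 <- min(i0 + chunk - 1L, n_cells)
      nm <- B[i0:i1, , drop = FALSE] %*% tW       # cells_chunk x n_boot
      cm <- rowMeans(nm)
      mu[i0:i1] <- cm
      sd[i0:i1] <- sqrt(pmax(0, (rowSums(nm^2) - n_boot * cm^2) / (n_boot - 1)))
    }
  } else {
    mu <- mu_b
    sd <- sqrt(ss / (m - 1))
  }
  if (any(sd == 0)) {
    ind <- arrayInd(which(sd == 0)[1], d[1:3])
    stop("degenerate bootstrap null (zero SD) for trial ", ind[1], ", channel ",
         ind[2], ", frequency ", power$freqs[ind[3]], " Hz")
  }
  # standardize in place, chunked, to avoid a third tensor-sized allocation
  step <- max(1L, floor(5e7 / ncol(P)))
  for (i0 in seq(1L, n_cells, by = step)) {
    i1 <- min(i0 + step - 1L, n_cells)
    P[i0:i1, ] <- (P[i0:i1, , drop = FALSE] - mu[i0:i1]) / sd[i0:i1]
  }
  dim(P) <- d
  structure(list(z_power = P, freqs = power$freqs, times = power$times,
                 baseline_window = baseline_window, edge_valid = power$edge_valid,
                 channels = power$channels, trials = power$trials,
                 epoch_def = power$epoch_def),
            class = "wm_tfr")
}

#' @export
print.wm_tfr <- function(x, ...) {
  d <- dim(x$z_power)
  cat("<wm_tfr> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " freqs x ", d[4], " times (z-scored power)\n", sep = "")
  invisible(x)
}
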