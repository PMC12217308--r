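# Small builders used across the suite. Everything is generated in code;
# no fixture files.

# compact epoch layout (1.6 s total) for I/O and bookkeeping tests
mini_epochs <- function(fs = 50) {
  epoch_definition(baseline = c(-0.4, 0), encoding = c(0, 0.4),
                   maintenance = c(0.4, 1.2), retrieval = c(1.2, 1.6),
                   sampling_rate = fs)
}

# full 8 s layout at a test-friendly rate
std_epochs <- function(fs = 100) epoch_definition(sampling_rate = fs)

# deterministic sinusoid dataset: one sinusoid per channel, optional phase
# shift per channel, identical across trials
sine_dataset <- function(freq = 10, fs = 100, n_trials = 2, phases = c(0, 0),
                         amplitude = 1, epochs = std_epochs(fs),
                         regions = NULL, hemis = NULL) {
  tt <- epoch_times(epochs)
  n_ch <- length(phases)
  v <- array(0, c(n_trials, n_ch, length(tt)))
  for (j in seq_len(n_ch))
    v[, j, ] <- matrix(amplitude * cos(2 * pi * freq * tt + phases[j]),
                       n_trials, length(tt), byrow = TRUE)
  if (is.null(regions)) regions <- rep_len(c("HIPP", "EC", "LTC"), n_ch)
  if (is.null(hemis)) hemis <- rep("L", n_ch)
  recording_dataset(v,
                    channel_info(sprintf("ch%02d", seq_len(n_ch)), regions, hemis),
                    trial_info(seq_len(n_trials), "S01",
                               rep_len(c(4L, 6L), n_trials), TRUE),
                    epochs)
}

random_dataset <- function(n_trials = 4, n_ch = 4, fs = 50, seed = 99,
                           epochs = mini_epochs(fs)) {
  tt <- epoch_times(epochs)
  v <- array(withr::with_seed(seed, stats::rnorm(n_trials * n_ch * length(tt))),
             c(n_trials, n_ch, length(tt)))
  recording_dataset(v,
                    channel_info(sprintf("ch%02d", seq_len(n_ch)),
                                 rep_len(c("HIPP", "EC", "LTC"), n_ch),
                                 rep_len(c("L", "R"), n_ch)),
                    trial_info(seq_len(n_trials), "S01",
                               rep_len(c(4L, 6L, 8L), n_trials), TRUE),
                    epochs)
}

# hand-built z-power container for feature tests: z[tr, ch, f, t]
toy_tfr <- function(z, freqs, times, epochs, channels, trials) {
  structure(list(z_power = z, freqs = freqs, times = times,
                 baseline_window = c(-0.5, 0), edge_valid = NULL,
                 channels = channels, trials = trials, epoch_def = epochs),
            class = "wm_tfr")
}

# feature matrix with a class-dependent mean shift on selected columns
toy_features <- function(n_per_class = 30, F = 40, effect = 1, signal_cols = 1:5,
                         region = "EC", seed = 1, noise = 1) {
  y <- rep(c(6L, 8L), each = n_per_class)
  X <- withr::with_seed(seed, {
    X <- matrix(stats::rnorm(2 * n_per_class * F, sd = noise), ncol = F)
    X[y == 8L, signal_cols] <- X[y == 8L, signal_cols] + effect
    X
  })
  structure(list(X = X, y = y, region = region,
                 trial_index = paste0("S01:", seq_along(y)),
                 subjects = rep("S01", length(y)),
                 freqs = seq_len(F), times = 1),
            class = "wm_features")
}

# tiny synthetic study for pipeline-level tests
tiny_config <- function(seed = 1, n_subjects = 2, tpl = 12, fs = 100) {
  synthetic_config(n_subjects = n_subjects,
                   trials_per_load = stats::setNames(rep(tpl, 3), c(4, 6, 8)),
                   epoch_def = epoch_definition(sampling_rate = fs),
                   seed = seed)
}
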