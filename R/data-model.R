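#' @keywords internal
"_PACKAGE"

REGIONS <- c("HIPP", "EC", "LTC")
HEMISPHERES <- c("L", "R")
LOADS <- c(4L, 6L, 8L)

#' Epoch definition for trial-based recordings
#'
#' Describes the four task epochs of a trial on a time axis in seconds
#' relative to stimulus (letter-array) onset. Intervals are half-open
#' `[start, end)` so adjacent epochs never double-count a sample. The
#' defaults follow the standard Sternberg layout: 1 s fixation baseline,
#' 2 s encoding, 3 s maintenance, 2 s retrieval.
#'
#' @param baseline,encoding,maintenance,retrieval Numeric length-2 vectors,
#'   `c(start, end)` in seconds relative to stimulus onset.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `wm_epochs`.
#' @export
epoch_definition <- function(baseline = c(-1, 0), encoding = c(0, 2),
                             maintenance = c(2, 5), retrieval = c(5, 7),
                             sampling_rate = 1000) {
  ivs <- list(baseline = baseline, encoding = encoding,
              maintenance = maintenance, retrieval = retrieval)
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (length(iv) != 2 || !is.numeric(iv) || iv[2] <= iv[1])
      stop("epoch interval '", nm, "' must be c(start, end) with end > start")
  }
  bounds <- do.call(rbind, ivs)
  if (any(diff(as.vector(t(bounds))) < 0))
    stop("epoch intervals must be ordered and non-overlapping")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  structure(c(ivs, list(sampling_rate = sampling_rate)), class = "wm_epochs")
}

#' Sample time axis of an epoch definition
#'
#' @param epoch_def A [epoch_definition()] object.
#' @return Numeric vector of sample times (s), spanning
#'   `[baseline start, retrieval end)` at `1/sampling_rate` steps.
#' @export
epoch_times <- function(epoch_def) {
  fs <- epoch_def$sampling_rate
  t0 <- epoch_def$baseline[1]
  t1 <- epoch_def$retrieval[2]
  n <- round((t1 - t0) * fs)
  t0 + (seq_len(n) - 1L) / fs
}

#' Channel metadata table
#'
#' @param channel_id Character vector, unique channel labels.
#' @param region Region of each contact: `"HIPP"`, `"EC"` or `"LTC"`.
#' @param hemisphere `"L"` or `"R"`.
#' @param soz Logical, seizure-onset-zone flag (default `FALSE`).
#' @return A `data.frame` with one row per channel.
#' @export
channel_info <- function(channel_id, region, hemisphere, soz = FALSE) {
  channel_id <- as.character(channel_id)
  if (anyDuplicated(channel_id)) stop("channel_id values must be unique")
  region <- match.arg(as.character(region), REGIONS, several.ok = TRUE)
  hemisphere <- match.arg(as.character(hemisphere), HEMISPHERES, several.ok = TRUE)
  data.frame(channel_id = channel_id,
             region = rep_len(region, length(channel_id)),
             hemisphere = rep_len(hemisphere, length(channel_id)),
             soz = rep_len(as.logical(soz), length(channel_id)),
             stringsAsFactors = FALSE)
}

#' Trial metadata table
#'
#' @param trial_id Integer trial identifiers, unique within a subject.
#' @param subject_id Character subject labels.
#' @param load Working-memory load, one of 4, 6, 8.
#' @param correct Logical, whether the probe response was correct.
#' @param session Integer session index (default 1).
#' @param probe_in Optional logical, whether the probe letter was in the set.
#' @param response_in Optional logical, whether the response was "IN".
#' @return A `data.frame` with one row per trial.
#' @export
trial_info <- function(trial_id, subject_id, load, correct, session = 1L,
                       probe_in = NULL, response_in = NULL) {
  load <- as.integer(load)
  if (!all(load %in% LOADS)) stop("load must be one of 4, 6, 8")
  out <- data.frame(trial_id = as.integer(trial_id),
                    subject_id = as.character(subject_id),
                    load = load,
                    correct = as.logical(correct),
                    session = as.integer(session),
                    stringsAsFactors = FALSE)
  if (!is.null(probe_in)) out$probe_in <- as.logical(probe_in)
  if (!is.null(response_in)) out$response_in <- as.logical(response_in)
  if (anyDuplicated(out[c("subject_id", "trial_id")]))
    stop("trial_id must be unique within subject")
  out
}

#' Trial-epoched multichannel recording
#'
#' The universal input of the pipeline: a voltage tensor
#' `[trials x channels x samples]` (microvolts) together with channel and
#' trial metadata and the epoch layout.
#'
#' @param voltages 3-d numeric array `[trials x channels x samples]`.
#' @param channels Channel table from [channel_info()].
#' @param trials Trial table from [trial_info()].
#' @param epoch_def An [epoch_definition()].
#' @return An object of class `wm_dataset`.
#' @export
recording_dataset <- function(voltages, channels, trials, epoch_def) {
  stopifnot(inherits(epoch_def, "wm_epochs"))
  d <- dim(voltages)
  if (length(d) != 3) stop("voltages must be a 3-d array [trials x channels x samples]")
  if (d[1] == 0) stop("dataset must contain at least one trial")
  if (d[1] != nrow(trials))
    stop("integrity error: voltage tensor has ", d[1], " trials but trial table has ", nrow(trials))
  if (d[2] != nrow(channels))
    stop("integrity error: voltage tensor has ", d[2], " channels but channel table has ", nrow(channels))
  n_expected <- length(epoch_times(epoch_def))
  if (d[3] != n_expected)
    stop("integrity error: ", d[3], " samples but epoch span implies ", n_expected)
  if (anyNA(voltages)) stop("voltages contain missing values")
  if (anyDuplicated(channels$channel_id)) stop("channel_id values must be unique")
  structure(list(voltages = voltages, channels = channels, trials = trials,
                 epoch_def = epoch_def),
            class = "wm_dataset")
}

#' @export
print.wm_dataset <- function(x, ...) {
  d <- dim(x$voltages)
  cat("<wm_dataset> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$epoch_def$sampling_rate, " Hz\n", sep = "")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$channels$region)),
                                  table(x$channels$region)), collapse = " "), "\n")
  cat("  loads:  ", paste(sprintf("%s=%d", names(table(x$trials$load)),
                                  table(x$trials$load)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a dataset by trials
#'
#' Selections preserve input order; trials are never silently reordered.
#'
#' @param dataset A `wm_dataset`.
#' @param idx Integer or logical index into the trial dimension.
#' @return A `wm_dataset` with the selected trials.
#' @export
select_trials <- function(dataset, idx) {
  if (is.logical(idx)) idx <- which(idx)
  recording_dataset(dataset$voltages[idx, , , drop = FALSE],
                    dataset$channels,
                    dataset$trials[idx, , drop = FALSE],
                    dataset$epoch_def)
}

#' Keep only correct trials
#'
#' Analyses are run on correct trials by default; this is the explicit
#' filtering step.
#'
#' @param dataset A `wm_dataset`.
#' @return A `wm_dataset` restricted to rows with `correct == TRUE`.
#' @export
correct_trials <- function(dataset) select_trials(dataset, dataset$trials$correct)

#' Write a dataset to disk
#'
#' Writes a directory container: the voltage tensor as an Arrow Feather
#' table (`voltages.feather`, one column per channel plus trial/sample
#' indices), channel and trial metadata as CSV, and the epoch definition as
#' a JSON sidecar — every piece inspectable without custom tooling.
#'
#' @param dataset A `wm_dataset`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "wm_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  d <- dim(dataset$voltages)
  # long layout: rows ordered trial-major, then sample; one column per channel
  flat <- aperm(dataset$voltages, c(3, 1, 2))      # samples x trials x channels
  dim(flat) <- c(d[3] * d[1], d[2])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[3]),
                   sample = rep(seq_len(d[3]), times = d[1]))
  volt <- as.data.frame(flat)
  names(volt) <- dataset$channels$channel_id
  arrow::write_feather(cbind(df, volt), file.path(path, "voltages.feather"))
  utils::write.csv(dataset$channels, file.path(path, "channels.csv"), row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(path, "trials.csv"), row.names = FALSE)
  ep <- dataset$epoch_def
  jsonlite::write_json(list(baseline = ep$baseline, encoding = ep$encoding,
                            maintenance = ep$maintenance, retrieval = ep$retrieval,
                            sampling_rate = ep$sampling_rate),
                       file.path(path, "epochs.json"), digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Directory containing the container layout.
#' @return A `wm_dataset`; all invariants are re-validated on load.
#' @export
read_dataset <- function(path) {
  for (f in c("voltages.feather", "channels.csv", "trials.csv", "epochs.json"))
    if (!file.exists(file.path(path, f)))
      stop("format error: missing '", f, "' in ", path)
  ep <- jsonlite::read_json(file.path(path, "epochs.json"), simplifyVector = TRUE)
  epoch_def <- epoch_definition(ep$baseline, ep$encoding, ep$maintenance,
                                ep$retrieval, ep$sampling_rate)
  channels <- utils::read.csv(file.path(path, "channels.csv"), stringsAsFactors = FALSE)
  for (col in c("channel_id", "region", "hemisphere", "soz"))
    if (is.null(channels[[col]]))
      stop("format error: channels.csv lacks required column '", col, "'")
  trials <- utils::read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  for (col in c("trial_id", "subject_id", "load", "correct"))
    if (is.null(trials[[col]]))
      stop("format error: trials.csv lacks required column '", col, "'")
  tab <- as.data.frame(arrow::read_feather(file.path(path, "voltages.feather")))
  n_trials <- nrow(trials); n_ch <- nrow(channels)
  n_samp <- nrow(tab) / n_trials
  if (n_samp != round(n_samp))
    stop("integrity error: voltage rows not a multiple of trial count")
  flat <- as.matrix(tab[, channels$channel_id, drop = FALSE])
  dim(flat) <- c(n_samp, n_trials, n_ch)
  voltages <- aperm(flat, c(2, 3, 1))
  recording_dataset(voltages, channels, trials, epoch_def)
}

#' Common average reference
#'
#' Subtracts, at every sample of every trial, the mean voltage across all
#' channels. Idempotent; after referencing the channel mean is zero at every
#' sample.
#'
#' @param dataset A `wm_dataset` with at least two channels.
#' @return A re-referenced `wm_dataset`.
#' @export
common_average_reference <- function(dataset) {
  d <- dim(dataset$voltages)
  if (d[2] < 2) stop("common average reference undefined for a single channel")
  m <- apply(dataset$voltages, c(1, 3), mean)        # trials x samples
  v <- dataset$voltages - aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
  out <- dataset
  out$voltages <- v
  out
}

#' Multi-subject study container
#'
#' A study is a named list of per-subject [recording_dataset()]s sharing one
#' epoch layout; keeping subjects separate avoids padding a single tensor
#' with channels that were never recorded for a given trial.
#'
#' @param datasets Named list of `wm_dataset`, one per subject.
#' @param config Optional configuration echo (e.g. the generator config).
#' @return An object of class `wm_study`.
#' @export
wm_study <- function(datasets, config = NULL) {
  stopifnot(length(datasets) >= 1, all(vapply(datasets, inherits, TRUE, "wm_dataset")))
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    names(datasets) <- vapply(datasets, function(d) d$trials$subject_id[1], "")
  structure(list(subjects = datasets, config = config), class = "wm_study")
}

#' @export
print.wm_study <- function(x, ...) {
  cat("<wm_study> ", length(x$subjects), " subjects: ",
      paste(names(x$subjects), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a study (one sub-directory per subject)
#' @param study A `wm_study`.
#' @param path Directory root.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$subjects))
    write_dataset(study$subjects[[nm]], file.path(path, nm))
  jsonlite::write_json(list(subjects = names(study$subjects)),
                       file.path(path, "study.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a study written by [write_study()]
#' @param path Directory root.
#' @return A `wm_study`.
#' @export
read_study <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "study.json"), simplifyVector = TRUE)
  ds <- lapply(meta$subjects, function(nm) read_dataset(file.path(path, nm)))
  names(ds) <- meta$subjects
  wm_study(ds)
}

# restore the caller's RNG state after seeded internal draws
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# k independent sub-seeds derived from one master seed
derive_seeds <- function(seed, k) with_seed(seed, sample.int(.Machine$integer.max, k))
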