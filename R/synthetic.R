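#' Per-region generator specification
#'
#' Describes the signal carried by one region's channels in the synthetic
#' generator: a band-limited oscillation whose amplitude may depend on
#' working-memory load, a `hub_weight`-scaled copy of the study-wide shared
#' latent oscillation, and white noise.
#'
#' @param region `"HIPP"`, `"EC"` or `"LTC"`.
#' @param n_channels_per_subject Channels implanted per subject in this region.
#' @param band Length-2 numeric, the region's oscillation band (Hz); each
#'   channel's carrier frequency is drawn uniformly inside it.
#' @param power_by_load Named numeric (`"4"`, `"6"`, `"8"`), amplitude
#'   multipliers (> 0) of the region's own oscillation per load.
#' @param hub_weight Fraction in `[0, 1]` scaling the shared latent copy.
#' @param own_amp_sd Per-trial log-normal SD of the region's own task-period
#'   oscillation amplitude (load-independent trial-to-trial variability).
#' @param noise_sd White-noise standard deviation (microvolts).
#' @return An object of class `wm_region_spec`.
#' @export
region_spec <- function(region, n_channels_per_subject = 2,
                        band = c(8, 12),
                        power_by_load = c(`4` = 1, `6` = 1, `8` = 1),
                        hub_weight = 0.5, own_amp_sd = 0.3, noise_sd = 1) {
  region <- match.arg(region, REGIONS)
  stopifnot(length(band) == 2, band[1] <= band[2], band[1] > 0)
  power_by_load <- unlist(power_by_load)[as.character(LOADS)]
  if (anyNA(power_by_load) || any(power_by_load <= 0))
    stop("power_by_load must give a positive multiplier for loads 4, 6, 8")
  if (hub_weight < 0 || hub_weight > 1) stop("hub_weight must be in [0, 1]")
  structure(list(region = region, n_channels_per_subject = n_channels_per_subject,
                 band = band, power_by_load = power_by_load,
                 hub_weight = hub_weight, own_amp_sd = own_amp_sd,
                 noise_sd = noise_sd),
            class = "wm_region_spec")
}

#' Inter-regional phase-coupling specification
#'
#' Phase coupling is routed through the hub region's shared latent: the
#' non-hub member of `pair` receives the latent with a per-trial von Mises
#' phase offset of concentration `kappa_by_load[load]`. `kappa = 0` means
#' independent phases; the expected narrow-band PLV at the latent frequency
#' is `I1(kappa)/I0(kappa)` in the noise-free limit.
#'
#' @param pair Character length-2, the two regions; one must be the hub.
#' @param kappa_by_load Named non-negative numeric for loads 4, 6, 8.
#' @param latent_freq Frequency (Hz) of this pathway's latent component;
#'   `NULL` falls back to the configuration-level `latent_freq`.
#' @return An object of class `wm_coupling_spec`.
#' @export
coupling_spec <- function(pair, kappa_by_load = c(`4` = 0, `6` = 0, `8` = 0),
                          latent_freq = NULL) {
  pair <- match.arg(pair, REGIONS, several.ok = TRUE)
  if (length(pair) != 2 || pair[1] == pair[2]) stop("pair must name two distinct regions")
  kappa_by_load <- unlist(kappa_by_load)[as.character(LOADS)]
  if (anyNA(kappa_by_load) || any(!is.finite(kappa_by_load)) || any(kappa_by_load < 0))
    stop("kappa_by_load must be finite and >= 0 for loads 4, 6, 8")
  structure(list(pair = pair, kappa_by_load = kappa_by_load,
                 latent_freq = latent_freq),
            class = "wm_coupling_spec")
}

#' Synthetic study configuration
#'
#' Defaults describe the package's reference simulation: a hub-structured
#' study in which the entorhinal cortex carries a full-weight copy of a
#' load-modulated 25 Hz latent oscillation and routes it — with
#' load-dependent phase concentration — to hippocampus and lateral temporal
#' cortex, whose own band oscillations are load-flat. Scaled for desk-top
#' runtimes: 4 subjects, 60 trials/load, 2 channels/region, 200 Hz.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_load Named positive integers for loads 4, 6, 8.
#' @param epoch_def An [epoch_definition()].
#' @param regions List of [region_spec()]s.
#' @param couplings List of [coupling_spec()]s; every pair must include `hub`.
#' @param hub Region through which all cross-region sharing is routed.
#' @param latent_freq Fallback frequency (Hz) for pathways that do not set
#'   their own `latent_freq`.
#' @param cross_leak Fraction of the amplitude at which each non-hub region
#'   also receives the other pathways' latent components (background
#'   synchrony between the hub's targets; phases keep the region's
#'   load-dependent von Mises offset).
#' @param leak_load_mix Fraction in `[0, 1]` of the leak amplitude that
#'   follows the load multiplier; the remainder is fixed at the across-load
#'   mean. 0 makes leak power load-flat, 1 makes it fully load-scaled.
#' @param latent_power_by_load Amplitude multipliers of the latent per load;
#'   this is the load signal broadcast by the hub.
#' @param latent_amp_sd Per-trial log-normal SD of each pathway's latent
#'   amplitude, shared by the hub's copy and the target's copy (trial-to-
#'   trial fluctuation of the broadcast itself).
#' @param relay_amp_sd Additional per-trial log-normal SD of the relay gain
#'   applied only to the non-hub target's copy (transmission variability on
#'   top of the shared fluctuation).
#' @param subject_sd Between-subject SD of log amplitude multipliers
#'   (log-normal heterogeneity).
#' @param subject_kappa_sd Between-subject SD of the log phase-coupling
#'   concentration (log-normal scaling of every kappa for that subject).
#' @param behavioral_accuracy_by_load Probability correct per load, in (0, 1].
#' @param subject_latent_scale Optional numeric of length `n_subjects`
#'   multiplying each subject's latent amplitude (default 1); used to build
#'   performance-contrast cohorts.
#' @param subject_accuracy_shift Optional per-subject additive shift of the
#'   behavioural accuracies (default 0).
#' @param seed Master RNG seed; the whole study is reproducible from it.
#' @return An object of class `wm_synth_config`.
#' @export
synthetic_config <- function(n_subjects = 4,
                             trials_per_load = c(`4` = 60, `6` = 60, `8` = 60),
                             epoch_def = epoch_definition(sampling_rate = 200),
                             regions = list(
                               region_spec("HIPP", 4, band = c(4, 7), hub_weight = 0.5,
                                           own_amp_sd = 0.3),
                               region_spec("EC", 4, band = c(10, 13), hub_weight = 0.5,
                                           own_amp_sd = 0.3),
                               region_spec("LTC", 4, band = c(36, 39), hub_weight = 0.5,
                                           own_amp_sd = 0.3)),
                             couplings = list(
                               coupling_spec(c("EC", "HIPP"),
                                             c(`4` = 0.2, `6` = 1.5, `8` = 5),
                                             latent_freq = 24),
                               coupling_spec(c("EC", "LTC"),
                                             c(`4` = 0.15, `6` = 1.2, `8` = 4),
                                             latent_freq = 32)),
                             hub = "EC",
                             latent_freq = 25,
                             cross_leak = 0.9,
                             leak_load_mix = 0,
                             latent_power_by_load = c(`4` = 1, `6` = 1.6, `8` = 2.4),
                             latent_amp_sd = 0.25,
                             relay_amp_sd = 0,
                             subject_sd = 0.1,
                             subject_kappa_sd = 0.4,
                             behavioral_accuracy_by_load = c(`4` = 0.95, `6` = 0.92, `8` = 0.88),
                             subject_latent_scale = NULL,
                             subject_accuracy_shift = NULL,
                             seed = 1) {
  trials_per_load <- unlist(trials_per_load)[as.character(LOADS)]
  if (anyNA(trials_per_load) || any(trials_per_load <= 0))
    stop("trials_per_load must be positive for loads 4, 6, 8")
  acc <- unlist(behavioral_accuracy_by_load)[as.character(LOADS)]
  if (anyNA(acc) || any(acc <= 0) || any(acc > 1))
    stop("behavioral_accuracy_by_load must be in (0, 1]")
  region_names <- vapply(regions, `[[`, "", "region")
  if (anyDuplicated(region_names)) stop("duplicate region specs")
  for (cp in couplings) {
    if (!all(cp$pair %in% region_names))
      stop("config error: coupling references region(s) absent from `regions`: ",
           paste(setdiff(cp$pair, region_names), collapse = ", "))
    if (!hub %in% cp$pair)
      stop("config error: coupling ", paste(cp$pair, collapse = "-"),
           " does not include the hub region '", hub, "'")
  }
  if (length(couplings) > 0 && !hub %in% region_names)
    stop("config error: hub region '", hub, "' not in `regions`")
  lat <- unlist(latent_power_by_load)[as.character(LOADS)]
  if (anyNA(lat) || any(lat <= 0)) stop("latent_power_by_load must be positive")
  structure(list(n_subjects = n_subjects, trials_per_load = trials_per_load,
                 epoch_def = epoch_def, regions = regions,
                 couplings = couplings, hub = hub, latent_freq = latent_freq,
                 cross_leak = cross_leak, leak_load_mix = leak_load_mix,
                 latent_power_by_load = lat, latent_amp_sd = latent_amp_sd,
                 relay_amp_sd = relay_amp_sd,
                 subject_sd = subject_sd, subject_kappa_sd = subject_kappa_sd,
                 behavioral_accuracy_by_load = acc,
                 subject_latent_scale = subject_latent_scale,
                 subject_accuracy_shift = subject_accuracy_shift,
                 seed = seed),
            class = "wm_synth_config")
}

#' von Mises random deviates
#'
#' Best-Fisher rejection sampler; `kappa = 0` reduces to the uniform
#' distribution on `(-pi, pi]`.
#'
#' @param n Number of deviates.
#' @param mu Mean direction (radians).
#' @param kappa Concentration, finite and `>= 0`.
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, is.finite(kappa))
  if (kappa < 1e-10) {
    theta <- stats::runif(n, -pi, pi)
    return(theta)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out <- c(out, theta[ok])
  }
  th <- (mu + out[seq_len(n)] + pi) %% (2 * pi) - pi
  ifelse(th == -pi, pi, th)
}

# per-region phase-offset concentration for a given load, derived from the
# hub-routed couplings; the hub itself carries the latent with zero offset
region_kappa <- function(config, load) {
  region_names <- vapply(config$regions, `[[`, "", "region")
  k <- stats::setNames(rep(0, length(region_names)), region_names)
  k[config$hub] <- Inf
  for (cp in config$couplings) {
    other <- setdiff(cp$pair, config$hub)
    k[other] <- cp$kappa_by_load[[as.character(load)]]
  }
  k
}

generate_subject <- function(config, subject_id, subject_index, seed) {
  with_seed(seed, {
    ep <- config$epoch_def
    t <- epoch_times(ep)
    task <- t >= ep$encoding[1]
    base <- !task
    region_names <- vapply(config$regions, `[[`, "", "region")

    # channels: alternate hemispheres within region
    ch <- do.call(rbind, lapply(config$regions, function(rs) {
      n <- rs$n_channels_per_subject
      channel_info(sprintf("%s_%s_%02d", subject_id, rs$region, seq_len(n)),
                   rs$region,
                   rep_len(HEMISPHERES, n))
    }))
    ch_region <- ch$region
    ch_freq <- numeric(nrow(ch))
    for (rs in config$regions) {
      sel <- ch_region == rs$region
      ch_freq[sel] <- stats::runif(sum(sel), rs$band[1], rs$band[2])
    }
    # per-contact polarity of the latent copy (dipole orientation), balanced
    # within each region so the shared component cancels exactly in the
    # common average; power and pairwise phase locking are unaffected (a
    # fixed pi offset leaves PLV unchanged)
    lat_sign <- numeric(nrow(ch))
    for (rn in region_names) {
      sel <- which(ch_region == rn)
      lat_sign[sel] <- rep_len(c(1, -1), length(sel))
    }

    # subject-level log-normal amplitude heterogeneity
    subj_fac <- stats::setNames(exp(stats::rnorm(length(region_names), 0, config$subject_sd)),
                                region_names)
    subj_lat <- exp(stats::rnorm(1, 0, config$subject_sd))
    subj_kap <- exp(stats::rnorm(1, 0, config$subject_kappa_sd))
    if (!is.null(config$subject_latent_scale))
      subj_lat <- subj_lat * config$subject_latent_scale[[subject_index]]

    loads <- rep(LOADS, times = config$trials_per_load)
    n_trials <- length(loads)
    acc <- config$behavioral_accuracy_by_load[as.character(loads)]
    if (!is.null(config$subject_accuracy_shift))
      acc <- pmin(1, pmax(1e-6, acc + config$subject_accuracy_shift[[subject_index]]))
    probe_in <- stats::runif(n_trials) < 0.5
    correct <- stats::runif(n_trials) < acc
    response_in <- ifelse(correct, probe_in, !probe_in)
    trials <- trial_info(seq_len(n_trials), subject_id, loads, correct,
                         probe_in = probe_in, response_in = response_in)

    kap <- lapply(stats::setNames(LOADS, LOADS), function(L) region_kappa(config, L))
    hub_w <- stats::setNames(vapply(config$regions, `[[`, 0, "hub_weight"), region_names)
    mult <- do.call(rbind, lapply(config$regions, `[[`, "power_by_load"))
    rownames(mult) <- region_names
    noise_sd <- stats::setNames(vapply(config$regions, `[[`, 0, "noise_sd"), region_names)
    own_sd <- stats::setNames(vapply(config$regions, `[[`, 0, "own_amp_sd"), region_names)

    # hub-routed latent pathways: one latent component per coupling
    pathways <- lapply(config$couplings, function(cp) list(
      target = setdiff(cp$pair, config$hub),
      freq = if (is.null(cp$latent_freq)) config$latent_freq else cp$latent_freq))

    v <- array(0, c(n_trials, nrow(ch), length(t)))
    two_pi <- 2 * pi
    for (i in seq_len(n_trials)) {
      L <- as.character(loads[i])
      a_lat <- config$latent_power_by_load[[L]] * subj_lat
      own_gain <- vapply(region_names, function(r)
        exp(stats::rnorm(1, 0, own_sd[[r]])), 0)
      delta <- vapply(region_names, function(r) {
        k <- kap[[L]][[r]] * subj_kap
        if (is.infinite(k)) 0 else rvonmises(1, 0, k)
      }, 0)
      # per-region latent waveform over the task period, shared by the
      # region's channels: the hub carries every pathway's component
      # cleanly; a non-hub target receives its pathway's component through
      # a per-trial log-normal relay gain, plus a weak (cross_leak) copy of
      # the other pathways, all shifted by the region's von Mises offset
      lat_wave <- stats::setNames(vector("list", length(region_names)), region_names)
      for (p in pathways) {
        psi <- stats::runif(1, -pi, pi)
        g_path <- exp(stats::rnorm(1, 0, config$latent_amp_sd))
        for (r in region_names) {
          coef <- if (r == config$hub) hub_w[[r]] * a_lat * g_path
          else if (r == p$target)
            hub_w[[r]] * a_lat * g_path * exp(stats::rnorm(1, 0, config$relay_amp_sd))
          else config$cross_leak * hub_w[[r]] *
            (config$leak_load_mix * a_lat * g_path +
             (1 - config$leak_load_mix) * subj_lat *
               mean(config$latent_power_by_load))
          if (coef == 0) next
          w <- coef * cos(two_pi * p$freq * t[task] + psi + delta[[r]])
          lat_wave[[r]] <- if (is.null(lat_wave[[r]])) w else lat_wave[[r]] + w
        }
      }
      for (j in seq_len(nrow(ch))) {
        r <- ch_region[j]
        sig <- stats::rnorm(length(t), 0, noise_sd[[r]])
        # load-independent oscillation in the fixation baseline
        sig[base] <- sig[base] +
          cos(two_pi * ch_freq[j] * t[base] + stats::runif(1, -pi, pi))
        # region's own band oscillation during the task period
        sig[task] <- sig[task] +
          mult[r, L] * subj_fac[[r]] * own_gain[[r]] *
          cos(two_pi * ch_freq[j] * t[task] + stats::runif(1, -pi, pi))
        if (!is.null(lat_wave[[r]]))
          sig[task] <- sig[task] + lat_sign[j] * lat_wave[[r]]
        v[i, j, ] <- sig
      }
    }
    recording_dataset(v, ch, trials, ep)
  })
}

#' Generate a synthetic multi-subject study
#'
#' Produces one [recording_dataset()] per subject with the statistical
#' structure the downstream analyses assume: load-dependent band power,
#' a hub-shared latent oscillation, load-dependent inter-regional phase
#' coupling, and Bernoulli behavioural responses. Bit-reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A [wm_study()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "wm_synth_config"))
  seeds <- derive_seeds(config$seed, config$n_subjects)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  ds <- lapply(seq_len(config$n_subjects), function(s)
    generate_subject(config, ids[s], s, seeds[s]))
  names(ds) <- ids
  wm_study(ds, config = config)
}

#' Null variant of a synthetic configuration
#'
#' Removes every source of load dependence: all amplitude multipliers and
#' phase concentrations are fixed at their load-4 value and behavioural
#' accuracy at its across-load mean. Used for type-I-error calibration.
#'
#' @param config A [synthetic_config()].
#' @return A [wm_study()] generated from the flattened configuration.
#' @export
null_dataset <- function(config) {
  generate_dataset(null_config(config))
}

#' @rdname null_dataset
#' @export
null_config <- function(config) {
  flat <- function(x) stats::setNames(rep(x[[1]], length(LOADS)), as.character(LOADS))
  config$latent_power_by_load <- flat(config$latent_power_by_load)
  config$regions <- lapply(config$regions, function(rs) {
    rs$power_by_load <- flat(rs$power_by_load); rs
  })
  config$couplings <- lapply(config$couplings, function(cp) {
    cp$kappa_by_load <- flat(cp$kappa_by_load); cp
  })
  config$behavioral_accuracy_by_load <-
    stats::setNames(rep(mean(config$behavioral_accuracy_by_load), length(LOADS)),
                    as.character(LOADS))
  config
}
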