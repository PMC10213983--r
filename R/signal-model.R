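# Synthetic polysomnography generator.
#
# Emulates only the statistical structure the classifier exploits: stage-
# specific EEG band composition, stage-specific EOG event rates and EMG
# tone/burst rates, and three difficulty tiers that control which modality
# carries the discriminative content.  It is not a physiological simulator
# (no K-complexes, spindles or artifacts).

#' Frequency bands used by the stage templates (Hz)
#' @export
EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8),
                  alpha = c(8, 13), beta = c(13, 30))

# relative band amplitudes; delta is the strict maximum for N3, alpha
# dominates delta in W (the waking posterior rhythm)
.stage_templates <- list(
  W   = list(band_weights = c(delta = 0.5, theta = 0.7, alpha = 2.0, beta = 1.0),
             eog_event_rate = 8,   emg_tone = 1.00, emg_burst_rate = 12),
  N1  = list(band_weights = c(delta = 0.8, theta = 2.0, alpha = 0.8, beta = 0.4),
             eog_event_rate = 4,   emg_tone = 0.60, emg_burst_rate = 8),
  N2  = list(band_weights = c(delta = 1.2, theta = 1.6, alpha = 0.6, beta = 0.3),
             eog_event_rate = 1,   emg_tone = 0.45, emg_burst_rate = 5),
  N3  = list(band_weights = c(delta = 3.0, theta = 1.0, alpha = 0.4, beta = 0.2),
             eog_event_rate = 0.2, emg_tone = 0.30, emg_burst_rate = 2),
  REM = list(band_weights = c(delta = 0.8, theta = 1.5, alpha = 0.7, beta = 0.6),
             eog_event_rate = 6,   emg_tone = 0.10, emg_burst_rate = 0.5)
)

# stages whose EEG signatures are blended to make EEG alone ambiguous
.confusable_pair <- c(W = "N1", N1 = "W", N2 = "N3", N3 = "N2", REM = "N1")

#' Fixed spectral/behavioral template of a sleep stage
#'
#' Returns the deterministic generator template for one AASM stage: relative
#' EEG band amplitudes (delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta
#' 13-30 Hz), the expected number of ocular events per 30-s epoch, and the
#' chin-EMG tone and burst rate.  Delta is the strictly dominant band of N3;
#' alpha dominates delta in W.
#'
#' @param stage One of `"W"`, `"N1"`, `"N2"`, `"N3"`, `"REM"`.
#' @return A list of class `"StageTemplate"` with fields `stage`,
#'   `band_weights`, `eog_event_rate`, `emg_tone`, `emg_burst_rate`.
#' @examples
#' tpl <- stageTemplate("N3")
#' names(which.max(tpl$band_weights))  # "delta"
#' @export
stageTemplate <- function(stage) {
  if (!is.character(stage) || length(stage) != 1 ||
      !stage %in% names(.stage_templates))
    stop("unknown stage label: ", deparse(stage))
  c(list(stage = stage), .stage_templates[[stage]]) |>
    structure(class = "StageTemplate")
}

#' Configuration for the synthetic epoch generator
#'
#' Defaults emulate the Sleep-EDF-20 recording shape: 100 Hz on every
#' modality after rate harmonization, and class proportions equal to that
#' dataset's printed stage counts.  Tier proportions default to half
#' EEG-separable, 30 percent needing EOG and 20 percent needing EMG.
#'
#' @param n_epochs Number of epochs to generate.
#' @param class_proportions Nonnegative fractions over (W, N1, N2, N3, REM)
#'   summing to 1.
#' @param tier_proportions Nonnegative fractions over
#'   (eeg_separable, eog_required, emg_required) summing to 1.
#' @param sampling_rates Named Hz per modality.
#' @param noise_sd Gaussian background noise standard deviation (amplitude
#'   units of the unit-scale band oscillations).
#' @param seed Integer seed controlling the whole dataset.
#' @param n_subjects Number of synthetic subject identifiers to cycle over.
#' @param epoch_seconds Epoch duration (s).
#' @return A list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(n_epochs = 1000,
                            class_proportions = defaultClassProportions(),
                            tier_proportions = c(eeg_separable = 0.5,
                                                 eog_required = 0.3,
                                                 emg_required = 0.2),
                            sampling_rates = c(eeg = 100, eog = 100, emg = 100),
                            noise_sd = 1.0,
                            seed = 1L,
                            n_subjects = 4L,
                            epoch_seconds = 30) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (abs(sum(tier_proportions) - 1) > 1e-9)
    stop("tier_proportions must sum to 1")
  if (any(sampling_rates <= 0)) stop("sampling rates must be positive")
  structure(list(n_epochs = as.integer(n_epochs),
                 class_proportions = class_proportions,
                 tier_proportions = tier_proportions,
                 sampling_rates = sampling_rates,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects),
                 epoch_seconds = epoch_seconds),
            class = "SyntheticConfig")
}

#' Default stage proportions (Sleep-EDF-20 stage counts, normalized)
#' @return Named numeric vector over the five stages summing to 1.
#' @export
defaultClassProportions <- function() {
  counts <- psgClassCounts[["sleep-edf-20"]]
  counts / sum(counts)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

.band_signal <- function(n, rate, weights, n_osc = 2L) {
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (b in names(weights)) {
    band <- EEG_BANDS[[b]]
    for (j in seq_len(n_osc)) {
      f <- stats::runif(1, band[1], min(band[2], rate / 2))
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + weights[[b]] / sqrt(n_osc) * sin(2 * pi * f * t + ph)
    }
  }
  x
}

.eog_signal <- function(n, rate, event_rate, noise_sd, dur) {
  t <- (seq_len(n) - 1) / rate
  x <- 0.5 * sin(2 * pi * stats::runif(1, 0.2, 0.5) * t +
                   stats::runif(1, 0, 2 * pi))
  k <- stats::rpois(1, event_rate)
  if (k > 0) {
    centers <- stats::runif(k, 0.5, dur - 0.5)
    for (cc in centers) {
      # biphasic deflection (derivative-of-Gaussian), ~0.6 s wide
      g <- -(t - cc) / 0.15^2 * exp(-(t - cc)^2 / (2 * 0.15^2))
      x <- x + 3 * g / max(abs(g))
    }
  }
  x + stats::rnorm(n, 0, noise_sd)
}

.emg_signal <- function(n, rate, tone, burst_rate, noise_sd, dur) {
  t <- (seq_len(n) - 1) / rate
  x <- tone * stats::rnorm(n)
  k <- stats::rpois(1, burst_rate)
  if (k > 0) {
    centers <- stats::runif(k, 0.3, dur - 0.3)
    for (cc in centers) {
      env <- exp(-(t - cc)^2 / (2 * 0.1^2))
      x <- x + 2.0 * env * stats::rnorm(n)
    }
  }
  x + stats::rnorm(n, 0, 0.1 * noise_sd)
}

.tier_levels <- c("eeg_separable", "eog_required", "emg_required")

#' Generate one synthetic labeled polysomnography epoch
#'
#' EEG is a sum of band-limited sinusoids (uniform random frequency within
#' each band, random phase) weighted by the stage template, plus Gaussian
#' noise; EOG carries stage-rate-dependent biphasic eye-movement events; EMG
#' carries stage-dependent muscle tone and burst rate.  The difficulty tier
#' controls which modalities remain discriminative: `eeg_separable` keeps the
#' full EEG signature; `eog_required` blends the EEG template to the midpoint
#' of the stage's confusable partner (W with N1, N2 with N3, REM with N1) so
#' the ocular channel is needed; `emg_required` additionally replaces the EEG
#' template by the across-stage mean and the EOG event rate by the
#' across-stage mean rate, leaving the EMG channel as the only cue.
#' Identical arguments produce bit-identical records.
#'
#' @param stage AASM stage label.
#' @param tier One of `"eeg_separable"`, `"eog_required"`, `"emg_required"`.
#' @param config A [syntheticConfig()].
#' @param seed Integer seed for this epoch.
#' @return A list of class `"EpochRecord"`: `signals` (named list of numeric
#'   waveforms), `rates`, `duration`, `label`, `tier`.
#' @export
synthesizeEpoch <- function(stage, tier = "eeg_separable",
                            config = syntheticConfig(), seed = 1L) {
  tpl <- stageTemplate(stage)
  tier <- match.arg(tier, .tier_levels)
  rates <- config$sampling_rates
  if (any(rates <= 0)) stop("sampling rates must be positive")
  dur <- config$epoch_seconds

  w <- tpl$band_weights
  eog_rate <- tpl$eog_event_rate
  if (tier == "eog_required") {
    w <- (w + .stage_templates[[.confusable_pair[[stage]]]]$band_weights) / 2
  } else if (tier == "emg_required") {
    w <- Reduce(`+`, lapply(.stage_templates, `[[`, "band_weights")) /
      length(.stage_templates)
    eog_rate <- mean(vapply(.stage_templates, `[[`, numeric(1),
                            "eog_event_rate"))
  }

  signals <- with_seed(seed, {
    out <- list()
    for (m in names(rates)) {
      n <- round(dur * rates[[m]])
      out[[m]] <- switch(m,
        eeg = .band_signal(n, rates[[m]], w) +
          stats::rnorm(n, 0, config$noise_sd),
        eog = .eog_signal(n, rates[[m]], eog_rate, config$noise_sd, dur),
        emg = .emg_signal(n, rates[[m]], tpl$emg_tone, tpl$emg_burst_rate,
                          config$noise_sd, dur),
        # auxiliary modalities fall back to the EEG recipe
        .band_signal(n, rates[[m]], w) + stats::rnorm(n, 0, config$noise_sd))
    }
    out
  })
  structure(list(signals = signals, rates = rates, duration = dur,
                 label = stage, tier = tier), class = "EpochRecord")
}

#' Largest-remainder apportionment of n items over fractions
#'
#' @param n Total count.
#' @param proportions Nonnegative fractions summing to 1.
#' @return Integer vector summing to `n`; each count is within one of
#'   `n * proportion`.  Ties in fractional remainders break by position.
#' @export
apportionCounts <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  quota <- n * proportions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic labeled dataset
#'
#' Class and tier counts follow the configured proportions by
#' largest-remainder apportionment (realized counts within one epoch of the
#' quota per class); records are deterministically shuffled under the
#' config seed and subjects assigned round-robin.  All modalities must share
#' one sampling rate (harmonize first for mixed-rate designs).
#'
#' @param config A [syntheticConfig()].
#' @return An [EpochSet-class].
#' @examples
#' es <- synthesizeDataset(syntheticConfig(n_epochs = 10, seed = 7))
#' table(stages(es))
#' @export
synthesizeDataset <- function(config = syntheticConfig()) {
  n <- config$n_epochs
  nonzero <- sum(config$class_proportions > 0)
  if (n < nonzero)
    stop("n_epochs (", n, ") smaller than number of classes with nonzero ",
         "proportion (", nonzero, ")")
  if (length(unique(config$sampling_rates)) != 1)
    stop("synthesizeDataset requires a common sampling rate per modality")

  class_counts <- apportionCounts(n, config$class_proportions)
  names(class_counts) <- SLEEP_STAGES
  labels <- rep(SLEEP_STAGES, class_counts)
  tiers <- unlist(lapply(class_counts, function(k) {
    rep(.tier_levels, apportionCounts(k, config$tier_proportions))
  }), use.names = FALSE)

  ord <- with_seed(config$seed, sample.int(n))
  labels <- labels[ord]
  tiers <- tiers[ord]
  subj <- paste0("S", (seq_len(n) - 1) %% config$n_subjects + 1)

  rate <- config$sampling_rates[[1]]
  npts <- round(config$epoch_seconds * rate)
  mods <- names(config$sampling_rates)
  mats <- lapply(mods, function(m) matrix(0, npts, n))
  names(mats) <- mods
  for (i in seq_len(n)) {
    sd_i <- (config$seed * 7919 + i * 104729) %% 2147483647
    rec <- synthesizeEpoch(labels[i], tiers[i], config, seed = sd_i)
    for (m in mods) mats[[m]][, i] <- rec$signals[[m]]
  }
  es <- EpochSet(mats, stage = labels, sampleRate = rate,
                 epochSeconds = config$epoch_seconds,
                 tier = tiers, subject = subj)
  metadata(es)$synthetic_config <- config
  es
}

#' Periodogram band power
#'
#' Total periodogram power of a waveform inside a frequency band, computed by
#' direct discrete Fourier transform.  `bandPower(x, rate, 0, rate/2)` is the
#' total power.
#'
#' @param x Numeric waveform.
#' @param rate Sampling rate (Hz).
#' @param lower,upper Band edges in Hz (half-open, `lower <= f < upper`).
#' @return Nonnegative scalar.
#' @export
bandPower <- function(x, rate, lower, upper) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * rate / n
  keep <- f >= lower & f < upper & f <= rate / 2
  sum(p[keep])
}
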