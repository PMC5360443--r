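#' Synthetic EEG forward model for hierarchical frequency tagging
#'
#' Generates multichannel recordings containing a bottom-up source at the
#' contrast frequency f1 (plus its second harmonic), a top-down source at
#' the image-cycle frequency f2 (with a 1/k harmonic series), and a
#' multiplicative interaction of the two that produces intermodulation
#' components at n1*f1 + n2*f2. Certainty enters linearly: the top-down
#' amplitude falls and the interaction gain rises with certainty, matching
#' the qualitative pattern the analysis pipeline is meant to recover.
#' Background noise is 1/f ("pink") spectrum-shaped Gaussian noise,
#' independent across channels.
#'
#' @name neural-sim
NULL

#' Simulation parameters
#'
#' @param f1 bottom-up (SSVEP) response frequency, Hz.
#' @param f2 top-down (SWIFT) response frequency, Hz.
#' @param a1 bottom-up source amplitude, microvolts; its second harmonic has
#'   amplitude `0.3 * a1`.
#' @param a2_base,a2_slope top-down amplitude intercept (at certainty 0.5)
#'   and linear slope per unit certainty: `a2 = a2_base + a2_slope *
#'   (certainty - 0.5)` (negative slope at defaults).
#' @param g_base,g_slope interaction gain intercept and (positive) slope,
#'   same linear coding.
#' @param n_harmonics_swift number of top-down harmonics, amplitudes
#'   decaying as 1/k (default 8).
#' @param noise_exponent spectral exponent of the background noise power
#'   (power ~ 1/f^exponent, default 1).
#' @param noise_floor expected one-sided amplitude-spectrum level of the
#'   noise at the 10 Hz reference bin, microvolts (2/N amplitude
#'   convention).
#' @param n_channels montage size: 64 (default), 32 or 16.
#' @param fs sampling rate, Hz.
#' @param duration_s trial duration, s. Together with `f1`/`f2` this should
#'   put all tagged frequencies on the FFT grid (50 s puts them on the
#'   0.02 Hz grid).
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(f1 = 10, f2 = 1.3, a1 = 4,
                       a2_base = 3, a2_slope = -3,
                       g_base = 0.05, g_slope = 0.7,
                       n_harmonics_swift = 8L,
                       noise_exponent = 1, noise_floor = 0.1,
                       n_channels = 64L, fs = 500, duration_s = 50) {
  stopifnot(a1 >= 0, a2_base >= 0, noise_floor >= 0, fs > 0, duration_s > 0)
  structure(list(f1 = f1, f2 = f2, a1 = a1,
                 a2_base = a2_base, a2_slope = a2_slope,
                 g_base = g_base, g_slope = g_slope,
                 n_harmonics_swift = as.integer(n_harmonics_swift),
                 noise_exponent = noise_exponent, noise_floor = noise_floor,
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s),
            class = "sim_params")
}

# 1/f spectrum-shaped Gaussian noise, one column per channel.
# Calibrated so the expected one-sided (2/N) amplitude at `f_ref` equals
# `floor_amp`; the shaping is flattened below 0.5 Hz to avoid a DC blow-up.
pink_noise <- function(n, n_channels, fs, exponent, floor_amp, f_ref = 10) {
  if (floor_amp <= 0) return(matrix(0, n_channels, n))
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  shape <- (pmax(f, 0.5) / f_ref)^(-exponent / 2)
  scale <- floor_amp * (n / 2) / (sqrt(pi) / 2) * shape
  z <- matrix(complex(real = stats::rnorm(half * n_channels),
                      imaginary = stats::rnorm(half * n_channels)) / sqrt(2),
              nrow = half)
  Z <- matrix(0 + 0i, n, n_channels)
  Z[2:(half + 1), ] <- z * scale
  if (n %% 2 == 0) Z[half + 1, ] <- complex(real = Re(z[half, ])) * scale[half] # real Nyquist
  Z[n:(n - half + 2), ] <- Conj(Z[2:half, ])
  t(Re(stats::mvfft(Z, inverse = TRUE)) / n)
}

source_waveforms <- function(params, certainty, t) {
  a2 <- max(params$a2_base + params$a2_slope * (certainty - 0.5), 0)
  g <- max(params$g_base + params$g_slope * (certainty - 0.5), 0)
  b <- params$a1 * sin(2 * pi * params$f1 * t) +
    0.3 * params$a1 * sin(2 * pi * 2 * params$f1 * t)
  s <- 0
  for (k in seq_len(params$n_harmonics_swift))
    s <- s + (1 / k) * sin(2 * pi * k * params$f2 * t)
  s <- a2 * s
  list(b = b, s = s, i = g * b * s, a2 = a2, g = g)
}

#' Simulate one tagged-EEG trial
#'
#' @param params a `"sim_params"`.
#' @param certainty certainty level in `[0.5, 1]` (proportion of cycles
#'   showing the dominant image).
#' @param seed optional integer seed; identical seed and parameters give a
#'   bit-identical recording.
#' @param keep_components if `TRUE`, attach the clean source waveforms as
#'   attribute `"components"`.
#' @param amp_scale optional length-3 multiplier on the (bottom-up,
#'   top-down, interaction) source amplitudes (participant random effects).
#' @return an `"eeg_recording"` with `cycle_onsets` at the f2 cycle starts
#'   and attribute `"certainty"`.
#' @export
simulate_trial <- function(params, certainty, seed = NULL,
                           keep_components = FALSE, amp_scale = c(1, 1, 1)) {
  stopifnot(inherits(params, "sim_params"))
  if (certainty < 0.5 || certainty > 1)
    stop("`certainty` must lie in [0.5, 1]")
  n <- round(params$fs * params$duration_s)
  t <- (seq_len(n) - 1) / params$fs
  src <- source_waveforms(params, certainty, t)
  labels <- hft_montage(params$n_channels)
  W <- source_topography(labels)
  clean <- W[, "bottom_up"] %o% (amp_scale[1] * src$b) +
    W[, "top_down"] %o% (amp_scale[2] * src$s) +
    W[, "interaction"] %o% (amp_scale[3] * src$i)
  noise <- with_seed(seed,
    pink_noise(n, params$n_channels, params$fs,
               params$noise_exponent, params$noise_floor))
  n_cycles <- floor(params$duration_s * params$f2)
  onsets <- floor((seq_len(n_cycles) - 1) / params$f2 * params$fs) + 1L
  rec <- eeg_recording(clean + noise, fs = params$fs, labels = labels,
                       cycle_onsets = onsets)
  attr(rec, "certainty") <- certainty
  if (keep_components) attr(rec, "components") <- src
  rec
}

#' Simulate a full multi-participant session
#'
#' Each participant receives `trials_per_participant` trials whose
#' dominant-image proportions are drawn without replacement from
#' `certainty_grid` (default: the 56-point design grid spanning
#' `[0.5, 1]`). Participant random effects are lognormal multipliers on the
#' three source amplitudes. Behavioral responses are the true dominant /
#' target counts plus sporadic integer errors.
#'
#' @param params a `"sim_params"`.
#' @param n_participants number of participants.
#' @param trials_per_participant trials per participant (default 56).
#' @param certainty_grid pool of dominant proportions to sample from.
#' @param error_rate probability a trial's count response is off by 1-2.
#' @param re_sd standard deviation (log scale) of the participant
#'   amplitude random effects.
#' @param seed optional integer seed.
#' @param trial_fun optional function `(rec, info)` applied to each
#'   recording as it is produced; when given, its results are stored in
#'   `$derived` and raw recordings are dropped (streaming mode, keeps
#'   memory flat for large sessions).
#' @return an object of class `"hft_session"`: list with `behavior` (one
#'   row per trial: participant, trial, p_dominant, certainty_bin,
#'   true_count, response_count) and either `recordings` or `derived`.
#' @export
simulate_session <- function(params, n_participants,
                             trials_per_participant = 56L,
                             certainty_grid = NULL, error_rate = 0.1,
                             re_sd = 0.15, seed = NULL, trial_fun = NULL) {
  stopifnot(inherits(params, "sim_params"), n_participants >= 1)
  grid <- certainty_grid %||% design_proportions(56L)
  if (trials_per_participant > length(grid))
    stop("more trials than design-grid proportions")
  with_seed(seed, {
    n_cycles <- floor(params$duration_s * params$f2)
    rows <- list(); store <- list()
    idx <- 0L
    for (p in seq_len(n_participants)) {
      amp <- exp(stats::rnorm(3, 0, re_sd))
      ps <- sample(grid, trials_per_participant)
      for (tr in seq_len(trials_per_participant)) {
        idx <- idx + 1L
        rec <- simulate_trial(params, certainty = ps[tr], amp_scale = amp)
        true_count <- round_half_up(ps[tr] * n_cycles)
        err <- if (stats::runif(1) < error_rate)
          sample(c(-2L, -1L, 1L, 2L), 1) else 0L
        rows[[idx]] <- data.frame(
          participant = p, trial = tr, p_dominant = ps[tr],
          certainty_bin = certainty_bin(ps[tr])$index,
          true_count = true_count,
          response_count = max(true_count + err, 0L))
        store[[idx]] <- if (is.null(trial_fun)) rec else
          trial_fun(rec, rows[[idx]])
      }
    }
    out <- list(behavior = do.call(rbind, rows), params = params)
    if (is.null(trial_fun)) out$recordings <- store else out$derived <- store
    structure(out, class = "hft_session")
  })
}

#' Inject gross artifacts into selected cycles
#'
#' Marks a random subset of cycles and, within each, replaces a fraction of
#' (channel, sample) points with large-amplitude spikes that violate the
#' absolute-amplitude and sample-to-sample-step screening rules by a factor
#' of two. Ground truth is attached as attribute `"injected_cycles"`.
#'
#' @param rec an `"eeg_recording"` with cycle onsets.
#' @param cycle_fraction fraction of cycles to corrupt, in `[0, 1]`.
#' @param seed optional integer seed.
#' @param amplitude spike amplitude in microvolts (default 160, twice the
#'   80 microvolt screening threshold).
#' @param point_fraction fraction of points corrupted within a bad cycle
#'   (default 0.04, twice the 2% noisy-cycle threshold).
#' @return the corrupted `"eeg_recording"`.
#' @export
inject_artifacts <- function(rec, cycle_fraction, seed = NULL,
                             amplitude = 160, point_fraction = 0.04) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cycle_fraction < 0 || cycle_fraction > 1)
    stop("`cycle_fraction` must lie in [0, 1]")
  ranges <- cycle_ranges(rec)
  n_bad <- round_half_up(cycle_fraction * length(ranges))
  if (n_bad == 0) {
    attr(rec, "injected_cycles") <- integer(0)
    return(rec)
  }
  with_seed(seed, {
    bad <- sort(sample(length(ranges), n_bad))
    for (ci in bad) {
      cols <- ranges[[ci]]
      npts <- ceiling(point_fraction * length(cols) * nrow(rec$data))
      pick <- cbind(sample(nrow(rec$data), npts, replace = TRUE),
                    sample(cols, npts, replace = TRUE))
      rec$data[pick] <- amplitude * sample(c(-1, 1), npts, replace = TRUE)
    }
    attr(rec, "injected_cycles") <- bad
    rec
  })
}
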