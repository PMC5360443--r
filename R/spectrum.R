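#' Spectral analysis: preprocessing, amplitude spectra, neighbour-bin SNR
#'
#' The tagged-frequency statistic is the amplitude signal-to-noise ratio:
#' the one-sided FFT amplitude at a bin divided by the mean amplitude of the
#' 20 surrounding bins (10 each side), so a value of 1 means "no tagging".
#' At the canonical 50 s / 500 Hz trial the grid resolution is 0.02 Hz and
#' the neighbour window spans +-0.2 Hz.
#'
#' @name spectrum
NULL

#' Preprocess a raw recording
#'
#' Resamples 1000 Hz data to 500 Hz (ideal FFT-domain anti-aliased
#' decimation), applies a zero-phase high-pass at `hp_hz` (squared 4th-order
#' Butterworth magnitude applied in the frequency domain, i.e. the
#' forward-backward response), and converts to average reference.
#'
#' @param rec an `"eeg_recording"` sampled at 500 or 1000 Hz.
#' @param hp_hz high-pass cutoff in Hz (default 0.6).
#' @return an `"eeg_recording"` at 500 Hz, average-referenced.
#' @export
preprocess_eeg <- function(rec, hp_hz = 0.6) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!rec$fs %in% c(500, 1000))
    stop("unsupported sampling rate: ", rec$fs, " (need 500 or 1000 Hz)")
  data <- rec$data
  onsets <- rec$cycle_onsets
  if (rec$fs == 1000) {
    n <- ncol(data)
    if (n %% 2 != 0) stop("resampling by 2 requires an even sample count")
    m <- n / 2
    X <- stats::mvfft(t(data))
    Y <- matrix(0 + 0i, m, nrow(data))
    Y[1:(m / 2), ] <- X[1:(m / 2), ]
    Y[(m / 2 + 2):m, ] <- X[(n - m / 2 + 2):n, ]
    data <- t(Re(stats::mvfft(Y / 2, inverse = TRUE)) / m)
    if (!is.null(onsets)) onsets <- pmax((onsets - 1L) %/% 2L + 1L, 1L)
  }
  n <- ncol(data)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * 500 / n
  full_gain <- 1 / (1 + (hp_hz / pmax(f, 1e-12))^8) # |H|^2, 4th-order Butterworth
  full_gain[1] <- 0
  X <- stats::mvfft(t(data)) * full_gain
  data <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  data <- sweep(data, 2, colMeans(data)) # average reference
  out <- eeg_recording(data, fs = 500, labels = rec$labels,
                       cycle_onsets = onsets)
  attr(out, "certainty") <- attr(rec, "certainty")
  out
}

#' One-sided FFT amplitude spectrum
#'
#' Uses the 2/N one-sided scaling so a unit-amplitude sinusoid on the grid
#' yields amplitude 1.0 at its bin.
#'
#' @param rec an `"eeg_recording"`.
#' @return an object of class `"amplitude_spectrum"`: list with `freqs`
#'   (bin centers, Hz), `amplitude` (channels x bins, microvolts),
#'   `resolution` (`1/duration`, Hz), `fs`, `labels`.
#' @export
amplitude_spectrum <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  X <- stats::mvfft(t(rec$data))
  nb <- floor(n / 2) + 1
  amp <- t(Mod(X[1:nb, , drop = FALSE])) * 2 / n
  amp[, 1] <- amp[, 1] / 2
  if (n %% 2 == 0) amp[, nb] <- amp[, nb] / 2
  structure(list(freqs = (0:(nb - 1)) * rec$fs / n, amplitude = amp,
                 resolution = rec$fs / n, fs = rec$fs,
                 labels = rec$labels),
            class = "amplitude_spectrum")
}

bin_index <- function(spec, f, tol = 1e-9) {
  k <- round(f / spec$resolution)
  if (abs(k * spec$resolution - f) > tol)
    stop("frequency ", f, " Hz is not on the ", spec$resolution,
         " Hz bin grid (no interpolation)")
  k + 1L
}

#' Neighbour-bin SNR at one frequency
#'
#' Amplitude at `f` divided by the mean amplitude over the `n_neighbors`
#' bins on each side (the bin at `f` itself excluded): 20 neighbours in
#' total at the default, spanning f-0.2..f-0.02 and f+0.02..f+0.2 Hz on the
#' 0.02 Hz grid.
#'
#' @param spec an `"amplitude_spectrum"`.
#' @param f frequency in Hz; must coincide with a bin center.
#' @param n_neighbors bins per side (default 10).
#' @return numeric vector, one SNR per channel.
#' @export
snr_at <- function(spec, f, n_neighbors = 10L) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  k <- bin_index(spec, f)
  nb <- length(spec$freqs)
  if (k - n_neighbors < 2L || k + n_neighbors > nb)
    stop("frequency ", f, " Hz is within ",
         n_neighbors * spec$resolution, " Hz of the spectrum edge")
  nbr <- c((k - n_neighbors):(k - 1L), (k + 1L):(k + n_neighbors))
  spec$amplitude[, k] / rowMeans(spec$amplitude[, nbr, drop = FALSE])
}

#' Enumerate intermodulation components
#'
#' @param f1,f2 fundamental frequencies in Hz.
#' @param orders list (or 2-column matrix) of `(n1, n2)` integer pairs,
#'   both nonzero. Default: the four lowest-order components
#'   `(1,-2), (1,-1), (1,1), (1,2)`.
#' @return data.frame with columns `n1`, `n2`, `freq`, `order`
#'   (`|n1| + |n2|`), sorted by frequency, restricted to positive
#'   frequencies. Components colliding with a pure harmonic of `f1` or `f2`
#'   are dropped and reported in attribute `"collisions"` (and a warning).
#' @export
enumerate_im <- function(f1, f2,
                         orders = list(c(1, -2), c(1, -1), c(1, 1), c(1, 2))) {
  stopifnot(f1 > 0, f2 > 0)
  if (is.matrix(orders)) orders <- asplit(orders, 1)
  tab <- do.call(rbind, lapply(orders, function(o) {
    n1 <- as.integer(o[1]); n2 <- as.integer(o[2])
    if (n1 == 0L || n2 == 0L)
      stop("n1 = 0 or n2 = 0 describes a harmonic, not an intermodulation")
    data.frame(n1 = n1, n2 = n2, freq = n1 * f1 + n2 * f2,
               order = abs(n1) + abs(n2))
  }))
  tab <- unique(tab[tab$freq > 0, ])
  is_harm <- function(f, base) {
    r <- f / base
    abs(r - round(r)) < 1e-9 & round(r) >= 1
  }
  coll <- is_harm(tab$freq, f1) | is_harm(tab$freq, f2)
  out <- tab[!coll, ]
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  attr(out, "collisions") <- tab[coll, ]
  if (any(coll))
    warning("dropped IM component(s) colliding with pure harmonics: ",
            paste(tab$freq[coll], collapse = ", "), " Hz")
  out
}

#' The full set of frequencies of interest
#'
#' @param f1,f2 response frequencies in Hz.
#' @param n_ssvep_harmonics harmonics of f1 to track (default 2: f1, 2*f1).
#' @param n_swift_harmonics harmonics of f2 to track (default 8).
#' @param im_orders passed to [enumerate_im()].
#' @param duration_s if given, every frequency is checked to fall exactly
#'   on the `1/duration_s` Hz FFT grid (error if not, tolerance 1e-9 Hz).
#' @return data.frame with columns `freq`, `role`
#'   (`ssvep`/`swift`/`harmonic`/`im`), `n1`, `n2`.
#' @export
frequency_set <- function(f1 = 10, f2 = 1.3, n_ssvep_harmonics = 2L,
                          n_swift_harmonics = 8L, im_orders = NULL,
                          duration_s = NULL) {
  ims <- if (is.null(im_orders)) enumerate_im(f1, f2)
         else enumerate_im(f1, f2, im_orders)
  tab <- rbind(
    data.frame(freq = f1, role = "ssvep", n1 = 1L, n2 = 0L),
    if (n_ssvep_harmonics >= 2)
      data.frame(freq = (2:n_ssvep_harmonics) * f1, role = "harmonic",
                 n1 = 2:n_ssvep_harmonics, n2 = 0L),
    data.frame(freq = f2, role = "swift", n1 = 0L, n2 = 1L),
    if (n_swift_harmonics >= 2)
      data.frame(freq = (2:n_swift_harmonics) * f2, role = "harmonic",
                 n1 = 0L, n2 = 2:n_swift_harmonics),
    data.frame(freq = ims$freq, role = "im", n1 = ims$n1, n2 = ims$n2))
  tab <- tab[order(tab$freq), ]
  rownames(tab) <- NULL
  if (!is.null(duration_s)) {
    off <- abs(tab$freq * duration_s - round(tab$freq * duration_s))
    if (any(off > 1e-9 * duration_s))
      stop("frequencies off the 1/", duration_s, " s grid: ",
           paste(tab$freq[off > 1e-9 * duration_s], collapse = ", "))
  }
  tab
}

#' Tidy SNR table for one recording
#'
#' @param rec an `"eeg_recording"` (preprocessed).
#' @param foi frequencies of interest, as returned by [frequency_set()].
#' @param participant,trial identifiers copied into the table.
#' @param certainty_bin optional certainty bin copied into the table.
#' @return data.frame: participant, trial, channel, freq, role, snr,
#'   log2snr (one row per channel x frequency).
#' @export
snr_table <- function(rec, foi = frequency_set(), participant = 1L,
                      trial = 1L, certainty_bin = NA_integer_) {
  spec <- amplitude_spectrum(rec)
  out <- do.call(rbind, lapply(seq_len(nrow(foi)), function(i) {
    s <- snr_at(spec, foi$freq[i])
    data.frame(participant = participant, trial = trial,
               channel = spec$labels %||% seq_along(s),
               freq = foi$freq[i], role = foi$role[i],
               certainty_bin = certainty_bin, snr = s)
  }))
  if (any(out$snr <= 0)) stop("non-positive SNR encountered")
  out$log2snr <- log2(out$snr)
  rownames(out) <- NULL
  out
}

#' Group-level significance of tagged frequencies
#'
#' One-sample t-test of per-participant mean SNR against 1 at each
#' frequency of interest (one-sided, SNR > 1, by default), with
#' Benjamini-Hochberg false-discovery-rate adjustment across all tested
#' frequencies. Frequencies are restricted to `range_hz`.
#'
#' @param snr_by_participant data.frame with columns `participant`, `freq`
#'   and `snr` (one value per participant per frequency, e.g. averaged over
#'   channels and trials).
#' @param alpha significance level applied to FDR-adjusted p-values
#'   (default 0.01).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param range_hz frequencies-of-interest range (default 1-40 Hz).
#' @return data.frame: freq, mean_snr, t, df, p_raw, p_fdr, significant.
#' @export
group_significance <- function(snr_by_participant, alpha = 0.01,
                               alternative = c("greater", "two.sided"),
                               range_hz = c(1, 40)) {
  alternative <- match.arg(alternative)
  d <- snr_by_participant
  stopifnot(all(c("participant", "freq", "snr") %in% names(d)))
  d <- d[d$freq >= range_hz[1] & d$freq <= range_hz[2], ]
  freqs <- sort(unique(d$freq))
  rows <- lapply(freqs, function(f) {
    x <- d$snr[d$freq == f]
    if (length(x) < 2) stop("need >= 2 participants at ", f, " Hz")
    if (stats::sd(x) == 0) {
      tt <- list(statistic = c(t = 0), parameter = length(x) - 1,
                 p.value = 1)
    } else tt <- stats::t.test(x, mu = 1, alternative = alternative)
    data.frame(freq = f, mean_snr = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_fdr < alpha
  out
}
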