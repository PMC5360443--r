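#' Behavioral and EEG quality control
#'
#' Screening rules applied before spectral analysis: noisy sample points
#' are detected per channel, cycles with too many noisy points are replaced
#' by the channel's trial mean, and participants or single trials with poor
#' counting behaviour or poor recordings are excluded.
#'
#' @name quality
NULL

#' Flag noisy sample points
#'
#' A sample is noisy if, in its channel, (1) its absolute value exceeds
#' `abs_uv` microvolts, (2) it jumps by more than `step_uv` microvolts from
#' the previous sample, or (3) it lies more than `sd_mult` standard
#' deviations from the channel's trial mean (mean/SD computed on the data
#' as given, before any replacement).
#'
#' @param rec an `"eeg_recording"` (preprocessed).
#' @param abs_uv absolute-amplitude threshold (default 80).
#' @param step_uv sample-to-sample step threshold (default 40).
#' @param sd_mult standard-deviation multiplier (default 6).
#' @return an object of class `"noise_mask"`: list with `flags` (logical
#'   channels x samples matrix) and the thresholds used.
#' @export
flag_noisy_samples <- function(rec, abs_uv = 80, step_uv = 40, sd_mult = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  f1 <- abs(x) > abs_uv
  dx <- cbind(0, abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]))
  f2 <- dx > step_uv
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  f3 <- abs(x - mu) > sd_mult * sd_
  structure(list(flags = f1 | f2 | f3, abs_uv = abs_uv, step_uv = step_uv,
                 sd_mult = sd_mult),
            class = "noise_mask")
}

#' Flag noisy cycles
#'
#' A cycle is noisy when the fraction of flagged sample points within it,
#' pooled over all channels, strictly exceeds `threshold` ("over 2%").
#'
#' @param mask a `"noise_mask"` from [flag_noisy_samples()].
#' @param rec the `"eeg_recording"` the mask was computed on (provides the
#'   cycle onsets).
#' @param threshold noisy-point fraction above which a cycle is flagged
#'   (default 0.02, strict inequality).
#' @return the `"noise_mask"` augmented with `cycle_flags` (logical, one
#'   per cycle) and `fraction_noisy_cycles`.
#' @export
flag_noisy_cycles <- function(mask, rec, threshold = 0.02) {
  stopifnot(inherits(mask, "noise_mask"), inherits(rec, "eeg_recording"))
  ranges <- cycle_ranges(rec)
  frac <- vapply(ranges, function(ix)
    mean(mask$flags[, ix, drop = FALSE]), numeric(1))
  mask$cycle_fraction_noisy_points <- frac
  mask$cycle_flags <- frac > threshold
  mask$fraction_noisy_cycles <- mean(mask$cycle_flags)
  mask
}

#' Replace noisy cycles by the channel trial mean
#'
#' Within every flagged cycle, each channel's samples are set to that
#' channel's mean over the whole trial (computed before replacement).
#' Samples outside flagged cycles are returned bit-identical.
#'
#' @param rec an `"eeg_recording"`.
#' @param mask a `"noise_mask"` with `cycle_flags` (see
#'   [flag_noisy_cycles()]).
#' @return the cleaned `"eeg_recording"`.
#' @export
replace_noisy_cycles <- function(rec, mask) {
  stopifnot(inherits(rec, "eeg_recording"), !is.null(mask$cycle_flags))
  if (!any(mask$cycle_flags)) return(rec)
  mu <- rowMeans(rec$data)
  ranges <- cycle_ranges(rec)
  for (ci in which(mask$cycle_flags)) rec$data[, ranges[[ci]]] <- mu
  rec
}

#' Participant-level exclusion report
#'
#' A participant is excluded when the Pearson correlation between counted
#' and true presentations across trials is below `r_min` (strictly), or
#' when more than `noisy_max` of their cycles are noisy (strictly).
#' Zero-variance counts make r undefined; such participants are flagged
#' for manual review.
#'
#' @param behavior data.frame with columns `participant`, `response_count`,
#'   `true_count` (one row per trial).
#' @param noisy_fraction named numeric vector: fraction of noisy cycles per
#'   participant (names = participant ids), or `NULL` to skip the EEG rule.
#' @param r_min counting-accuracy cutoff (default 0.9).
#' @param noisy_max noisy-cycle fraction cutoff (default 0.10).
#' @return data.frame: participant, r, fraction_noisy_cycles, excluded,
#'   reason.
#' @export
exclude_participants <- function(behavior, noisy_fraction = NULL,
                                 r_min = 0.9, noisy_max = 0.10) {
  stopifnot(all(c("participant", "response_count", "true_count")
                %in% names(behavior)))
  ids <- sort(unique(behavior$participant))
  rows <- lapply(ids, function(p) {
    b <- behavior[behavior$participant == p, ]
    r <- if (stats::sd(b$response_count) == 0 || stats::sd(b$true_count) == 0)
      NA_real_ else stats::cor(b$response_count, b$true_count)
    nf <- if (is.null(noisy_fraction)) NA_real_
          else unname(noisy_fraction[as.character(p)])
    reason <- character(0)
    if (is.na(r)) reason <- c(reason, "undefined r: manual review")
    else if (r < r_min) reason <- c(reason, sprintf("r = %.3f < %.2f", r, r_min))
    if (!is.na(nf) && nf > noisy_max)
      reason <- c(reason, sprintf("noisy cycles %.1f%% > %.0f%%",
                                  100 * nf, 100 * noisy_max))
    data.frame(participant = p, r = r, fraction_noisy_cycles = nf,
               excluded = (!is.na(r) && r < r_min) ||
                 (!is.na(nf) && nf > noisy_max),
               manual_review = is.na(r),
               reason = paste(reason, collapse = "; "))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within-participant trial exclusion
#'
#' Keeps trial t iff the signed counting error `d_t = response - true`
#' lies within `sd_mult` standard deviations of the participant's mean
#' error. With zero error variance, all trials are kept. An `absolute`
#' switch uses the unsigned distance instead.
#'
#' @param behavior data.frame with columns `response_count`, `true_count`
#'   (one participant's trials).
#' @param sd_mult cutoff in standard deviations (default 2.5).
#' @param absolute use `|response - true|` instead of the signed
#'   difference.
#' @return logical keep mask, one entry per trial (in input order).
#' @export
exclude_trials <- function(behavior, sd_mult = 2.5, absolute = FALSE) {
  stopifnot(all(c("response_count", "true_count") %in% names(behavior)))
  d <- behavior$response_count - behavior$true_count
  if (absolute) d <- abs(d)
  if (length(d) < 3) stop("need >= 3 trials")
  s <- stats::sd(d)
  if (s == 0) return(rep(TRUE, length(d)))
  abs(d - mean(d)) <= sd_mult * s
}
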