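#' End-to-end convenience pipeline
#'
#' Helpers that chain the forward simulator, preprocessing and the spectral
#' statistics while keeping memory flat (recordings are analysed as they
#' are generated, then dropped).
#'
#' @name pipeline
NULL

#' Simulate a session and return its tidy SNR table
#'
#' @param params a `"sim_params"`.
#' @param n_participants,trials_per_participant session size.
#' @param foi frequencies of interest ([frequency_set()]).
#' @param preprocess apply [preprocess_eeg()] to every trial first
#'   (default `TRUE`).
#' @param certainty_grid,error_rate,re_sd,seed passed to
#'   [simulate_session()].
#' @return list with `snr` (tidy SNR table across all trials, including
#'   `p_dominant`) and `behavior`.
#' @export
session_snr_table <- function(params, n_participants,
                              trials_per_participant = 56L,
                              foi = frequency_set(params$f1, params$f2),
                              preprocess = TRUE, certainty_grid = NULL,
                              error_rate = 0.1, re_sd = 0.15, seed = NULL) {
  fun <- function(rec, info) {
    if (preprocess) rec <- preprocess_eeg(rec)
    tab <- snr_table(rec, foi = foi, participant = info$participant,
                     trial = info$trial,
                     certainty_bin = info$certainty_bin)
    tab$p_dominant <- info$p_dominant
    tab
  }
  ses <- simulate_session(params, n_participants, trials_per_participant,
                          certainty_grid = certainty_grid,
                          error_rate = error_rate, re_sd = re_sd,
                          seed = seed, trial_fun = fun)
  list(snr = do.call(rbind, ses$derived), behavior = ses$behavior,
       params = params)
}

#' Per-participant mean SNR by frequency
#'
#' Averages a tidy SNR table over channels and trials, the shape expected
#' by [group_significance()].
#'
#' @param snr_tab tidy SNR table.
#' @param channels optional channel subset (e.g. [posterior_roi()]).
#' @return data.frame: participant, freq, role, snr.
#' @export
participant_mean_snr <- function(snr_tab, channels = NULL) {
  if (!is.null(channels)) snr_tab <- restrict_roi(snr_tab, channels)
  agg <- stats::aggregate(snr ~ participant + freq + role, data = snr_tab,
                          FUN = mean)
  agg[order(agg$participant, agg$freq), ]
}

#' Mean-SNR scalp maps
#'
#' Averages a tidy SNR table over participants and trials per channel, one
#' column per frequency role needed by [topo_correlation_compare()]: the
#' SSVEP and SWIFT fundamentals plus each IM component.
#'
#' @param snr_tab tidy SNR table.
#' @return numeric matrix channels x maps with columns `ssvep`, `swift`,
#'   `im_<freq>`.
#' @export
snr_scalp_maps <- function(snr_tab) {
  d <- snr_tab[snr_tab$role %in% c("ssvep", "swift", "im"), ]
  d$map <- ifelse(d$role == "im", paste0("im_", d$freq), d$role)
  agg <- stats::aggregate(snr ~ channel + map, data = d, FUN = mean)
  maps <- sort(unique(agg$map))
  chans <- unique(snr_tab$channel)
  out <- matrix(NA_real_, length(chans), length(maps),
                dimnames = list(chans, maps))
  for (m in maps) {
    sub <- agg[agg$map == m, ]
    out[match(sub$channel, chans), m] <- sub$snr
  }
  out
}
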