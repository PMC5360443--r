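#' Hierarchical frequency tagging trial assembly
#'
#' A trial is a 50 s movie: 65 SWIFT cycles at F2 = 1.3 Hz, each cycle
#' showing either the face or the house image (blended with the noise cycle
#' of the other category), in a pseudorandom order whose dominant-category
#' proportion sets the certainty level, with a global sinusoidal contrast
#' modulation at F1 = 10 Hz superimposed on the whole movie.
#'
#' @name hft-trial
NULL

#' Trial specification
#'
#' @param duration_s trial duration in seconds (default 50).
#' @param F1 contrast (SSVEP) modulation frequency in Hz (default 10).
#' @param F2 SWIFT cycle frequency in Hz (default 1.3).
#' @param p_dominant proportion of cycles showing the dominant category,
#'   in `[0.5, 1]`.
#' @param dominant dominant category, `"face"` or `"house"`.
#' @param task_target category the observer is instructed to count.
#' @param display_rate display frame rate in frames/s (default 120).
#' @param contrast_depth modulation depth `d` in `[0, 1]`; the per-frame gain
#'   is `(1 - d/2) + (d/2) * sin(2*pi*F1*t)`, so `d = 1` spans `[0, 1]`.
#' @param background background luminance about which contrast is modulated
#'   (mid-grey, 0.5).
#' @return an object of class `"trial_spec"`; `n_cycles` is derived as
#'   `floor(duration_s * F2)` (65 at defaults).
#' @export
trial_spec <- function(duration_s = 50, F1 = 10, F2 = 1.3,
                       p_dominant = 0.75, dominant = c("face", "house"),
                       task_target = NULL, display_rate = 120,
                       contrast_depth = 1, background = 0.5) {
  dominant <- match.arg(dominant)
  if (p_dominant < 0.5 || p_dominant > 1)
    stop("`p_dominant` must lie in [0.5, 1]")
  if (contrast_depth < 0 || contrast_depth > 1)
    stop("`contrast_depth` must lie in [0, 1]")
  task_target <- task_target %||% dominant
  structure(list(duration_s = duration_s, F1 = F1, F2 = F2,
                 n_cycles = as.integer(floor(duration_s * F2)),
                 p_dominant = p_dominant, dominant = dominant,
                 task_target = match.arg(task_target, c("face", "house")),
                 display_rate = display_rate,
                 contrast_depth = contrast_depth, background = background),
            class = "trial_spec")
}

#' Pseudorandom cycle schedule for a trial
#'
#' A uniformly random permutation of `round_half_up(p_dominant * n_cycles)`
#' dominant-category labels and the remaining non-dominant labels.
#'
#' @param spec a `"trial_spec"`.
#' @param seed optional integer seed.
#' @return an object of class `"cycle_schedule"`: list with `labels`
#'   (character vector of length `n_cycles`), `counts` (named) and
#'   `true_count` (presentations of `spec$task_target`).
#' @export
schedule_cycles <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- spec$n_cycles
  n_dom <- as.integer(round_half_up(spec$p_dominant * n))
  other <- setdiff(c("face", "house"), spec$dominant)
  labels <- c(rep(spec$dominant, n_dom), rep(other, n - n_dom))
  labels <- with_seed(seed, sample(labels))
  counts <- c(sum(labels == "face"), sum(labels == "house"))
  names(counts) <- c("face", "house")
  structure(list(labels = labels, counts = counts,
                 true_count = unname(counts[spec$task_target])),
            class = "cycle_schedule")
}

#' Assemble a full HFT trial movie
#'
#' Blends each image cycle with the noise cycle of the *other* category
#' (face + house-noise, house + face-noise), lays the blended cycles out in
#' the scheduled order, samples display frames by time (frame at time `t`
#' shows scheduled cycle `floor(t * F2) + 1` at rotation phase
#' `t * F2 mod 1`, quantized to the cycle's frame grid), and applies the
#' global sinusoidal contrast gain about the background grey.
#'
#' Frames are stored compactly: the movie keeps the two blended cycle stacks
#' plus per-frame indices and gains; [movie_frame()] materializes any frame.
#'
#' @param spec a `"trial_spec"`.
#' @param face_cycle,house_cycle `"swift_cycle"` objects for the two images.
#' @param face_noise,house_noise optional precomputed noise cycles; generated
#'   from the image cycles when omitted.
#' @param seed optional integer seed (drives noise-cycle generation and the
#'   schedule).
#' @return an object of class `"trial_movie"`.
#' @export
assemble_trial <- function(spec, face_cycle, house_cycle,
                           face_noise = NULL, house_noise = NULL,
                           seed = NULL) {
  stopifnot(inherits(spec, "trial_spec"),
            inherits(face_cycle, "swift_cycle"),
            inherits(house_cycle, "swift_cycle"))
  if (!identical(dim(face_cycle$frames), dim(house_cycle$frames)))
    stop("face and house cycles differ in shape")
  with_seed(seed, {
    face_noise <- face_noise %||% make_noise_cycle(face_cycle)
    house_noise <- house_noise %||% make_noise_cycle(house_cycle)
    blended <- list(
      face = blend_cycles(face_cycle, house_noise),
      house = blend_cycles(house_cycle, face_noise)
    )
    schedule <- schedule_cycles(spec)
    n_frames <- as.integer(round(spec$duration_s * spec$display_rate))
    t <- (seq_len(n_frames) - 1) / spec$display_rate
    cyc_pos <- t * spec$F2
    cycle_of_frame <- pmin(floor(cyc_pos) + 1L, spec$n_cycles)
    phase <- cyc_pos - floor(cyc_pos)
    K <- face_cycle$frames_per_cycle
    peak <- face_cycle$peak_index
    frame_in_cycle <- 1L + ((peak - 1L + as.integer(round(phase * K))) %% K)
    gain <- (1 - spec$contrast_depth / 2) +
      (spec$contrast_depth / 2) * sin(2 * pi * spec$F1 * t)
    # per-frame mean luminance of the underlying (unmodulated) frames
    base_means <- lapply(blended, function(b) apply(b$frames, 3, mean))
    lum <- vapply(seq_len(n_frames), function(i) {
      base_means[[schedule$labels[cycle_of_frame[i]]]][frame_in_cycle[i]]
    }, numeric(1))
    lum <- spec$background + gain * (lum - spec$background)
    structure(list(spec = spec, schedule = schedule, cycles = blended,
                   n_frames = n_frames, times = t,
                   cycle_of_frame = cycle_of_frame,
                   frame_in_cycle = frame_in_cycle,
                   contrast_gain = gain, mean_luminance = lum,
                   true_count = schedule$true_count),
              class = "trial_movie")
  })
}

#' Materialize one display frame of a trial movie
#'
#' @param movie a `"trial_movie"`.
#' @param i 1-based frame index.
#' @return numeric matrix: the contrast-modulated frame.
#' @export
movie_frame <- function(movie, i) {
  stopifnot(inherits(movie, "trial_movie"))
  i <- as.integer(i)
  if (i < 1L || i > movie$n_frames) stop("frame index out of range")
  lab <- movie$schedule$labels[movie$cycle_of_frame[i]]
  f <- movie$cycles[[lab]]$frames[, , movie$frame_in_cycle[i]]
  movie$spec$background +
    movie$contrast_gain[i] * (f - movie$spec$background)
}

#' Per-frame mean luminance trace of a movie
#'
#' Cheap accessor (precomputed at assembly) used to verify the 10 Hz
#' contrast tag spectrally without materializing frames.
#'
#' @param movie a `"trial_movie"`.
#' @return numeric vector of length `n_frames`.
#' @export
movie_luminance <- function(movie) {
  stopifnot(inherits(movie, "trial_movie"))
  movie$mean_luminance
}

#' Session design grid of dominant-image proportions
#'
#' Proportions spanning the full `[0.5, 1]` certainty range, one per trial,
#' sampled without replacement so no proportion repeats within a session.
#'
#' @param n_trials trials per session (default 56).
#' @return numeric vector of length `n_trials`.
#' @export
design_proportions <- function(n_trials = 56L) {
  seq(0.5, 1, length.out = as.integer(n_trials))
}

#' @export
print.trial_movie <- function(x, ...) {
  cat("<trial_movie> ", x$spec$duration_s, " s @ ", x$spec$display_rate,
      " fps (", x$n_frames, " frames), ", x$spec$n_cycles,
      " cycles, p_dominant = ", x$spec$p_dominant, " (", x$spec$dominant,
      "), true ", x$spec$task_target, " count = ", x$true_count, "\n",
      sep = "")
  invisible(x)
}
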