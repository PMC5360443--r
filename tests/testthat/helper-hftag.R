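# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# 64x64 procedural images and a small SWIFT cycle reused across files
fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  .fixtures[[name]] <- switch(
    name,
    face64 = synthetic_image("face", 64, seed = 101),
    house64 = synthetic_image("house", 64, seed = 202),
    face_cycle = generate_cycle(fixture("face64"), frames_per_cycle = 24,
                                peak_index = 5, seed = 11,
                                image_id = "face64"),
    house_cycle = generate_cycle(fixture("house64"), frames_per_cycle = 24,
                                 peak_index = 5, seed = 12,
                                 image_id = "house64"),
    stop("unknown fixture: ", name)
  )
  .fixtures[[name]]
}

# scaled-down simulator world used in tests: canonical 50 s trials and
# frequency layout, but 100 Hz sampling and the 16-channel montage so the
# full suite stays within minutes (see the methods vignette)
test_params <- function(...) {
  args <- list(n_channels = 16, fs = 100, duration_s = 50)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

test_foi <- function() {
  if (is.null(.fixtures$foi)) .fixtures$foi <- frequency_set(duration_s = 50)
  .fixtures$foi
}

rms_contrast <- function(img) stats::sd(as.vector(img))
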