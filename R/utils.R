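# Run expr with a locally seeded RNG stream; restores the caller's stream.
# seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic grayscale face-like or house-like image
#'
#' Deterministic procedural stand-ins for the face/house photograph pools
#' used in frequency-tagging experiments (no such images ship with the
#' package). Faces are built from an elliptical head with eye/mouth blobs,
#' houses from rectangular facade, roof and window edges; both get a smooth
#' low-contrast texture so every wavelet level carries energy. Values lie in
#' `[0.05, 0.95]` on a mid-grey background.
#'
#' @param kind `"face"` or `"house"`.
#' @param size image side in pixels, a power of two (default 256).
#' @param seed optional integer; jitters feature positions so repeated calls
#'   emulate different exemplars.
#' @return a `size` x `size` numeric matrix in `[0, 1]`.
#' @export
synthetic_image <- function(kind = c("face", "house"), size = 256L, seed = NULL) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 16L || bitwAnd(size, size - 1L) != 0L)
    stop("`size` must be a power of two >= 16")
  with_seed(seed, {
    u <- (seq_len(size) - 0.5) / size # in (0,1)
    X <- matrix(u, size, size)
    Y <- t(X)
    j <- function(s) stats::runif(1, -s, s)
    img <- matrix(0.5, size, size)
    if (kind == "face") {
      cx <- 0.5 + j(0.03); cy <- 0.45 + j(0.03)
      head <- ((X - cx) / 0.28)^2 + ((Y - cy) / 0.36)^2
      img <- img + 0.28 * exp(-head^2) - 0.18 * pmax(0, 1 - head)^0.5 * 0.5
      for (sx in c(-1, 1)) {
        ex <- cx + sx * (0.11 + j(0.01)); ey <- cy - 0.08 + j(0.01)
        eye <- ((X - ex) / 0.045)^2 + ((Y - ey) / 0.03)^2
        img <- img - 0.35 * exp(-eye)
      }
      mouth <- ((X - cx) / 0.12)^2 + ((Y - (cy + 0.18 + j(0.01))) / 0.025)^2
      img <- img - 0.3 * exp(-mouth)
      nose <- ((X - cx) / 0.02)^2 + ((Y - (cy + 0.05)) / 0.08)^2
      img <- img + 0.12 * exp(-nose)
    } else {
      left <- 0.22 + j(0.02); right <- 0.78 + j(0.02)
      top <- 0.38 + j(0.02); bottom <- 0.85
      facade <- (X > left & X < right & Y > top & Y < bottom)
      img <- img + 0.22 * facade
      roof <- (Y < top & Y > top - 0.22 &
                 abs(X - 0.5) < 0.62 * (Y - (top - 0.25)))
      img <- img - 0.25 * roof
      for (wx in c(0.34, 0.66)) {
        win <- (abs(X - wx - j(0.01)) < 0.07 & abs(Y - 0.52 - j(0.01)) < 0.08)
        img <- img - 0.3 * win
      }
      door <- (abs(X - 0.5) < 0.06 & Y > 0.68 & Y < bottom)
      img <- img - 0.22 * door
    }
    # smooth texture so coarse and fine scales are all populated
    ph <- stats::runif(6, 0, 2 * pi)
    img <- img +
      0.04 * sin(2 * pi * 3 * X + ph[1]) * cos(2 * pi * 2 * Y + ph[2]) +
      0.025 * sin(2 * pi * 7 * X + ph[3]) * sin(2 * pi * 6 * Y + ph[4]) +
      0.015 * cos(2 * pi * 13 * X + ph[5]) * sin(2 * pi * 11 * Y + ph[6])
    pmin(pmax(img, 0.05), 0.95)
  })
}
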