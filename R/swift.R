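#' SWIFT: cyclic local-contour scrambling in the wavelet domain
#'
#' At every wavelet scale and location the three detail coefficients
#' (horizontal, vertical, diagonal) form a 3D "contour vector" whose length
#' encodes local contrast and whose direction encodes contour orientation.
#' SWIFT rotates each vector along a random circle drawn on the sphere of its
#' own radius, so frames morph between the intact image (rotation phase 0)
#' and scrambled versions while local energy -- hence luminance, contrast and
#' the spatial-frequency distribution -- stays constant.
#'
#' @name swift
NULL

.norm_eps <- 1e-12

#' Random norm-preserving circular scramble path for one contour vector
#'
#' Builds the unique circle through `v` and two random vectors of the same
#' Euclidean length. Every point of the path lies on the sphere of radius
#' `|v|`; phase 0 maps exactly to `v`. Vectors with negligible norm
#' (`< 1e-12`) get a degenerate path that holds them fixed.
#'
#' @param v numeric length-3 contour vector.
#' @param seed optional integer seed for the random draws.
#' @return an object of class `"scramble_path"` with fields `center`,
#'   `basis` (2 x 3 orthonormal rows), `radius`, `norm` and `degenerate`.
#' @examples
#' p <- make_scramble_path(c(1, 0, 0), seed = 7)
#' max(abs(path_point(p, 0) - c(1, 0, 0)))
#' @export
make_scramble_path <- function(v, seed = NULL) {
  stopifnot(is.numeric(v), length(v) == 3, all(is.finite(v)))
  r <- sqrt(sum(v^2))
  if (r < .norm_eps) {
    return(structure(list(center = v, basis = matrix(0, 2, 3), radius = 0,
                          norm = r, degenerate = TRUE),
                     class = "scramble_path"))
  }
  with_seed(seed, {
    for (try in 1:100) {
      p2 <- stats::rnorm(3); p2 <- p2 / sqrt(sum(p2^2)) * r
      p3 <- stats::rnorm(3); p3 <- p3 / sqrt(sum(p3^2)) * r
      n <- cross3(p2 - v, p3 - v)
      nn <- sqrt(sum(n^2))
      if (nn > 1e-8 * r^2) break
    }
    if (nn <= 1e-8 * r^2) stop("could not find a non-collinear triple")
    nhat <- n / nn
    dctr <- sum(v * nhat)
    center <- dctr * nhat
    radius <- sqrt(max(r^2 - dctr^2, 0))
    u <- (v - center) / radius
    w <- cross3(nhat, u)
    structure(list(center = center, basis = rbind(u, w), radius = radius,
                   norm = r, degenerate = FALSE),
              class = "scramble_path")
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Evaluate a scramble path at a rotation phase
#'
#' @param path a `"scramble_path"`.
#' @param phase rotation phase; interpreted modulo 1 (0 returns the original
#'   vector, 0.5 the antipode on the circle).
#' @return numeric length-3 vector with the same Euclidean norm as the
#'   original.
#' @export
path_point <- function(path, phase) {
  stopifnot(inherits(path, "scramble_path"))
  if (path$degenerate) return(path$center)
  th <- 2 * pi * (phase %% 1)
  path$center + path$radius *
    (cos(th) * path$basis[1, ] + sin(th) * path$basis[2, ])
}

# Vectorized path set for one detail triplet (H, V, D matrices).
# Returns per-location circle geometry as matrices matching dim(H).
band_paths <- function(H, V, D) {
  r2 <- H^2 + V^2 + D^2
  r <- sqrt(r2)
  live <- r >= .norm_eps
  m <- length(H)
  gauss_sphere <- function() {
    g1 <- stats::rnorm(m); g2 <- stats::rnorm(m); g3 <- stats::rnorm(m)
    gn <- sqrt(g1^2 + g2^2 + g3^2)
    list(x = g1 / gn * r, y = g2 / gn * r, z = g3 / gn * r)
  }
  p2 <- gauss_sphere(); p3 <- gauss_sphere()
  for (try in 1:50) {
    ax <- p2$x - H; ay <- p2$y - V; az <- p2$z - D
    bx <- p3$x - H; by <- p3$y - V; bz <- p3$z - D
    nx <- ay * bz - az * by
    ny <- az * bx - ax * bz
    nz <- ax * by - ay * bx
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    bad <- live & (nn <= 1e-8 * r2)
    if (!any(bad)) break
    idx <- which(bad)
    g <- matrix(stats::rnorm(6 * length(idx)), ncol = 6)
    s1 <- sqrt(rowSums(g[, 1:3, drop = FALSE]^2))
    s2 <- sqrt(rowSums(g[, 4:6, drop = FALSE]^2))
    p2$x[idx] <- g[, 1] / s1 * r[idx]; p2$y[idx] <- g[, 2] / s1 * r[idx]
    p2$z[idx] <- g[, 3] / s1 * r[idx]
    p3$x[idx] <- g[, 4] / s2 * r[idx]; p3$y[idx] <- g[, 5] / s2 * r[idx]
    p3$z[idx] <- g[, 6] / s2 * r[idx]
  }
  nn[nn == 0] <- 1
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  dctr <- H * nx + V * ny + D * nz
  cx <- dctr * nx; cy <- dctr * ny; cz <- dctr * nz
  rho <- sqrt(pmax(r2 - dctr^2, 0))
  safe <- live & rho > 0
  inv <- ifelse(safe, 1 / ifelse(rho == 0, 1, rho), 0)
  ux <- (H - cx) * inv; uy <- (V - cy) * inv; uz <- (D - cz) * inv
  wx <- ny * uz - nz * uy
  wy <- nz * ux - nx * uz
  wz <- nx * uy - ny * ux
  # degenerate locations: hold the original triplet fixed
  cx[!safe] <- H[!safe]; cy[!safe] <- V[!safe]; cz[!safe] <- D[!safe]
  rho[!safe] <- 0
  list(cx = cx, cy = cy, cz = cz, rho = rho,
       ux = ux, uy = uy, uz = uz, wx = wx, wy = wy, wz = wz)
}

band_at_phase <- function(p, phase) {
  th <- 2 * pi * (phase %% 1)
  ct <- cos(th); st <- sin(th)
  list(h = p$cx + p$rho * (ct * p$ux + st * p$wx),
       v = p$cy + p$rho * (ct * p$uy + st * p$wy),
       d = p$cz + p$rho * (ct * p$uz + st * p$wz))
}

#' Generate one SWIFT scrambling cycle from an image
#'
#' Decomposes the image at `levels` scales, draws an independent random
#' circular path for every (level, location) contour vector, and
#' reconstructs `frames_per_cycle` frames at uniformly spaced common rotation
#' phases. The unscrambled image reappears at `peak_index`
#' (phase `(k - peak_index)/frames_per_cycle`); the approximation band is
#' never touched, so mean luminance is conserved exactly, and norm
#' conservation makes RMS contrast and the per-level energy profile constant
#' across frames.
#'
#' @param image square numeric matrix, side divisible by `2^levels`.
#' @param frames_per_cycle integer `>= 2`; default 92 frames, approximately
#'   one 769 ms cycle at a 120 Hz display.
#' @param peak_index 1-based index of the frame carrying the intact image.
#' @param levels wavelet levels (default 6).
#' @param seed optional integer seed (same seed, same cycle, bit for bit).
#' @param image_id label stored with the cycle.
#' @return an object of class `"swift_cycle"`: list with `frames`
#'   (side x side x frames array), `frames_per_cycle`, `peak_index`,
#'   `source_image`, `source_image_id`, `levels`.
#' @export
generate_cycle <- function(image, frames_per_cycle = 92L, peak_index = 1L,
                           levels = 6L, seed = NULL, image_id = "image") {
  frames_per_cycle <- as.integer(frames_per_cycle)
  if (frames_per_cycle < 2L) stop("`frames_per_cycle` must be >= 2")
  peak_index <- as.integer(peak_index)
  if (peak_index < 1L || peak_index > frames_per_cycle)
    stop("`peak_index` must lie in 1..frames_per_cycle")
  dec <- swift_decompose(image, levels)
  with_seed(seed, {
    paths <- lapply(dec$details, function(dl) band_paths(dl$h, dl$v, dl$d))
    n <- dec$side
    frames <- array(NA_real_, c(n, n, frames_per_cycle))
    for (k in seq_len(frames_per_cycle)) {
      phase <- (k - peak_index) / frames_per_cycle
      dk <- dec
      for (l in seq_len(levels)) {
        b <- band_at_phase(paths[[l]], phase)
        dk$details[[l]] <- list(h = b$h, v = b$v, d = b$d)
      }
      frames[, , k] <- swift_reconstruct(dk)
    }
    structure(list(frames = frames, frames_per_cycle = frames_per_cycle,
                   peak_index = peak_index, source_image = image,
                   source_image_id = image_id, levels = levels),
              class = "swift_cycle")
  })
}

#' Pixel-domain distance between two frames
#'
#' Euclidean (L2) distance in pixel space, the metric used to pick the
#' "most scrambled" frame of a cycle when building noise sequences.
#'
#' @param frame,original numeric matrices of identical shape.
#' @return non-negative scalar; 0 iff the frames are identical.
#' @export
scramble_distance <- function(frame, original) {
  if (!identical(dim(frame), dim(original)))
    stop("frames differ in shape")
  sqrt(sum((frame - original)^2))
}

#' Index of the most scrambled frame of a cycle
#' @param cycle a `"swift_cycle"`.
#' @return 1-based frame index maximizing [scramble_distance()] to the
#'   source image.
#' @export
most_scrambled_frame <- function(cycle) {
  stopifnot(inherits(cycle, "swift_cycle"))
  d <- apply(cycle$frames, 3, scramble_distance, original = cycle$source_image)
  which.max(d)
}

#' Build a noise cycle from an image cycle
#'
#' Takes the frame of `cycle` most distant from its source image and runs the
#' SWIFT scrambling on *that* frame, yielding a sequence with the same local
#' low-level statistics but no recognizable image at its peak.
#'
#' @param cycle a `"swift_cycle"`.
#' @param seed optional integer seed.
#' @return a `"swift_cycle"` whose `source_image` is the selected scrambled
#'   frame (id suffixed `"_noise"`).
#' @export
make_noise_cycle <- function(cycle, seed = NULL) {
  stopifnot(inherits(cycle, "swift_cycle"))
  k <- most_scrambled_frame(cycle)
  generate_cycle(cycle$frames[, , k],
                 frames_per_cycle = cycle$frames_per_cycle,
                 peak_index = cycle$peak_index,
                 levels = cycle$levels, seed = seed,
                 image_id = paste0(cycle$source_image_id, "_noise"))
}

#' Alpha-blend two cycles with equal weights
#'
#' Per-frame pixel average (weights 0.5/0.5) of an image cycle with the
#' noise cycle of the other category, so low-level properties are constant
#' across all frames of a trial regardless of which image each cycle carries.
#' `peak_index` and identity metadata are inherited from `image_cycle`.
#'
#' @param image_cycle,noise_cycle `"swift_cycle"` objects of identical frame
#'   count and shape.
#' @return a `"swift_cycle"`.
#' @export
blend_cycles <- function(image_cycle, noise_cycle) {
  stopifnot(inherits(image_cycle, "swift_cycle"),
            inherits(noise_cycle, "swift_cycle"))
  if (image_cycle$frames_per_cycle != noise_cycle$frames_per_cycle ||
      !identical(dim(image_cycle$frames), dim(noise_cycle$frames)))
    stop("cycles differ in shape")
  out <- image_cycle
  out$frames <- 0.5 * image_cycle$frames + 0.5 * noise_cycle$frames
  out$source_image_id <- paste0(image_cycle$source_image_id, "+",
                                noise_cycle$source_image_id)
  out
}

#' @export
print.swift_cycle <- function(x, ...) {
  cat("<swift_cycle> ", x$source_image_id, ": ",
      dim(x$frames)[1], "x", dim(x$frames)[2], " px, ",
      x$frames_per_cycle, " frames, peak at ", x$peak_index, "\n", sep = "")
  invisible(x)
}
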