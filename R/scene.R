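#' Discrete vergence action set (pixels)
#'
#' The 11 signed horizontal shift increments available to the vergence
#' controller: powers of two up to 16 px in both directions, plus 0.
#' @export
ACTIONS_VERG <- c(-16L, -8L, -4L, -2L, -1L, 0L, 1L, 2L, 4L, 8L, 16L)

## Shift support: the vergence shift d is clamped to this range, which is
## also the support of the truncated-Laplacian disparity prior.
SHIFT_MAX <- 40L

#' Scene generator configuration
#'
#' @param width,height frame size in pixels.
#' @param n_planes number of textured foreground planes (default 5).
#' @param disparity_range integer range the plane disparities are drawn from,
#'   uniformly (default `c(-20, 20)`). Larger disparity means nearer.
#' @param texture texture family for foreground planes: `"onef"` (broadband
#'   noise with a 1/f amplitude spectrum), `"gratings"`, or `"dead_leaves"`.
#' @param background_texture texture family for the background plane.
#'   The default `"mixed"` is 1/f texture with several near-constant
#'   low-texture rectangles — the indoor-scene-like mixture that makes
#'   fixation targets genuinely unequal in information content. `"onef"`
#'   textures everything; `"flat"` is entirely near-constant (used by the
#'   entropy protocol for maximal contrast with textured objects).
#' @param background_disparity integer disparity of the background plane.
#' @param plane_frac range of plane side lengths as a fraction of the smaller
#'   frame dimension.
#' @return a `scene_config` list.
#' @export
scene_config <- function(width = 320L, height = 240L, n_planes = 5L,
                         disparity_range = c(-20L, 20L),
                         texture = c("onef", "gratings", "dead_leaves"),
                         background_texture = "mixed",
                         background_disparity = 0L,
                         plane_frac = c(0.2, 0.45)) {
  texture <- match.arg(texture)
  stopifnot(width >= 32, height >= 32, n_planes >= 0,
            length(disparity_range) == 2,
            disparity_range[1] <= disparity_range[2],
            abs(disparity_range) <= SHIFT_MAX / 2)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_planes = as.integer(n_planes),
                 disparity_range = as.integer(disparity_range),
                 texture = texture, background_texture = background_texture,
                 background_disparity = as.integer(background_disparity),
                 plane_frac = plane_frac),
            class = "scene_config")
}

## ---- textures -------------------------------------------------------------
## All textures are generated on a canvas wider than the frame by SHIFT_MAX on
## each side so that horizontally shifted (right-eye) views never run out of
## texture.

texture_onef <- function(h, w) {
  z <- matrix(stats::rnorm(h * w), h, w)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  f <- sqrt(outer(fy^2, fx^2, `+`))
  f[1, 1] <- Inf                       # kill DC
  amp <- 1 / f
  t <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (h * w)
  rng <- range(t)
  (t - rng[1]) / (rng[2] - rng[1])
}

texture_gratings <- function(h, w) {
  n <- 3L
  t <- matrix(0, h, w)
  for (i in seq_len(n)) {
    th <- stats::runif(1, 0, pi)
    f <- stats::runif(1, 1 / 40, 1 / 8)
    ph <- stats::runif(1, 0, 2 * pi)
    gx <- cos(th) * f; gy <- sin(th) * f
    t <- t + sin(2 * pi * (outer(seq_len(h) * gy, seq_len(w) * gx, `+`)) + ph)
  }
  (t - min(t)) / (max(t) - min(t))
}

texture_dead_leaves <- function(h, w) {
  t <- matrix(stats::runif(1), h, w)
  n_disc <- 60L
  ys <- stats::runif(n_disc, 1, h); xs <- stats::runif(n_disc, 1, w)
  rs <- stats::runif(n_disc, 3, min(h, w) / 6)
  vals <- stats::runif(n_disc)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_disc)) {
    m <- (yy - ys[i])^2 + (xx - xs[i])^2 <= rs[i]^2
    t[m] <- vals[i]
  }
  t
}

## Near-constant: a uniform level plus faint sensor-like noise. Exactly
## constant regions would normalize to zero patch vectors with zero
## reconstruction error, creating a degenerate "look at nothing" optimum
## that photographic scenes do not have.
texture_flat <- function(h, w) {
  lvl <- stats::runif(1, 0.3, 0.7)
  pmin(pmax(matrix(lvl + stats::rnorm(h * w, 0, 0.01), h, w), 0), 1)
}

## Broadband 1/f texture with several near-constant rectangles stamped in:
## the indoor-scene-like mixture of textured surfaces and low-texture
## regions (walls, shadows) that makes fixation targets genuinely unequal.
texture_mixed <- function(h, w) {
  t <- texture_onef(h, w)
  n_flat <- 4L
  for (i in seq_len(n_flat)) {
    fw <- as.integer(stats::runif(1, 0.2, 0.45) * w)
    fh <- as.integer(stats::runif(1, 0.2, 0.45) * h)
    x0 <- sample.int(w - fw, 1L); y0 <- sample.int(h - fh, 1L)
    lvl <- stats::runif(1, 0.3, 0.7)
    t[y0:(y0 + fh), x0:(x0 + fw)] <-
      pmin(pmax(lvl + stats::rnorm((fh + 1L) * (fw + 1L), 0, 0.01), 0), 1)
  }
  t
}

make_texture <- function(family, h, w) {
  switch(family,
         onef = texture_onef(h, w),
         gratings = texture_gratings(h, w),
         dead_leaves = texture_dead_leaves(h, w),
         flat = texture_flat(h, w),
         mixed = texture_mixed(h, w),
         stop("unknown texture family: ", family))
}

## ---- scene ----------------------------------------------------------------

#' Generate a synthetic stereo scene
#'
#' Builds a scene of textured fronto-parallel planes at integer disparities
#' over a (by default near-constant) background plane, together with the
#' dense ground-truth disparity map seen by the left eye. Nearer planes
#' (larger disparity) occlude farther ones. Deterministic for a given seed.
#'
#' @param config a [scene_config()].
#' @param seed integer seed; the same seed reproduces the scene exactly.
#' @return a `stereo_scene` with fields `width`, `height`, `planes`,
#'   `disparity` (height x width integer matrix) and the generating config.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$width; h <- config$height
  ext <- SHIFT_MAX
  with_seed(seed, {
    bg <- list(x0 = 1L, x1 = w, y0 = 1L, y1 = h,
               disparity = config$background_disparity,
               canvas = make_texture(config$background_texture, h, w + 2L * ext))
    planes <- list()
    if (config$n_planes > 0) {
      side_lo <- config$plane_frac[1] * min(w, h)
      side_hi <- config$plane_frac[2] * min(w, h)
      for (i in seq_len(config$n_planes)) {
        sw <- as.integer(round(stats::runif(1, side_lo, side_hi)))
        sh <- as.integer(round(stats::runif(1, side_lo, side_hi)))
        x0 <- as.integer(sample.int(w - sw, 1L))
        y0 <- as.integer(sample.int(h - sh, 1L))
        dsp <- as.integer(sample(config$disparity_range[1]:config$disparity_range[2], 1L))
        planes[[i]] <- list(
          x0 = x0, x1 = x0 + sw - 1L, y0 = y0, y1 = y0 + sh - 1L,
          disparity = dsp,
          canvas = make_texture(config$texture, sh, sw + 2L * ext))
      }
    }
    ## painter order: background first, then far-to-near (disparity ascending,
    ## stable so later planes win ties)
    ord <- if (length(planes)) order(vapply(planes, `[[`, integer(1), "disparity")) else integer(0)
    planes <- planes[ord]
    disparity <- matrix(bg$disparity, h, w)
    for (p in planes) {
      disparity[p$y0:p$y1, p$x0:p$x1] <- p$disparity
    }
    structure(list(width = w, height = h, background = bg, planes = planes,
                   disparity = disparity, config = config, seed = seed),
              class = "stereo_scene")
  })
}

#' Render a scene into a rectified stereo image pair
#'
#' The left image shows each plane's texture at its scene position; the right
#' image shows the same texture shifted left by the plane's disparity, with
#' occlusions resolved near-over-far and disoccluded pixels taken from the
#' background plane. For a single full-frame plane at disparity D this gives
#' `right[x, y] == left[x + D, y]` exactly.
#'
#' @param scene a `stereo_scene`.
#' @return a `stereo_frame` with matrices `left` and `right` in `[0, 1]`.
#' @export
render_stereo <- function(scene) {
  stopifnot(inherits(scene, "stereo_scene"))
  w <- scene$width; h <- scene$height; ext <- SHIFT_MAX
  paint <- function(img, p, shift) {
    ## footprint of plane p in this eye's image, content = canvas(x + shift)
    x0 <- max(1L, p$x0 - shift); x1 <- min(w, p$x1 - shift)
    if (x0 > x1) return(img)
    rows <- p$y0:p$y1
    ## canvas col index: image col x maps to canvas col (x + shift) - p$x0 + 1 + ext
    cc <- (x0:x1) + shift - p$x0 + 1L + ext
    img[rows, x0:x1] <- p$canvas[, cc, drop = FALSE]
    img
  }
  left <- matrix(0, h, w); right <- matrix(0, h, w)
  left <- paint(left, scene$background, 0L)
  right <- paint(right, scene$background, scene$background$disparity)
  for (p in scene$planes) {
    left <- paint(left, p, 0L)
    right <- paint(right, p, p$disparity)
  }
  structure(list(left = left, right = right, seed = scene$seed),
            class = "stereo_frame")
}

## ---- fixation state -------------------------------------------------------

#' Fixation state
#'
#' Tracks the left fixation point, the horizontal vergence shift `d` (the
#' 2-D stand-in for the vergence angle), the frame-within-fixation counter
#' and the fixation index. The shift is carried across saccades unchanged.
#'
#' @param x,y left fixation point, pixels (1-based).
#' @param d horizontal shift in pixels; the right window is centred at
#'   `(x - d, y)`.
#' @param frame frame counter within the fixation, 0-9.
#' @param fixation fixation index.
#' @export
fixation_state <- function(x, y, d = 0L, frame = 0L, fixation = 1L) {
  stopifnot(frame >= 0, frame <= 9)
  structure(list(x = as.integer(x), y = as.integer(y), d = as.integer(d),
                 frame = as.integer(frame), fixation = as.integer(fixation)),
            class = "fixation_state")
}

#' Apply a vergence action to a fixation state
#'
#' Adds the chosen pixel shift to `d`, clamps to the supported shift range
#' (+/- 40 px) and advances the frame counter.
#'
#' @param fix a [fixation_state()].
#' @param action one of the 11 values in [ACTIONS_VERG].
#' @export
apply_vergence_action <- function(fix, action) {
  if (!action %in% ACTIONS_VERG) {
    stop("action ", action, " is not in the vergence action set")
  }
  fix$d <- as.integer(max(-SHIFT_MAX, min(SHIFT_MAX, fix$d + action)))
  fix$frame <- fix$frame + 1L
  fix
}

#' Retinal disparity at the fixation point
#'
#' The difference between the current shift and the scene disparity at the
#' left fixation point: zero means the fine-scale windows are aligned.
#'
#' @param scene a `stereo_scene`.
#' @param fix a [fixation_state()].
#' @return signed disparity in pixels.
#' @export
retinal_disparity <- function(scene, fix) {
  stopifnot(fix$x >= 1, fix$x <= scene$width, fix$y >= 1, fix$y <= scene$height)
  fix$d - scene$disparity[fix$y, fix$x]
}

## ---- window extraction ----------------------------------------------------

## Centred window bounds for size S at centre c: start = c - (S-1) %/% 2.
win_bounds <- function(centre, size) {
  start <- centre - (size - 1L) %/% 2L
  c(start, start + size - 1L)
}

#' Valid fixation margin
#'
#' Fixation points are restricted so that the coarse vergence window (4x the
#' fine window size) plus the maximum shift stays inside the frame for both
#' eyes. Saccade target distributions are zeroed outside this margin.
#'
#' @param width,height frame size.
#' @param window fine-scale window size in pixels.
#' @param max_shift largest supported |d| (default 40).
#' @return list with inclusive pixel ranges `x0,x1,y0,y1` and a `height` x
#'   `width` logical `mask`.
#' @export
valid_margin <- function(width, height, window = 55L, max_shift = SHIFT_MAX) {
  S <- window * 4L
  lo <- (S - 1L) %/% 2L
  hi <- S - 1L - lo
  x0 <- 1L + lo + max_shift; x1 <- width - hi - max_shift
  y0 <- 1L + lo; y1 <- height - hi
  if (x0 > x1 || y0 > y1) {
    stop("frame ", width, "x", height, " too small for a ", S, "x", S,
         " coarse window plus shift ", max_shift, "; minimum size ",
         S + 2L * max_shift + 1L, "x", S + 1L)
  }
  mask <- matrix(FALSE, height, width)
  mask[y0:y1, x0:x1] <- TRUE
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, mask = mask)
}

extract_window <- function(img, cx, cy, size) {
  b_x <- win_bounds(cx, size); b_y <- win_bounds(cy, size)
  if (b_x[1] < 1 || b_y[1] < 1 || b_x[2] > ncol(img) || b_y[2] > nrow(img)) {
    stop("window of size ", size, " at (", cx, ",", cy, ") leaves the image")
  }
  img[b_y[1]:b_y[2], b_x[1]:b_x[2], drop = FALSE]
}

#' Extract the three-scale binocular vergence input
#'
#' Windows are centred at the left fixation point in the left image and at
#' `(x - d, y)` in the right image. The coarse scale is a 4x window down-
#' sampled by 4, medium 2x down-sampled by 2, fine the raw window; all three
#' are exactly `window` x `window`.
#'
#' @param frame a `stereo_frame`.
#' @param fix a [fixation_state()].
#' @param window fine-scale window size (55 at full scale).
#' @return list of scales `coarse`, `medium`, `fine`, each `list(left, right)`.
#' @export
extract_vergence_input <- function(frame, fix, window = 55L) {
  out <- list()
  for (sc in list(c("coarse", 4L), c("medium", 2L), c("fine", 1L))) {
    f <- as.integer(sc[2]); size <- window * f
    L <- extract_window(frame$left, fix$x, fix$y, size)
    R <- extract_window(frame$right, fix$x - fix$d, fix$y, size)
    if (f > 1L) {
      L <- resize_bicubic(L, window, window)
      R <- resize_bicubic(R, window, window)
    }
    out[[sc[1]]] <- list(left = L, right = R)
  }
  out
}

#' Extract the aligned coarse-scale saccade input
#'
#' Crops the largest equally sized sub-windows such that the left and right
#' fixation columns are aligned (for shift d >= 0: left columns `d+1..N`,
#' right columns `1..N-d`; mirrored for d < 0), then down-samples both by 4.
#'
#' @param frame a `stereo_frame`.
#' @param d current horizontal shift in pixels (may be negative).
#' @param factor down-sampling factor (4).
#' @return `list(left, right, col_offset)` where `col_offset` is the 0-based
#'   full-resolution column offset of the cropped window in the left image.
#' @export
extract_saccade_input <- function(frame, d, factor = 4L) {
  M <- nrow(frame$left); N <- ncol(frame$left)
  if (abs(d) >= N) stop("shift |d| = ", abs(d), " >= image width ", N)
  if (d >= 0) {
    L <- frame$left[, (d + 1L):N, drop = FALSE]
    R <- frame$right[, 1L:(N - d), drop = FALSE]
    off <- d
  } else {
    L <- frame$left[, 1L:(N + d), drop = FALSE]
    R <- frame$right[, (-d + 1L):N, drop = FALSE]
    off <- 0L
  }
  oh <- M %/% factor; ow <- (N - abs(d)) %/% factor
  list(left = resize_bicubic(L, oh, ow),
       right = resize_bicubic(R, oh, ow),
       col_offset = as.integer(off))
}

#' Construct a two-depth probe scene
#'
#' Two equally sized textured planes, side by side at two distinct
#' disparities over a background at 0 — the standard construction for
#' probing whether fixation-dependent (local) saliency targets the object
#' the system is not currently fixating.
#'
#' @param seed texture seed.
#' @param disparities length-2 integer disparities of the left and right
#'   plane.
#' @param config a [scene_config()]; plane sizes are taken from its
#'   `plane_frac`.
#' @return a `stereo_scene` whose `planes` are the two probe objects.
#' @export
two_depth_scene <- function(seed = 1L, disparities = c(-10L, 10L),
                            config = scene_config(n_planes = 2L,
                                                  plane_frac = c(0.5, 0.6))) {
  stopifnot(length(disparities) == 2)
  sc <- generate_scene(config, seed)
  w <- sc$width; h <- sc$height
  for (i in 1:2) {
    p <- sc$planes[[i]]
    p$disparity <- as.integer(disparities[i])
    pw <- p$x1 - p$x0; ph <- p$y1 - p$y0
    p$x0 <- as.integer(if (i == 1) 30L else w - 30L - pw)
    p$x1 <- p$x0 + pw
    p$y0 <- as.integer((h - ph) %/% 2); p$y1 <- p$y0 + ph
    sc$planes[[i]] <- p
  }
  ## keep painter order far-to-near (the probe planes never overlap, but
  ## the scene invariant is maintained regardless of the disparities given)
  sc$planes <- sc$planes[order(vapply(sc$planes, `[[`, integer(1),
                                      "disparity"))]
  sc$disparity <- matrix(sc$background$disparity, h, w)
  for (p in sc$planes) sc$disparity[p$y0:p$y1, p$x0:p$x1] <- p$disparity
  sc
}

## ---- disparity prior ------------------------------------------------------

#' Truncated Laplacian disparity prior
#'
#' `P(d) = M exp(-|d|/D)` normalised over integer `d` in `[-40, 40]`; `D`
#' controls the spread.
#'
#' @param D spread parameter, > 0.
#' @return named numeric vector of 81 probabilities.
#' @export
laplacian_disparity_pmf <- function(D) {
  if (!is.numeric(D) || D <= 0) stop("spread D must be > 0")
  d <- -SHIFT_MAX:SHIFT_MAX
  p <- exp(-abs(d) / D)
  stats::setNames(p / sum(p), d)
}

#' Sample disparities from the truncated Laplacian prior
#'
#' @param D spread parameter, > 0.
#' @param n number of draws.
#' @return integer vector in `[-40, 40]`.
#' @export
sample_laplacian_disparity <- function(D, n = 1L) {
  p <- laplacian_disparity_pmf(D)
  sample(-SHIFT_MAX:SHIFT_MAX, n, replace = TRUE, prob = p)
}

## ---- I/O ------------------------------------------------------------------

#' Export a stereo frame (and optionally its disparity map) to disk
#'
#' Writes 8-bit grayscale PNGs `<prefix>_left.png` / `<prefix>_right.png` and,
#' when a scene is supplied, `<prefix>_disparity.csv` (plain integer CSV).
#'
#' @param frame a `stereo_frame`.
#' @param prefix file path prefix.
#' @param scene optional `stereo_scene` providing the ground-truth disparity.
#' @return invisibly, the paths written.
#' @export
export_stereo_frame <- function(frame, prefix, scene = NULL) {
  clamp <- function(m) pmin(pmax(m, 0), 1)
  paths <- c(paste0(prefix, "_left.png"), paste0(prefix, "_right.png"))
  png::writePNG(clamp(frame$left), paths[1])
  png::writePNG(clamp(frame$right), paths[2])
  if (!is.null(scene)) {
    p <- paste0(prefix, "_disparity.csv")
    utils::write.table(scene$disparity, p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a user-supplied rectified stereo pair
#'
#' Loads two equally sized grayscale PNGs as a `stereo_frame`. Without a
#' ground-truth disparity map, disparity-dependent metrics are unavailable.
#'
#' @param left_path,right_path PNG file paths.
#' @export
read_stereo_pair <- function(left_path, right_path) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a
  }
  L <- to_gray(png::readPNG(left_path))
  R <- to_gray(png::readPNG(right_path))
  if (!all(dim(L) == dim(R))) stop("left and right images differ in size")
  structure(list(left = L, right = R, seed = NA_integer_),
            class = "stereo_frame")
}
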