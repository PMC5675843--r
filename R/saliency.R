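## Binocular saliency by self-information maximization (global and local
## variants) computed from the coarse-scale GASSOM responses.

#' Coarse-scale response maps for saliency
#'
#' Cuts the aligned coarse binocular pair into 10x10 patches with stride 1
#' (an (M1-9) x (M2-9) grid), normalizes them as for the encoder and
#' computes the subspace energy responses of the chosen feature extractors.
#' The monocular variant zeroes the right half of every patch vector and
#' rescales the left half by sqrt(2) so the vector energy matches the
#' binocular case — the in-package monocular (texture-only) baseline.
#'
#' @param bank a `gassom_bank`.
#' @param pair `list(left, right)` from [extract_saccade_input()].
#' @param features integer indices of the feature extractors to use
#'   (default: all).
#' @param monocular use left-eye information only.
#' @return a `response_map_stack`: list with `resp` (|features| x P), the
#'   feature indices, and the patch grid dims `ny`, `nx`.
#' @export
coarse_response_maps <- function(bank, pair, features = NULL,
                                 monocular = FALSE) {
  if (nrow(pair$left) < 10 || ncol(pair$left) < 10) {
    stop("saliency input smaller than a 10x10 patch")
  }
  pt <- patchify(pair$left, pair$right, stride = 1L)
  x <- pt$x
  if (monocular) {
    x[101:200, ] <- 0
    x[1:100, ] <- x[1:100, ] * sqrt(2)
  }
  if (is.null(features)) features <- seq_len(bank$n)
  sub <- bank
  sub$phi <- bank$phi[features]
  sub$n <- length(features)
  resp <- subspace_responses(sub, x)
  structure(list(resp = resp, features = as.integer(features),
                 ny = pt$ny, nx = pt$nx,
                 low_contrast = pt$low_contrast),
            class = "response_map_stack")
}

## Bin index for a value in [0,1] with K equal-width bins; 1.0 goes to the
## top bin (its half-open interval is closed above).
bin_index <- function(v, K) {
  pmin(floor(v * K), K - 1L) + 1L
}

#' Empirical response histogram over a context
#'
#' Equal-width bins on `[0, 1]` over the (min-max normalized) responses of
#' one feature map, restricted to the patches of the estimation context.
#'
#' @param values normalized responses in `[0, 1]`.
#' @param context integer indices of the context patches (default: all).
#' @param K number of bins; defaults to the context size, as in the model
#'   definition (`K = P_sal`).
#' @return numeric vector of K bin weights summing to 1.
#' @export
build_histogram <- function(values, context = seq_along(values), K = NULL) {
  if (!length(context)) stop("empty histogram context")
  if (is.null(K)) K <- length(context)
  v <- values[context]
  tabulate(bin_index(v, K), nbins = K) / length(v)
}

#' Per-patch Shannon self-information
#'
#' `S_n = -ln(alpha + (1 - alpha) h_n(bin))`, bounded by `-ln(alpha)`.
#'
#' @param values normalized responses in `[0, 1]` (all patches).
#' @param hist histogram from [build_histogram()].
#' @param alpha probability floor (1e-6).
#' @return nonnegative self-information per patch.
#' @export
self_information <- function(values, hist, alpha = 1e-6) {
  K <- length(hist)
  p <- alpha + (1 - alpha) * hist[bin_index(values, K)]
  -log(p)
}

## Min-max normalize one response map; a constant map goes to all zeros.
normalize_map <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

## Patch indices of the local (31x31) context around a patch-grid position,
## clipped at the borders.
local_context <- function(ny, nx, centre, size = 31L) {
  half <- (size - 1L) %/% 2L
  py <- max(1L, centre[1] - half):min(ny, centre[1] + half)
  px <- max(1L, centre[2] - half):min(nx, centre[2] + half)
  as.vector(outer(py, (px - 1L) * ny, `+`))
}

#' Coarse-scale saliency map
#'
#' Sums, over the chosen feature extractors, the self-information of each
#' patch's response under the empirical response histogram. The global
#' variant (GBAIM) estimates each histogram over all patches; the local
#' variant (LBAIM) over a 31x31 patch neighbourhood of the current fixation,
#' making saliency fixation-dependent.
#'
#' @param stack a `response_map_stack`.
#' @param context `NULL` for global, or `c(row, col)` patch-grid coordinates
#'   of the current fixation for the local variant.
#' @param local_size side of the local context in patches (31).
#' @param K number of histogram bins (default: context size).
#' @param alpha probability floor.
#' @return a `saliency_map`: list with matrix `S` (ny x nx), the feature
#'   indices and the context description.
#' @export
saliency_map <- function(stack, context = NULL, local_size = 31L,
                         K = NULL, alpha = 1e-6) {
  if (!length(stack$features)) stop("empty feature subset")
  P <- stack$ny * stack$nx
  ctx <- if (is.null(context)) seq_len(P) else {
    local_context(stack$ny, stack$nx, as.integer(context), local_size)
  }
  S <- numeric(P)
  for (i in seq_len(nrow(stack$resp))) {
    v <- normalize_map(stack$resp[i, ])
    h <- build_histogram(v, ctx, K)
    S <- S + self_information(v, h, alpha)
  }
  structure(list(S = matrix(S, stack$ny, stack$nx),
                 features = stack$features,
                 context = if (is.null(context)) "global" else context),
            class = "saliency_map")
}

#' Upsample a coarse saliency map to full resolution
#'
#' Zero-pads the (M1-9) x (M2-9) patch map back to the coarse image size
#' M1 x M2 (centred: 4 before, 5 after), then upsamples by `factor` with
#' bicubic interpolation; interpolation undershoot is clamped at 0.
#'
#' @param smap a `saliency_map` (or matrix).
#' @param coarse_dim `c(M1, M2)` coarse image size.
#' @param factor upsampling factor (4).
#' @return `(factor * M1) x (factor * M2)` nonnegative matrix.
#' @export
upsample_saliency <- function(smap, coarse_dim, factor = 4L) {
  S <- if (inherits(smap, "saliency_map")) smap$S else smap
  M1 <- coarse_dim[1]; M2 <- coarse_dim[2]
  stopifnot(nrow(S) <= M1, ncol(S) <= M2)
  padded <- matrix(0, M1, M2)
  r0 <- (M1 - nrow(S)) %/% 2L; c0 <- (M2 - ncol(S)) %/% 2L
  padded[r0 + seq_len(nrow(S)), c0 + seq_len(ncol(S))] <- S
  up <- resize_bicubic(padded, M1 * factor, M2 * factor)
  up[up < 0] <- 0
  up
}

#' Pearson correlation between two saliency maps
#'
#' @param s1,s2 equally sized maps (matrices or `saliency_map`s).
#' @return correlation coefficient in `[-1, 1]`; errors on constant maps.
#' @export
correlation_coefficient <- function(s1, s2) {
  v1 <- as.vector(if (inherits(s1, "saliency_map")) s1$S else s1)
  v2 <- as.vector(if (inherits(s2, "saliency_map")) s2$S else s2)
  stopifnot(length(v1) == length(v2))
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("correlation undefined for a constant saliency map")
  }
  stats::cor(v1, v2)
}

#' Similarity of subset-based saliency maps to the full-bank map
#'
#' For each subset size, draws random feature subsets, computes the global
#' saliency map from each and correlates it with the map from all features,
#' over a set of synthetic scenes.
#'
#' @param bank a `gassom_bank`.
#' @param frames list of aligned coarse pairs (from [extract_saccade_input()]).
#' @param sizes subset sizes to probe.
#' @param reps random subsets per size and frame.
#' @param seed RNG seed.
#' @return tibble with `size`, `mean_cc`, `sd_cc`, `n`.
#' @export
subset_cc_curve <- function(bank, frames, sizes = c(1L, 5L, 25L, 100L, 324L),
                            reps = 3L, seed = 1L) {
  sizes <- sizes[sizes <= bank$n]
  res <- with_seed(seed, {
    rows <- list()
    for (fr in frames) {
      stack <- coarse_response_maps(bank, fr)
      full <- saliency_map(stack)
      for (sz in sizes) {
        for (rep in seq_len(reps)) {
          sub <- sort(sample.int(bank$n, sz))
          sstack <- stack
          sstack$resp <- stack$resp[sub, , drop = FALSE]
          sstack$features <- sub
          cc <- correlation_coefficient(saliency_map(sstack), full)
          rows[[length(rows) + 1L]] <- c(size = sz, cc = cc)
        }
      }
    }
    do.call(rbind, rows)
  })
  df <- as.data.frame(res)
  agg <- stats::aggregate(cc ~ size, df, function(v) c(m = mean(v), s = stats::sd(v), n = length(v)))
  tibble::tibble(size = agg$size,
                 mean_cc = agg$cc[, "m"],
                 sd_cc = agg$cc[, "s"],
                 n = as.integer(agg$cc[, "n"]))
}

#' Full-resolution saliency map in frame coordinates
#'
#' Convenience pipeline: extract the aligned coarse pair at the current
#' shift, compute the chosen saliency variant, upsample and place the map
#' into a frame-sized canvas at the cropped window's column offset.
#'
#' @param bank coarse-scale `gassom_bank`.
#' @param frame a `stereo_frame`.
#' @param d current shift in pixels.
#' @param variant one of `"gbaim"`, `"lbaim"`, `"aim-mono"`.
#' @param fixation `c(x, y)` full-resolution left fixation (required for
#'   `"lbaim"`).
#' @param features feature subset indices (default: 25 drawn with the
#'   current RNG).
#' @param subset_size number of features when `features` is NULL.
#' @return list with the frame-sized matrix `S` and the feature indices.
#' @export
frame_saliency <- function(bank, frame, d, variant = c("gbaim", "lbaim", "aim-mono"),
                           fixation = NULL, features = NULL, subset_size = 25L) {
  variant <- match.arg(variant)
  if (is.null(features)) {
    features <- sort(sample.int(bank$n, min(subset_size, bank$n)))
  }
  pair <- extract_saccade_input(frame, d)
  stack <- coarse_response_maps(bank, pair, features,
                                monocular = variant == "aim-mono")
  context <- NULL
  if (variant == "lbaim") {
    if (is.null(fixation)) stop("lbaim needs the current fixation point")
    ## map full-res fixation to its patch-grid position in the cropped,
    ## down-sampled window (patch centres sit at patch index + 4.5)
    cy <- (fixation[2] - 1) / 4 + 1 - 4.5
    cx <- (fixation[1] - 1 - pair$col_offset) / 4 + 1 - 4.5
    context <- c(min(max(round(cy), 1), stack$ny),
                 min(max(round(cx), 1), stack$nx))
  }
  smap <- saliency_map(stack, context = context)
  coarse_dim <- dim(pair$left)
  up <- upsample_saliency(smap, coarse_dim)
  S <- matrix(0, nrow(frame$left), ncol(frame$left))
  rr <- seq_len(min(nrow(up), nrow(S)))
  cc <- seq_len(min(ncol(up), ncol(S) - pair$col_offset))
  S[rr, pair$col_offset + cc] <- up[rr, cc]
  list(S = S, features = features, variant = variant)
}
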