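#' @keywords internal
#' @useDynLib aecvision, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Catmull-Rom / Keys cubic convolution kernel, a = -0.5.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  i2 <- t > 1 & t < 2
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

## Reflect an integer index into 1..n (symmetric boundary: 0 -> 1, -1 -> 2,
## n+1 -> n). Indices must be within one reflection of the valid range,
## which the 4-tap cubic footprint guarantees for n >= 2.
reflect_index <- function(idx, n) {
  lo <- idx < 1L
  idx[lo] <- 1L - idx[lo]
  hi <- idx > n
  idx[hi] <- 2L * n + 1L - idx[hi]
  idx
}

.resample_cache <- new.env(parent = emptyenv())

## Dense row-resampling matrix mapping n_in samples to n_out samples by
## cubic interpolation at pixel-centre-aligned positions. Cached, since the
## simulator reuses a handful of sizes millions of times.
resample_matrix <- function(n_in, n_out) {
  key <- paste0(n_in, ">", n_out)
  cached <- .resample_cache[[key]]
  if (!is.null(cached)) return(cached)
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) * scale + 0.5
    base <- floor(u)
    idx <- (base - 1L):(base + 2L)
    w <- cubic_kernel(u - idx)
    idx <- reflect_index(idx, n_in)
    for (k in seq_along(idx)) W[i, idx[k]] <- W[i, idx[k]] + w[k]
  }
  .resample_cache[[key]] <- W
  W
}

#' Resize a grayscale image by bicubic interpolation
#'
#' Separable cubic-convolution (Keys, a = -0.5) resampling with reflected
#' boundaries, used for all multi-scale down-sampling in the simulator.
#'
#' @param img numeric matrix (rows = y, cols = x), values typically in `[0,1]`.
#' @param out_h,out_w output dimensions in pixels.
#' @return an `out_h` by `out_w` numeric matrix.
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  if (out_h == nrow(img) && out_w == ncol(img)) return(img)
  Wr <- resample_matrix(nrow(img), out_h)
  Wc <- resample_matrix(ncol(img), out_w)
  Wr %*% img %*% t(Wc)
}

## Numerically safe softmax with max subtraction.
softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## Deterministic substream seeds derived from one master seed. Stream ids are
## fixed small integers so that, e.g., scene streams are shared across policy
## variants run from the same master seed while action/saccade streams differ.
SUBSTREAMS <- c(
  scenes = 1L, bank_init = 2L, policy_init = 3L, train = 4L,
  eval = 5L, subset = 6L, texture = 7L
)

substream_seed <- function(master, stream, k = 0L) {
  id <- SUBSTREAMS[[stream]]
  as.integer((as.double(master) * 97 + id * 1000003 + k * 131) %% 2147483647)
}

## Run expr with a local RNG state seeded by `seed`; restores the caller's
## RNG afterwards so seeded helpers do not perturb the main stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
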