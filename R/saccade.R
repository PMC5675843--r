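## Saccade target selection: saliency x inhibition-of-return, restricted to
## the valid fixation margin.

#' Fixation history for inhibition of return
#'
#' Holds at most the two most recent fixation points; the most recent is
#' suppressed with width `sigma1` = 20 px, the second most recent with
#' `sigma2` = 10 px, giving an IOR window of two fixations (800 ms at 400 ms
#' per fixation).
#'
#' @param sigma1,sigma2 suppression widths in pixels (`sigma1 > sigma2 > 0`).
#' @export
fixation_history <- function(sigma1 = 20, sigma2 = 10) {
  stopifnot(sigma1 > sigma2, sigma2 > 0)
  structure(list(points = list(), sigma1 = sigma1, sigma2 = sigma2),
            class = "fixation_history")
}

#' Push a fixation point into the history
#'
#' @param history a [fixation_history()].
#' @param point `c(x, y)` in pixels.
#' @export
push_fixation <- function(history, point) {
  history$points <- c(list(as.numeric(point)),
                      history$points)[seq_len(min(2L, length(history$points) + 1L))]
  history
}

## f(j, k, sigma^2) = 1 - exp(-||p_j - p_k||^2 / (2 sigma^2)) evaluated for
## every pixel against one remembered point.
ior_factor <- function(width, height, point, sigma) {
  dx2 <- (seq_len(width) - point[1])^2
  dy2 <- (seq_len(height) - point[2])^2
  1 - exp(-outer(dy2, dx2, `+`) / (2 * sigma^2))
}

#' Inhibition-of-return mask
#'
#' Per-pixel product of the suppression factors of the (up to two)
#' remembered fixation points; identically 1 for an empty history and
#' exactly 0 at each remembered point.
#'
#' @param history a [fixation_history()].
#' @param width,height frame size.
#' @return `height` x `width` matrix in `[0, 1]`.
#' @export
ior_mask <- function(history, width, height) {
  mask <- matrix(1, height, width)
  sig <- c(history$sigma1, history$sigma2)
  for (i in seq_along(history$points)) {
    mask <- mask * ior_factor(width, height, history$points[[i]], sig[i])
  }
  mask
}

#' Saccade-target distribution
#'
#' Normalized elementwise product of the full-resolution saliency map, the
#' IOR mask and the valid-fixation-margin mask. If the product is entirely
#' zero (e.g. a blank saliency map), falls back to a uniform distribution
#' over the valid margin and flags it.
#'
#' @param saliency frame-sized nonnegative matrix.
#' @param ior frame-sized IOR mask.
#' @param margin_mask logical frame-sized matrix of valid fixations.
#' @return list with the probability matrix `p` (sums to 1) and `fallback`.
#' @export
target_distribution <- function(saliency, ior, margin_mask) {
  stopifnot(all(dim(saliency) == dim(ior)), all(dim(ior) == dim(margin_mask)))
  w <- saliency * ior
  w[!margin_mask] <- 0
  tot <- sum(w)
  fallback <- FALSE
  if (tot <= 0) {
    w <- matrix(0, nrow(saliency), ncol(saliency))
    w[margin_mask] <- 1
    tot <- sum(w)
    fallback <- TRUE
  }
  list(p = w / tot, fallback = fallback)
}

#' Sample the next fixation point
#'
#' Draws a pixel from the target distribution and pushes it into the
#' history (most recent first). The vergence shift is carried over
#' unchanged by the caller.
#'
#' @param dist probability matrix (from [target_distribution()]).
#' @param history a [fixation_history()].
#' @return list with `point` = `c(x, y)` and the updated `history`.
#' @export
sample_fixation <- function(dist, history = fixation_history()) {
  p <- if (is.list(dist)) dist$p else dist
  idx <- sample.int(length(p), 1L, prob = as.vector(p))
  y <- ((idx - 1L) %% nrow(p)) + 1L
  x <- ((idx - 1L) %/% nrow(p)) + 1L
  list(point = c(x = x, y = y), history = push_fixation(history, c(x, y)))
}

#' Random saccade policy
#'
#' Uniform distribution over the valid fixation margin — the control
#' condition against which saliency-driven saccades are compared.
#'
#' @param margin_mask logical frame-sized matrix.
#' @return `c(x, y)` fixation point.
#' @export
random_saccade_policy <- function(margin_mask) {
  idx <- which(margin_mask)
  pick <- idx[sample.int(length(idx), 1L)]
  y <- ((pick - 1L) %% nrow(margin_mask)) + 1L
  x <- ((pick - 1L) %/% nrow(margin_mask)) + 1L
  c(x = x, y = y)
}
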