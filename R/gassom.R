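## Binocular patch encoding and the online adaptive-subspace SOM.

## Cache of linear-index matrices for patch extraction, keyed by
## "<rows>x<cols>:<stride>".
.patch_idx_cache <- new.env(parent = emptyenv())

patch_index <- function(nr, nc, stride, psize = 10L) {
  key <- paste0(nr, "x", nc, ":", stride)
  if (!is.null(.patch_idx_cache[[key]])) return(.patch_idx_cache[[key]])
  ys <- seq(1L, nr - psize + 1L, by = stride)
  xs <- seq(1L, nc - psize + 1L, by = stride)
  one <- as.vector(outer(0:(psize - 1L), (0:(psize - 1L)) * nr, `+`)) + 1L
  starts <- as.vector(outer(ys - 1L, (xs - 1L) * nr, `+`))
  idx <- outer(one, starts, `+`)          # (psize^2) x P
  out <- list(idx = idx, ny = length(ys), nx = length(xs), ys = ys, xs = xs)
  .patch_idx_cache[[key]] <- out
  out
}

#' Cut a binocular window pair into normalized 200-d patch vectors
#'
#' Extracts 10x10 patches on a regular grid (stride 5 for vergence pooling,
#' stride 1 for saliency), concatenates left above right into 200-d vectors,
#' and normalizes each 100-d monocular half separately to zero mean and unit
#' variance. Halves with standard deviation below `1e-6` are treated as
#' low-contrast: their std is clamped (a constant patch becomes the zero
#' vector) and the patch is flagged so learning can skip it.
#'
#' @param left,right equally sized numeric matrices (at least 10x10).
#' @param stride patch grid stride in pixels (1 or 5).
#' @return list with `x` (200 x P matrix of patch vectors, grid scanned
#'   column-major), `low_contrast` (logical P), and grid dims `ny`, `nx`.
#' @export
patchify <- function(left, right, stride = 5L) {
  stopifnot(all(dim(left) == dim(right)), nrow(left) >= 10, ncol(left) >= 10)
  pi_ <- patch_index(nrow(left), ncol(left), as.integer(stride))
  out <- patchify_core(left, right, pi_$idx)
  list(x = out$x, low_contrast = out$low_contrast,
       ny = pi_$ny, nx = pi_$nx)
}

## Gram-Schmidt orthonormalization of a 2-column basis.
orthonormalize2 <- function(phi) {
  q1 <- phi[, 1] / sqrt(sum(phi[, 1]^2))
  q2 <- phi[, 2] - sum(q1 * phi[, 2]) * q1
  q2 <- q2 / sqrt(sum(q2^2))
  cbind(q1, q2, deparse.level = 0)
}

#' Initialize a bank of two-dimensional subspaces
#'
#' Each of the `n` feature extractors is a 2-column orthonormal basis of the
#' 200-d binocular patch space, drawn isotropically then orthonormalized.
#'
#' @param n number of subspaces (324 at full scale).
#' @param dim patch-vector dimension (200).
#' @param seed integer seed; the same seed reproduces the bank exactly.
#' @param sigma_e responsibility softness (response units).
#' @param omega stickiness prior mass on the previous winner, in (0,1).
#' @param lambda base learning rate.
#' @param mode `"soft"` responsibilities or `"hard"` winner-take-all.
#' @return a `gassom_bank`.
#' @export
init_gassom_bank <- function(n = 324L, dim = 200L, seed = 1L,
                             sigma_e = 0.2, omega = 0.5, lambda = 0.005,
                             mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  phi <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      orthonormalize2(matrix(stats::rnorm(dim * 2L), dim, 2L))
    })
  })
  structure(list(phi = phi, n = as.integer(n), dim = as.integer(dim),
                 sigma_e = sigma_e, omega = omega, lambda = lambda,
                 mode = mode, prev_winner = NULL),
            class = "gassom_bank")
}

## Flattened dim x 2n basis matrix for fast batched projection. The bank
## stores the subspaces as a list of dim x 2 matrices.
bank_matrix <- function(bank) {
  do.call(cbind, bank$phi)
}

#' Subspace energy responses
#'
#' The response of feature extractor n to patch vector x is the squared
#' length of the projection of x onto its 2-d subspace (the complex-cell
#' energy analogue): `r_n = ||Phi_n' x||^2`.
#'
#' @param bank a `gassom_bank`.
#' @param x a patch vector, or a `dim` x P matrix of patch vectors.
#' @return an `n` x P matrix of nonnegative responses (P = 1 for a vector).
#' @export
subspace_responses <- function(bank, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  C <- crossprod(bank_matrix(bank), x)        # 2n x P
  odd <- seq(1L, 2L * bank$n, by = 2L)
  C[odd, , drop = FALSE]^2 + C[odd + 1L, , drop = FALSE]^2
}

#' Best-fitting subspace and reconstruction error
#'
#' Selects, per patch, the subspace with the largest response (ties to the
#' lowest index) and returns the squared residual of the patch after
#' projection onto it: `e = ||x||^2 - max_n r_n`.
#'
#' @param bank a `gassom_bank`.
#' @param x patch vector or `dim` x P matrix.
#' @param resp optional precomputed response matrix from
#'   [subspace_responses()].
#' @return list with integer vector `m` (winner indices) and numeric `e`
#'   (residual errors, >= 0).
#' @export
best_subspace_and_error <- function(bank, x, resp = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (is.null(resp)) resp <- subspace_responses(bank, x)
  m <- max.col(t(resp), ties.method = "first")
  r_m <- resp[cbind(m, seq_len(ncol(x)))]
  e <- pmax(colSums(x^2) - r_m, 0)
  list(m = m, e = e)
}

#' Mean reconstruction error of one scale
#'
#' @param bank a `gassom_bank`.
#' @param patches output of [patchify()] (or a patch matrix).
#' @return mean squared residual over the patches.
#' @export
scale_error <- function(bank, patches) {
  x <- if (is.list(patches)) patches$x else patches
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (ncol(x) == 0L) stop("empty patch list")
  mean(best_subspace_and_error(bank, x)$e)
}

#' Average reconstruction error across the three scales
#'
#' @param e_coarse,e_medium,e_fine per-scale mean errors.
#' @return `(E_C + E_M + E_F) / 3`; the vergence reward is its negative.
#' @export
average_error <- function(e_coarse, e_medium, e_fine) {
  (e_coarse + e_medium + e_fine) / 3
}

#' Responsibilities of the subspaces for a batch of patches
#'
#' Soft assignment combining sparsity and slowness: `h_n` is proportional to
#' `exp(r_n / (2 sigma_e^2))` times a prior that places mass `omega` on the
#' patch's previous winner and `(1-omega)/(N-1)` on every other subspace
#' (uniform when there is no previous winner). Columns sum to one. In
#' `"hard"` mode the winner takes all.
#'
#' @param bank a `gassom_bank`.
#' @param resp `n` x P response matrix.
#' @param prev integer vector of previous winner indices per patch (NA or
#'   NULL for none).
#' @return `n` x P matrix of responsibilities.
#' @export
responsibilities <- function(bank, resp, prev = NULL) {
  n <- bank$n; P <- ncol(resp)
  if (bank$mode == "hard") {
    m <- max.col(t(resp), ties.method = "first")
    H <- matrix(0, n, P)
    H[cbind(m, seq_len(P))] <- 1
    return(H)
  }
  lw <- resp / (2 * bank$sigma_e^2)
  if (!is.null(prev)) {
    lp <- matrix(log((1 - bank$omega) / (n - 1)), n, P)
    ok <- which(!is.na(prev))
    lp[cbind(prev[ok], ok)] <- log(bank$omega)
    has <- !is.na(prev)
    lw[, has] <- lw[, has, drop = FALSE] + lp[, has, drop = FALSE]
  }
  cmax <- lw[cbind(max.col(t(lw), ties.method = "first"), seq_len(P))]
  lw <- lw - rep(cmax, each = n)
  H <- exp(lw)
  sweep(H, 2L, colSums(H), `/`)
}

#' Online subspace update
#'
#' Rotates each subspace toward the patches it is responsible for:
#' `DeltaPhi_n = sum_j h_{n,j} xtilde_{j,n} (x_j' Phi_n) / (||xhat_{j,n}|| ||x_j||)`
#' with `xhat` the projection of the patch onto the subspace and `xtilde`
#' the residual, followed by `Phi <- orthonormalize(Phi + lambda DeltaPhi)`.
#' Patches flagged low-contrast, patches with (numerically) zero norm or
#' zero projection, and patches whose responsibility is below `1e-12`
#' contribute nothing.
#'
#' @param bank a `gassom_bank`.
#' @param x `dim` x P patch matrix.
#' @param H `n` x P responsibility matrix.
#' @param lambda learning rate (> 0); defaults to the bank's.
#' @param exclude logical P vector of patches to skip (e.g. low-contrast).
#' @return the updated `gassom_bank`.
#' @export
update_gassom_bank <- function(bank, x, H, lambda = bank$lambda,
                               exclude = NULL) {
  stopifnot(lambda > 0)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  P <- ncol(x)
  if (is.null(exclude)) exclude <- rep(FALSE, P)
  flat <- gassom_update_core(bank_matrix(bank), x, H, lambda, exclude)
  bank$phi <- lapply(seq_len(bank$n), function(i) {
    flat[, c(2L * i - 1L, 2L * i), drop = FALSE]
  })
  bank
}

#' One full encode-and-learn step on a window's patches
#'
#' Computes responses, winners, residual errors and responsibilities (using
#' the winners stored from the previous call as the slowness context), then
#' optionally updates the bank and stores the new winners.
#'
#' @param bank a `gassom_bank`.
#' @param patches output of [patchify()].
#' @param update whether to apply the subspace update.
#' @param lambda learning rate for the update.
#' @return list with the updated `bank`, `resp` (n x P), `m`, `e`, and the
#'   scale error `E` (mean of `e`).
#' @export
gassom_step <- function(bank, patches, update = TRUE, lambda = bank$lambda) {
  x <- patches$x
  resp <- subspace_responses(bank, x)
  be <- best_subspace_and_error(bank, x, resp)
  prev <- bank$prev_winner
  if (!is.null(prev) && length(prev) != ncol(x)) prev <- NULL
  if (update) {
    H <- responsibilities(bank, resp, prev)
    bank <- update_gassom_bank(bank, x, H, lambda,
                               exclude = patches$low_contrast)
  }
  bank$prev_winner <- be$m
  list(bank = bank, resp = resp, m = be$m, e = be$e, E = mean(be$e))
}

#' Clear the slowness context of a bank
#'
#' Called at saccades/scene changes: the next step's responsibilities use a
#' uniform prior instead of favouring the previous winners.
#'
#' @param bank a `gassom_bank`.
#' @export
reset_bank_context <- function(bank) {
  bank$prev_winner <- NULL
  bank
}
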