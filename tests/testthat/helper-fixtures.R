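# Shared fixtures, built in code. Heavier shared objects (trained systems)
# are cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small textured stereo scene and frame.
tiny_scene <- function(seed = 3L, n_planes = 2L) {
  generate_scene(scene_config(width = 320L, height = 240L,
                              n_planes = n_planes), seed)
}

# Random orthonormal 2-column basis in d dimensions.
random_basis <- function(d = 200L) {
  qr.Q(qr(matrix(rnorm(d * 2L), d, 2L)))
}

# A random small bank whose subspaces are known exactly.
small_bank <- function(n = 8L, d = 20L, seed = 1L, ...) {
  init_gassom_bank(n = n, dim = d, seed = seed, ...)
}

# Patches drawn from planted 2-d subspaces (+ optional noise), the standard
# recovery testbed for subspace learning.
planted_patches <- function(bases, per_subspace = 20L, noise = 0) {
  d <- nrow(bases[[1]])
  X <- matrix(0, d, length(bases) * per_subspace)
  k <- 0L
  for (B in bases) {
    for (i in seq_len(per_subspace)) {
      k <- k + 1L
      X[, k] <- B %*% rnorm(2L) + if (noise > 0) rnorm(d, 0, noise) else 0
    }
  }
  X
}

# Desk-scale config small enough for unit tests.
test_config <- function(...) {
  run_config("desk", n_subspaces = 16L, n_fixations = 6L,
             scene_period = 3L, ...)
}
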