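# Self-information saliency: histograms, maps, upsampling, subset similarity.

test_that("a 55x55 input yields the full stride-1 patch grid", {
  set.seed(1)
  bank <- init_gassom_bank(8L, seed = 1)
  pair <- list(left = matrix(runif(55 * 55), 55, 55),
               right = matrix(runif(55 * 55), 55, 55))
  stack <- coarse_response_maps(bank, pair)
  expect_equal(stack$ny * stack$nx, 46L * 46L)   # 2,116 positions
  expect_equal(dim(stack$resp), c(8L, 2116L))
  expect_error(coarse_response_maps(bank, list(left = matrix(0, 5, 5),
                                               right = matrix(0, 5, 5))),
               "10x10")
  # constant input: all patches low contrast, all responses 0
  cpair <- list(left = matrix(0.5, 20, 20), right = matrix(0.5, 20, 20))
  cstack <- coarse_response_maps(bank, cpair)
  expect_true(all(cstack$resp == 0))
  # spot-check one response against the naive patch loop
  probe <- patchify(pair$left, pair$right, 1L)
  j <- 123L
  expect_equal(stack$resp[3, j],
               sum(crossprod(bank$phi[[3]], probe$x[, j])^2))
})

test_that("histograms conserve mass, bin as printed, and close the top bin", {
  v <- c(0, 0.09, 0.5, 0.91, 1.0)
  h <- build_histogram(v, K = 10L)
  expect_equal(sum(h), 1)
  expect_equal(h[1], 0.4)    # 0 and 0.09 in bin 1
  expect_equal(h[10], 0.4)   # 0.91 and the closed-top 1.0 in bin 10
  expect_equal(h[6], 0.2)
  # identical responses: all mass in one bin
  h1 <- build_histogram(rep(0.3, 50), K = 7L)
  expect_equal(max(h1), 1)
  # context subsetting renormalizes
  h2 <- build_histogram(v, context = 3:5, K = 4L)
  expect_equal(sum(h2), 1)
  expect_error(build_histogram(v, context = integer(0)), "empty")
  # uniform grid spanning [0,1] -> near-uniform weights
  hu <- build_histogram(seq(0, 1, length.out = 1000), K = 10L)
  expect_true(all(abs(hu - 0.1) < 0.01))
})

test_that("self-information is -ln p with the alpha floor", {
  h <- c(1, 0, 0)
  expect_equal(self_information(0.1, h), 0, tolerance = 1e-6)
  expect_equal(self_information(0.5, h), -log(1e-6), tolerance = 1e-9)
  expect_equal(-log(1e-6), 13.8155, tolerance = 1e-4)
  # rarer bins are strictly more surprising
  h2 <- c(0.7, 0.2, 0.1)
  s <- self_information(c(0.1, 0.5, 0.9), h2)
  expect_true(all(diff(s) > 0))
})

test_that("saliency maps sum feature self-information over the subset", {
  set.seed(2)
  bank <- init_gassom_bank(12L, seed = 3)
  pair <- list(left = matrix(runif(30 * 40), 30, 40),
               right = matrix(runif(30 * 40), 30, 40))
  stack <- coarse_response_maps(bank, pair)
  full <- saliency_map(stack)
  expect_true(all(full$S >= 0))
  expect_true(all(full$S <= 12 * (-log(1e-6)) + 1e-9))
  # additivity: full map equals the sum of single-feature maps
  acc <- matrix(0, stack$ny, stack$nx)
  for (i in 1:12) {
    s1 <- stack; s1$resp <- stack$resp[i, , drop = FALSE]
    s1$features <- i
    acc <- acc + saliency_map(s1)$S
  }
  expect_equal(acc, full$S, tolerance = 1e-12)
  expect_error(saliency_map(structure(list(resp = stack$resp,
                                           features = integer(0),
                                           ny = stack$ny, nx = stack$nx),
                                      class = "response_map_stack")),
               "empty")
})

test_that("the local context is clipped at borders and changes the map", {
  set.seed(3)
  bank <- init_gassom_bank(6L, seed = 4)
  pair <- list(left = matrix(runif(50 * 50), 50, 50),
               right = matrix(runif(50 * 50), 50, 50))
  stack <- coarse_response_maps(bank, pair)
  corner <- saliency_map(stack, context = c(1L, 1L))
  centre <- saliency_map(stack, context = c(20L, 20L))
  expect_true(all(is.finite(corner$S)))
  expect_false(identical(corner$S, centre$S))
})

test_that("upsampling zero-pads, scales by 4 and clamps undershoot", {
  cm <- matrix(5, 11, 16)          # as if from a 20x25 coarse image
  up <- upsample_saliency(cm, c(20L, 25L))
  expect_equal(dim(up), c(80L, 100L))
  expect_true(all(up >= 0))
  expect_equal(up[40, 50], 5, tolerance = 0.05)  # interior preserved
  expect_lt(max(up[1:2, ]), 1)                   # padded border ring low
  expect_equal(upsample_saliency(matrix(0, 11, 16), c(20L, 25L)),
               matrix(0, 80, 100))
})

test_that("the correlation coefficient matches its textbook definition", {
  set.seed(4)
  S1 <- matrix(runif(100), 10, 10)
  S2 <- matrix(runif(100), 10, 10)
  expect_equal(correlation_coefficient(S1, S1), 1)
  expect_equal(correlation_coefficient(S1, -S1 + 3), -1)
  m1 <- mean(S1); m2 <- mean(S2)
  oracle <- sum((S1 - m1) * (S2 - m2)) /
    sqrt(sum((S1 - m1)^2) * sum((S2 - m2)^2))
  expect_equal(correlation_coefficient(S1, S2), oracle, tolerance = 1e-12)
  expect_error(correlation_coefficient(matrix(1, 5, 5), S1[1:5, 1:5]),
               "constant")
})

test_that("monocular degeneracy still yields a valid map", {
  set.seed(5)
  bank <- init_gassom_bank(10L, seed = 6)
  pair <- list(left = matrix(runif(40 * 40), 40, 40),
               right = matrix(runif(40 * 40), 40, 40))
  stack <- coarse_response_maps(bank, pair, monocular = TRUE)
  sm <- saliency_map(stack)
  expect_true(all(is.finite(sm$S)))
  expect_true(all(sm$S >= 0))
  expect_gt(sd(sm$S), 0)
})

test_that("subset similarity grows with subset size up to CC = 1", {
  set.seed(6)
  cfg <- scene_config(width = 200L, height = 150L, n_planes = 2L)
  bank <- init_gassom_bank(24L, seed = 7)
  frames <- lapply(1:2, function(i) {
    extract_saccade_input(render_stereo(generate_scene(cfg, seed = i)), 0L)
  })
  curve <- subset_cc_curve(bank, frames, sizes = c(1L, 8L, 24L), reps = 3L,
                           seed = 9)
  expect_equal(curve$mean_cc[curve$size == 24], 1)
  expect_lt(curve$mean_cc[curve$size == 1], curve$mean_cc[curve$size == 8])
})
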