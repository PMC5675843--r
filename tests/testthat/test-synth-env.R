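# Scene generation, stereo rendering and the window-shift eye-movement model.

test_that("degenerate and single-plane scenes have the stated disparity maps", {
  sc0 <- generate_scene(scene_config(n_planes = 0L, background_disparity = 0L),
                        seed = 1)
  expect_true(all(sc0$disparity == 0))

  cfg <- scene_config(n_planes = 0L, background_disparity = 0L)
  sc1 <- generate_scene(cfg, seed = 2)
  sc1$planes <- list(list(x0 = 101L, x1 = 200L, y0 = 101L, y1 = 200L,
                          disparity = 8L,
                          canvas = matrix(0.5, 100L, 100L + 80L)))
  sc1$disparity[101:200, 101:200] <- 8L
  expect_true(all(sc1$disparity[101:200, 101:200] == 8))
  expect_true(all(sc1$disparity[1:100, ] == 0))
})

test_that("scene generation is byte-identical for a fixed seed", {
  a <- generate_scene(scene_config(), seed = 11)
  b <- generate_scene(scene_config(), seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_scene(scene_config(), seed = 12)))
})

test_that("scene generation rejects frames too small for the windows", {
  expect_error(valid_margin(100, 100, 55L), "minimum size")
})

test_that("rendering a zero-disparity scene gives identical eyes, and a pure
           shift for a full-frame plane", {
  sc <- generate_scene(scene_config(n_planes = 0L,
                                    background_texture = "onef"), seed = 5)
  fr <- render_stereo(sc)
  expect_equal(fr$left, fr$right)

  sc4 <- generate_scene(scene_config(n_planes = 0L, background_disparity = 4L,
                                     background_texture = "onef"), seed = 5)
  fr4 <- render_stereo(sc4)
  w <- sc4$width
  expect_equal(fr4$right[, 1:(w - 4)], fr4$left[, 5:w])
})

# Independent painter's-algorithm oracle: per pixel, scan planes far to near.
render_oracle <- function(scene) {
  w <- scene$width; h <- scene$height; ext <- 40L
  planes <- c(list(scene$background), scene$planes)
  left <- matrix(NA_real_, h, w); right <- matrix(NA_real_, h, w)
  for (p in planes) {   # already ordered far -> near, background first
    for (y in p$y0:p$y1) {
      for (x in p$x0:p$x1) {
        left[y, x] <- p$canvas[y - p$y0 + 1L, x - p$x0 + 1L + ext]
        xr <- x - p$disparity
        if (xr >= 1 && xr <= w) {
          right[y, xr] <- p$canvas[y - p$y0 + 1L, x - p$x0 + 1L + ext]
        }
      }
    }
  }
  list(left = left, right = right)
}

test_that("rendering matches the brute-force painter's oracle exactly", {
  for (seed in c(2, 9)) {
    sc <- generate_scene(scene_config(width = 120L, height = 90L,
                                      n_planes = 3L), seed = seed)
    fr <- render_stereo(sc)
    or <- render_oracle(sc)
    expect_equal(fr$left, or$left)
    expect_equal(fr$right, or$right)
  }
})

test_that("vergence windows are 55x55 at all scales and align at zero
           retinal disparity", {
  sc <- generate_scene(scene_config(width = 640L, height = 480L, n_planes = 0L,
                                    background_disparity = 6L,
                                    background_texture = "onef"), seed = 7)
  fr <- render_stereo(sc)
  fix <- fixation_state(320L, 240L, d = 6L)
  w <- extract_vergence_input(fr, fix, 55L)
  for (s in w) {
    expect_equal(dim(s$left), c(55L, 55L))
    expect_equal(dim(s$right), c(55L, 55L))
  }
  expect_equal(w$fine$left, w$fine$right)

  const <- fr; const$left <- matrix(0.5, 480, 640); const$right <- const$left
  wc <- extract_vergence_input(const, fix, 55L)
  expect_equal(wc$coarse$left, matrix(0.5, 55, 55))
})

test_that("window extraction is translation-covariant away from borders", {
  sc <- tiny_scene(seed = 4)
  fr <- render_stereo(sc)
  f1 <- fixation_state(160L, 120L, d = 0L)
  f2 <- fixation_state(165L, 117L, d = 0L)
  w1 <- extract_vergence_input(fr, f1, 35L)$fine
  w2 <- extract_vergence_input(fr, f2, 35L)$fine
  expect_equal(w1$left[1:20, 6:35], w2$left[4:23, 1:30])
})

test_that("saccade input follows the corner formula and its arithmetic", {
  fr <- list(left = matrix(runif(640 * 480), 480, 640),
             right = matrix(runif(640 * 480), 480, 640))
  si <- extract_saccade_input(fr, 8L)
  expect_equal(dim(si$left), c(120L, 158L))   # (480, 632) / 4
  expect_equal(dim(si$right), dim(si$left))

  si0 <- extract_saccade_input(fr, 0L)
  expect_equal(dim(si0$left), c(120L, 160L))
  expect_error(extract_saccade_input(fr, 640L), "width")

  sc <- generate_scene(scene_config(n_planes = 0L, background_disparity = 7L,
                                    background_texture = "onef"), seed = 3)
  fr7 <- render_stereo(sc)
  si7 <- extract_saccade_input(fr7, 7L)
  expect_equal(si7$left, si7$right)
})

test_that("retinal disparity is shift minus scene disparity", {
  sc <- tiny_scene(seed = 8)
  expect_equal(retinal_disparity(sc, fixation_state(150L, 120L,
                                                    d = sc$disparity[120, 150])),
               0)
  expect_equal(retinal_disparity(sc, fixation_state(150L, 120L, d = 0L)),
               -sc$disparity[120, 150])
  # brute-force: visible plane at each probe = last painted covering plane
  set.seed(2)
  for (i in 1:20) {
    x <- sample(320, 1); y <- sample(240, 1); d <- sample(-10:10, 1)
    covering <- sc$background$disparity
    for (p in sc$planes) {
      if (x >= p$x0 && x <= p$x1 && y >= p$y0 && y <= p$y1) {
        covering <- p$disparity
      }
    }
    expect_equal(retinal_disparity(sc, fixation_state(x, y, d = d)),
                 d - covering)
  }
})

test_that("vergence actions shift and clamp, and the set is the printed one", {
  expect_equal(ACTIONS_VERG, c(-16L, -8L, -4L, -2L, -1L, 0L, 1L, 2L, 4L, 8L, 16L))
  expect_equal(sort(ACTIONS_VERG), sort(-ACTIONS_VERG))
  fix <- fixation_state(100L, 100L, d = 10L)
  expect_equal(apply_vergence_action(fix, -8L)$d, 2L)
  f0 <- apply_vergence_action(fix, 0L)
  expect_equal(f0$d, 10L)
  expect_equal(f0$frame, fix$frame + 1L)
  expect_error(apply_vergence_action(fix, 3L), "action set")
  fix$d <- 39L
  expect_equal(apply_vergence_action(fix, 16L)$d, 40L)
})

test_that("every disparity in [-20, 20] is cancellable within 10 actions", {
  reachable <- 0L
  for (target in -20:20) {
    best <- abs(target)
    d <- -target
    # greedy-complete search: BFS over sums of <= 10 actions
    frontier <- d
    for (step in 1:10) {
      frontier <- unique(as.vector(outer(frontier, ACTIONS_VERG, `+`)))
      frontier <- frontier[abs(frontier) <= 40]
      best <- min(best, min(abs(frontier)))
      if (best == 0) break
    }
    if (best == 0) reachable <- reachable + 1L
  }
  expect_equal(reachable, 41L)
})

test_that("the truncated Laplacian prior is normalized, symmetric and has
           the right decay", {
  p <- laplacian_disparity_pmf(5)
  expect_equal(sum(p), 1)
  expect_equal(unname(p[as.character(7)]), unname(p[as.character(-7)]))
  expect_equal(unname(p["0"] / p["5"]), exp(1), tolerance = 1e-12)
  p_small <- laplacian_disparity_pmf(0.05)
  expect_gt(unname(p_small["0"]), 0.999)
  expect_error(laplacian_disparity_pmf(0), "> 0")
  expect_error(laplacian_disparity_pmf(-3), "> 0")
})

test_that("Laplacian sampler matches its law in total variation", {
  # n is chosen so the expected multinomial TV noise (~ sum_k
  # sqrt(2 p_k (1-p_k) / (pi n)) / 2, about 0.006 at n = 4e5 for the
  # near-uniform D = 50 case) sits well below the 0.01 bound.
  n <- 4e5
  for (D in c(5, 50)) {
    set.seed(20 + D)
    draws <- sample_laplacian_disparity(D, n)
    emp <- tabulate(draws + 41L, nbins = 81L) / n
    tv <- sum(abs(emp - laplacian_disparity_pmf(D))) / 2
    expect_lt(tv, 0.01)
  }
})

test_that("stereo frames round-trip through PNG export", {
  sc <- tiny_scene(seed = 6)
  fr <- render_stereo(sc)
  pre <- file.path(tempdir(), "frame")
  paths <- export_stereo_frame(fr, pre, scene = sc)
  expect_true(all(file.exists(paths)))
  rt <- read_stereo_pair(paths[1], paths[2])
  expect_equal(dim(rt$left), dim(fr$left))
  expect_lt(max(abs(rt$left - pmin(pmax(fr$left, 0), 1))), 1 / 255)
  dsp <- as.matrix(utils::read.csv(paths[3], header = FALSE))
  expect_equal(unname(dsp), unname(sc$disparity))
})
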