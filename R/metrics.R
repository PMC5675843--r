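## Evaluation protocols: vergence RMSE, fixation entropy, disparity-tuning
## curves and V-fits, expected disparity differences, within-fixation error
## decrease.

## Pooled, standardized features of a system for a single-plane scene at a
## given shift; no learning. Uses the policy's frozen running feature scale.
system_features <- function(system, frame, fix) {
  cfg <- system$config
  windows <- extract_vergence_input(frame, fix, cfg$window)
  enc <- encode_windows(system$banks, windows, cfg$stride, update = FALSE)
  r <- apply_feature_transform(system$policy, enc$pooled)
  list(r = r, e_avg = enc$e_avg)
}

## A textured single-plane evaluation scene (full-frame plane, disparity 0,
## textured background) so that shift == retinal disparity.
flat_eval_scene <- function(config, seed) {
  generate_scene(scene_config(
    width = config$width, height = config$height, n_planes = 0L,
    background_texture = config$texture, background_disparity = 0L), seed)
}

#' Vergence-policy RMSE
#'
#' Presents the policy with single-plane inputs at initial retinal
#' disparities spanning `disparities`, lets it run for `iterations` steps,
#' and returns the root mean squared final retinal disparity over all
#' initial disparities and `reps` textured inputs per disparity.
#'
#' @param system an `aec_system`.
#' @param disparities initial disparities (default -20..20 px).
#' @param reps inputs per disparity (100 in the reference protocol).
#' @param iterations vergence steps per input (10).
#' @param seed evaluation seed (scene stream disjoint from training).
#' @return list with `rmse` (px) and per-trial tibble `trials`.
#' @export
policy_rmse <- function(system, disparities = -20:20, reps = 5L,
                        iterations = 10L, seed = 1L) {
  cfg <- system$config
  cx <- as.integer(round(cfg$width / 2)); cy <- as.integer(round(cfg$height / 2))
  rows <- with_seed(seed, {
    out <- list()
    for (rep in seq_len(reps)) {
      scene <- flat_eval_scene(cfg, seed + 7717L * rep)
      frame <- render_stereo(scene)
      for (d0 in disparities) {
        d <- as.integer(d0)
        for (it in seq_len(iterations)) {
          fix <- fixation_state(cx, cy, d)
          sf <- system_features(system, frame, fix)
          a <- sample_action(policy_distribution(system$policy, sf$r))
          d <- max(-SHIFT_MAX, min(SHIFT_MAX, d + ACTIONS_VERG[a]))
        }
        out[[length(out) + 1L]] <- c(d0 = d0, rep = rep, final = d)
      }
    }
    do.call(rbind, out)
  })
  trials <- tibble::as_tibble(as.data.frame(rows))
  list(rmse = sqrt(mean(trials$final^2)), trials = trials)
}

#' Modal vergence action per initial disparity
#'
#' For each initial disparity, takes the policy's modal (highest
#' probability) action over `reps` textured single-plane inputs and reports
#' the majority vote — the anti-diagonal structure of a learned policy has
#' modal action sign opposite to the disparity.
#'
#' @param system an `aec_system`.
#' @param disparities initial disparities to probe.
#' @param reps textures per disparity.
#' @param seed evaluation seed.
#' @return tibble with `d0`, `modal_action`, `opposite_sign`.
#' @export
policy_action_map <- function(system, disparities = setdiff(-16:16, 0L),
                              reps = 5L, seed = 1L) {
  cfg <- system$config
  cx <- as.integer(round(cfg$width / 2)); cy <- as.integer(round(cfg$height / 2))
  rows <- lapply(disparities, function(d0) {
    acts <- vapply(seq_len(reps), function(rep) {
      scene <- flat_eval_scene(cfg, seed + 7717L * rep)
      frame <- render_stereo(scene)
      fix <- fixation_state(cx, cy, as.integer(d0))
      sf <- system_features(system, frame, fix)
      greedy_action(system$policy, sf$r)
    }, numeric(1))
    tab <- sort(table(acts), decreasing = TRUE)
    modal <- as.numeric(names(tab)[1])
    tibble::tibble(d0 = d0, modal_action = modal,
                   opposite_sign = sign(modal) == -sign(d0))
  })
  do.call(rbind, rows)
}

#' Shannon entropy of a grayscale window
#'
#' Intensities in `[0, 1]` are quantized to 256 equal-width levels; the
#' entropy of the level histogram is returned in bits (0 to 8).
#'
#' @param window numeric matrix with values in `[0, 1]`.
#' @export
window_entropy <- function(window) {
  idx <- pmin(pmax(floor(as.vector(window) * 256), 0), 255) + 1L
  p <- tabulate(idx, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Median fine-window entropy at the fixations a saccade policy selects
#'
#' Runs the system's saccade machinery (representation and vergence policy
#' frozen) on freshly seeded scenes for `n_fixations` fixations per scene
#' and returns the median over fixations of the left/right-averaged entropy
#' of the fine-scale window.
#'
#' @param system an `aec_system`.
#' @param variant saccade variant (defaults to the system's).
#' @param n_scenes,n_fixations evaluation scenes and fixations per scene.
#' @param background_texture background family of the evaluation scenes;
#'   the protocol default `"flat"` creates textured objects on a
#'   near-constant background, so policies genuinely differ in the texture
#'   content of the windows they select.
#' @param seed evaluation seed.
#' @return list with `median`, `sem` and the per-fixation `entropies`.
#' @export
median_fixation_entropy <- function(system, variant = system$config$variant,
                                    n_scenes = 3L, n_fixations = 10L,
                                    background_texture = "flat",
                                    seed = 1L) {
  cfg <- system$config
  cfg$variant <- variant
  cfg$background_texture <- background_texture
  sysv <- system; sysv$config <- cfg
  margin <- valid_margin(cfg$width, cfg$height, cfg$window)
  ents <- with_seed(seed, {
    out <- numeric(0)
    for (i in seq_len(n_scenes)) {
      scene <- scene_from_config(cfg, seed + 104729L * i)
      frame <- render_stereo(scene)
      history <- fixation_history()
      last_point <- NULL
      d <- 0L
      for (f in seq_len(n_fixations)) {
        sac <- do_saccade(sysv, frame, d, history, margin, last_point)
        history <- sac$history; last_point <- sac$point
        fix <- fixation_state(sac$point[1], sac$point[2], d)
        win <- extract_vergence_input(frame, fix, cfg$window)$fine
        out <- c(out, (window_entropy(win$left) + window_entropy(win$right)) / 2)
        ## frozen vergence rollout so the shift evolves as in the protocol
        for (k in seq_len(cfg$fixation_frames)) {
          sf <- system_features(sysv, frame, fixation_state(sac$point[1], sac$point[2], d))
          a <- sample_action(policy_distribution(sysv$policy, sf$r))
          d <- max(-SHIFT_MAX, min(SHIFT_MAX, d + ACTIONS_VERG[a]))
        }
      }
    }
    out
  })
  list(median = stats::median(ents),
       sem = stats::sd(ents) / sqrt(length(ents)),
       entropies = ents)
}

#' Reconstruction error as a function of retinal disparity
#'
#' For each disparity on the grid, averages the three-scale reconstruction
#' error over textured single-plane inputs viewed at that retinal disparity.
#'
#' @param system an `aec_system` (or list with `banks` and `config`).
#' @param disparities disparity grid in pixels.
#' @param n_samples textured inputs per disparity.
#' @param seed evaluation seed.
#' @return tibble with `disparity` and `e_avg`.
#' @export
reconstruction_error_curve <- function(system, disparities = seq(-20L, 20L, 4L),
                                       n_samples = 5L, seed = 1L) {
  cfg <- system$config
  cx <- as.integer(round(cfg$width / 2)); cy <- as.integer(round(cfg$height / 2))
  e <- vapply(disparities, function(d) {
    vals <- vapply(seq_len(n_samples), function(i) {
      scene <- flat_eval_scene(cfg, seed + 15485863L * i)
      frame <- render_stereo(scene)
      fix <- fixation_state(cx, cy, as.integer(d))
      windows <- extract_vergence_input(frame, fix, cfg$window)
      enc <- encode_windows(system$banks, windows, cfg$stride, update = FALSE)
      enc$e_avg
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  tibble::tibble(disparity = as.numeric(disparities), e_avg = e)
}

#' Fit the V-curve model to an error-vs-disparity curve
#'
#' Nonlinear least squares of `f(d) = c - a exp(-|d - mu| / b)`; the V's
#' sharpness is the slope `a / b` at the minimum. Initialization:
#' `mu` = argmin, `c` = max, `a` = c - min, `b` = 5.
#'
#' @param curve tibble/data.frame with columns `disparity` and `e_avg`
#'   (at least 6 points).
#' @return a `vcurve_fit` with fields `a`, `mu`, `b`, `c`, `slope`,
#'   `fitted`, `rss`, `data`.
#' @export
fit_vcurve <- function(curve) {
  stopifnot(nrow(curve) >= 6)
  d <- curve$disparity; e <- curve$e_avg
  start <- list(a = max(e) - min(e), mu = d[which.min(e)], b = 5,
                cc = max(e))
  fit <- tryCatch(
    minpack.lm::nlsLM(e ~ cc - a * exp(-abs(d - mu) / b),
                      start = start,
                      lower = c(a = 0, mu = min(d) - 1, b = 1e-6,
                                cc = -Inf),
                      upper = c(a = Inf, mu = max(d) + 1, b = Inf, cc = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) err)
  if (inherits(fit, "error")) {
    ## fall back to direct SSE minimization over a mu grid
    sse <- function(par, mu) {
      sum((e - (par[3] - par[1] * exp(-abs(d - mu) / max(par[2], 1e-6))))^2)
    }
    best <- NULL
    for (mu in d) {
      o <- stats::optim(c(start$a, start$b, start$cc), sse, mu = mu)
      if (is.null(best) || o$value < best$value) best <- c(o, list(mu = mu))
    }
    if (is.null(best)) {
      stop("V-curve fit failed to converge; residual range ",
           paste(signif(range(e), 4), collapse = " .. "))
    }
    pars <- c(a = max(best$par[1], 0), mu = best$mu, b = max(best$par[2], 1e-6),
              cc = best$par[3])
  } else {
    pars <- stats::coef(fit)
  }
  fitted <- pars[["cc"]] - pars[["a"]] * exp(-abs(d - pars[["mu"]]) / pars[["b"]])
  structure(list(a = pars[["a"]], mu = pars[["mu"]], b = pars[["b"]],
                 c = pars[["cc"]], slope = pars[["a"]] / pars[["b"]],
                 fitted = fitted, rss = sum((e - fitted)^2),
                 data = tibble::tibble(disparity = d, e_avg = e)),
            class = "vcurve_fit")
}

#' @export
print.vcurve_fit <- function(x, ...) {
  cat(sprintf("<vcurve_fit> f(d) = %.4g - %.4g exp(-|d - %.3g| / %.4g); slope a/b = %.4g\n",
              x$c, x$a, x$mu, x$b, x$slope))
  invisible(x)
}

#' Tidy a V-curve fit
#' @param x a `vcurve_fit`.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.vcurve_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "mu", "b", "c"),
                 estimate = c(x$a, x$mu, x$b, x$c))
}

#' One-row summary of a V-curve fit
#' @param x a `vcurve_fit`.
#' @param ... unused.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.vcurve_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, rss = x$rss, n = nrow(x$data))
}

#' Expected absolute disparity difference between successive fixations
#'
#' Exact expectation, per current fixation j, of `|D_i - D_j|` with the
#' next fixation i drawn from the (IOR-free) saccade-target distribution of
#' the chosen variant over the valid margin; averaged over `n_fixations`
#' current fixations drawn uniformly over the margin. The shift is held at
#' 0 so that only the LBAIM context depends on the current fixation.
#'
#' @param system an `aec_system`.
#' @param variant saccade variant, or `"random"` for the uniform baseline.
#' @param scene optional `stereo_scene` (default: one from the config).
#' @param n_fixations number of current fixation points.
#' @param features fixed feature subset (shared across variants for
#'   comparability); default 25 drawn from `seed`.
#' @param seed evaluation seed.
#' @return list with `delta_d` and the per-fixation values.
#' @export
expected_disparity_difference <- function(system, variant = system$config$variant,
                                          scene = NULL, n_fixations = 20L,
                                          features = NULL, seed = 1L) {
  cfg <- system$config
  if (is.null(scene)) scene <- scene_from_config(cfg, seed + 3L)
  frame <- render_stereo(scene)
  margin <- valid_margin(cfg$width, cfg$height, cfg$window)
  bank <- system$banks$coarse
  if (is.null(features) && variant != "random") {
    features <- with_seed(seed, sort(sample.int(bank$n, min(cfg$subset_size, bank$n))))
  }
  idx <- which(margin$mask)
  Dmap <- scene$disparity
  Dvals <- Dmap[idx]
  vals <- with_seed(seed + 1L, {
    fix_idx <- idx[sample.int(length(idx), n_fixations, replace = TRUE)]
    vapply(fix_idx, function(jj) {
      jy <- ((jj - 1L) %% nrow(Dmap)) + 1L
      jx <- ((jj - 1L) %/% nrow(Dmap)) + 1L
      if (variant == "random") {
        p <- rep(1 / length(idx), length(idx))
      } else {
        fs <- frame_saliency(bank, frame, 0L, variant = variant,
                             fixation = c(jx, jy), features = features)
        s <- fs$S[idx]
        p <- if (sum(s) > 0) s / sum(s) else rep(1 / length(idx), length(idx))
      }
      sum(abs(Dvals - Dmap[jy, jx]) * p)
    }, numeric(1))
  })
  list(delta_d = mean(vals), per_fixation = vals, variant = variant)
}

#' Normalized within-fixation decrease of the reconstruction error
#'
#' Per fixation, `(E_start - E_end) / E_start` from a per-frame error trace;
#' fixations with `E_start == 0` are excluded (and counted). A running mean
#' with a configurable window tracks the trend over training.
#'
#' @param frames per-frame log (tibble with `fixation`, `frame`, `e_avg`),
#'   e.g. `system$logs$frames`.
#' @param window running-average window in fixations (3000 at full scale).
#' @return tibble with `fixation`, `decrease`, `running`; the number of
#'   excluded fixations is attached as attribute `excluded`.
#' @export
fixation_error_decrease <- function(frames, window = 3000L) {
  sp <- split(frames$e_avg, frames$fixation)
  fix_ids <- as.numeric(names(sp))
  dec <- vapply(sp, function(e) {
    if (e[1] == 0) return(NA_real_)
    (e[1] - e[length(e)]) / e[1]
  }, numeric(1))
  keep <- !is.na(dec)
  d <- unname(dec[keep])
  w <- min(window, length(d))
  running <- stats::filter(d, rep(1 / w, w), sides = 1)
  out <- tibble::tibble(fixation = fix_ids[keep], decrease = d,
                        running = as.numeric(running))
  attr(out, "excluded") <- sum(!keep)
  out
}
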