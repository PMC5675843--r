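## The joint training loop: saccade -> 10-frame fixation with simultaneous
## GASSOM and actor-critic updates -> scene change every 30 fixations.

#' Simulation configuration
#'
#' Bundles the scene, encoder, vergence-learning and saccade parameters.
#' Two profiles are provided: `"desk"` (320x240 frames, 35-px fine window,
#' 64 subspaces — minutes-scale experiments) and `"full"` (640x480 frames,
#' 55-px windows, 324 subspaces, 100 patches per scale and a 972-d pooled
#' vector — the full-scale architecture).
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... overrides for any field (see Details in the vignette).
#' @return a `run_config` list.
#' @export
run_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(width = 320L, height = 240L, window = 35L, n_subspaces = 64L)
  } else {
    list(width = 640L, height = 480L, window = 55L, n_subspaces = 324L)
  }
  cfg <- c(base, list(
    profile = profile,
    stride = 5L,
    n_planes = 5L, disparity_range = c(-20L, 20L),
    texture = "onef", background_texture = "mixed",
    sigma_e = 0.2, omega = 0.5, lambda = 0.02, lambda_decay = TRUE,
    lambda_floor_frac = 0.3,
    gamma = 0.3, alpha_critic = 0.1, alpha_actor = 1.0, alpha_w = 0.3,
    beta = 1, standardize = TRUE,
    variant = "lbaim", subset_size = 25L,
    reward_scale = 200,
    fixation_frames = 10L, scene_period = 30L,
    n_fixations = 900L, n_checkpoints = 0L
  ))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

## Patches per scale for a config (grid of 10x10 patches at stride 5).
patches_per_scale <- function(config) {
  ((config$window - 10L) %/% config$stride + 1L)^2
}

#' Build an untrained system from a configuration
#'
#' Initializes the three per-scale subspace banks (shared init seed stream,
#' so different saccade variants start from identical representations) and
#' the vergence policy.
#'
#' @param config a [run_config()].
#' @param seed master seed.
#' @return an `aec_system`.
#' @export
init_aec_system <- function(config, seed = 1L) {
  bseed <- substream_seed(seed, "bank_init")
  banks <- list(
    coarse = init_gassom_bank(config$n_subspaces, seed = bseed,
                              sigma_e = config$sigma_e, omega = config$omega,
                              lambda = config$lambda),
    medium = init_gassom_bank(config$n_subspaces, seed = bseed + 1L,
                              sigma_e = config$sigma_e, omega = config$omega,
                              lambda = config$lambda),
    fine = init_gassom_bank(config$n_subspaces, seed = bseed + 2L,
                            sigma_e = config$sigma_e, omega = config$omega,
                            lambda = config$lambda)
  )
  policy <- init_vergence_policy(
    3L * config$n_subspaces, seed = substream_seed(seed, "policy_init"),
    gamma = config$gamma, alpha_critic = config$alpha_critic,
    alpha_actor = config$alpha_actor, alpha_w = config$alpha_w,
    beta = config$beta, standardize = config$standardize)
  structure(list(banks = banks, policy = policy, config = config,
                 seed = as.integer(seed), trained_fixations = 0L,
                 logs = NULL, checkpoints = list()),
            class = "aec_system")
}

scene_from_config <- function(config, seed) {
  generate_scene(scene_config(
    width = config$width, height = config$height, n_planes = config$n_planes,
    disparity_range = config$disparity_range, texture = config$texture,
    background_texture = config$background_texture), seed)
}

## Encode the three-scale vergence input; optionally update the banks.
encode_windows <- function(banks, windows, stride, update = FALSE,
                           lambda = NULL) {
  out <- list()
  for (s in c("coarse", "medium", "fine")) {
    pt <- patchify(windows[[s]]$left, windows[[s]]$right, stride)
    st <- gassom_step(banks[[s]], pt, update = update,
                      lambda = if (is.null(lambda)) banks[[s]]$lambda else lambda)
    banks[[s]] <- st$bank
    out[[s]] <- st
  }
  list(banks = banks, steps = out,
       e_avg = average_error(out$coarse$E, out$medium$E, out$fine$E),
       pooled = pooled_features(out$coarse$resp, out$medium$resp,
                                out$fine$resp))
}

## One saccade under the configured variant. Returns the new fixation point
## and updated history.
do_saccade <- function(system, frame, d, history, margin, last_point) {
  cfg <- system$config
  if (cfg$variant == "random") {
    pt <- random_saccade_policy(margin$mask)
    return(list(point = pt, history = push_fixation(history, pt),
                fallback = FALSE))
  }
  fixation <- if (is.null(last_point)) {
    c(round(cfg$width / 2), round(cfg$height / 2))
  } else last_point
  fs <- frame_saliency(system$banks$coarse, frame, d,
                       variant = cfg$variant, fixation = fixation,
                       subset_size = cfg$subset_size)
  ior <- ior_mask(history, cfg$width, cfg$height)
  td <- target_distribution(fs$S, ior, margin$mask)
  sf <- sample_fixation(td, history)
  list(point = sf$point, history = sf$history, fallback = td$fallback)
}

#' Train the integrated system
#'
#' Runs the joint loop: per fixation one saccade under the configured
#' variant, then 10 frames of vergence control with simultaneous subspace
#' updates at all three scales and actor-critic updates strictly within the
#' fixation (9 transitions). The scene is regenerated every
#' `scene_period` fixations from a scene-seed stream derived only from the
#' master seed, so different variants trained from the same master seed see
#' identical scene sequences. Bit-reproducible per (config, seed).
#'
#' @param config a [run_config()].
#' @param seed master seed.
#' @param system optionally, an existing `aec_system` to continue training.
#' @param learn_bank,learn_policy switches to freeze either learner.
#' @return the trained `aec_system` with per-frame and per-fixation logs
#'   (tibbles) and optional checkpoints.
#' @export
train <- function(config = run_config(), seed = 1L, system = NULL,
                  learn_bank = TRUE, learn_policy = TRUE) {
  if (is.null(system)) system <- init_aec_system(config, seed)
  cfg <- system$config
  margin <- valid_margin(cfg$width, cfg$height, cfg$window)
  n_fix <- cfg$n_fixations
  total_frames <- n_fix * cfg$fixation_frames
  ckpt_at <- if (cfg$n_checkpoints > 0) {
    unique(round(seq_len(cfg$n_checkpoints) * n_fix / cfg$n_checkpoints))
  } else integer(0)

  frame_log <- vector("list", total_frames)
  fix_log <- vector("list", n_fix)
  scene <- NULL; frame <- NULL; scene_idx <- 0L
  history <- fixation_history()
  d <- 0L; last_point <- NULL
  frame_count <- 0L

  set.seed(substream_seed(seed, "train",
                          match(cfg$variant,
                                c("random", "gbaim", "lbaim", "aim-mono"))))
  for (f in seq_len(n_fix)) {
    if ((f - 1L) %% cfg$scene_period == 0L) {
      scene_idx <- scene_idx + 1L
      scene <- scene_from_config(cfg, substream_seed(seed, "scenes", scene_idx))
      frame <- render_stereo(scene)
      history <- fixation_history()
      last_point <- NULL
      d <- 0L   # vergence posture re-centred when the scene is replaced
      for (s in names(system$banks)) {
        system$banks[[s]] <- reset_bank_context(system$banks[[s]])
      }
    }
    sac <- do_saccade(system, frame, d, history, margin, last_point)
    history <- sac$history
    last_point <- sac$point
    system$policy <- episode_boundary(system$policy)
    for (s in names(system$banks)) {
      system$banks[[s]] <- reset_bank_context(system$banks[[s]])
    }
    fx <- sac$point[1]; fy <- sac$point[2]
    prev_r <- NULL; prev_a <- NULL
    for (k in 0:(cfg$fixation_frames - 1L)) {
      frame_count <- frame_count + 1L
      ## representation rate anneals to a 10% floor over the first
      ## lambda_floor_frac of the run, so the features the policy learns on
      ## are quasi-stationary for the remainder
      lam <- if (cfg$lambda_decay) {
        p <- frame_count / (total_frames * cfg$lambda_floor_frac)
        cfg$lambda * max(0.1, 1 - 0.9 * p)
      } else cfg$lambda
      fix <- fixation_state(fx, fy, d, frame = min(k, 9L), fixation = f)
      windows <- extract_vergence_input(frame, fix, cfg$window)
      enc <- encode_windows(system$banks, windows, cfg$stride,
                            update = learn_bank, lambda = lam)
      system$banks <- enc$banks
      sf <- vergence_features(system$policy, enc$pooled)
      system$policy <- sf$policy
      r_std <- sf$r
      ## reward in units of the patch-vector energy (~200 for normalized
      ## 200-d patches) so actor/critic step sizes are scale-free
      reward <- vergence_reward(enc$e_avg) / cfg$reward_scale
      if (learn_policy && !is.null(prev_r)) {
        system$policy <- nac_step(system$policy, list(
          features = prev_r, action = prev_a,
          reward = reward, next_features = r_std))
      }
      pi_v <- policy_distribution(system$policy, r_std)
      a <- sample_action(pi_v)
      ret <- d - scene$disparity[fy, fx]   # retinal disparity before the action
      fix <- apply_vergence_action(fix, ACTIONS_VERG[a])
      frame_log[[frame_count]] <- c(
        fixation = f, frame = k, e_avg = enc$e_avg,
        retinal = ret, d = d, action = ACTIONS_VERG[a])
      d <- fix$d
      prev_r <- r_std; prev_a <- a
    }
    fix_log[[f]] <- c(fixation = f, scene = scene_idx,
                      x = fx, y = fy, d_final = d,
                      scene_disp = scene$disparity[fy, fx],
                      fallback = as.integer(sac$fallback))
    if (f %in% ckpt_at) {
      system$checkpoints[[length(system$checkpoints) + 1L]] <-
        list(fixation = f, banks = system$banks, policy = system$policy)
    }
  }
  fl <- tibble::as_tibble(as.data.frame(do.call(rbind, frame_log)))
  system$logs <- list(
    frames = fl,
    fixations = tibble::as_tibble(as.data.frame(do.call(rbind, fix_log))))
  system$trained_fixations <- system$trained_fixations + n_fix
  system
}

#' Train the perceptual representation under controlled disparity statistics
#'
#' Trains the three subspace banks (policy untouched) on textured
#' single-plane inputs whose retinal disparity is drawn i.i.d. from the
#' truncated Laplacian prior with spread `D` — the protocol that isolates
#' the effect of the input disparity statistics on the learned
#' representation. The texture changes every `texture_period` steps.
#'
#' @param config a [run_config()].
#' @param D Laplacian spread parameter (5 = tightly verged, 50 = broad).
#' @param n_steps number of window presentations.
#' @param seed master seed.
#' @param lambda learning rate (default: the config's).
#' @param texture_period steps between texture changes.
#' @return an `aec_system` with trained banks.
#' @export
train_disparity_bank <- function(config, D, n_steps = 1500L, seed = 1L,
                                 lambda = config$lambda,
                                 texture_period = 10L) {
  system <- init_aec_system(config, seed)
  margin <- valid_margin(config$width, config$height, config$window)
  set.seed(substream_seed(seed, "train", 7L + round(D)))
  frame <- NULL
  for (t in seq_len(n_steps)) {
    if ((t - 1L) %% texture_period == 0L) {
      scene <- flat_eval_scene(config, substream_seed(seed, "scenes", t))
      frame <- render_stereo(scene)
      for (s in names(system$banks)) {
        system$banks[[s]] <- reset_bank_context(system$banks[[s]])
      }
    }
    d <- max(-SHIFT_MAX, min(SHIFT_MAX, sample_laplacian_disparity(D)))
    fx <- sample(margin$x0:margin$x1, 1L)
    fy <- sample(margin$y0:margin$y1, 1L)
    fix <- fixation_state(fx, fy, d)
    windows <- extract_vergence_input(frame, fix, config$window)
    enc <- encode_windows(system$banks, windows, config$stride,
                          update = TRUE, lambda = lambda)
    system$banks <- enc$banks
  }
  system$trained_fixations <- n_steps
  system
}

#' Run a named evaluation protocol on a system
#'
#' Evaluation scenes are drawn from a seed stream disjoint from the
#' training scene stream.
#'
#' @param system an `aec_system`.
#' @param protocol one of `"rmse"`, `"entropy"`, `"vcurve"`, `"delta-d"`,
#'   `"error-decrease"`, `"cc-curve"`.
#' @param ... protocol-specific arguments passed through.
#' @param seed evaluation master seed.
#' @return an `evaluation_report` (list with `protocol`, `result`, `seed`).
#' @export
evaluate <- function(system, protocol, ..., seed = system$seed) {
  eseed <- substream_seed(seed, "eval")
  result <- switch(protocol,
    "rmse" = policy_rmse(system, seed = eseed, ...),
    "entropy" = median_fixation_entropy(system, seed = eseed, ...),
    "vcurve" = {
      curve <- reconstruction_error_curve(system, seed = eseed, ...)
      list(curve = curve, fit = fit_vcurve(curve))
    },
    "delta-d" = expected_disparity_difference(system, seed = eseed, ...),
    "error-decrease" = fixation_error_decrease(system$logs$frames, ...),
    "cc-curve" = {
      frames <- eval_saccade_frames(system, seed = eseed, ...)
      subset_cc_curve(system$banks$coarse, frames, seed = eseed)
    },
    stop("unknown protocol '", protocol, "'; options: rmse, entropy, ",
         "vcurve, delta-d, error-decrease, cc-curve"))
  structure(list(protocol = protocol, result = result, seed = eseed,
                 config = system$config),
            class = "evaluation_report")
}

## A few aligned coarse pairs from freshly seeded evaluation scenes.
eval_saccade_frames <- function(system, n_scenes = 3L, seed = 1L) {
  lapply(seq_len(n_scenes), function(i) {
    sc <- scene_from_config(system$config, seed + 7919L * i)
    extract_saccade_input(render_stereo(sc), 0L)
  })
}

#' Train and compare saccade-policy variants
#'
#' Trains each variant with `n_seeds` replicate master seeds; for a given
#' replicate all variants share the bank initialization and the scene
#' stream, differing only in how saccade targets are chosen. Reports the
#' vergence RMSE of the initial and final policies.
#'
#' @param config a [run_config()] (the `variant` field is overridden).
#' @param variants subset of `c("random", "gbaim", "lbaim", "aim-mono")`.
#' @param n_seeds replicate runs per variant (3 in the reference protocol).
#' @param base_seed first master seed; replicates use consecutive seeds.
#' @param rmse_args list of arguments for [policy_rmse()].
#' @return list with `table` (tibble: variant, seed, stage, rmse) and the
#'   trained `systems`.
#' @export
compare_policies <- function(config, variants = c("random", "lbaim"),
                             n_seeds = 3L, base_seed = 1L,
                             rmse_args = list()) {
  rows <- list(); systems <- list()
  for (sd in base_seed + seq_len(n_seeds) - 1L) {
    init_rmse <- NULL
    for (v in variants) {
      cfg <- config; cfg$variant <- v
      sys0 <- init_aec_system(cfg, sd)
      if (is.null(init_rmse)) {
        init_rmse <- do.call(policy_rmse,
                             c(list(sys0, seed = substream_seed(sd, "eval")),
                               rmse_args))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variant = "initial", seed = sd, stage = "initial",
          rmse = init_rmse$rmse)
      }
      sys <- train(cfg, sd, system = sys0)
      fin <- do.call(policy_rmse,
                     c(list(sys, seed = substream_seed(sd, "eval")),
                       rmse_args))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant = v, seed = sd, stage = "final", rmse = fin$rmse)
      systems[[paste(v, sd, sep = "_")]] <- sys
    }
  }
  list(table = do.call(rbind, rows), systems = systems)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$protocol, "(seed", x$seed, ")\n")
  print(x$result)
  invisible(x)
}
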