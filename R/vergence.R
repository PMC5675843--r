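## Vergence control: pooled features -> softmax policy over 11 pixel shifts,
## learned by a natural actor-critic with reward = -E_avg.

#' Pool per-scale response maps into the vergence feature vector
#'
#' Entry (s, n) is the mean response of feature extractor n over the P
#' patches of scale s; scales are concatenated coarse, medium, fine, giving
#' a 3N-dimensional vector (972 at full scale).
#'
#' @param resp_coarse,resp_medium,resp_fine `n` x P response matrices.
#' @return numeric vector of length 3n.
#' @export
pooled_features <- function(resp_coarse, resp_medium, resp_fine) {
  if (is.null(resp_coarse) || is.null(resp_medium) || is.null(resp_fine)) {
    stop("all three scales are required")
  }
  c(rowMeans(resp_coarse), rowMeans(resp_medium), rowMeans(resp_fine))
}

#' Initialize a vergence policy
#'
#' Linear-softmax actor over the pooled feature vector with 11 discrete
#' actions, plus a linear TD(0) critic and natural-gradient weight matrix.
#'
#' @param n_features pooled feature dimension (3N; 972 at full scale).
#' @param seed integer seed for the (zero by default) initialization.
#' @param gamma discount factor within a fixation.
#' @param alpha_critic,alpha_actor,alpha_w learning rates for the critic,
#'   the actor, and the natural-gradient running average.
#' @param beta softmax temperature (1 in all experiments).
#' @param standardize centre and scale features by running statistics
#'   before use (see [vergence_features()]).
#' @return a `vergence_policy`.
#' @export
init_vergence_policy <- function(n_features, seed = 1L, gamma = 0.3,
                                 alpha_critic = 0.1, alpha_actor = 1.0,
                                 alpha_w = 0.3, beta = 1,
                                 standardize = TRUE) {
  k <- length(ACTIONS_VERG)
  nf <- as.integer(n_features)
  structure(list(
    theta = matrix(0, nf, k),
    v = numeric(nf), b = 0,
    w = matrix(0, nf, k),
    n_features = as.integer(n_features), n_actions = k,
    actions = ACTIONS_VERG,
    gamma = gamma, alpha_critic = alpha_critic, alpha_actor = alpha_actor,
    alpha_w = alpha_w, beta = beta,
    standardize = standardize,
    feat_mu = NULL, feat_scale = NA_real_,
    td_state = list(last_delta = 0, steps_in_fixation = 0L),
    seed = as.integer(seed)
  ), class = "vergence_policy")
}

## Running feature standardization. Pooled subspace energies share a large
## common mean across stimuli; without centring, the actor's gradient is
## dominated by that common direction and the policy collapses toward a
## state-independent action preference (which, without centring, also
## saturates the softmax and kills exploration). We therefore subtract a
## running mean vector and divide by a running mean of the centred norm.
## The actor deliberately has no intercept pathway — constant action
## preferences carry no information for vergence — while the critic keeps
## its explicit bias term.
standardize_features <- function(policy, r, rho = 0.01) {
  if (!policy$standardize) return(list(policy = policy, r = r))
  if (is.null(policy$feat_mu)) {
    ## warm-up: the first observation defines the mean; its centred norm is
    ## exactly 0, so it must not seed the scale estimate
    policy$feat_mu <- r
    return(list(policy = policy, r = numeric(length(r))))
  }
  policy$feat_mu <- (1 - rho) * policy$feat_mu + rho * r
  centred <- r - policy$feat_mu
  m <- sqrt(sum(centred^2))
  if (is.na(policy$feat_scale)) {
    if (m > 1e-6) policy$feat_scale <- m else {
      return(list(policy = policy, r = numeric(length(r))))
    }
  } else {
    policy$feat_scale <- (1 - rho) * policy$feat_scale + rho * m
  }
  out <- centred / max(policy$feat_scale, 1e-8)
  ## cap transient spikes so a single outlier frame cannot destabilize the
  ## critic before the running scale catches up
  nrm <- sqrt(sum(out^2))
  if (nrm > 10) out <- out * (10 / nrm)
  list(policy = policy, r = out)
}

## The frozen version used during evaluation: applies the stored statistics
## without updating them.
apply_feature_transform <- function(policy, r) {
  if (!policy$standardize) return(r)
  if (is.null(policy$feat_mu) || is.na(policy$feat_scale)) {
    return(numeric(length(r)))
  }
  centred <- r - policy$feat_mu
  out <- centred / max(policy$feat_scale, 1e-8)
  nrm <- sqrt(sum(out^2))
  if (nrm > 10) out <- out * (10 / nrm)
  out
}

#' Action probabilities of the vergence policy
#'
#' Softmax (with max subtraction) of `theta' r / beta`.
#'
#' @param policy a `vergence_policy`.
#' @param r pooled feature vector (already standardized if the policy
#'   standardizes; see [vergence_features()]).
#' @return probability vector over the 11 actions.
#' @export
policy_distribution <- function(policy, r) {
  z <- drop(crossprod(policy$theta, r))
  if (any(!is.finite(z))) {
    stop("non-finite activation for action(s) ",
         paste(which(!is.finite(z)), collapse = ", "))
  }
  softmax(z / policy$beta)
}

#' Standardize pooled features with the policy's running statistics
#'
#' Centres the raw pooled vector by a running mean and scales by a running
#' mean of the centred norm (see the methods vignette for why centring
#' matters for the actor). With `standardize = FALSE` the raw vector passes
#' through unchanged.
#'
#' @param policy a `vergence_policy`.
#' @param r raw pooled feature vector.
#' @return list with the updated `policy` and the transformed `r`.
#' @export
vergence_features <- function(policy, r) standardize_features(policy, r)

#' Sample a vergence action index from a probability vector
#'
#' @param pi_verg probability vector over the action set.
#' @return integer action index in 1..11 (see `ACTIONS_VERG` for values).
#' @export
sample_action <- function(pi_verg) {
  stopifnot(length(pi_verg) == length(ACTIONS_VERG),
            all(pi_verg >= 0), abs(sum(pi_verg) - 1) < 1e-8)
  sample.int(length(pi_verg), 1L, prob = pi_verg)
}

#' Vergence reward
#'
#' The negative of the average squared reconstruction error across scales.
#'
#' @param e_avg average reconstruction error, >= 0.
#' @export
vergence_reward <- function(e_avg) {
  stopifnot(e_avg >= 0)
  -e_avg
}

#' One natural actor-critic update within a fixation
#'
#' TD(0) on a linear value function `V(r) = v'r + b`; compatible features
#' `psi(a, r) = (1_a - pi) (x) r`; the natural-gradient weights `w` are an
#' exponential running average of `delta * psi`, and the actor moves along
#' `w`. Updates are only legal within a fixation — the caller must mark
#' saccade boundaries with [episode_boundary()].
#'
#' @param policy a `vergence_policy`.
#' @param transition list with `features` (standardized pooled vector),
#'   `action` (index), `reward`, `next_features`.
#' @return the updated `vergence_policy`.
#' @export
nac_step <- function(policy, transition) {
  r <- transition$features; a <- transition$action
  rn <- transition$next_features
  v_s <- sum(policy$v * r) + policy$b
  v_sn <- sum(policy$v * rn) + policy$b
  delta <- transition$reward + policy$gamma * v_sn - v_s
  ## critic
  policy$v <- policy$v + policy$alpha_critic * delta * r
  policy$b <- policy$b + policy$alpha_critic * delta
  ## compatible features psi = r (x) (1_a - pi)
  p <- policy_distribution(policy, r)
  ind <- numeric(policy$n_actions); ind[a] <- 1
  psi <- outer(r, ind - p)
  ## natural-gradient running average and actor step
  policy$w <- (1 - policy$alpha_w) * policy$w + policy$alpha_w * delta * psi
  policy$theta <- policy$theta + policy$alpha_actor * policy$w
  policy$td_state$last_delta <- delta
  policy$td_state$steps_in_fixation <- policy$td_state$steps_in_fixation + 1L
  policy
}

#' Mark a saccade boundary
#'
#' Clears cross-step temporal-difference state; the learned weights are
#' untouched. No actor/critic update is ever applied across a saccade.
#'
#' @param policy a `vergence_policy`.
#' @export
episode_boundary <- function(policy) {
  policy$td_state <- list(last_delta = 0, steps_in_fixation = 0L)
  policy
}

#' Greedy (modal) action of the policy for a feature vector
#'
#' Ties break to the lowest action index.
#'
#' @param policy a `vergence_policy`.
#' @param r standardized pooled feature vector.
#' @return action value in pixels.
#' @export
greedy_action <- function(policy, r) {
  p <- policy_distribution(policy, r)
  policy$actions[which.max(p)]
}
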