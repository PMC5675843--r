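# Trained systems shared across test files (built once per test session).
# Sizes are the desk-scale study conditions described in the vignette.

# Banks trained under controlled disparity statistics (tight / broad prior).
disparity_bank <- function(D) {
  cached(paste0("bank_d", D), function() {
    train_disparity_bank(run_config("desk"), D = D, n_steps = 1500L,
                         seed = 2, lambda = 0.02)
  })
}

# Joint training of the integrated system: LBAIM-driven and random saccades,
# three replicate master seeds each, shared scene streams per seed.
joint_comparison <- function() {
  cached("joint_comparison", function() {
    compare_policies(run_config("desk", n_fixations = 2000L),
                     variants = c("random", "lbaim"), n_seeds = 3L,
                     base_seed = 1L, rmse_args = list(reps = 2L))
  })
}
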