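# Small scenario builders shared across test files. Desk-scale defaults keep
# single tests fast; tests that need the full 10,000-trio scale say so.

tiny_config <- function(...) {
  defaults <- list(n_trios = 500L, n_replicates = 2L, n_variants = 8L,
                   q_x = 0.02, seed = 101L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

mid_config <- function(...) {
  defaults <- list(n_trios = 4000L, n_replicates = 2L, n_variants = 15L,
                   q_x = 0.02, seed = 202L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

# mean point estimate of one strategy over R replicates
mean_estimate <- function(cfg, strategy, R) {
  est <- run_scenario(cfg, n_replicates = R, strategies = strategy)
  s <- summarize_replicates(est, cfg$gamma)
  s[s$method == strategy, ]
}

# hand-rolled iv_estimate for tests that need explicit CI bounds
manual_estimate <- function(beta, ci_low, ci_high, se = (ci_high - beta) / 1.96,
                            label = "unadjusted") {
  structure(list(method_label = label, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, n_used = 100L,
                 first_stage_F = NA_real_),
            class = "iv_estimate")
}

# synthetic variant summaries: beta_y = gamma * beta_x + alpha + noise
synthetic_summaries <- function(k, gamma, alpha = 0, se_y = 0.01,
                                se_x = 1e-4, noise = TRUE, seed = 1) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.25)
  by <- gamma * bx + alpha + if (noise) rnorm(k, 0, se_y) else 0
  orient_summaries(data.frame(variant = seq_len(k), beta_x = bx,
                              se_x = se_x, beta_y = by, se_y = se_y))
}
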