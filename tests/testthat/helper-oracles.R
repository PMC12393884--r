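# Brute-force joint-Gaussian log-likelihood of an endpoint sequence by
# explicit noise stacking: every state is written as a linear combination of
# the initial-reach draw and the per-trial (e, p, m) standard-normal draws,
# giving the exact covariance of s_{1:T} without any Kalman recursion.
stacked_gaussian_loglik <- function(variant, params, rewards, first_gate,
                                    endpoints, prior_sd = 20) {
  Tt <- length(rewards)
  r_lag <- c(first_gate, rewards[-Tt])
  always <- variant$has_planning && variant$planning_gate == "always"
  nz <- 1 + 3 * Tt
  xc <- numeric(nz)
  xc[1] <- prior_sd
  L <- matrix(0, Tt, nz)
  for (t in seq_len(Tt)) {
    ec <- numeric(nz); ec[1 + 3 * (t - 1) + 1] <- (1 - r_lag[t]) * params$sigma_e
    pc <- numeric(nz); pc[1 + 3 * (t - 1) + 2] <- params$sigma_p
    mc <- numeric(nz); mc[1 + 3 * (t - 1) + 3] <- params$sigma_m
    L[t, ] <- xc + ec + pc + mc
    rp <- if (always) 1 else rewards[t]
    xc <- xc + params$eta_e * rewards[t] * ec + params$eta_p * rp * pc
  }
  S <- L %*% t(L)
  -0.5 * (Tt * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            drop(endpoints %*% solve(S, endpoints)))
}

# random admissible variant with random in-bounds parameters
random_variant_instance <- function() {
  vs <- enumerate_variants()
  v <- vs[[sample(length(vs), 1)]]
  nm <- reachrl:::free_param_names(v)
  fr <- ifelse(startsWith(nm, "sigma"),
               stats::runif(length(nm), 0.1, 5),
               stats::runif(length(nm), 0, 2))
  list(variant = v, params = reachrl:::params_from_free(v, fr))
}

# minimal fit_result to drive simulate_ensemble without fitting
fake_fit_result <- function(variant, params, task = "CP",
                            init_mean = 0, init_var = 0,
                            trial_range = "learning_plus_clamps",
                            first_gate = 1L,
                            block_plan = default_block_plan()) {
  structure(list(variant = variant, params_hat = params,
                 loglik = NA_real_, n_trials = NA_integer_, bic = NA_real_,
                 init_posterior_mean = c(init_mean, 0, 0, 0),
                 init_posterior_cov = diag(c(init_var, 0, 0, 0)),
                 converged = TRUE, n_restarts_used = 0L,
                 trial_range = trial_range, task = task,
                 block_plan = block_plan, first_gate = first_gate,
                 participant_id = "fake", age = NA_real_),
            class = "fit_result")
}

# a session built directly from endpoint vectors (blocks sized to match)
session_from_endpoints <- function(baseline = rep(0, 20),
                                   learning = rep(-12, 100),
                                   success_clamp = rep(-12, 10),
                                   fail_clamp = rep(-12, 10),
                                   single_target = rep(0, 10),
                                   baseline_targets = rep(0, length(baseline)),
                                   rewards_learning = rep(1L, length(learning)),
                                   age = NA_real_, id = "manual") {
  blocks <- c(rep("baseline", length(baseline)),
              rep("learning", length(learning)),
              rep("success_clamp", length(success_clamp)),
              rep("fail_clamp", length(fail_clamp)),
              rep("single_target", length(single_target)))
  endpoint <- c(baseline, learning, success_clamp, fail_clamp, single_target)
  reward <- c(rep(1L, length(baseline)), rewards_learning,
              rep(1L, length(success_clamp)), rep(0L, length(fail_clamp)),
              rep(1L, length(single_target)))
  target <- c(baseline_targets, rep(NA_real_, length(learning)),
              rep(NA_real_, length(success_clamp) + length(fail_clamp)),
              rep(0, length(single_target)))
  new_session(data.frame(block = blocks, trial_index = seq_along(blocks),
                         endpoint = endpoint, reward = reward,
                         target_center = target),
              participant_id = id, age = age)
}
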