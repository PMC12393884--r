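#' Reward-driven state-space form of a model variant
#'
#' Any admissible variant is a time-varying linear-Gaussian state-space
#' system in the 4-state vector (desired reach, exploration, planning,
#' motor). The transition matrix carries the reinforced-update row
#' `[1, eta_e * r_{t-1}, eta_p * rp_{t-1}, 0]` (remaining rows zero: the
#' variability states are redrawn each trial), the noise loading puts
#' `(1 - r_{t-1}) * sigma_e`, `sigma_p`, `sigma_m` on the three variability
#' states, and the observation row is all ones — the endpoint is the exact
#' sum of the four states, so there is no separate observation noise. The
#' system depends only on the observed rewards and theta, never on the
#' endpoints. The initial state has mean zero with a wide prior (SD 20 GU)
#' on the desired reach and the gated variability SDs on the remaining
#' states; the gate for trial 1 is `first_gate` (the reward preceding the
#' fitted range, 1 when unknown).
#'
#' @param variant A `model_variant`.
#' @param params A `model_params` consistent with `variant`.
#' @param rewards Integer 0/1 vector, the observed rewards of the fitted
#'   trials (length T >= 1).
#' @param first_gate 0/1 reward preceding trial 1.
#' @param prior_sd Prior SD on the initial desired reach (GU), default 20.
#' @return An object of class `state_space_system` holding the compact
#'   time-varying quantities; `system_matrices()` materializes the full
#'   `A_t`, `B_t` for one trial.
#' @export
build_system <- function(variant, params, rewards, first_gate = 1L,
                         prior_sd = 20) {
  check_params(variant, params)
  rewards <- as.integer(rewards)
  stopifnot(length(rewards) >= 1, all(rewards %in% c(0L, 1L)),
            first_gate %in% c(0L, 1L))
  Tt <- length(rewards)
  r_lag <- c(as.integer(first_gate), rewards[-Tt])  # r_{t-1} for t = 1..T
  rp_lag <- if (variant$has_planning && variant$planning_gate == "always")
    rep(1L, Tt) else r_lag
  structure(list(
    variant = variant, params = params, rewards = rewards,
    first_gate = as.integer(first_gate), n_trials = Tt,
    r_lag = r_lag, rp_lag = rp_lag,
    # per-trial first-row transition entries (used for the step t-1 -> t);
    # absent sources have their rows/columns zeroed outright
    a_e = if (variant$has_exploration) params$eta_e * r_lag else rep(0, Tt),
    a_p = if (variant$has_planning) params$eta_p * rp_lag else rep(0, Tt),
    # per-trial noise loadings
    b_e = (1 - r_lag) * params$sigma_e,
    b_p = rep(params$sigma_p, Tt), b_m = rep(params$sigma_m, Tt),
    prior_sd = prior_sd
  ), class = "state_space_system")
}

#' Materialize the state-space matrices for one trial
#'
#' Returns the 4x4 transition matrix `A` (mapping the state at trial
#' `t - 1` to trial `t`), the 4x3 noise loading `B` for trial `t`, and the
#' 1x4 observation row `C`.
#'
#' @param system A [build_system()] object.
#' @param t Trial index in 1..T (for `t = 1`, `A` uses the `first_gate`).
#' @return A list with `A`, `B`, `C`.
#' @export
system_matrices <- function(system, t) {
  stopifnot(t >= 1, t <= system$n_trials)
  A <- matrix(0, 4, 4)
  A[1, ] <- c(1, system$a_e[t], system$a_p[t], 0)
  B <- matrix(0, 4, 3)
  B[2, 1] <- system$b_e[t]
  B[3, 2] <- system$b_p[t]
  B[4, 3] <- system$b_m[t]
  list(A = A, B = B, C = matrix(1, 1, 4))
}

# initial (t = 1) prior moments
system_prior <- function(system) {
  list(mean = rep(0, 4),
       cov = diag(c(system$prior_sd^2, system$b_e[1]^2,
                    system$b_p[1]^2, system$b_m[1]^2)))
}

# Kalman filter. The predicted covariance is diagonal by construction
# (only the desired-reach state survives a transition), which keeps the
# recursion in scalar arithmetic. Returns filtered moments and the
# innovation decomposition of the log-likelihood.
kalman_filter <- function(system, endpoints) {
  Tt <- system$n_trials
  stopifnot(length(endpoints) == Tt, all(is.finite(endpoints)))
  mf <- matrix(0, Tt, 4)          # filtered means
  Pf <- vector("list", Tt)        # filtered covariances (4x4)
  mp_x <- numeric(Tt)             # predicted mean (x component; others 0)
  vp <- matrix(0, Tt, 4)          # predicted covariance diagonals
  pr <- system_prior(system)
  m_pred <- pr$mean
  P_diag <- diag(pr$cov)
  ll <- 0
  for (t in seq_len(Tt)) {
    mp_x[t] <- m_pred[1]
    vp[t, ] <- P_diag
    S <- sum(P_diag)
    if (S <= 0) stop("zero innovation variance at trial ", t)
    innov <- endpoints[t] - sum(m_pred)
    ll <- ll + stats::dnorm(innov, 0, sqrt(S), log = TRUE)
    K <- P_diag / S
    m_filt <- m_pred + K * innov
    P_filt <- diag(P_diag) - outer(K, P_diag)
    mf[t, ] <- m_filt
    Pf[[t]] <- P_filt
    if (t < Tt) {
      a <- c(1, system$a_e[t + 1], system$a_p[t + 1], 0)
      m_pred <- c(sum(a * m_filt), 0, 0, 0)
      P_diag <- c(drop(a %*% P_filt %*% a),
                  system$b_e[t + 1]^2, system$b_p[t + 1]^2,
                  system$b_m[t + 1]^2)
    }
  }
  list(loglik = ll, mean_filt = mf, cov_filt = Pf,
       mean_pred_x = mp_x, cov_pred_diag = vp)
}

#' Exact log-likelihood of endpoints under a state-space system
#'
#' Gaussian log-likelihood by innovation decomposition of the Kalman
#' filter; exact for the unclipped linear-Gaussian model (clipping exists
#' only in simulation).
#'
#' @param system A [build_system()] object.
#' @param endpoints Numeric endpoint sequence, same length as the system's
#'   rewards.
#' @return Log-likelihood in nats.
#' @export
kalman_loglik <- function(system, endpoints) {
  kalman_filter(system, endpoints)$loglik
}

#' Fixed-interval smoother and endpoint decomposition
#'
#' Rauch-Tung-Striebel smoothing of the state-space system. Because only
#' the desired-reach state survives a transition, the smoother gain has a
#' single nonzero column and the recursion is exact without any
#' pseudo-inverse. The smoothed per-trial states decompose each observed
#' endpoint into desired-reach, exploration, planning and motor components
#' (they sum to the endpoint exactly, the observation being noiseless), and
#' the smoothed trial-1 state is the initial-state posterior used to seed
#' Monte-Carlo ensembles.
#'
#' @inheritParams kalman_loglik
#' @return A list: `mean_smooth` (T x 4), `cov_smooth` (list of 4x4),
#'   `init_posterior_mean` (4-vector), `init_posterior_cov` (4x4),
#'   `loglik`.
#' @export
smoother_posterior <- function(system, endpoints) {
  kf <- kalman_filter(system, endpoints)
  Tt <- system$n_trials
  ms <- kf$mean_filt
  Ps <- kf$cov_filt
  if (Tt > 1) {
    for (t in (Tt - 1):1) {
      a <- c(1, system$a_e[t + 1], system$a_p[t + 1], 0)
      v_pred <- kf$cov_pred_diag[t + 1, 1]    # predicted var of x_{t+1}
      if (v_pred > 0) {
        j <- drop(Ps[[t]] %*% a) / v_pred     # single nonzero smoother column
        dx <- ms[t + 1, 1] - kf$mean_pred_x[t + 1]
        dP <- Ps[[t + 1]][1, 1] - v_pred
        ms[t, ] <- kf$mean_filt[t, ] + j * dx
        Ps[[t]] <- kf$cov_filt[[t]] + outer(j, j) * dP
      }
    }
  }
  colnames(ms) <- c("x", "e", "p", "m")
  list(mean_smooth = ms, cov_smooth = Ps,
       init_posterior_mean = ms[1, ], init_posterior_cov = Ps[[1]],
       loglik = kf$loglik)
}

#' Default optimizer configuration
#'
#' Bounded simplex search settings: number of jittered restarts, relative
#' tolerance, iteration cap, SD upper bound (GU) and the seed driving the
#' restart jitter.
#'
#' @param n_restarts,reltol,maxit,sigma_max,seed See description.
#' @return A list.
#' @export
optimizer_config <- function(n_restarts = 5, reltol = 1e-6, maxit = 1000,
                             sigma_max = 20, seed = 1L) {
  list(n_restarts = n_restarts, reltol = reltol, maxit = maxit,
       sigma_max = sigma_max, seed = seed)
}

#' Maximum-likelihood fit of one variant to one session
#'
#' Maximizes the Kalman log-likelihood over the variant's free parameters
#' within bounds (SDs in `[1e-3, 20]` GU, learning rates in `[0, 2]`) by
#' bounded derivative-free simplex search with jittered restarts. Rewards
#' driving the time-varying system are the observed rewards (clamp rewards
#' included when in range); the gate for the first fitted trial is the last
#' observed reward before the range (1 if there is none). Model selection
#' conventionally uses `"learning_only"` (the 100 learning trials); final
#' parameter estimates use `"learning_plus_clamps"` (120 trials).
#'
#' @param session An `rl_session`.
#' @param variant A `model_variant`.
#' @param trial_range `"learning_only"` or `"learning_plus_clamps"`.
#' @param config An [optimizer_config()].
#' @return An object of class `fit_result`: `variant`, `params_hat`,
#'   `loglik`, `n_trials`, `bic`, `init_posterior_mean`,
#'   `init_posterior_cov`, `converged`, `n_restarts_used`, `trial_range`,
#'   plus bookkeeping (`task`, `block_plan`, `first_gate`,
#'   `participant_id`, `age`) used by [simulate_ensemble()].
#' @export
fit_variant <- function(session, variant,
                        trial_range = c("learning_plus_clamps", "learning_only"),
                        config = optimizer_config()) {
  trial_range <- match.arg(trial_range)
  rows <- trial_range_rows(session, trial_range)
  if (!length(rows)) stop("no trials in range ", trial_range)
  endpoints <- session$trials$endpoint[rows]
  rewards <- as.integer(session$trials$reward[rows])
  first_gate <- pre_range_gate(session, rows)
  b <- param_bounds(variant, sigma_max = config$sigma_max)
  k <- length(b$names)
  negfree <- function(free) {
    sys <- build_system(variant, params_from_free(variant, free), rewards,
                        first_gate)
    kalman_loglik(sys, endpoints)
  }
  if (k == 0L) {
    opt <- list(par = numeric(0), value = negfree(numeric(0)),
                converged = TRUE, n_restarts_used = 0L)
  } else {
    s_all <- stats::sd(endpoints)
    n_sig <- sum(startsWith(b$names, "sigma"))
    start <- ifelse(startsWith(b$names, "sigma"),
                    max(min(s_all / sqrt(max(n_sig, 1)), 19), 0.05), 1)
    start <- pmin(pmax(start, b$lower), b$upper)
    opt <- bounded_maximize(negfree, b$lower, b$upper, start,
                            n_restarts = config$n_restarts,
                            reltol = config$reltol, maxit = config$maxit,
                            seed = config$seed)
  }
  params_hat <- params_from_free(variant, opt$par)
  sys <- build_system(variant, params_hat, rewards, first_gate)
  sm <- smoother_posterior(sys, endpoints)
  n <- length(endpoints)
  structure(list(
    variant = variant, params_hat = params_hat,
    loglik = opt$value, n_trials = n,
    bic = bic(opt$value, n_free_params(variant), n),
    init_posterior_mean = sm$init_posterior_mean,
    init_posterior_cov = sm$init_posterior_cov,
    converged = opt$converged,
    n_restarts_used = opt$n_restarts_used,
    trial_range = trial_range,
    task = session$task,
    block_plan = {
      tb <- table(factor(session$trials$block, levels = BLOCKS))
      stats::setNames(as.integer(tb), names(tb))
    },
    first_gate = first_gate,
    participant_id = session$participant_id,
    age = session$age
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s on %s trials of %s (loglik %.3f, BIC %.3f)\n",
              variant_signature(x$variant), x$n_trials, x$participant_id,
              x$loglik, x$bic))
  ph <- x$params_hat
  cat(sprintf("  sigma_m=%.3f sigma_e=%.3f sigma_p=%.3f eta_e=%.3f eta_p=%.3f\n",
              ph$sigma_m, ph$sigma_e, ph$sigma_p, ph$eta_e, ph$eta_p))
  invisible(x)
}

#' Parameter-recovery study
#'
#' Simulates one session per true parameter set under `variant`, refits it
#' with the packaged optimizer, and reports the Pearson correlation between
#' true and fitted values for each free parameter — the standard
#' simulate-then-refit validation of the fitting pipeline.
#'
#' @param true_params_list List of `model_params` (>= 10 sets spanning a
#'   nondegenerate range).
#' @param variant A `model_variant`.
#' @param task Task code or landscape.
#' @param trial_range Fitted range; sessions always include the standard
#'   five blocks.
#' @param seed Master seed; per-set seeds are derived.
#' @param config Optimizer configuration.
#' @return A list: `correlations` (named per free parameter), `table`
#'   (true/fitted pairs, one row per set).
#' @export
recover_parameters <- function(true_params_list, variant, task = "CP",
                               trial_range = "learning_plus_clamps",
                               seed = 1L, config = optimizer_config()) {
  stopifnot(length(true_params_list) >= 2)
  nm <- free_param_names(variant)
  rows <- lapply(seq_along(true_params_list), function(i) {
    p <- true_params_list[[i]]
    check_params(variant, p)
    s <- simulate_session(variant, p, task, seed = derive_seed(seed, i),
                          participant_id = sprintf("rec%03d", i))
    cfg <- config
    cfg$seed <- derive_seed(seed, 10000 + i)
    fit <- fit_variant(s, variant, trial_range, cfg)
    tv <- unlist(p[nm]); fv <- unlist(fit$params_hat[nm])
    stats::setNames(c(tv, fv), c(paste0("true_", nm), paste0("fit_", nm)))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  cors <- vapply(nm, function(n) {
    tv <- tab[[paste0("true_", n)]]
    if (stats::sd(tv) == 0) stop("degenerate (constant) true values for ", n)
    stats::cor(tv, tab[[paste0("fit_", n)]])
  }, numeric(1))
  list(correlations = cors, table = tab)
}
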