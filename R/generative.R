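#' Simulate a single learning trial
#'
#' One step of the generative model: draw exploration, planning and motor
#' variability (exploration gated by the previous trial's failure), produce
#' the endpoint, sample reward from the landscape, and update the desired
#' reach by the reinforced variability. For discrete landscapes the endpoint
#' is snapped to the nearest target center before the reward draw, but the
#' latent update uses the unsnapped draw — discreteness enters only at the
#' observation/reward level. Desired and actual reach are clipped to the
#' workspace.
#'
#' The RNG consumption per trial is fixed (three normals, then one uniform
#' unless `force_reward` is given), so identical seeds give identical
#' sessions.
#'
#' @param state List with `x` (desired reach, GU) and `r_prev` (previous
#'   reward 0/1).
#' @param params A `model_params` consistent with `variant`.
#' @param variant A `model_variant`.
#' @param landscape A `reward_landscape`.
#' @param clip Clip desired and actual reach to the workspace (default TRUE).
#' @param force_reward `NULL` for landscape-sampled reward, or 0/1 to clamp
#'   the feedback regardless of the endpoint.
#' @return A list: `endpoint` (GU, observed), `reward` (0/1), and `state`
#'   (next trial's latent state: `x`, `e`, `p`, `m`, `r_prev`).
#' @export
simulate_trial <- function(state, params, variant, landscape,
                           clip = TRUE, force_reward = NULL) {
  check_params(variant, params)
  ws <- landscape$workspace
  e_raw <- stats::rnorm(1, 0, params$sigma_e)
  p_draw <- stats::rnorm(1, 0, params$sigma_p)
  m_draw <- stats::rnorm(1, 0, params$sigma_m)
  e_gated <- (1 - state$r_prev) * e_raw
  s <- state$x + e_gated + p_draw + m_draw
  if (clip) s <- min(max(s, ws[1]), ws[2])
  s_obs <- if (landscape$target_mode == "discrete") snap_to_target(landscape, s) else s
  reward <- if (is.null(force_reward)) sample_reward(landscape, s_obs)
            else as.integer(force_reward)
  rp <- if (variant$has_planning && variant$planning_gate == "always") 1L else reward
  x_next <- state$x + params$eta_e * reward * e_gated + params$eta_p * rp * p_draw
  if (clip) x_next <- min(max(x_next, ws[1]), ws[2])
  list(endpoint = s_obs, reward = reward,
       state = list(x = x_next, e = e_gated, p = p_draw, m = m_draw,
                    r_prev = reward))
}

#' Default five-block trial plan
#'
#' 20 baseline, 100 learning, 10 success-clamp, 10 fail-clamp and 10
#' single-target trials.
#'
#' @return Named integer vector.
#' @export
default_block_plan <- function() {
  c(baseline = 20L, learning = 100L, success_clamp = 10L,
    fail_clamp = 10L, single_target = 10L)
}

# Vectorized multi-run session engine. All runs share the block structure;
# per-trial draw order per run is e, p, m, then a reward uniform only on
# landscape-sampled trials, so the n_runs = 1 stream matches a scalar
# simulate_trial() loop.
#
# initial_x: length-n vector of initial desired reaches (used from the start;
# baseline trials are target-anchored and do not move the latent x).
# Returns matrices [T x n] of endpoints/rewards plus per-trial block labels.
run_engine <- function(variant, params, landscape, block_plan, initial_x,
                       initial_r_prev = 1L, clip = TRUE,
                       baseline_schedule = default_baseline_schedule(),
                       single_target_center = 0,
                       baseline_half_width = 2.5,
                       keep_latents = FALSE) {
  check_params(variant, params)
  stopifnot(all(block_plan >= 0))
  ws <- landscape$workspace
  n <- length(initial_x)
  Tt <- sum(block_plan)
  blocks <- rep(names(block_plan), block_plan)
  S <- matrix(NA_real_, Tt, n)
  R <- matrix(NA_integer_, Tt, n)
  TC <- rep(NA_real_, Tt)
  X <- if (keep_latents) matrix(NA_real_, Tt, n) else NULL
  E <- if (keep_latents) matrix(NA_real_, Tt, n) else NULL
  x <- pmin(pmax(as.numeric(initial_x), ws[1]), ws[2])
  r_prev <- rep(as.integer(initial_r_prev), length.out = n)
  n_clip <- 0L
  i_base <- 0L
  discrete <- landscape$target_mode == "discrete"
  rp_always <- variant$has_planning && variant$planning_gate == "always"
  for (t in seq_len(Tt)) {
    bl <- blocks[t]
    e_raw <- stats::rnorm(n, 0, params$sigma_e)
    p_draw <- stats::rnorm(n, 0, params$sigma_p)
    m_draw <- stats::rnorm(n, 0, params$sigma_m)
    if (bl %in% c("baseline", "single_target")) {
      centre <- if (bl == "baseline") {
        i_base <- i_base + 1L
        baseline_schedule[(i_base - 1L) %% length(baseline_schedule) + 1L]
      } else single_target_center
      s <- centre + m_draw
      if (clip) {
        n_clip <- n_clip + sum(s < ws[1] | s > ws[2])
        s <- pmin(pmax(s, ws[1]), ws[2])
      }
      reward <- as.integer(abs(s - centre) <= baseline_half_width)
      TC[t] <- centre
      # target-anchored trials leave the latent desired reach untouched
      S[t, ] <- s
      R[t, ] <- reward
      if (keep_latents) { X[t, ] <- x; E[t, ] <- 0 }
      r_prev <- reward
      next
    }
    e_gated <- (1 - r_prev) * e_raw
    s <- x + e_gated + p_draw + m_draw
    if (clip) {
      n_clip <- n_clip + sum(s < ws[1] | s > ws[2])
      s <- pmin(pmax(s, ws[1]), ws[2])
    }
    s_obs <- if (discrete) snap_to_target(landscape, s) else s
    reward <- switch(bl,
      success_clamp = rep(1L, n),
      fail_clamp = rep(0L, n),
      sample_reward(landscape, s_obs))
    rp <- if (rp_always) 1L else reward
    x <- x + params$eta_e * reward * e_gated + params$eta_p * rp * p_draw
    if (clip) x <- pmin(pmax(x, ws[1]), ws[2])
    S[t, ] <- s_obs
    R[t, ] <- reward
    if (keep_latents) { X[t, ] <- x; E[t, ] <- e_gated }
    r_prev <- reward
  }
  list(endpoints = S, rewards = R, block = blocks, target_center = TC,
       clip_fraction = n_clip / (Tt * n), x_latent = X, e_latent = E)
}

#' Simulate a full session
#'
#' Forward-simulates the five-block session under any admissible variant.
#' Baseline and single-target blocks anchor the reach to the displayed
#' target (motor noise only; reward = target hit); the learning block runs
#' the generative dynamics against the task landscape; the success and fail
#' clamps force reward 1 and 0 respectively while the latent dynamics
#' continue across block boundaries. The learning-phase gate for its first
#' trial is the last baseline reward (or `initial_r_prev` if the baseline
#' block is absent).
#'
#' @param variant A `model_variant`.
#' @param params A `model_params` consistent with `variant`.
#' @param task Task code, or a `reward_landscape`.
#' @param block_plan Named trial counts, default [default_block_plan()].
#' @param initial_x Initial desired reach (GU). `NA` (default) draws it
#'   uniformly over the workspace at the start of the session.
#' @param initial_r_prev Gate for the first simulated trial (default 1: no
#'   exploration before any feedback).
#' @param seed Integer seed; the session is a deterministic function of it.
#' @param clip Clip desired and actual reach to the workspace.
#' @param baseline_schedule Baseline target centers, recycled over the
#'   baseline block.
#' @param participant_id,age Session metadata.
#' @return An `rl_session` with `true_params` and `seed` recorded.
#' @examples
#' s <- simulate_session(preferred_variant(),
#'                       make_params(sigma_m = 2, sigma_e = 3), "CP", seed = 1)
#' session_metrics(s)
#' @export
simulate_session <- function(variant, params, task,
                             block_plan = default_block_plan(),
                             initial_x = NA, initial_r_prev = 1L,
                             seed = 1L, clip = TRUE,
                             baseline_schedule = default_baseline_schedule(),
                             participant_id = "sim", age = NA_real_) {
  landscape <- if (inherits(task, "reward_landscape")) task else make_landscape(task)
  with_seed(seed, {
    if (is.na(initial_x))
      initial_x <- stats::runif(1, landscape$workspace[1], landscape$workspace[2])
    eng <- run_engine(variant, params, landscape, block_plan, initial_x,
                      initial_r_prev, clip, baseline_schedule)
  })
  trials <- data.frame(
    block = eng$block,
    trial_index = seq_along(eng$block),
    endpoint = eng$endpoints[, 1],
    reward = eng$rewards[, 1],
    target_center = ifelse(is.na(eng$target_center) & landscape$target_mode == "discrete",
                           eng$endpoints[, 1], eng$target_center)
  )
  new_session(trials,
              participant_id = participant_id, age = age,
              task = if (inherits(task, "reward_landscape")) landscape$task else task,
              true_params = params, seed = as.integer(seed),
              workspace = landscape$workspace)
}

#' Monte-Carlo ensemble from a fitted model
#'
#' Re-simulates the fitted trial range many times, initializing the desired
#' reach of each run by sampling the Kalman smoother's initial-state
#' posterior (its desired-reach marginal), and summarizes the ensemble:
#' per-trial median and SD across runs, the pooled within-run SD of clamp
#' trials 2–10 (square root of the mean within-run variance, which is
#' unbiased for the generating SD), and the fraction of clipped endpoints.
#'
#' @param fit A [fit_variant()] result.
#' @param n_runs Number of Monte-Carlo runs (>= 2), default 4000.
#' @param seed Integer seed.
#' @param clip Clip reaches to the workspace (default TRUE; disable to
#'   compare against unclipped closed forms).
#' @return An object of class `simulation_ensemble`: `n_runs`, `median`
#'   and `sd` per-trial series, `block` labels, `success_clamp_sd`,
#'   `fail_clamp_sd`, `clip_fraction`.
#' @export
simulate_ensemble <- function(fit, n_runs = 4000, seed = 1L, clip = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  if (n_runs < 2) stop("n_runs must be >= 2")
  landscape <- make_landscape(fit$task)
  plan <- fit$block_plan
  plan <- plan[names(plan) %in%
                 (if (fit$trial_range == "learning_only") "learning"
                  else c("learning", "success_clamp", "fail_clamp"))]
  mu <- fit$init_posterior_mean[1]
  sdev <- sqrt(max(fit$init_posterior_cov[1, 1], 0))
  with_seed(seed, {
    x0 <- stats::rnorm(n_runs, mu, sdev)
    eng <- run_engine(fit$variant, fit$params_hat, landscape, plan, x0,
                      initial_r_prev = fit$first_gate, clip = clip)
  })
  clamp_pooled_sd <- function(block_name) {
    idx <- which(eng$block == block_name)
    if (length(idx) < 3) return(NA_real_)
    idx <- idx[-1]  # trials 2..k of the clamp
    sqrt(mean(apply(eng$endpoints[idx, , drop = FALSE], 2, stats::var)))
  }
  structure(list(
    n_runs = n_runs,
    block = eng$block,
    median = apply(eng$endpoints, 1, stats::median),
    sd = apply(eng$endpoints, 1, stats::sd),
    success_clamp_sd = clamp_pooled_sd("success_clamp"),
    fail_clamp_sd = clamp_pooled_sd("fail_clamp"),
    clip_fraction = eng$clip_fraction
  ), class = "simulation_ensemble")
}
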