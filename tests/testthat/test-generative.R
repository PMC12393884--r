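test_that("degenerate noise freezes the trial dynamics", {
  cp <- make_landscape("CP")
  v <- full_variant()
  p0 <- make_params()  # all SDs zero
  st <- list(x = -12, r_prev = 0L)
  set.seed(1)
  out <- simulate_trial(st, p0, v, cp)
  expect_equal(out$endpoint, -12)
  expect_equal(out$state$x, -12)
  set.seed(2)
  out2 <- simulate_trial(list(x = 3, r_prev = 1L), p0, v, cp)
  expect_equal(out2$endpoint, 3)
  expect_equal(out2$state$x, 3)
})

test_that("exploration is gated by previous failure and incorporated on success", {
  cp <- make_landscape("CP")
  v <- preferred_variant()
  # after success: endpoint = x + m only, even with huge sigma_e
  p <- make_params(sigma_m = 0, sigma_e = 50)
  set.seed(5)
  out <- simulate_trial(list(x = -12, r_prev = 1L), p, v, cp)
  expect_equal(out$endpoint, -12)
  # after failure with a forced success: full incorporation (eta_e = 1)
  set.seed(6)
  out <- simulate_trial(list(x = 0, r_prev = 0L), make_params(sigma_m = 0, sigma_e = 3),
                        v, cp, force_reward = 1)
  expect_equal(out$state$x, out$endpoint)  # x' = x + e = endpoint when m = 0
  expect_false(out$state$x == 0)
})

test_that("sessions respect block structure, clamps and clipping", {
  v <- preferred_variant()
  p <- make_params(sigma_m = 3, sigma_e = 8)
  s <- simulate_session(v, p, "CP", seed = 42)
  tr <- s$trials
  expect_equal(nrow(tr), 150)
  expect_true(all(tr$reward[tr$block == "success_clamp"] == 1))
  expect_true(all(tr$reward[tr$block == "fail_clamp"] == 0))
  expect_true(all(tr$endpoint >= -24 & tr$endpoint <= 24))
  # byte-identical reproduction under the same seed
  expect_identical(simulate_session(v, p, "CP", seed = 42), s)
  expect_false(identical(simulate_session(v, p, "CP", seed = 43)$trials, tr))
})

test_that("with no exploration the preferred model's desired reach is constant", {
  v <- preferred_variant()
  s <- simulate_session(v, make_params(sigma_m = 0, sigma_e = 0), "CP",
                        initial_x = 5, seed = 9)
  learn <- s$trials[s$trials$block %in%
                      c("learning", "success_clamp", "fail_clamp"), ]
  expect_true(all(learn$endpoint == 5))
})

test_that("every nonzero exploration draw follows a failure", {
  v <- preferred_variant()
  p <- make_params(sigma_m = 2, sigma_e = 4)
  eng <- reachrl:::with_seed(13, reachrl:::run_engine(
    v, p, make_landscape("CP"), default_block_plan(), initial_x = 0,
    keep_latents = TRUE))
  keep <- which(eng$block %in% c("learning", "success_clamp", "fail_clamp"))
  r_prev <- eng$rewards[keep - 1, 1]          # block before learning exists
  e <- eng$e_latent[keep, 1]
  expect_true(all(e[r_prev == 1] == 0))
  expect_true(any(e[r_prev == 0] != 0))
  # desired reach moves only on success preceded by failure
  x <- eng$x_latent[keep, 1]
  moved <- which(diff(x) != 0) + 1  # change between t-1 and t is due to trial t
  r_now <- eng$rewards[keep, 1]
  expect_true(all(r_now[moved] == 1 & r_prev[moved] == 0))
})

test_that("the single-run engine reproduces a simulate_trial loop", {
  v <- full_variant()
  p <- make_params(sigma_m = 1.5, sigma_e = 2, sigma_p = 1, eta_e = 0.7,
                   eta_p = 0.4)
  cp <- make_landscape("CP")
  eng <- reachrl:::with_seed(77, reachrl:::run_engine(
    v, p, cp, c(learning = 50L), initial_x = 4, initial_r_prev = 1L))
  set.seed(77)
  st <- list(x = 4, r_prev = 1L)
  ep <- numeric(50); rw <- integer(50)
  for (t in 1:50) {
    out <- simulate_trial(st, p, v, cp)
    ep[t] <- out$endpoint; rw[t] <- out$reward; st <- out$state
  }
  expect_identical(eng$endpoints[, 1], ep)
  expect_identical(eng$rewards[, 1], rw)
})

test_that("clamp-phase endpoint SDs reach their closed-form limits", {
  # preferred model, no clipping: success clamp SD -> sigma_m (x frozen after
  # success, no exploration); fail clamp SD -> sqrt(sigma_e^2 + sigma_m^2)
  p <- make_params(sigma_m = 2, sigma_e = 3)
  fit <- fake_fit_result(preferred_variant(), p, init_mean = 0, init_var = 0)
  en <- simulate_ensemble(fit, n_runs = 1e4, seed = 3, clip = FALSE)
  expect_equal(en$success_clamp_sd, 2, tolerance = 0.02)
  expect_equal(en$fail_clamp_sd, sqrt(2^2 + 3^2), tolerance = 0.02)
  expect_equal(en$clip_fraction, 0)
})

test_that("ensembles honor run counts and degenerate posteriors", {
  p <- make_params(sigma_m = 1, sigma_e = 2)
  fit <- fake_fit_result(preferred_variant(), p)
  en <- simulate_ensemble(fit, n_runs = 50, seed = 1)
  expect_equal(en$n_runs, 50)
  expect_length(en$median, 120)        # learning + both clamps
  expect_length(en$sd, 120)
  expect_true(all(en$sd >= 0))
  # zero posterior covariance + zero SDs: all runs identical
  fit0 <- fake_fit_result(preferred_variant(), make_params(), init_mean = -5)
  en0 <- simulate_ensemble(fit0, n_runs = 20, seed = 2)
  expect_true(all(en0$sd == 0))
  expect_true(all(en0$median == -5))
  expect_error(simulate_ensemble(fit, n_runs = 1), "n_runs")
})

test_that("discrete-task endpoints land on target centers", {
  v <- preferred_variant()
  s <- simulate_session(v, make_params(sigma_m = 2, sigma_e = 4), "DP", seed = 8)
  learn <- s$trials[s$trials$block == "learning", ]
  expect_true(all(learn$endpoint %in% c(-18, -12, -6, 0, 6, 12, 18)))
})
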