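test_that("single-trial likelihood matches the conjugate closed form", {
  v <- motor_only_variant()
  sys <- build_system(v, make_params(sigma_m = 1), rewards = 0L)
  # s_1 ~ N(0, 20^2 + 1^2)
  expect_equal(kalman_loglik(sys, 0), -0.5 * log(2 * pi * 401),
               tolerance = 1e-12)
  sm <- smoother_posterior(sys, 10)
  expect_equal(unname(sm$init_posterior_mean[1]), 10 * 400 / 401,
               tolerance = 1e-12)
})

test_that("system matrices realize the reward-gated structure", {
  p <- make_params(sigma_m = 1, sigma_e = 2)
  v <- preferred_variant()
  sys <- build_system(v, p, rewards = c(1L, 0L, 1L), first_gate = 1L)
  m2 <- system_matrices(sys, 2)   # r_1 = 1: no exploration loading
  expect_equal(m2$A[1, ], c(1, 1, 0, 0))  # eta_e = 1 times r_1 = 1
  expect_equal(m2$B[2, 1], 0)
  m3 <- system_matrices(sys, 3)   # r_2 = 0: exploration active
  expect_equal(m3$B[2, 1], 2)
  expect_equal(m3$A[1, 2], 0)
  expect_equal(m3$C, matrix(1, 1, 4))
  # full model, always-gated planning
  vf <- find_variant(TRUE, TRUE, TRUE, "both_free", "always")
  pf <- make_params(1, 1, 1, eta_e = 0.5, eta_p = 0.25)
  sysf <- build_system(vf, pf, rewards = c(1L, 1L), first_gate = 1L)
  expect_equal(system_matrices(sysf, 2)$A[1, ], c(1, 0.5, 0.25, 0))
  # motor-only: only the motor loading is ever nonzero
  sysm <- build_system(motor_only_variant(), make_params(sigma_m = 3),
                       rewards = c(0L, 1L))
  for (t in 1:2) {
    B <- system_matrices(sysm, t)$B
    expect_equal(B[c(2, 3), ], matrix(0, 2, 3))
    expect_equal(B[4, 3], 3)
  }
})

test_that("doubling all scales shifts the log-likelihood by -T log 2", {
  set.seed(4)
  v <- preferred_variant()
  rw <- rbinom(30, 1, 0.5)
  ep <- rnorm(30, 0, 4)
  p1 <- make_params(sigma_m = 1.5, sigma_e = 2.5)
  p2 <- make_params(sigma_m = 3, sigma_e = 5)
  ll1 <- kalman_loglik(build_system(v, p1, rw, 1L, prior_sd = 20), ep)
  ll2 <- kalman_loglik(build_system(v, p2, rw, 1L, prior_sd = 40), 2 * ep)
  expect_equal(ll2, ll1 - 30 * log(2), tolerance = 1e-9)
})

test_that("smoothed components reconstruct the observation exactly", {
  set.seed(10)
  v <- full_variant()
  p <- make_params(2, 3, 1, eta_e = 0.8, eta_p = 0.3)
  rw <- rbinom(40, 1, 0.4)
  ep <- rnorm(40, 0, 5)
  sm <- smoother_posterior(build_system(v, p, rw, 0L), ep)
  expect_equal(unname(rowSums(sm$mean_smooth)), ep, tolerance = 1e-8)
  # posterior covariance is symmetric PSD
  P1 <- sm$init_posterior_cov
  expect_equal(P1, t(P1), tolerance = 1e-10)
  expect_true(all(eigen(P1, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  # zero exploration loading everywhere => smoothed e-component identically 0
  sm2 <- smoother_posterior(build_system(v, p, rep(1L, 40), 1L), ep)
  expect_equal(unname(sm2$mean_smooth[, "e"]), rep(0, 40))
})

test_that("likelihood ignores rewards that never enter the gating", {
  set.seed(2)
  v <- preferred_variant()
  p <- make_params(sigma_m = 2, sigma_e = 3)
  rw <- rbinom(25, 1, 0.5)
  ep <- rnorm(25, 0, 4)
  rw_flip <- rw; rw_flip[25] <- 1L - rw_flip[25]  # final reward gates nothing
  expect_equal(kalman_loglik(build_system(v, p, rw, 1L), ep),
               kalman_loglik(build_system(v, p, rw_flip, 1L), ep))
})

test_that("maximum likelihood recovers the motor-noise scale", {
  v <- motor_only_variant()
  p <- make_params(sigma_m = 2)
  fits <- vapply(1:50, function(i) {
    # center start keeps the session clear of the workspace edge, so the
    # unclipped likelihood sees untruncated data
    s <- simulate_session(v, p, "CP", initial_x = 0, seed = derive_seed(321, i))
    fit_variant(s, v)$params_hat$sigma_m
  }, numeric(1))
  # single sessions within 20%, pooled mean within 3%
  expect_true(all(abs(fits - 2) / 2 < 0.2))
  expect_equal(mean(fits), 2, tolerance = 0.03)
})

test_that("a zero-exploration truth drives sigma_e to the boundary", {
  s <- simulate_session(preferred_variant(), make_params(sigma_m = 2, sigma_e = 0),
                        "CP", seed = 99)
  f <- fit_variant(s, preferred_variant())
  expect_lt(f$params_hat$sigma_e, 0.3)
})

test_that("fits are seed-deterministic and respect model nesting", {
  s <- simulate_session(preferred_variant(), make_params(sigma_m = 2, sigma_e = 3),
                        "CP", seed = 12)
  f1 <- fit_variant(s, preferred_variant(), config = optimizer_config(seed = 5))
  f2 <- fit_variant(s, preferred_variant(), config = optimizer_config(seed = 5))
  expect_identical(f1$params_hat, f2$params_hat)
  expect_identical(f1$loglik, f2$loglik)
  # BIC recomputable from fields
  expect_equal(f1$bic, n_free_params(f1$variant) * log(f1$n_trials) - 2 * f1$loglik)
  # nesting: richer model can only do better (up to optimizer tolerance)
  fm <- fit_variant(s, motor_only_variant())
  expect_gte(f1$loglik, fm$loglik - 1e-3)
  ff <- fit_variant(s, full_variant())
  expect_gte(ff$loglik, f1$loglik - 1e-3)
})

test_that("recovery bookkeeping: shuffled pairing destroys the correlation", {
  set.seed(31)
  tp <- lapply(1:12, function(i)
    make_params(sigma_m = runif(1, 1, 4), sigma_e = runif(1, 1, 6)))
  rec <- recover_parameters(tp, preferred_variant(), "CP", seed = 44)
  expect_named(rec$correlations, c("sigma_m", "sigma_e"))
  expect_true(all(rec$correlations > 0.5))
  shuf <- cor(rec$table$true_sigma_e, sample(rec$table$fit_sigma_e))
  expect_lt(abs(shuf), abs(cor(rec$table$true_sigma_e, rec$table$fit_sigma_e)))
  expect_error(recover_parameters(lapply(1:10, function(i)
    make_params(sigma_m = 2, sigma_e = 3)), preferred_variant(), seed = 1),
    "degenerate")
})
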