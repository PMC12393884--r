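test_that("value posterior behaves like a local kernel learner", {
  prm <- make_value_params(sigma_l = 3, sigma_s = 2, b = 1)
  grid <- value_grid(n = 201)
  expect_equal(value_posterior(data.frame(endpoint = numeric(0),
                                          reward = integer(0)), prm, grid),
               rep(0, 201))
  # a single rewarded reach: value peaks there and decays with distance
  v <- value_posterior(data.frame(endpoint = 0, reward = 1), prm, grid)
  expect_equal(grid[which.max(v)], 0, tolerance = 0.2)
  right <- v[grid >= 0]
  expect_true(all(diff(right) <= 1e-10))
  left <- v[grid <= 0]
  expect_true(all(diff(left) >= -1e-10))
  # a failed reach drives value down locally
  vf <- value_posterior(data.frame(endpoint = 5, reward = 0), prm, grid)
  expect_lt(min(vf), 0)
  expect_equal(grid[which.min(vf)], 5, tolerance = 0.2)
  # degenerate prior strength learns nothing
  expect_equal(value_posterior(data.frame(endpoint = 0, reward = 1),
                               make_value_params(3, 0, 1), grid), rep(0, 201))
})

test_that("softmax policy normalizes and hits its limits", {
  set.seed(6)
  v <- rnorm(500)
  p <- softmax_policy(v, 2.5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(softmax_policy(v, 0), rep(1 / 500, 500))
  expect_equal(softmax_policy(rep(3.3, 500), 7), rep(1 / 500, 500))
  p_hot <- softmax_policy(v, 500)
  expect_gt(p_hot[which.max(v)], 0.999)
})

test_that("a temperature-free policy has the exact uniform likelihood", {
  s <- simulate_session(preferred_variant(), make_params(sigma_m = 2, sigma_e = 3),
                        "CP", block_plan = c(baseline = 2L, learning = 20L,
                                             success_clamp = 3L, fail_clamp = 3L,
                                             single_target = 2L), seed = 4)
  rows <- which(s$trials$block %in% c("learning", "success_clamp", "fail_clamp"))
  grid <- value_grid()
  ll <- reachrl:::value_model_loglik(s$trials$endpoint[rows],
                                     s$trials$reward[rows],
                                     make_value_params(5, 1, 0), grid)
  expect_equal(ll, length(rows) * log(1 / 500), tolerance = 1e-10)
})

test_that("more restarts never worsen the best likelihood", {
  s <- simulate_session(preferred_variant(), make_params(sigma_m = 2, sigma_e = 4),
                        "CP", block_plan = c(baseline = 0L, learning = 15L,
                                             success_clamp = 0L, fail_clamp = 0L,
                                             single_target = 0L), seed = 5)
  f1 <- fit_value_model(s, "learning_only", n_restarts = 1, seed = 9,
                        grid = value_grid(n = 200))
  f3 <- fit_value_model(s, "learning_only", n_restarts = 3, seed = 9,
                        grid = value_grid(n = 200))
  expect_gte(f3$loglik, f1$loglik - 1e-9)
  expect_equal(f3$bic, 3 * log(15) - 2 * f3$loglik)
})

test_that("distinct parameter triples can be near-indistinguishable", {
  # a non-learning record: nothing pins down the kernel, mirroring the
  # weak identifiability of the value model
  set.seed(12)
  ep <- runif(20, -20, 20)
  rw <- rep(0L, 20)
  grid <- value_grid(n = 200)
  ll1 <- reachrl:::value_model_loglik(ep, rw, make_value_params(1, 1e-3, 5), grid)
  ll2 <- reachrl:::value_model_loglik(ep, rw, make_value_params(20, 1e-3, 1), grid)
  expect_equal(ll1, ll2, tolerance = 1e-3)
})

test_that("the noise-based model outranks the value model on its own data", {
  plan <- c(baseline = 5L, learning = 40L, success_clamp = 5L,
            fail_clamp = 5L, single_target = 0L)
  grid <- value_grid(n = 250)
  bic_noise <- 0; bic_value <- 0
  for (i in 1:3) {
    s <- simulate_session(preferred_variant(),
                          make_params(sigma_m = 2, sigma_e = 3.5), "CP",
                          block_plan = plan, seed = derive_seed(72, i),
                          participant_id = sprintf("vm%d", i))
    bic_noise <- bic_noise + fit_variant(s, preferred_variant())$bic
    bic_value <- bic_value + fit_value_model(s, n_restarts = 4,
                                             seed = derive_seed(73, i),
                                             grid = grid, maxit = 150)$bic
  }
  expect_lt(bic_noise, bic_value)
})
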