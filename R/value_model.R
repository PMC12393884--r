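#' Parameters of the kernel value-learning model
#'
#' The alternative learner represents the value of every endpoint location
#' and chooses where to reach through a softmax policy. The latent value
#' function carries a squared-exponential kernel prior with length scale
#' `sigma_l` (GU; how far learning generalizes) and strength `sigma_s`
#' (how much is learned, akin to a learning rate); binary rewards enter
#' through a logistic likelihood; `b` is the softmax inverse temperature.
#'
#' @param sigma_l Kernel length scale, GU (> 0).
#' @param sigma_s Kernel strength (>= 0).
#' @param b Softmax inverse temperature (>= 0).
#' @return An object of class `value_model_params`.
#' @export
make_value_params <- function(sigma_l = 5, sigma_s = 1, b = 1) {
  stopifnot(sigma_l > 0, sigma_s >= 0, b >= 0)
  structure(list(sigma_l = sigma_l, sigma_s = sigma_s, b = b),
            class = "value_model_params")
}

#' Default value grid
#'
#' The workspace discretized into 500 equally spaced locations.
#'
#' @param workspace Length-2 numeric (GU).
#' @param n Number of grid points, default 500.
#' @return Numeric vector.
#' @export
value_grid <- function(workspace = c(-24, 24), n = 500) {
  seq(workspace[1], workspace[2], length.out = n)
}

se_kernel <- function(x1, x2, sigma_l, sigma_s) {
  sigma_s^2 * exp(-outer(x1, x2, function(a, b) (a - b)^2) / (2 * sigma_l^2))
}

#' Posterior mode of the value function
#'
#' Laplace (Newton) mode finding for the latent value function under the
#' squared-exponential prior and Bernoulli-logistic observations at the
#' visited locations, evaluated over the grid. An empty history returns the
#' prior mean (zero everywhere).
#'
#' @param history A data.frame with columns `endpoint`, `reward` (may have
#'   zero rows).
#' @param params A [make_value_params()].
#' @param grid Evaluation locations, default [value_grid()].
#' @param tol,max_iter Newton convergence controls.
#' @return Numeric value estimate per grid point.
#' @export
value_posterior <- function(history, params, grid = value_grid(),
                            tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(params, "value_model_params"), all(is.finite(grid)))
  history <- as.data.frame(history)
  if (!nrow(history)) return(numeric(length(grid)))
  stopifnot(all(is.finite(history$endpoint)), all(history$reward %in% 0:1))
  if (params$sigma_s == 0) return(numeric(length(grid)))
  xo <- history$endpoint
  y <- as.numeric(history$reward)
  n <- length(xo)
  K <- se_kernel(xo, xo, params$sigma_l, params$sigma_s) + diag(1e-8, n)
  f <- numeric(n)
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(f)
    W <- pmax(p * (1 - p), 1e-12)
    sW <- sqrt(W)
    B <- diag(n) + sW * t(sW * K)       # I + sqrtW K sqrtW
    L <- chol(B)
    bb <- W * f + (y - p)
    v <- backsolve(L, forwardsolve(t(L), sW * (K %*% bb)))
    a <- bb - sW * v
    f <- drop(K %*% a)
    obj <- -0.5 * sum(a * f) + sum(stats::dbinom(y, 1, stats::plogis(f), log = TRUE))
    if (is.finite(obj) && abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  if (it == max_iter && abs(obj - obj_old) >= sqrt(tol))
    stop("value-posterior mode finding did not converge")
  # predictive mode at grid locations: k*' grad log p(y | f_hat)
  p_hat <- stats::plogis(f)
  Ks <- se_kernel(grid, xo, params$sigma_l, params$sigma_s)
  drop(Ks %*% (y - p_hat))
}

#' Softmax policy over the value grid
#'
#' `P(x) proportional to exp(b * v(x))`, normalized over the grid with
#' log-sum-exp stabilization; `b = 0` or a constant value function gives
#' the uniform policy.
#'
#' @param v Value estimate per grid point (finite).
#' @param b Inverse temperature (>= 0).
#' @return Probability per grid point (sums to 1).
#' @export
softmax_policy <- function(v, b) {
  stopifnot(all(is.finite(v)), b >= 0)
  z <- b * v
  z <- z - max(z)
  w <- exp(z)
  w / sum(w)
}

# sequential policy log-likelihood of grid-snapped endpoints
value_model_loglik <- function(endpoints, rewards, params, grid) {
  idx <- vapply(endpoints, function(s) which.min(abs(grid - s)), integer(1))
  snapped <- grid[idx]
  ll <- 0
  for (t in seq_along(endpoints)) {
    v <- if (t == 1) numeric(length(grid))
         else value_posterior(data.frame(endpoint = snapped[seq_len(t - 1)],
                                         reward = rewards[seq_len(t - 1)]),
                              params, grid)
    pol <- softmax_policy(v, params$b)
    ll <- ll + log(max(pol[idx[t]], 1e-300))
  }
  ll
}

#' Fit the value-based model to a session
#'
#' Maximizes, over `(sigma_l, sigma_s, b)`, the product across trials of
#' the softmax policy probability of the chosen (grid-snapped) endpoint,
#' the value state being refit from the preceding history before every
#' trial. The likelihood surface is multimodal, so the optimizer restarts
#' from random initializations drawn in the parameter box (50 by default)
#' and keeps the best. BIC uses k = 3.
#'
#' @param session An `rl_session`.
#' @param trial_range `"learning_plus_clamps"` or `"learning_only"`.
#' @param n_restarts Random initializations, default 50.
#' @param grid Value grid, default [value_grid()] on the session workspace.
#' @param seed Seed for the restart draws.
#' @param reltol,maxit Simplex controls.
#' @param bounds List with `lower`/`upper` for `(sigma_l, sigma_s, b)`.
#' @return A list: `params` (`value_model_params`), `loglik`, `bic`,
#'   `n_trials`, `n_restarts_used`.
#' @export
fit_value_model <- function(session,
                            trial_range = c("learning_plus_clamps", "learning_only"),
                            n_restarts = 50,
                            grid = value_grid(session$workspace),
                            seed = 1L, reltol = 1e-6, maxit = 300,
                            bounds = list(lower = c(0.1, 1e-3, 0),
                                          upper = c(48, 10, 50))) {
  trial_range <- match.arg(trial_range)
  rows <- trial_range_rows(session, trial_range)
  if (!length(rows)) stop("no trials in range")
  endpoints <- session$trials$endpoint[rows]
  rewards <- as.integer(session$trials$reward[rows])
  fn <- function(theta)
    value_model_loglik(endpoints, rewards,
                       make_value_params(theta[1], theta[2], theta[3]), grid)
  lo <- bounds$lower; up <- bounds$upper
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i)
      lo + stats::runif(3) * (up - lo))
  })
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      bounded_maximize(fn, lo, up, st, n_restarts = 1,
                       reltol = reltol, maxit = maxit),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value > best$value)) best <- res
  }
  if (is.null(best)) stop("all restarts failed")
  n <- length(endpoints)
  list(params = make_value_params(best$par[1], best$par[2], best$par[3]),
       loglik = best$value,
       bic = bic(best$value, 3, n),
       n_trials = n,
       n_restarts_used = as.integer(n_restarts))
}
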