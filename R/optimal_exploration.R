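#' Expected learning distance for one (motor noise, exploration) setting
#'
#' Mean absolute distance of the endpoint from the always-rewarded zone
#' center over the 100 learning trials, averaged over Monte-Carlo runs of
#' the preferred model (failure-gated exploration + motor noise), with the
#' initial desired reach drawn per `init_spec` for every run. This is the
#' quantity whose (sigma_m, sigma_e) landscape exposes the optimal amount
#' of exploration for a given level of motor noise.
#'
#' @param sigma_m,sigma_e Motor-noise and exploration SDs (GU, >= 0).
#' @param task Task code or `reward_landscape`.
#' @param init_spec Either `"uniform"` (initial desired reach uniform over
#'   the workspace, standing in for per-participant initial-state
#'   posteriors) or a numeric vector of initial reaches sampled uniformly
#'   with replacement.
#' @param n_sims Monte-Carlo runs (>= 1), default 2000.
#' @param n_trials Learning trials per run, default 100.
#' @param seed Integer seed.
#' @param zone_center GU, default -12.
#' @return Expected distance (GU).
#' @export
expected_distance <- function(sigma_m, sigma_e, task = "CP",
                              init_spec = "uniform", n_sims = 2000,
                              n_trials = 100, seed = 1L,
                              zone_center = -12) {
  stopifnot(sigma_m >= 0, sigma_e >= 0, n_sims >= 1)
  landscape <- if (inherits(task, "reward_landscape")) task else make_landscape(task)
  variant <- preferred_variant()
  params <- make_params(sigma_m = sigma_m, sigma_e = sigma_e)
  ws <- landscape$workspace
  with_seed(seed, {
    x0 <- if (identical(init_spec, "uniform"))
      stats::runif(n_sims, ws[1], ws[2])
    else sample(as.numeric(init_spec), n_sims, replace = TRUE)
    eng <- run_engine(variant, params, landscape,
                      c(learning = as.integer(n_trials)), x0,
                      initial_r_prev = 1L, clip = TRUE)
  })
  mean(abs(eng$endpoints - zone_center))
}

#' Grid of expected learning distance over (sigma_m, sigma_e)
#'
#' Fills a matrix of [expected_distance()] values cell by cell; each cell
#' uses its own derived seed, so results are independent of evaluation
#' order and reproducible. The conventional resolution is 50 x 50; coarse
#' grids (e.g. 8 x 8) give desk-scale versions of the same analysis.
#'
#' @param task Task code or landscape.
#' @param sigma_m_grid,sigma_e_grid Numeric axes (GU); defaults bracket the
#'   fitted developmental ranges: 50 values over `[0.25, 6]` and `[0, 8]`.
#' @param n_sims Simulations per cell.
#' @param seed Master seed (per-cell seeds derived).
#' @param ... Passed to [expected_distance()].
#' @return An object of class `distance_grid`: `sigma_m`, `sigma_e`,
#'   `expected_distance` (matrix, rows = sigma_m, cols = sigma_e),
#'   `n_sims`, `task`.
#' @export
distance_grid <- function(task = "CP",
                          sigma_m_grid = seq(0.25, 6, length.out = 50),
                          sigma_e_grid = seq(0, 8, length.out = 50),
                          n_sims = 4000, seed = 1L, ...) {
  stopifnot(length(sigma_m_grid) >= 1, length(sigma_e_grid) >= 1)
  M <- matrix(NA_real_, length(sigma_m_grid), length(sigma_e_grid))
  for (i in seq_along(sigma_m_grid))
    for (j in seq_along(sigma_e_grid))
      M[i, j] <- expected_distance(sigma_m_grid[i], sigma_e_grid[j],
                                   task = task, n_sims = n_sims,
                                   seed = derive_seed(seed, (i - 1) * 1000 + j),
                                   ...)
  structure(list(sigma_m = sigma_m_grid, sigma_e = sigma_e_grid,
                 expected_distance = M, n_sims = n_sims,
                 task = if (inherits(task, "reward_landscape")) task$task else task),
            class = "distance_grid")
}

#' Optimal exploration variability per motor-noise level
#'
#' For each row (motor-noise level) of a [distance_grid()], the exploration
#' SD minimizing expected distance; ties break to the smaller sigma_e.
#' Optionally applies isotonic (non-increasing) smoothing across
#' motor-noise levels, which removes Monte-Carlo jitter before checking the
#' monotone relation between motor noise and optimal exploration.
#'
#' @param grid A `distance_grid`.
#' @param smooth Apply non-increasing isotonic regression to the argmin
#'   sequence (default FALSE).
#' @return A data.frame: `sigma_m`, `optimal_sigma_e` (and
#'   `optimal_sigma_e_smoothed` when `smooth = TRUE`).
#' @export
optimal_sigma_e <- function(grid, smooth = FALSE) {
  stopifnot(inherits(grid, "distance_grid"))
  if (anyNA(grid$expected_distance)) stop("grid not fully filled")
  arg <- apply(grid$expected_distance, 1, function(row)
    grid$sigma_e[which(row == min(row))[1]])  # first minimum = smaller sigma_e
  out <- data.frame(sigma_m = grid$sigma_m, optimal_sigma_e = arg)
  if (smooth) {
    # non-increasing fit: isoreg() fits non-decreasing, so flip the x-axis
    n <- length(arg)
    iso <- stats::isoreg(seq_len(n), rev(arg))
    out$optimal_sigma_e_smoothed <- rev(iso$yf)
  }
  out
}
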