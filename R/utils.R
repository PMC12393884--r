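# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed
#'
#' Splitmix-style integer mixing of a master seed and a stream index, kept
#' below 2^31 so results are portable across platforms. Used to give each
#' synthetic participant, optimizer restart and grid cell its own
#' deterministic stream.
#'
#' @param master_seed Integer master seed.
#' @param index Integer stream index (>= 0).
#' @return A positive integer seed < 2^31.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime; doubles stay exact below 2^53)
  x <- (as.numeric(master_seed) %% m + 1) * 48271 %% m
  x <- (x + as.numeric(index) * 69621) %% m
  x <- (x * 16807) %% m
  as.integer(if (x == 0) 1 else x)
}

# Bounded derivative-free maximization: logistic-transformed Nelder-Mead
# (fminsearchbnd-style) with jittered multi-starts; 1-D problems use
# optimize() on the box directly. fn is maximized.
bounded_maximize <- function(fn, lower, upper, start,
                             n_restarts = 5, reltol = 1e-6,
                             maxit = 1000, seed = 1L) {
  k <- length(lower)
  stopifnot(length(upper) == k, length(start) == k,
            all(start >= lower), all(start <= upper))
  safe_fn <- function(theta) {
    v <- tryCatch(fn(theta), error = function(e) -Inf)
    if (!is.finite(v)) -1e10 else v
  }
  if (k == 1L) {
    best <- stats::optimize(function(x) safe_fn(x), lower = lower,
                            upper = upper, maximum = TRUE,
                            tol = max(reltol, 1e-8))
    return(list(par = best$maximum, value = best$objective,
                converged = TRUE, n_restarts_used = 1L))
  }
  to_u <- function(theta) {
    z <- (theta - lower) / (upper - lower)
    z <- pmin(pmax(z, 1e-6), 1 - 1e-6)
    log(z / (1 - z))
  }
  to_theta <- function(u) lower + (upper - lower) / (1 + exp(-u))
  obj <- function(u) -safe_fn(to_theta(u))
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1) start
      else pmin(pmax(start * exp(stats::rnorm(k, 0, 0.5)) +
                       stats::rnorm(k, 0, 0.05 * (upper - lower)),
                     lower), upper)
    })
  })
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    res <- stats::optim(to_u(st), obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || res$value < best$value) {
      best <- res
      conv <- res$convergence == 0
    }
  }
  list(par = to_theta(best$par), value = -best$value,
       converged = conv, n_restarts_used = as.integer(n_restarts))
}
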