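#' Reward landscapes for the reaching task
#'
#' A reward landscape maps a movement endpoint (the x-coordinate, in game
#' units, where the reach crosses the far edge of the workspace) to a
#' probability of binary reward. Four stock regimes are provided, crossing
#' target type (continuous span vs. seven discrete targets) with feedback
#' type (probabilistic gradient vs. deterministic 0/1). In all four the
#' always-rewarded ("100%") zone is centered at x = -12 GU.
#'
#' Continuous landscapes are defined by anchor points `(x, p)` with linear
#' interpolation between anchors and constant extrapolation outside their
#' range. Discrete landscapes are defined by disjoint targets
#' `(center, half_width, p)`; an endpoint inside a target span earns that
#' target's probability, and 0 between targets.
#'
#' @param task One of `"CP"` (continuous probabilistic), `"DP"` (discrete
#'   probabilistic), `"CD"` (continuous deterministic), `"DD"` (discrete
#'   deterministic).
#' @param workspace Numeric length-2, the reachable x-interval in GU.
#' @return An object of class `reward_landscape`.
#' @examples
#' ls <- make_landscape("CP")
#' reward_probability(ls, -12)   # 1 at the zone center
#' reward_probability(ls, -30)   # 0.33, constant outside the anchors
#' @export
make_landscape <- function(task = c("CP", "DP", "CD", "DD"),
                           workspace = c(-24, 24)) {
  task <- match.arg(task)
  stopifnot(length(workspace) == 2, workspace[1] < workspace[2])
  half_width <- 2.5
  centers <- c(-18, -12, -6, 0, 6, 12, 18)
  obj <- switch(task,
    CP = list(
      target_mode = "continuous", reward_mode = "probabilistic",
      anchors = data.frame(x = c(-24, -14.5, -9.5, 1.1875),
                           p = c(0.33, 1.0, 1.0, 0.25))
    ),
    DP = list(
      target_mode = "discrete", reward_mode = "probabilistic",
      targets = data.frame(center = centers, half_width = half_width,
                           p = c(0.66, 1.0, 0.66, 0.33, 0.25, 0.25, 0.25))
    ),
    CD = list(
      target_mode = "continuous", reward_mode = "deterministic",
      # probability 1 on the zone, 0 elsewhere; steps encoded as tight ramps
      # are avoided by evaluating deterministic continuous zones directly
      anchors = data.frame(x = c(-14.5, -9.5), p = c(1, 1)),
      zone = c(-14.5, -9.5)
    ),
    DD = list(
      target_mode = "discrete", reward_mode = "deterministic",
      targets = data.frame(center = centers, half_width = half_width,
                           p = c(0, 1, 0, 0, 0, 0, 0))
    )
  )
  obj$task <- task
  obj$workspace <- as.numeric(workspace)
  obj$zone_center <- -12
  class(obj) <- "reward_landscape"
  validate_landscape(obj)
  obj
}

validate_landscape <- function(ls) {
  stopifnot(inherits(ls, "reward_landscape"))
  if (ls$target_mode == "continuous" && is.null(ls[["zone"]])) {
    a <- ls$anchors
    stopifnot(all(a$p >= 0 & a$p <= 1), all(diff(a$x) > 0))
  }
  if (ls$target_mode == "discrete") {
    tg <- ls$targets[order(ls$targets$center), ]
    stopifnot(all(tg$p >= 0 & tg$p <= 1))
    lo <- tg$center - tg$half_width
    hi <- tg$center + tg$half_width
    if (nrow(tg) > 1) stopifnot(all(lo[-1] > hi[-nrow(tg)]))
  }
  invisible(ls)
}

#' Reward probability at an endpoint
#'
#' Piecewise-linear interpolation between anchors for continuous landscapes
#' (constant outside the anchor range); for discrete landscapes, the target's
#' probability if `x` lies within a target span and 0 otherwise. Vectorized
#' over `x`.
#'
#' @param landscape A [make_landscape()] object.
#' @param x Endpoint(s) in GU; must be finite.
#' @return Probability in `[0, 1]`, same length as `x`.
#' @export
reward_probability <- function(landscape, x) {
  stopifnot(inherits(landscape, "reward_landscape"), all(is.finite(x)))
  if (landscape$target_mode == "continuous") {
    if (!is.null(landscape[["zone"]])) {
      z <- landscape[["zone"]]
      return(as.numeric(x >= z[1] & x <= z[2]))
    }
    a <- landscape$anchors
    stats::approx(a$x, a$p, xout = x, rule = 2)$y
  } else {
    tg <- landscape$targets
    p <- numeric(length(x))
    for (i in seq_len(nrow(tg))) {
      inside <- abs(x - tg$center[i]) <= tg$half_width[i]
      p[inside] <- tg$p[i]
    }
    p
  }
}

#' Sample a binary reward at an endpoint
#'
#' Draws reward 1 with probability [reward_probability()]. Consumes exactly
#' one uniform variate per endpoint from the current RNG stream, so
#' simulation streams are reproducible trial by trial.
#'
#' @inheritParams reward_probability
#' @return Integer 0/1, same length as `x`.
#' @export
sample_reward <- function(landscape, x) {
  p <- reward_probability(landscape, x)
  as.integer(stats::runif(length(x)) < p)
}

#' Snap an endpoint to the nearest discrete target center
#'
#' Discrete tasks require every reach to land on one of the targets (trials
#' between targets reset); generative simulation therefore snaps the
#' continuous model endpoint to the nearest target center before the reward
#' draw. Ties break toward the lower-x target. Vectorized over `x`.
#'
#' @inheritParams reward_probability
#' @return Target center(s), GU.
#' @export
snap_to_target <- function(landscape, x) {
  stopifnot(inherits(landscape, "reward_landscape"))
  if (landscape$target_mode != "discrete")
    stop("snap_to_target() requires a discrete-mode landscape")
  centers <- sort(landscape$targets$center)
  vapply(x, function(xi) {
    d <- abs(xi - centers)
    centers[which(d == min(d))[1]]  # sorted ascending: first minimum = lower x
  }, numeric(1))
}

#' Serialize a landscape to JSON (and back)
#'
#' Round-trips all fields so custom landscapes can be stored in plain-text
#' configuration.
#'
#' @param landscape A `reward_landscape`.
#' @param json A JSON string produced by `landscape_to_json()`.
#' @return `landscape_to_json()`: a JSON string. `landscape_from_json()`: a
#'   `reward_landscape`.
#' @export
landscape_to_json <- function(landscape) {
  stopifnot(inherits(landscape, "reward_landscape"))
  jsonlite::toJSON(unclass(landscape), auto_unbox = TRUE, digits = NA)
}

#' @rdname landscape_to_json
#' @export
landscape_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  for (f in c("anchors", "targets"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.data.frame(obj[[f]])
  obj$workspace <- as.numeric(obj$workspace)
  if (!is.null(obj[["zone"]])) obj$zone <- as.numeric(obj[["zone"]])
  class(obj) <- "reward_landscape"
  validate_landscape(obj)
  obj
}
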