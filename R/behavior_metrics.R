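#' Endpoint interpolation at the far edge
#'
#' The trial endpoint is the x-coordinate where the movement crosses
#' y = 24 GU, linearly interpolated between the last sample below and the
#' first sample at or beyond the edge (input devices sample at uneven
#' rates, so the crossing rarely falls on a sample).
#'
#' @param trajectory A data.frame or matrix with columns `x`, `y` (ordered
#'   samples of one trial).
#' @param y_edge Crossing line, default 24 GU.
#' @return Endpoint x (GU).
#' @export
interpolate_endpoint <- function(trajectory, y_edge = 24) {
  tr <- as.data.frame(trajectory)
  stopifnot(nrow(tr) >= 2, all(c("x", "y") %in% names(tr)))
  after <- which(tr$y >= y_edge)
  if (!length(after) || after[1] == 1)
    stop("trajectory never crosses y = ", y_edge, " from below")
  i2 <- after[1]
  i1 <- i2 - 1L
  dy <- tr$y[i2] - tr$y[i1]
  if (dy == 0) return(tr$x[i2])
  tr$x[i1] + (tr$x[i2] - tr$x[i1]) * (y_edge - tr$y[i1]) / dy
}

#' Path-length ratio of a trajectory
#'
#' Actual path length (sum of segment lengths) divided by the straight-line
#' distance from the first to the last sample; 1 for a straight reach,
#' larger for curved movements.
#'
#' @inheritParams interpolate_endpoint
#' @return Dimensionless ratio >= 1.
#' @export
path_length_ratio <- function(trajectory) {
  tr <- as.data.frame(trajectory)
  stopifnot(nrow(tr) >= 2, all(c("x", "y") %in% names(tr)))
  seg <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  chord <- sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2)
  if (chord == 0) stop("coincident first and last samples")
  sum(seg) / chord
}

#' Behavioral metrics of one session
#'
#' The study's per-participant measures: baseline mean and precision
#' (mean and SD of signed endpoint deviation from the displayed target over
#' the 20 baseline trials), distance from target (mean absolute deviation
#' of the last 10 learning endpoints from the always-rewarded zone center),
#' clamp variabilities (sample SD of endpoints over trials 2–10 of each
#' clamp block), and the single-target mean deviation. Sample SDs use the
#' n - 1 denominator.
#'
#' @param session An `rl_session`.
#' @param zone_center Center of the 100% reward zone (GU), default -12.
#' @param last_n Number of final learning trials averaged (default 10).
#' @return A one-row data.frame of class `session_metrics` columns:
#'   `participant_id`, `age`, `task`, `baseline_mean`, `baseline_precision`,
#'   `distance_from_target`, `success_clamp_sd`, `fail_clamp_sd`,
#'   `single_target_mean`.
#' @export
session_metrics <- function(session, zone_center = -12, last_n = 10) {
  tr <- session$trials
  need <- c("baseline", "learning", "success_clamp", "fail_clamp")
  missing_blocks <- setdiff(need, unique(tr$block))
  if (length(missing_blocks))
    stop("session lacks blocks: ", paste(missing_blocks, collapse = ", "))
  base <- tr[tr$block == "baseline", ]
  dev <- base$endpoint - base$target_center
  learn <- tr[tr$block == "learning", ]
  lastk <- utils::tail(learn$endpoint, last_n)
  clamp_sd <- function(name) {
    e <- tr$endpoint[tr$block == name]
    if (length(e) < 3) return(NA_real_)
    stats::sd(e[-1][seq_len(min(9, length(e) - 1))])
  }
  st <- tr[tr$block == "single_target", ]
  out <- data.frame(
    participant_id = session$participant_id,
    age = session$age,
    task = session$task,
    baseline_mean = mean(dev),
    baseline_precision = stats::sd(dev),
    distance_from_target = mean(abs(lastk - zone_center)),
    success_clamp_sd = clamp_sd("success_clamp"),
    fail_clamp_sd = clamp_sd("fail_clamp"),
    single_target_mean = if (nrow(st)) mean(st$endpoint - st$target_center)
                         else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("session_metrics", class(out))
  out
}

#' Metrics for a list of sessions
#'
#' @param sessions A list of `rl_session` objects.
#' @inheritParams session_metrics
#' @return A data.frame, one row per session.
#' @export
cohort_metrics <- function(sessions, zone_center = -12) {
  do.call(rbind, lapply(sessions, session_metrics, zone_center = zone_center))
}

#' Ordinary least-squares regression of a metric on age
#'
#' Fits `value ~ age` and re-expresses the intercept at the cohort's
#' youngest age, the convention used when comparing developmental
#' regressions between task groups.
#'
#' @param cohort_metrics A data.frame with columns `age` and `value` (or a
#'   metrics data.frame plus `value_col` naming the metric).
#' @param value_col Column to regress when `value` is absent.
#' @return A list: `slope` (per year), `intercept_at_youngest`,
#'   `r_squared`, `f_statistic`, `df`, `p_value`, `youngest_age`, `model`
#'   (the `lm` fit).
#' @export
age_regression <- function(cohort_metrics, value_col = "value") {
  d <- as.data.frame(cohort_metrics)
  if (!"value" %in% names(d)) d$value <- d[[value_col]]
  d <- d[is.finite(d$age) & is.finite(d$value), ]
  if (length(unique(d$age)) < 3) stop("need >= 3 distinct ages")
  a0 <- min(d$age)
  fit <- stats::lm(value ~ I(age - a0), data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept_at_youngest = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       f_statistic = unname(fstat[1]),
       df = unname(fstat[2:3]),
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       youngest_age = a0,
       model = fit)
}
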