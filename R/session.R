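#' Session objects
#'
#' A session is one participant's ordered trial record: five blocks
#' (baseline, learning, success clamp, fail clamp, single target), each
#' trial holding its block label, 1-based trial index, movement endpoint
#' (GU, interpolated at the far edge), binary reward, and — for
#' discrete-target trials — the target center.
#'
#' @param trials A data.frame with columns `block`, `trial_index`,
#'   `endpoint`, `reward`, `target_center`.
#' @param participant_id Character label.
#' @param age Age in years (or `NA`).
#' @param task Task code (`"CP"`, `"DP"`, `"CD"`, `"DD"`).
#' @param true_params Generating `model_params` for synthetic sessions, or
#'   `NULL`.
#' @param seed RNG seed used to generate the session, or `NA`.
#' @param workspace Length-2 numeric, GU.
#' @return An object of class `rl_session`.
#' @export
new_session <- function(trials, participant_id = "p1", age = NA_real_,
                        task = "CP", true_params = NULL, seed = NA_integer_,
                        workspace = c(-24, 24)) {
  stopifnot(is.data.frame(trials),
            all(c("block", "trial_index", "endpoint", "reward",
                  "target_center") %in% names(trials)))
  rownames(trials) <- NULL
  s <- structure(list(participant_id = participant_id, age = age,
                      task = task, trials = trials,
                      true_params = true_params, seed = seed,
                      workspace = as.numeric(workspace)),
                 class = "rl_session")
  validate_session(s)
  s
}

BLOCKS <- c("baseline", "learning", "success_clamp", "fail_clamp", "single_target")

#' Validate a session's invariants
#'
#' Checks block labels, contiguous trial indices, endpoints inside the
#' workspace, rewards in {0, 1}, and clamp-block reward consistency
#' (success clamp all 1, fail clamp all 0).
#'
#' @param session An `rl_session`.
#' @return The session, invisibly; errors name the offending trial.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  stopifnot(all(tr$block %in% BLOCKS))
  if (!identical(as.integer(tr$trial_index), seq_len(nrow(tr))))
    stop("trial_index must be contiguous 1..n")
  ws <- session$workspace
  bad <- which(tr$endpoint < ws[1] - 1e-9 | tr$endpoint > ws[2] + 1e-9)
  if (length(bad))
    stop("endpoint outside workspace at trial ", bad[1])
  if (!all(tr$reward %in% c(0L, 1L)))
    stop("rewards must be 0/1")
  if (any(tr$reward[tr$block == "success_clamp"] != 1L))
    stop("success-clamp trials must all have reward 1")
  if (any(tr$reward[tr$block == "fail_clamp"] != 0L))
    stop("fail-clamp trials must all have reward 0")
  invisible(session)
}

#' @export
print.rl_session <- function(x, ...) {
  cat(sprintf("rl_session %s (task %s, age %s): %d trials\n",
              x$participant_id, x$task,
              ifelse(is.na(x$age), "?", format(x$age, digits = 3)),
              nrow(x$trials)))
  print(table(factor(x$trials$block, levels = BLOCKS)))
  invisible(x)
}

# rows of the fitted trial range, in order
trial_range_rows <- function(session,
                             trial_range = c("learning_only",
                                             "learning_plus_clamps")) {
  trial_range <- match.arg(trial_range)
  keep <- if (trial_range == "learning_only") "learning"
          else c("learning", "success_clamp", "fail_clamp")
  which(session$trials$block %in% keep)
}

# reward of the last trial before the fitted range (gate for trial 1); 1 if none
pre_range_gate <- function(session, rows) {
  if (min(rows) == 1L) return(1L)
  as.integer(session$trials$reward[min(rows) - 1L])
}

#' Default baseline target schedule
#'
#' Twenty target-center locations spread over \[-18, 18\] GU in a fixed
#' shuffled order, standing in for the study's unpublished randomized
#' 20-location baseline schedule. Override via the `baseline_schedule`
#' argument of [simulate_session()].
#'
#' @return Numeric vector of 20 target centers (GU).
#' @export
default_baseline_schedule <- function() {
  locs <- seq(-18, 18, length.out = 20)
  perm <- c(7L, 14L, 2L, 18L, 10L, 5L, 20L, 1L, 12L, 16L,
            4L, 9L, 19L, 6L, 13L, 3L, 17L, 11L, 8L, 15L)
  locs[perm]
}
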