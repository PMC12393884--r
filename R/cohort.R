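#' Specification of a synthetic age-graded cohort
#'
#' A recipe for generating a cohort of simulated participants whose
#' generative parameters follow developmental gradients: motor noise
#' decreasing with age and exploration variability increasing with age.
#' The stock affine maps run from sigma_m = 4.0 GU at age 3 to 2.4 GU at
#' age 17 (a 40% decrease) and from sigma_e = 2.0 GU to 8.0 GU (a fourfold
#' increase) over the same range. The exploration scale is anchored so that
#' the variability after repeated failure roughly doubles across the age
#' range (sqrt(sigma_e^2 + sigma_m^2): 4.5 -> 8.4 GU), the developmental
#' pattern the clamp blocks are designed to expose.
#'
#' @param n Number of participants (>= 1).
#' @param age_range Length-2 numeric, years.
#' @param sigma_m_map,sigma_e_map Affine age maps: lists with `age`
#'   (length-2) and `value` (length-2); linear in between and extrapolated
#'   linearly outside.
#' @param task Task code.
#' @param master_seed Integer; per-participant seeds are derived from it.
#' @param block_plan Optional block-plan override.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100, age_range = c(3, 17),
                        sigma_m_map = list(age = c(3, 17), value = c(4.0, 2.4)),
                        sigma_e_map = list(age = c(3, 17), value = c(2.0, 8.0)),
                        task = "CP", master_seed = 1L,
                        block_plan = default_block_plan()) {
  stopifnot(n >= 1, length(age_range) == 2, age_range[1] < age_range[2])
  spec <- structure(list(n = as.integer(n), age_range = as.numeric(age_range),
                         sigma_m_map = sigma_m_map, sigma_e_map = sigma_e_map,
                         task = task, master_seed = as.integer(master_seed),
                         block_plan = block_plan),
                    class = "cohort_spec")
  for (a in seq(age_range[1], age_range[2], length.out = 5))
    if (affine_map(sigma_m_map, a) <= 0 || affine_map(sigma_e_map, a) <= 0)
      stop("parameter maps must yield positive SDs over the age range")
  spec
}

# evaluate an affine age map
affine_map <- function(map, age) {
  slope <- (map$value[2] - map$value[1]) / (map$age[2] - map$age[1])
  map$value[1] + slope * (age - map$age[1])
}

#' Generate a synthetic cohort
#'
#' Draws each participant's age uniformly over the spec's range, maps it to
#' generative parameters, and simulates a full five-block session under the
#' preferred model (failure-gated exploration + motor noise, full
#' incorporation on success). Every participant gets a derived seed, so the
#' cohort is a deterministic function of the spec.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `rl_session` objects with `true_params` recorded.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 3, master_seed = 7))
#' cohort_metrics(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  variant <- preferred_variant()
  ages <- with_seed(derive_seed(spec$master_seed, 0),
                    stats::runif(spec$n, spec$age_range[1], spec$age_range[2]))
  lapply(seq_len(spec$n), function(i) {
    p <- make_params(sigma_m = affine_map(spec$sigma_m_map, ages[i]),
                     sigma_e = affine_map(spec$sigma_e_map, ages[i]))
    simulate_session(variant, p, spec$task, block_plan = spec$block_plan,
                     seed = derive_seed(spec$master_seed, i),
                     participant_id = sprintf("syn%03d", i), age = ages[i])
  })
}

SESSIONS_SCHEMA_VERSION <- 1L
SESSIONS_COLUMNS <- c("participant_id", "age", "task", "block", "trial_index",
                      "endpoint", "reward", "target_center")

#' Write sessions to CSV (+ JSON sidecar)
#'
#' One CSV row per trial with the fixed column order `participant_id, age,
#' task, block, trial_index, endpoint, reward, target_center`; per-session
#' metadata (true parameters, seeds, workspace, schema version) goes to a
#' JSON sidecar at `<path>.json`. [read_sessions()] round-trips exactly and
#' validates session invariants, naming the offending trial on failure.
#'
#' @param sessions A list of `rl_session` objects.
#' @param path CSV path.
#' @return `write_sessions()`: the path, invisibly. `read_sessions()`: a
#'   list of `rl_session`s.
#' @export
write_sessions <- function(sessions, path) {
  stopifnot(all(vapply(sessions, inherits, logical(1), "rl_session")))
  tab <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(participant_id = s$participant_id, age = s$age, task = s$task,
               s$trials[, c("block", "trial_index", "endpoint", "reward",
                            "target_center")],
               stringsAsFactors = FALSE)
  }))
  tab <- tab[, SESSIONS_COLUMNS]
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(
    schema_version = SESSIONS_SCHEMA_VERSION,
    sessions = lapply(sessions, function(s) list(
      participant_id = s$participant_id,
      seed = s$seed,
      workspace = s$workspace,
      true_params = if (is.null(s$true_params)) NULL else unclass(s$true_params)
    ))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), SESSIONS_COLUMNS))
    stop("malformed sessions file: expected columns ",
         paste(SESSIONS_COLUMNS, collapse = ", "))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar,
                                                       simplifyVector = FALSE)
          else list(schema_version = SESSIONS_SCHEMA_VERSION, sessions = list())
  if (!identical(as.integer(meta$schema_version), SESSIONS_SCHEMA_VERSION))
    stop("schema-version mismatch: file has ", meta$schema_version,
         ", package reads ", SESSIONS_SCHEMA_VERSION)
  meta_by_id <- list()
  for (m in meta$sessions) meta_by_id[[m$participant_id]] <- m
  lapply(split(tab, factor(tab$participant_id, levels = unique(tab$participant_id))),
         function(d) {
    m <- meta_by_id[[d$participant_id[1]]]
    tp <- if (!is.null(m$true_params)) do.call(make_params, m$true_params) else NULL
    new_session(
      d[, c("block", "trial_index", "endpoint", "reward", "target_center")],
      participant_id = d$participant_id[1],
      age = d$age[1], task = d$task[1],
      true_params = tp,
      seed = if (!is.null(m$seed)) as.integer(m$seed) else NA_integer_,
      workspace = if (!is.null(m$workspace)) as.numeric(unlist(m$workspace))
                  else c(-24, 24)
    )
  })
}
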