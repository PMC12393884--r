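#' The model family: structural variants of the full learning model
#'
#' The full generative model of trial-by-trial learning writes the actual
#' reach as the desired reach plus failure-gated exploration variability
#' (SD `sigma_e`), planning variability (SD `sigma_p`) and motor noise
#' (SD `sigma_m`):
#' \deqn{s_t = x_t + (1 - r_{t-1}) e_t + p_t + m_t}
#' and updates the desired reach by the reinforced variability:
#' \deqn{x_{t+1} = x_t + \eta_e r_t (1 - r_{t-1}) e_t + \eta_p r^p_t p_t}
#' where \eqn{r^p_t} is either the trial's reward (reward-gated planning
#' update) or fixed at 1 (update on every trial). Structural variants switch
#' each variability source on or off, choose the learning-rate regime
#' (both free, shared, either or both pinned to unity) and the planning
#' gate. The unconstrained grid has 2 x 2 x 2 x 5 x 2 = 80 combinations;
#' four exclusion rules leave 31 admissible variants:
#' \itemize{
#'   \item no planning and no motor noise (no variability after success);
#'   \item no exploration source but an exploration learning rate;
#'   \item no planning source but a planning learning rate;
#'   \item no planning source but a reward-gated planning update.
#' }
#'
#' @name model_space
NULL

LR_MODES_TWO <- c("both_free", "shared", "eta_e_unity", "eta_p_unity", "both_unity")
LR_MODES_ONE <- c("eta_only_free", "eta_only_unity")

new_variant <- function(has_exploration, has_planning, has_motor,
                        lr_mode, planning_gate = "none",
                        canonical_index = NA_integer_) {
  v <- structure(list(
    has_exploration = has_exploration,
    has_planning = has_planning,
    has_motor = has_motor,
    lr_mode = lr_mode,
    planning_gate = planning_gate,
    canonical_index = canonical_index
  ), class = "model_variant")
  v
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("model variant %s [index %s]%s\n", variant_signature(x),
              x$canonical_index,
              if (!is.na(al <- literature_alias(x))) paste0(" (", al, ")") else ""))
  invisible(x)
}

#' Structural signature of a variant
#'
#' A compact stable string identifying the variant's structure, used for
#' alias lookup and serialization; independent of the canonical index.
#'
#' @param variant A `model_variant`.
#' @return A character scalar, e.g. `"E1P0M1|eta_only_unity|-"`.
#' @export
variant_signature <- function(variant) {
  sprintf("E%dP%dM%d|%s|%s",
          as.integer(variant$has_exploration),
          as.integer(variant$has_planning),
          as.integer(variant$has_motor),
          variant$lr_mode,
          if (variant$has_planning) variant$planning_gate else "-")
}

is_admissible_variant <- function(v) {
  if (!v$has_planning && !v$has_motor) return(FALSE)           # rule (i)
  if (!v$has_exploration && !v$has_planning) {
    if (v$lr_mode != "none") return(FALSE)
  } else if (v$has_exploration && v$has_planning) {
    if (!(v$lr_mode %in% LR_MODES_TWO)) return(FALSE)
  } else {
    # exactly one learning-rate symbol exists: collapsed modes only
    if (!(v$lr_mode %in% LR_MODES_ONE)) return(FALSE)          # rules (ii),(iii)
  }
  if (!v$has_planning && v$planning_gate != "none") return(FALSE)  # rule (iv)
  if (v$has_planning && !(v$planning_gate %in% c("reward_gated", "always")))
    return(FALSE)
  TRUE
}

#' Enumerate the admissible model variants
#'
#' Returns the 31 admissible variants in a fixed canonical order:
#' the motor-only model first; then exploration + motor (learning rate free,
#' then unity); then the planning-only branch (motor on/off crossed with
#' planning rate free/unity and planning gate); then the full
#' exploration + planning branch (motor on/off crossed with the five
#' two-rate regimes and the gate). The order is deterministic and stable
#' across runs.
#'
#' @return A list of `model_variant` objects, `canonical_index` 1..31.
#' @examples
#' length(enumerate_variants())  # 31
#' @export
enumerate_variants <- function() {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  # (E=0, P=0): motor only
  add(new_variant(FALSE, FALSE, TRUE, "none"))
  # (E=1, P=0): motor forced on by rule (i)
  for (lr in LR_MODES_ONE)
    add(new_variant(TRUE, FALSE, TRUE, lr))
  # (E=0, P=1)
  for (motor in c(TRUE, FALSE))
    for (lr in LR_MODES_ONE)
      for (gate in c("reward_gated", "always"))
        add(new_variant(FALSE, TRUE, motor, lr, gate))
  # (E=1, P=1)
  for (motor in c(TRUE, FALSE))
    for (lr in LR_MODES_TWO)
      for (gate in c("reward_gated", "always"))
        add(new_variant(TRUE, TRUE, motor, lr, gate))
  for (i in seq_along(out)) out[[i]]$canonical_index <- i
  stopifnot(all(vapply(out, is_admissible_variant, logical(1))))
  out
}

#' Size of the unconstrained structural grid
#'
#' The full cross of source on/off switches, five learning-rate regimes and
#' two planning gates before any exclusion rule is applied.
#'
#' @return Integer, 80.
#' @export
n_unconstrained_variants <- function() {
  2L * 2L * 2L * 5L * 2L
}

#' Number of free parameters of a variant
#'
#' Counts the variability SDs present plus the free learning rates implied
#' by the learning-rate regime. The full model has 5; the preferred model
#' (exploration + motor, unity rate) has 2; the motor-only model has 1.
#'
#' @param variant A `model_variant`.
#' @return Integer count.
#' @export
n_free_params <- function(variant) {
  if (!is_admissible_variant(variant)) stop("inadmissible variant")
  n_sigma <- sum(variant$has_exploration, variant$has_planning, variant$has_motor)
  n_eta <- switch(variant$lr_mode,
    both_free = 2L, shared = 1L, eta_e_unity = 1L, eta_p_unity = 1L,
    both_unity = 0L, eta_only_free = 1L, eta_only_unity = 0L, none = 0L)
  as.integer(n_sigma + n_eta)
}

# alias table: only signatures the source literature pins down structurally
.alias_table <- function() {
  c("E0P0M1|none|-"          = "Model 1 / motor-only",
    "E1P0M1|eta_only_unity|-" = "Model 11 / preferred",
    "E1P0M1|eta_only_free|-"  = "Model 28")
}

#' Literature label for a variant
#'
#' Looks up the packaged alias table by structural signature. Only variants
#' whose structure is pinned down in the source literature carry a label;
#' all others return `NA`.
#'
#' @param variant A `model_variant`.
#' @return Character label or `NA_character_`.
#' @export
literature_alias <- function(variant) {
  al <- .alias_table()[variant_signature(variant)]
  if (is.na(al)) NA_character_ else unname(al)
}

#' Convenience constructors for named variants
#'
#' `preferred_variant()`: exploration after failure plus motor noise with
#' full incorporation on success (`eta_e = 1`) — the family's preferred
#' model. `motor_only_variant()`: motor noise only (the task-comprehension
#' null). `full_variant()`: all three sources with both rates free and the
#' reward-gated planning update (5 parameters).
#'
#' @return A `model_variant`.
#' @export
preferred_variant <- function() find_variant(TRUE, FALSE, TRUE, "eta_only_unity")

#' @rdname preferred_variant
#' @export
motor_only_variant <- function() find_variant(FALSE, FALSE, TRUE, "none")

#' @rdname preferred_variant
#' @export
full_variant <- function() find_variant(TRUE, TRUE, TRUE, "both_free", "reward_gated")

#' Find an admissible variant by structure
#'
#' @param has_exploration,has_planning,has_motor Source switches.
#' @param lr_mode Learning-rate regime.
#' @param planning_gate Planning-update gate (`"none"` when no planning).
#' @return The matching `model_variant` with its canonical index.
#' @export
find_variant <- function(has_exploration, has_planning, has_motor,
                         lr_mode, planning_gate = "none") {
  want <- variant_signature(new_variant(has_exploration, has_planning,
                                        has_motor, lr_mode, planning_gate))
  for (v in enumerate_variants())
    if (variant_signature(v) == want) return(v)
  stop("no admissible variant with signature ", want)
}

#' Variant table
#'
#' The admissible family as a data frame (signature, canonical index,
#' alias, free-parameter count), suitable for export.
#'
#' @return A data.frame with 31 rows.
#' @export
variant_table <- function() {
  vs <- enumerate_variants()
  data.frame(
    canonical_index = vapply(vs, function(v) v$canonical_index, integer(1)),
    signature = vapply(vs, variant_signature, character(1)),
    alias = vapply(vs, function(v) {
      a <- literature_alias(v); if (is.na(a)) "" else a
    }, character(1)),
    n_free_params = vapply(vs, n_free_params, integer(1)),
    stringsAsFactors = FALSE
  )
}
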