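#' Bayesian Information Criterion
#'
#' `k * ln(n) - 2 * loglik`; smaller is better. Combined (group-level)
#' scores sum per-participant BICs.
#'
#' @param loglik Log-likelihood in nats.
#' @param k Number of free parameters (>= 0).
#' @param n Number of trials (>= 1).
#' @return BIC score.
#' @export
bic <- function(loglik, k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  stopifnot(all(k >= 0))
  k * log(n) - 2 * loglik
}

#' Collect fit results into a tidy table
#'
#' @param fits A list of `fit_result` objects.
#' @return A data.frame with one row per fit: participant, variant index and
#'   signature, free-parameter count, trial count, log-likelihood and BIC.
#' @export
fits_table <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "fit_result")))
  do.call(rbind, lapply(fits, function(f) data.frame(
    participant_id = f$participant_id,
    canonical_index = f$variant$canonical_index,
    signature = variant_signature(f$variant),
    k = n_free_params(f$variant),
    n_trials = f$n_trials,
    trial_range = f$trial_range,
    loglik = f$loglik,
    bic = f$bic,
    stringsAsFactors = FALSE
  )))
}

#' Group-level BIC model selection
#'
#' Sums per-participant BICs for each candidate variant and ranks the
#' family; every participant must contribute a fit for every candidate and
#' all fits must share the trial range. Fit tables from several task groups
#' can be concatenated before calling, pooling the evidence.
#'
#' @param fits A list of `fit_result` objects or a [fits_table()]
#'   data.frame covering a full participant x variant grid.
#' @return An object of class `selection_report`: `table` (per-variant
#'   combined BIC and `delta_bic`, ranked ascending, ties ordered by
#'   canonical index), `best_signature`, `winners` (per-participant best
#'   variant).
#' @export
select_model <- function(fits) {
  tab <- if (is.data.frame(fits)) fits else fits_table(fits)
  if (length(unique(tab$trial_range)) != 1)
    stop("all fits must share a trial range")
  grid <- table(tab$participant_id, tab$signature)
  if (any(grid != 1))
    stop("missing participant x variant cells: every participant needs one fit per candidate")
  agg <- stats::aggregate(bic ~ signature + canonical_index + k, data = tab, FUN = sum)
  names(agg)[names(agg) == "bic"] <- "combined_bic"
  agg <- agg[order(agg$combined_bic, agg$canonical_index), ]
  agg$delta_bic <- agg$combined_bic - agg$combined_bic[1]
  rownames(agg) <- NULL
  winners <- do.call(rbind, lapply(split(tab, tab$participant_id), function(d) {
    d <- d[order(d$bic, d$canonical_index), ]
    d[1, c("participant_id", "signature", "bic")]
  }))
  rownames(winners) <- NULL
  structure(list(table = agg, best_signature = agg$signature[1],
                 winners = winners),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("BIC model selection (combined across participants):\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Likelihood-ratio test of task comprehension
#'
#' Tests whether a participant's data support non-zero exploration after
#' failure: the preferred model (exploration + motor noise) against its
#' motor-only null, LR = 2 * (loglik_preferred - loglik_motor_only) floored
#' at 0, compared to a chi-square with df equal to the difference in free
#' parameters (1). The exploration SD sits on the boundary of its space
#' under the null, so the plain chi-square reference makes the test
#' conservative.
#'
#' @param fit_preferred,fit_motor_only `fit_result`s for the same trials of
#'   the same participant, the null nested in the alternative.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A list: `lr`, `df`, `p_value`, `comprehends` (logical flag).
#' @export
comprehension_lrt <- function(fit_preferred, fit_motor_only, alpha = 0.05) {
  if (fit_preferred$trial_range != fit_motor_only$trial_range ||
      fit_preferred$n_trials != fit_motor_only$n_trials)
    stop("fits must cover the same trials")
  if (!identical(fit_preferred$participant_id, fit_motor_only$participant_id))
    stop("fits must be for the same participant")
  df <- n_free_params(fit_preferred$variant) - n_free_params(fit_motor_only$variant)
  if (df < 1) stop("null model must be nested with fewer parameters")
  lr <- max(0, 2 * (fit_preferred$loglik - fit_motor_only$loglik))
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p, comprehends = p < alpha)
}
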