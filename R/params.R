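#' Parameter vectors for model variants
#'
#' A full parameter set is `theta = {sigma_m, sigma_e, sigma_p, eta_e,
#' eta_p}` (SDs in GU, learning rates dimensionless). A variant pins the
#' fields its structure removes: absent sources have their SD pinned to 0;
#' unity regimes pin the corresponding rate to 1; the shared regime ties
#' `eta_p` to `eta_e`.
#'
#' @param sigma_m,sigma_e,sigma_p Non-negative SDs (GU).
#' @param eta_e,eta_p Non-negative learning rates.
#' @return An object of class `model_params` (a named list).
#' @export
make_params <- function(sigma_m = 0, sigma_e = 0, sigma_p = 0,
                        eta_e = 1, eta_p = 1) {
  stopifnot(sigma_m >= 0, sigma_e >= 0, sigma_p >= 0, eta_e >= 0, eta_p >= 0)
  structure(list(sigma_m = sigma_m, sigma_e = sigma_e, sigma_p = sigma_p,
                 eta_e = eta_e, eta_p = eta_p),
            class = "model_params")
}

# names of the free parameters of a variant, in canonical order
free_param_names <- function(variant) {
  nm <- character(0)
  if (variant$has_motor) nm <- c(nm, "sigma_m")
  if (variant$has_exploration) nm <- c(nm, "sigma_e")
  if (variant$has_planning) nm <- c(nm, "sigma_p")
  nm <- c(nm, switch(variant$lr_mode,
    both_free = c("eta_e", "eta_p"),
    shared = "eta_e",
    eta_e_unity = "eta_p",
    eta_p_unity = "eta_e",
    eta_only_free = if (variant$has_exploration) "eta_e" else "eta_p",
    both_unity = , eta_only_unity = , none = character(0)))
  nm
}

# expand a free-parameter vector into a fully pinned model_params
params_from_free <- function(variant, free) {
  nm <- free_param_names(variant)
  stopifnot(length(free) == length(nm))
  names(free) <- nm
  p <- list(sigma_m = 0, sigma_e = 0, sigma_p = 0, eta_e = 1, eta_p = 1)
  for (n in nm) p[[n]] <- unname(free[[n]])
  if (variant$lr_mode == "shared") p$eta_p <- p$eta_e
  # pinned fields for absent sources stay at their neutral values
  if (!variant$has_motor) p$sigma_m <- 0
  if (!variant$has_exploration) p$sigma_e <- 0
  if (!variant$has_planning) p$sigma_p <- 0
  do.call(make_params, p)
}

# check that params respect the variant's pinning; returns invisibly
check_params <- function(variant, params) {
  stopifnot(inherits(params, "model_params"))
  if (!variant$has_motor && params$sigma_m != 0)
    stop("sigma_m must be 0 for a variant without motor noise")
  if (!variant$has_exploration && params$sigma_e != 0)
    stop("sigma_e must be 0 for a variant without exploration")
  if (!variant$has_planning && params$sigma_p != 0)
    stop("sigma_p must be 0 for a variant without planning variability")
  if (variant$lr_mode %in% c("eta_e_unity", "both_unity") && params$eta_e != 1)
    stop("eta_e pinned to 1 under this regime")
  if (variant$lr_mode %in% c("eta_p_unity", "both_unity") && params$eta_p != 1)
    stop("eta_p pinned to 1 under this regime")
  if (variant$lr_mode == "eta_only_unity") {
    if (variant$has_exploration && params$eta_e != 1)
      stop("eta_e pinned to 1 under this regime")
    if (variant$has_planning && params$eta_p != 1)
      stop("eta_p pinned to 1 under this regime")
  }
  if (variant$lr_mode == "shared" && params$eta_e != params$eta_p)
    stop("shared regime requires eta_e == eta_p")
  invisible(params)
}

# bounds for the free parameters (optimizer box)
param_bounds <- function(variant, sigma_max = 20) {
  nm <- free_param_names(variant)
  lower <- ifelse(startsWith(nm, "sigma"), 1e-3, 0)
  upper <- ifelse(startsWith(nm, "sigma"), sigma_max, 2)
  list(names = nm, lower = lower, upper = upper)
}
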