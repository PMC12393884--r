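test_that("BIC formula and penalty behave as expected", {
  expect_equal(bic(-300, 2, 120), 2 * log(120) + 600)
  expect_equal(bic(-300, 0, 120), 600)
  # equal fits, one extra parameter: penalty ln(n)
  expect_equal(bic(-300, 2, 120) - bic(-300, 1, 120), log(120))
  expect_error(bic(-10, 1, 0), "n")
})

make_fit_row <- function(id, variant, loglik, n = 100,
                         range = "learning_only") {
  data.frame(participant_id = id,
             canonical_index = variant$canonical_index,
             signature = variant_signature(variant),
             k = n_free_params(variant), n_trials = n, trial_range = range,
             loglik = loglik, bic = bic(loglik, n_free_params(variant), n),
             stringsAsFactors = FALSE)
}

test_that("combined BIC selection ranks, ties and shifts correctly", {
  # exact tie: equal loglik and equal free-parameter count
  va <- find_variant(FALSE, TRUE, TRUE, "eta_only_free", "reward_gated")
  vb <- find_variant(TRUE, TRUE, TRUE, "both_unity", "reward_gated")
  stopifnot(n_free_params(va) == n_free_params(vb))
  tab <- rbind(make_fit_row("a", va, -100), make_fit_row("a", vb, -100))
  rep <- select_model(tab)
  expect_equal(rep$table$delta_bic, c(0, 0))
  expect_equal(rep$table$canonical_index, sort(rep$table$canonical_index))
  # adding a constant c to every loglik shifts each BIC by -2c (the combined
  # score over two participants by -4c), leaving the ranking unchanged
  v1 <- motor_only_variant(); v2 <- preferred_variant()
  tab2 <- rbind(make_fit_row("a", v1, -120), make_fit_row("a", v2, -100),
                make_fit_row("b", v1, -80), make_fit_row("b", v2, -85))
  r1 <- select_model(tab2)
  tab3 <- tab2; tab3$loglik <- tab3$loglik + 7
  tab3$bic <- bic(tab3$loglik, tab3$k, tab3$n_trials)
  r2 <- select_model(tab3)
  expect_equal(r2$table$signature, r1$table$signature)
  expect_equal(r2$table$combined_bic, r1$table$combined_bic - 2 * 7 * 2)
  # participant order must not matter
  r3 <- select_model(tab2[c(3, 1, 4, 2), ])
  expect_equal(r3$table, r1$table)
  # missing cell
  expect_error(select_model(tab2[-4, ]), "missing")
})

test_that("comprehension LRT matches the chi-square reference", {
  s <- simulate_session(preferred_variant(), make_params(sigma_m = 2, sigma_e = 3),
                        "CP", seed = 21)
  fp <- fit_variant(s, preferred_variant())
  fm <- fit_variant(s, motor_only_variant())
  res <- comprehension_lrt(fp, fm)
  expect_equal(res$df, 1)
  expect_equal(res$lr, max(0, 2 * (fp$loglik - fm$loglik)))
  expect_equal(res$p_value, pchisq(res$lr, 1, lower.tail = FALSE))
  # boundary quantile: LR = 3.841 at df 1 sits at p = 0.05
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  # equal logliks give LR 0, p 1
  fm_eq <- fm; fm_eq$loglik <- fp$loglik
  expect_equal(comprehension_lrt(fp, fm_eq)$lr, 0)
  expect_equal(comprehension_lrt(fp, fm_eq)$p_value, 1)
  expect_false(comprehension_lrt(fp, fm_eq)$comprehends)
  fm2 <- fit_variant(s, motor_only_variant(), "learning_only")
  expect_error(comprehension_lrt(fp, fm2), "same trials")
})

test_that("the comprehension test has power and respects its size", {
  v <- preferred_variant(); v0 <- motor_only_variant()
  cfg <- optimizer_config(n_restarts = 2)
  flag_for <- function(sigma_e, i) {
    s <- simulate_session(v, make_params(sigma_m = 2, sigma_e = sigma_e), "CP",
                          seed = derive_seed(808, i))
    comprehension_lrt(fit_variant(s, v, config = cfg),
                      fit_variant(s, v0, config = cfg))$comprehends
  }
  # power: clear exploration is detected in the large majority of sessions
  power_flags <- vapply(1:40, function(i) flag_for(3, i), logical(1))
  expect_gte(mean(power_flags), 0.8)
  # size: under a zero-exploration truth the boundary makes the test
  # conservative; rejection rate stays near or below the nominal 5%
  size_flags <- vapply(1:500, function(i) flag_for(0, 1000 + i), logical(1))
  expect_lte(mean(size_flags), 0.07)
})
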