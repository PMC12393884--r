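Package: reachrl
Title: Trial-by-Trial Reinforcement Models of Reward-Based Motor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling reward-based motor learning in reaching tasks
    with binary feedback. Implements a family of trial-by-trial stochastic
    learning models combining motor noise, planning variability and
    failure-gated exploration; exact likelihoods via a reward-driven
    time-varying Kalman filter and smoother; bounded maximum-likelihood
    fitting with multi-start simplex search; BIC model selection and a
    likelihood-ratio task-comprehension test; Monte-Carlo simulation of
    sessions and clamp phases; behavioral metrics (baseline precision,
    distance from target, clamp variability, path-length ratio); grids of
    expected learning distance over motor-noise and exploration levels with
    extraction of the optimal exploration variability; an alternative
    kernel-based value-learning model with a softmax policy; and a generator
    of synthetic age-graded cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
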