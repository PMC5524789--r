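test_that("saturated closed forms hold exactly", {
  # binomial: empirical logits
  rec <- two_arm_records(8, 10, 5, 10)
  fit <- fit_glm(rec, model_spec("survival", terms = "treatment"))
  expect_equal(unname(fit$coefficients["(Intercept)"]), logit(0.8),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["treatmenttreated"]),
               logit(0.5) - logit(0.8), tolerance = 1e-8)
  expect_equal(fit$n, 20)

  # poisson: log arm means
  rec$size <- rep(c(2L, 8L), each = 10)
  pfit <- fit_glm(rec, model_spec("size", terms = "treatment"))
  expect_equal(unname(pfit$coefficients), c(log(2), log(4)),
               tolerance = 1e-8)

  # gaussian: arm means of log fecundity with OLS standard errors
  set.seed(1)
  rec$fecundity <- exp(rnorm(20, rep(c(3, 4), each = 10), 0.5))
  gfit <- fit_glm(rec, model_spec("log_fecundity", terms = "treatment"))
  y <- log(rec$fecundity)
  m <- tapply(y, rec$treatment, mean)
  expect_equal(unname(gfit$coefficients),
               unname(c(m["control"], m["treated"] - m["control"])),
               tolerance = 1e-8)
  ols <- lm(y ~ treatment, data = rec)
  expect_equal(unname(gfit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("fit_glm matches brute-force likelihood optimization", {
  set.seed(42)
  n <- 150
  rec <- data.frame(
    block = 1L, panel = "p1", plate = "l1",
    treatment = sample(c("control", "stress"), n, replace = TRUE),
    density = rpois(n, 3), size = NA_integer_, fecundity = NA_real_,
    stringsAsFactors = FALSE)
  eta <- -0.3 - 0.6 * (rec$treatment == "stress") + 0.2 * rec$density
  rec$survived <- rbinom(n, 1, inverse_logit(eta))
  spec <- model_spec("survival", terms = c("treatment", "density"))
  fit <- fit_glm(rec, spec)
  expect_equal(fit$log_likelihood, brute_force_loglik(rec, spec),
               tolerance = 1e-6)

  rec$size <- rpois(n, exp(1 + 0.5 * (rec$treatment == "stress")))
  pspec <- model_spec("size", terms = "treatment")
  expect_equal(fit_glm(rec, pspec)$log_likelihood,
               brute_force_loglik(rec, pspec), tolerance = 1e-6)
})

test_that("fits are invariant to row order", {
  rec <- simulate_experiment(experiment_design(n_blocks = 1),
                             generator_params(seed = 8, fecund_blocks = 1))
  spec <- model_spec("survival")
  f1 <- fit_glm(rec, spec)
  set.seed(2)
  f2 <- fit_glm(rec[sample(nrow(rec)), ], spec)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-8)
})

test_that("vcov diagonal matches std_errors and missing outcomes shrink n", {
  rec <- simulate_experiment(experiment_design(n_blocks = 4),
                             generator_params(seed = 8))
  fit <- fit_glm(rec, model_spec("survival"))
  expect_equal(sqrt(diag(fit$vcov)), fit$std_errors, tolerance = 1e-12)
  expect_equal(fit$n, nrow(rec))
  ffit <- fit_glm(rec, model_spec("log_fecundity",
                                  terms = c("treatment", "density")))
  expect_equal(ffit$n, sum(!is.na(rec$fecundity)))
  expect_lt(ffit$n, nrow(rec))
})

test_that("separation and empty levels are handled per contract", {
  rec <- two_arm_records(10, 10, 10, 10)  # everyone survives
  expect_warning(fit <- fit_glm(rec, model_spec("survival",
                                                terms = "treatment")),
                 "converge|separation")
  expect_false(fit$converged)

  rec2 <- two_arm_records(8, 10, 5, 10)
  rec2$fecundity <- ifelse(rec2$treatment == "treated", NA, exp(3))
  expect_error(fit_glm(rec2, model_spec("log_fecundity",
                                        terms = "treatment")),
               "treated")
})

test_that("wald_test computes the block chi-square", {
  fit <- tab3_fit()
  wt <- wald_test(fit, "density")
  expect_equal(wt$df, 1)
  expect_equal(wt$chi2, (0.17 / 0.06)^2, tolerance = 1e-10)
  expect_equal(wt$p, 2 * pnorm(0.17 / 0.06, lower.tail = FALSE),
               tolerance = 1e-10)
  wt_tr <- wald_test(fit, "treatment")
  expect_equal(wt_tr$df, 5)
  # diagonal published vcov: block chi2 is the sum of squared z-scores
  expect_equal(wt_tr$chi2, sum((tab3$effects / 0.22)^2), tolerance = 1e-10)

  zero <- survival_fit_from_coefs(-0.2, c(heat = -0.18), density = 0,
                                  se = c(0.3, 0.22, 0.06))
  wt0 <- wald_test(zero, "density")
  expect_equal(wt0$chi2, 0)
  expect_equal(wt0$p, 1)
  expect_error(wald_test(fit, "panel"), "not present")
})

test_that("lrt compares nested fits and rejects degenerate nesting", {
  rec <- simulate_experiment(experiment_design(n_blocks = 1),
                             generator_params(seed = 15, fecund_blocks = 1))
  full <- fit_glm(rec, model_spec("survival",
                                  terms = c("treatment", "density")))
  red <- fit_glm(rec, model_spec("survival", terms = "treatment"))
  res <- lrt(full, red)
  expect_equal(res$df, 1)
  expect_gte(res$chi2, 0)
  expect_error(lrt(full, full), "degenerate|parameter count")
  expect_error(lrt(red, full), "not nested")
  size_fit <- fit_glm(rec, model_spec("size", terms = "treatment"))
  expect_error(lrt(full, size_fit), "different outcomes")
})

test_that("lrt chi-square is ~ chi2(1) under a pure-noise covariate", {
  # Wilks oracle: adding a covariate with no effect gives chi2 with mean 1
  set.seed(99)
  chis <- vapply(1:200, function(r) {
    n <- 300
    rec <- data.frame(block = 1L, panel = "p1", plate = "l1",
                      treatment = rep(c("control", "x"), n / 2),
                      density = rpois(n, 3),
                      survived = rbinom(n, 1, 0.6),
                      size = NA_integer_, fecundity = NA_real_,
                      stringsAsFactors = FALSE)
    full <- fit_glm(rec, model_spec("survival",
                                    terms = c("treatment", "density")))
    red <- fit_glm(rec, model_spec("survival", terms = "treatment"))
    lrt(full, red)$chi2
  }, 0)
  expect_lt(abs(mean(chis) - 1), 3 * sqrt(2 / 200))  # Var(chi2_1) = 2
})

test_that("lrt detects a strong simulated effect", {
  params <- generator_params(
    beta_treatment = c(control = 0, delay = -1, salinity = -1, heat = -1,
                       copper = -1, multiple = -1), seed = 77)
  rec <- simulate_survival(generate_design(experiment_design()), params,
                           "exogenous")
  full <- fit_glm(rec, model_spec("survival",
                                  terms = c("treatment", "density")))
  red <- fit_glm(rec, model_spec("survival", terms = "density"))
  expect_lt(lrt(full, red)$p, 0.001)
})

test_that("prune_interactions drops noise and keeps signal", {
  spec <- model_spec("survival",
                     terms = c("treatment", "panel", "density"),
                     interactions = list(c("treatment", "panel"),
                                         c("treatment", "density")))
  # no-op when the spec has no interactions
  rec <- simulate_survival(generate_design(experiment_design(n_blocks = 1)),
                           generator_params(seed = 30), "exogenous")
  plain <- model_spec("survival", terms = c("treatment", "density"))
  res0 <- prune_interactions(rec, plain)
  expect_equal(nrow(res0$audit), 0)
  expect_equal(res0$fit$coefficients, fit_glm(rec, plain)$coefficients)

  # data simulated without interactions: main-effects-only final model in
  # most runs (each LRT falsely retains with prob ~0.05); 25 seeded runs
  kept_none <- vapply(1:25, function(r) {
    rec <- simulate_survival(generate_design(experiment_design()),
                             generator_params(seed = 400 + r), "exogenous")
    res <- suppressWarnings(prune_interactions(rec, spec))
    length(res$spec$interactions) == 0
  }, TRUE)
  expect_gte(mean(kept_none), 0.80)

  # strong treatment x density interaction is retained
  kept_td <- vapply(1:10, function(r) {
    skel <- generate_design(experiment_design())
    params <- generator_params(seed = 500 + r)
    rec <- simulate_survival(skel, params, "exogenous")
    # re-draw survival with an extra density slope of +1 in the multiple arm
    set.seed(600 + r)
    bp <- attr(rec, "beta_panel")
    eta <- params$beta_intercept +
      params$beta_treatment[rec$treatment] + bp[rec$panel] +
      (0.17 + (rec$treatment == "multiple")) * rec$density
    rec$survived <- rbinom(nrow(rec), 1, inverse_logit(eta))
    res <- suppressWarnings(prune_interactions(rec, spec))
    any(vapply(res$spec$interactions, function(p)
      setequal(p, c("treatment", "density")), TRUE))
  }, TRUE)
  expect_gte(mean(kept_td), 0.9)
})
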