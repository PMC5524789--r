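test_that("inverse_logit is correct, stable, and symmetric", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(inverse_logit(-0.2), 0.45017, tolerance = 1e-5)
  x <- seq(-700, 700, length.out = 101)
  expect_equal(inverse_logit(x) + inverse_logit(-x), rep(1, length(x)),
               tolerance = 1e-12)
  expect_true(all(is.finite(inverse_logit(x))))
  expect_error(inverse_logit(Inf), "finite")
})

test_that("predict_survival evaluates the published coefficients", {
  fit <- tab3_fit()
  expect_equal(predict_survival(fit, "control", 0)$probability,
               inverse_logit(-0.2), tolerance = 1e-12)
  expect_equal(predict_survival(fit, "multiple", 3)$probability,
               inverse_logit(-0.2 - 0.70 + 0.17 * 3), tolerance = 1e-12)
  expect_equal(round(predict_survival(fit, "multiple", 3)$probability, 3),
               0.404)
  # positive density coefficient: strictly increasing curves
  for (tr in c("control", "multiple")) {
    p <- predict_survival(fit, tr, 0:5)$probability
    expect_true(all(diff(p) > 0), info = tr)
  }
  expect_error(predict_survival(fit, "mystery", 3), "unknown treatment")
})

test_that("relative_survival reproduces the published conversions", {
  fit <- tab3_fit()
  rs <- relative_survival(fit, reference_density = 3, B = 500, seed = 1)
  est <- setNames(rs$estimate, rs$treatment)
  direct <- function(b) inverse_logit(-0.2 + b + 0.17 * 3) /
    inverse_logit(-0.2 + 0.17 * 3)
  for (tr in names(tab3$effects))
    expect_equal(unname(est[tr]), direct(tab3$effects[[tr]]),
                 tolerance = 1e-12, info = tr)
  expect_equal(unname(est["control"]), 1)
  expect_equal(rs$se[rs$treatment == "control"], 0)
})

test_that("bootstrap SE agrees with the delta-method oracle on a large fit", {
  set.seed(5)
  n <- 10000
  rec <- data.frame(block = 1L, panel = "p1", plate = "l1",
                    treatment = rep(c("control", "stress"), n / 2),
                    density = rpois(n, 3), size = NA_integer_,
                    fecundity = NA_real_, stringsAsFactors = FALSE)
  eta <- -0.2 - 0.6 * (rec$treatment == "stress") + 0.17 * rec$density
  rec$survived <- rbinom(n, 1, inverse_logit(eta))
  fit <- fit_glm(rec, model_spec("survival", terms = c("treatment",
                                                       "density")))
  rs <- relative_survival(fit, "stress", reference_density = 3, B = 20000,
                          seed = 2)
  # delta method: numeric gradient of the ratio w.r.t. the coefficients
  ratio <- function(b) {
    inverse_logit(b[1] + b[2] + b[3] * 3) / inverse_logit(b[1] + b[3] * 3)
  }
  b <- fit$coefficients
  g <- vapply(1:3, function(i) {
    h <- 1e-6
    bp <- b; bp[i] <- bp[i] + h
    bm <- b; bm[i] <- bm[i] - h
    (ratio(bp) - ratio(bm)) / (2 * h)
  }, 0)
  se_delta <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  expect_lt(abs(rs$se - se_delta) / se_delta, 0.15)
})

test_that("multiplicative null multiplies the printed relative survivals", {
  comp <- relative_survival_table(c("salinity", "heat", "copper", "delay"),
                                  c(0.77, 0.92, 0.81, 0.86))
  nul <- multiplicative_null(comp)
  expect_equal(nul$value, 0.4935, tolerance = 1e-4)
  expect_equal(round(100 * nul$value), 49)

  expect_equal(multiplicative_null(
    relative_survival_table(letters[1:4], rep(1, 4)))$value, 1)
  expect_equal(multiplicative_null(
    relative_survival_table(c("a", "b"), c(0.5, 0.5)))$value, 0.25)
})

test_that("null models respect their structural properties", {
  set.seed(7)
  for (r in 1:20) {
    k <- sample(2:5, 1)
    est <- runif(k, 0.05, 0.99)
    comp <- relative_survival_table(paste0("s", 1:k), est)
    perm <- relative_survival_table(paste0("s", 1:k)[sample(k)],
                                    est[sample(k)])
    m <- multiplicative_null(comp)$value
    expect_equal(m, prod(est), tolerance = 1e-12)
    expect_lt(m, min(est))                       # strictly below smallest
    a <- additive_null(comp)$value
    expect_lte(a, m + 1e-12)                     # additive <= multiplicative
  }
  # permutation invariance
  comp <- relative_survival_table(c("a", "b", "c"), c(0.9, 0.6, 0.75))
  perm <- relative_survival_table(c("c", "a", "b"), c(0.75, 0.9, 0.6))
  expect_equal(multiplicative_null(comp)$value,
               multiplicative_null(perm)$value)

  expect_error(multiplicative_null(
    relative_survival_table("a", 0.5)), "2 non-control")
  mixed <- relative_survival_table(c("a", "b"), c(0.5, 0.6),
                                   reference_density = c(3, 4))
  expect_error(multiplicative_null(mixed), "reference densities")
})

test_that("additive null floors at zero and matches direct arithmetic", {
  comp <- relative_survival_table(c("salinity", "heat", "copper", "delay"),
                                  c(0.77, 0.92, 0.81, 0.86))
  expect_equal(additive_null(comp)$value, 0.36, tolerance = 1e-12)
  expect_equal(additive_null(
    relative_survival_table(c("a", "b"), c(1, 1)))$value, 1)
  expect_equal(additive_null(
    relative_survival_table(c("a", "b"), c(0.4, 0.4)))$value, 0)
})

test_that("classify_interaction implements the SE-crossing rule", {
  nul <- multiplicative_null(relative_survival_table(
    c("a", "b"), c(0.7, 0.7)))
  expect_equal(nul$value, 0.49)
  obs <- function(e, s) relative_survival_table("multiple", e, s)
  expect_equal(classify_interaction(obs(0.70, 0.09), nul)$call,
               "antagonistic")
  expect_equal(classify_interaction(obs(0.49, 0.05), nul)$call,
               "indistinguishable")
  expect_equal(classify_interaction(obs(0.30, 0.05), nul)$call,
               "synergistic")
  # antisymmetry: reflecting the observed estimate about the null flips the
  # call, with se held fixed
  for (e in c(0.60, 0.65, 0.80)) {
    up <- classify_interaction(obs(e, 0.04), nul)$call
    down <- classify_interaction(obs(2 * nul$value - e, 0.04), nul)$call
    flip <- c(antagonistic = "synergistic", synergistic = "antagonistic",
              indistinguishable = "indistinguishable")
    expect_equal(down, unname(flip[up]), info = e)
  }
  # a wider interval multiplier can only move calls toward indistinguishable
  expect_equal(classify_interaction(obs(0.70, 0.09), nul,
                                    multiplier = 3)$call,
               "indistinguishable")
})

test_that("pipeline call matches the analytic comparison when the true gap is wide", {
  # truth fixed on the probability scale via the generating coefficients;
  # analytic call: compare true p_m/p_0 with the product of true p_i/p_0
  # at the reference density. 30 replicates per scenario (scaled down from
  # a larger study for runtime; the true gap here is > 2 true SEs).
  scenarios <- list(
    antagonistic = c(control = 0, delay = -0.3, salinity = -0.5,
                     heat = -0.2, copper = -0.4, multiple = -0.3),
    synergistic = c(control = 0, delay = -0.3, salinity = -0.5,
                    heat = -0.2, copper = -0.4, multiple = -2.2))
  skel <- generate_design(experiment_design())
  panels <- unique(skel$panel)
  zero_bp <- setNames(rep(0, length(panels)), panels)
  for (sc in names(scenarios)) {
    betas <- scenarios[[sc]]
    direct <- function(b) inverse_logit(-0.2 + b + 0.17 * 3) /
      inverse_logit(-0.2 + 0.17 * 3)
    truth_obs <- direct(betas[["multiple"]])
    truth_null <- prod(direct(betas[c("delay", "salinity", "heat",
                                      "copper")]))
    analytic <- if (truth_obs > truth_null) "antagonistic" else "synergistic"
    expect_equal(analytic, sc)
    hits <- vapply(1:30, function(r) {
      params <- generator_params(beta_treatment = betas,
                                 beta_panel = zero_bp,
                                 seed = 7000 + r)
      rec <- simulate_survival(skel, params, "exogenous")
      fit <- suppressWarnings(fit_glm(rec, model_spec(
        "survival", terms = c("treatment", "density"))))
      rs <- relative_survival(fit, reference_density = 3, B = 400,
                              seed = r)
      singles <- rs[rs$treatment %in% c("delay", "salinity", "heat",
                                        "copper"), ]
      attr(singles, "draws") <- attr(rs, "draws")[, singles$treatment]
      attr(singles, "control") <- "control"
      class(singles) <- class(rs)
      cl <- classify_interaction(rs[rs$treatment == "multiple", ],
                                 multiplicative_null(singles))
      cl$call == analytic
    }, TRUE)
    expect_gte(mean(hits), 0.9, label = paste("hit rate for", sc))
  }
})

test_that("density_curves emits one row per treatment-density pair", {
  fit <- tab3_fit()
  cur <- density_curves(fit, densities = 0:5, B = 500, seed = 3)
  expect_equal(nrow(cur), 6 * 6)
  expect_true(all(cur$probability > 0 & cur$probability < 1))
  expect_true(all(cur$se >= 0))
  ctrl <- cur[cur$treatment == "control", ]
  expect_equal(ctrl$probability, inverse_logit(-0.2 + 0.17 * (0:5)),
               tolerance = 1e-12)
})
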