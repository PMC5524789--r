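# published survival coefficients used as ground truth across tests
tab3 <- list(intercept = -0.2,
             effects = c(heat = -0.18, salinity = -0.53, copper = -0.45,
                         delay = -0.34, multiple = -0.70),
             density = 0.17,
             se = c("(Intercept)" = 0.3, heat = 0.22, salinity = 0.22,
                    copper = 0.22, delay = 0.22, multiple = 0.22,
                    density = 0.06))

tab3_fit <- function() {
  survival_fit_from_coefs(tab3$intercept, tab3$effects, tab3$density,
                          se = tab3$se)
}

tiny_design <- function(...) {
  experiment_design(n_blocks = 1, panels_per_block = 1, plates_per_panel = 1,
                    ...)
}

# a two-arm dataset with fixed survival counts, for closed-form checks
two_arm_records <- function(surv_a, n_a, surv_b, n_b) {
  data.frame(
    block = 1L, panel = "b1p1", plate = "b1p1l1",
    treatment = rep(c("control", "treated"), c(n_a, n_b)),
    survived = c(rep(1:0, c(surv_a, n_a - surv_a)),
                 rep(1:0, c(surv_b, n_b - surv_b))),
    size = NA_integer_, fecundity = NA_real_, density = 0L,
    stringsAsFactors = FALSE)
}

# brute-force maximum log-likelihood by direct numerical optimization,
# independent of the IRLS path used by fit_glm
brute_force_loglik <- function(records, spec) {
  y <- switch(spec$outcome, survival = records$survived,
              size = records$size, log_fecundity = log(records$fecundity))
  keep <- !is.na(y)
  y <- y[keep]
  X <- matrix(1, nrow = length(y), ncol = 1)
  if ("treatment" %in% spec$terms) {
    lev <- unique(records$treatment[keep])
    for (l in lev[-1]) X <- cbind(X, as.numeric(records$treatment[keep] == l))
  }
  if ("density" %in% spec$terms) X <- cbind(X, records$density[keep])
  negll <- switch(spec$family,
    "binomial-logit" = function(b) {
      eta <- drop(X %*% b)
      -sum(y * eta - log1p(exp(eta)))
    },
    "poisson-log" = function(b) {
      eta <- drop(X %*% b)
      -sum(y * eta - exp(eta) - lgamma(y + 1))
    },
    "gaussian-identity" = function(b) {
      # profile out sigma: at the optimum sigma^2 = RSS/n
      rss <- sum((y - drop(X %*% b))^2)
      n <- length(y)
      0.5 * n * (log(2 * pi * rss / n) + 1)
    })
  grad <- switch(spec$family,
    "binomial-logit" = function(b) {
      mu <- 1 / (1 + exp(-drop(X %*% b)))
      -drop(crossprod(X, y - mu))
    },
    "poisson-log" = function(b) -drop(crossprod(X, y - exp(drop(X %*% b)))),
    "gaussian-identity" = function(b) {
      r <- y - drop(X %*% b)
      -length(y) / sum(r^2) * drop(crossprod(X, r))
    })
  opt <- stats::optim(rep(0, ncol(X)), negll, gr = grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  -opt$value
}
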