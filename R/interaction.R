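# canonical survival-coefficient view of a fit (or injected table):
# intercept, named treatment offsets (reference = 0), density slope
survival_coefs <- function(fit) {
  stopifnot(inherits(fit, "ms_fit"))
  if (fit$spec$outcome != "survival")
    stop("not a survival fit", call. = FALSE)
  cf <- fit$coefficients
  tr_nm <- names(fit$term_of)[fit$term_of == "treatment"]
  if (!"density" %in% names(cf))
    stop("fit has no density term", call. = FALSE)
  eff <- cf[tr_nm]
  names(eff) <- sub("^treatment", "", tr_nm)
  ref <- fit$reference_treatment %||%
    levels(fit$glm$model$treatment)[1]
  treatment <- c(stats::setNames(0, ref), eff)
  list(intercept = unname(cf["(Intercept)"]),
       treatment = treatment,
       density = unname(cf["density"]),
       control = ref)
}

#' Build a survival fit from known coefficients
#'
#' Constructs an `ms_fit`-compatible object directly from logistic-regression
#' coefficients (and their standard errors or covariance), bypassing model
#' fitting. Used to analyse published coefficient tables. When only standard
#' errors are given the covariance is taken as diagonal (coefficients
#' treated as uncorrelated) — a simplification that should be stated wherever
#' the resulting uncertainties are reported.
#'
#' @param intercept Control log-odds at density 0.
#' @param treatment_effects Named log-odds offsets for non-control treatments.
#' @param density Log-odds per surviving conspecific.
#' @param se Named standard errors for `(Intercept)`, each treatment effect
#'   (same names as `treatment_effects`), and `density`; ignored if `vcov`
#'   is supplied.
#' @param vcov Optional full covariance matrix (rows/cols ordered intercept,
#'   treatment effects, density).
#' @param control Label of the control/reference treatment.
#' @return An object of class `ms_fit`.
#' @export
survival_fit_from_coefs <- function(intercept, treatment_effects, density,
                                    se = NULL, vcov = NULL,
                                    control = "control") {
  stopifnot(!is.null(names(treatment_effects)))
  nm <- c("(Intercept)", paste0("treatment", names(treatment_effects)),
          "density")
  est <- c(intercept, unname(treatment_effects), density)
  names(est) <- nm
  if (is.null(vcov)) {
    if (is.null(se)) se <- rep(0, length(est))
    if (!is.null(names(se)))
      se <- se[c("(Intercept)", names(treatment_effects), "density")]
    stopifnot(length(se) == length(est))
    vcov <- diag(as.numeric(se)^2, nrow = length(est))
  }
  dimnames(vcov) <- list(nm, nm)
  term_of <- c("(Intercept)", rep("treatment", length(treatment_effects)),
               "density")
  names(term_of) <- nm
  structure(
    list(spec = model_spec("survival", terms = c("treatment", "density")),
         coefficients = est,
         std_errors = sqrt(diag(vcov)),
         vcov = vcov,
         log_likelihood = NA_real_,
         n_params = length(est),
         n = NA_integer_,
         converged = TRUE,
         term_of = term_of,
         aliased = character(),
         reference_treatment = control,
         glm = NULL),
    class = "ms_fit")
}

#' Predict survival probability for a treatment at a given density
#'
#' probability = inverse_logit(intercept + treatment effect + density
#' coefficient x density). Panel effects are excluded (prediction at the
#' reference panel). Vectorized over `density`.
#'
#' @param fit A survival `ms_fit` (or [survival_fit_from_coefs()] object).
#' @param treatment Treatment label (the control has effect 0).
#' @param density Conspecific density (number of surviving plate-mates).
#' @return data.frame with columns treatment, density, probability.
#' @export
predict_survival <- function(fit, treatment, density) {
  sc <- survival_coefs(fit)
  if (!treatment %in% names(sc$treatment))
    stop("unknown treatment label '", treatment, "'", call. = FALSE)
  p <- inverse_logit(sc$intercept + sc$treatment[[treatment]] +
                       sc$density * density)
  data.frame(treatment = treatment, density = density, probability = p,
             stringsAsFactors = FALSE)
}

# draw B coefficient vectors from MVN(estimates, vcov); rows = draws
draw_coefs <- function(fit, B, seed) {
  set.seed(child_seed(seed, 5))
  MASS::mvrnorm(B, mu = fit$coefficients, Sigma = fit$vcov)
}

ratio_from_coefs <- function(coefs, treatment, sc_names, reference_density) {
  # coefs: matrix of draws (or 1-row matrix of point estimates) with named cols
  lp0 <- coefs[, "(Intercept)"] + coefs[, "density"] * reference_density
  tr_col <- paste0("treatment", treatment)
  lp1 <- if (tr_col %in% colnames(coefs)) lp0 + coefs[, tr_col] else lp0
  inverse_logit(lp1) / inverse_logit(lp0)
}

#' Treatment survival relative to control
#'
#' Converts fitted logistic coefficients into the treatment's survival
#' probability divided by the control's, both evaluated at
#' `reference_density` surviving conspecifics (and at the reference panel).
#' The standard error is obtained by parametric bootstrap: `B` coefficient
#' vectors are drawn from a multivariate normal with mean the estimates and
#' covariance the coefficient covariance; the ratio is recomputed for each
#' draw and its sample standard deviation reported. The same draws are shared
#' across treatments (so the control's self-ratio has se = 0 exactly).
#'
#' @param fit A converged survival `ms_fit` containing treatment and density
#'   terms.
#' @param treatment Treatment label(s); default all levels including control.
#' @param reference_density Density at which probabilities are compared
#'   (default 3; see the package vignette for why).
#' @param B Bootstrap draws (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `ms_relsurv`: data.frame with columns
#'   treatment, estimate, se, reference_density; bootstrap ratio draws kept
#'   in attribute `"draws"` for downstream shared-draw propagation.
#' @export
relative_survival <- function(fit, treatment = NULL, reference_density = 3,
                              B = 10000, seed = 1) {
  sc <- survival_coefs(fit)
  if (!isTRUE(fit$converged))
    stop("fit did not converge; relative survivals not reliable",
         call. = FALSE)
  if (is.null(treatment)) treatment <- names(sc$treatment)
  unknown <- setdiff(treatment, names(sc$treatment))
  if (length(unknown) > 0)
    stop("unknown treatment label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p0 <- inverse_logit(sc$intercept + sc$density * reference_density)
  if (p0 <= 0) stop("control prediction is zero", call. = FALSE)

  point <- matrix(fit$coefficients, nrow = 1,
                  dimnames = list(NULL, names(fit$coefficients)))
  draws <- draw_coefs(fit, B, seed)
  est <- se <- numeric(length(treatment))
  dr <- matrix(NA_real_, nrow = B, ncol = length(treatment),
               dimnames = list(NULL, treatment))
  for (i in seq_along(treatment)) {
    est[i] <- ratio_from_coefs(point, treatment[i], sc, reference_density)
    if (identical(treatment[i], sc$control)) {
      dr[, i] <- 1
      se[i] <- 0
    } else {
      dr[, i] <- ratio_from_coefs(draws, treatment[i], sc, reference_density)
      se[i] <- stats::sd(dr[, i])
    }
  }
  out <- data.frame(treatment = treatment, estimate = est, se = se,
                    reference_density = reference_density,
                    stringsAsFactors = FALSE)
  attr(out, "draws") <- dr
  attr(out, "control") <- sc$control
  class(out) <- c("ms_relsurv", "data.frame")
  out
}

#' @export
print.ms_relsurv <- function(x, ...) {
  cat("Survival relative to control at density",
      x$reference_density[1], "\n")
  tab <- data.frame(treatment = x$treatment,
                    `relative survival` =
                      sprintf("%d%% +/- %d%%", round(100 * x$estimate),
                              round(100 * x$se)),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Construct a relative-survival table from plain values
#'
#' Builds the `ms_relsurv` container from externally supplied estimates
#' (e.g. values printed in a publication), so null expectations can be
#' computed without a fitted model. No bootstrap draws are attached, so
#' downstream null expectations carry no standard error.
#'
#' @param treatment Treatment labels.
#' @param estimate Relative-survival point estimates (> 0).
#' @param se Standard errors (default 0).
#' @param reference_density Common reference density (default 3).
#' @param control Control label (such rows may be absent).
#' @return An `ms_relsurv` data.frame.
#' @export
relative_survival_table <- function(treatment, estimate, se = 0,
                                    reference_density = 3,
                                    control = "control") {
  stopifnot(length(treatment) == length(estimate), all(estimate > 0))
  out <- data.frame(treatment = treatment, estimate = estimate,
                    se = rep_len(se, length(treatment)),
                    reference_density = reference_density,
                    stringsAsFactors = FALSE)
  attr(out, "control") <- control
  class(out) <- c("ms_relsurv", "data.frame")
  out
}

check_null_components <- function(components) {
  stopifnot(inherits(components, "ms_relsurv"))
  ctrl <- attr(components, "control")
  comp <- components[components$treatment != (ctrl %||% ""), , drop = FALSE]
  if (nrow(comp) < 2)
    stop("need >= 2 non-control single-stressor components", call. = FALSE)
  if (length(unique(comp$reference_density)) != 1)
    stop("components have mismatched reference densities", call. = FALSE)
  comp
}

#' Multiplicative null expectation for combined stressors
#'
#' Under independent stressor action (an individual killed by one stressor
#' cannot be killed by another), the expected relative survival of the
#' combined arm is the product of the single-stressor relative survivals.
#'
#' @param components An [relative_survival()] table of the single-stressor
#'   arms (control rows are ignored).
#' @return Object of class `ms_null` with `method`, `value`, `se` (from the
#'   shared bootstrap draws when available) and `components`.
#' @export
multiplicative_null <- function(components) {
  comp <- check_null_components(components)
  value <- prod(comp$estimate)
  draws <- attr(components, "draws")
  se <- if (!is.null(draws)) {
    stats::sd(apply(draws[, comp$treatment, drop = FALSE], 1, prod))
  } else NA_real_
  structure(list(method = "multiplicative", value = value, se = se,
                 components = comp), class = "ms_null")
}

#' Additive null expectation for combined stressors
#'
#' Alternative null on the survival-fraction scale: expected relative
#' survival = 1 - sum of single-stressor survival reductions, floored at 0.
#' Flagged as non-default; the multiplicative null is the primary model.
#'
#' @inheritParams multiplicative_null
#' @return Object of class `ms_null` with `method = "additive"`.
#' @export
additive_null <- function(components) {
  comp <- check_null_components(components)
  value <- max(0, 1 - sum(1 - comp$estimate))
  draws <- attr(components, "draws")
  se <- if (!is.null(draws)) {
    stats::sd(pmax(0, 1 - rowSums(1 - draws[, comp$treatment, drop = FALSE])))
  } else NA_real_
  structure(list(method = "additive", value = value, se = se,
                 components = comp, non_default = TRUE), class = "ms_null")
}

#' @export
print.ms_null <- function(x, ...) {
  cat(sprintf("%s null expectation: %d%% relative survival\n",
              x$method, round(100 * x$value)))
  cat("  components:",
      paste(sprintf("%s %d%%", x$components$treatment,
                    round(100 * x$components$estimate)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify the multi-stressor interaction
#'
#' Compares the observed combined-stressor relative survival (+/- `multiplier`
#' standard errors) to the null expectation. If the null value falls inside
#' the interval the call is `"indistinguishable"` (synergism and antagonism
#' both refuted). Otherwise, observed survival above the null means the joint
#' effect on mortality is weaker than expected -> `"antagonistic"`; below ->
#' `"synergistic"`.
#'
#' @param observed One-row [relative_survival()] result (or its row) for the
#'   combined-stressor arm.
#' @param null An [multiplicative_null()] / [additive_null()] result.
#' @param multiplier Interval half-width in standard errors (default 1,
#'   mirroring the "standard errors crossed the null" rule).
#' @return Object of class `ms_call`: `call`, `observed`, `null`, `interval`.
#' @export
classify_interaction <- function(observed, null, multiplier = 1) {
  stopifnot(inherits(null, "ms_null"))
  if (is.data.frame(observed)) {
    if (nrow(observed) != 1)
      stop("observed must be a single treatment arm", call. = FALSE)
    obs_est <- observed$estimate
    obs_se <- observed$se
  } else {
    obs_est <- observed[["estimate"]]
    obs_se <- observed[["se"]]
  }
  if (is.na(obs_se) || obs_se < 0)
    stop("observed se must be >= 0", call. = FALSE)
  interval <- c(obs_est - multiplier * obs_se, obs_est + multiplier * obs_se)
  call <- if (null$value >= interval[1] && null$value <= interval[2]) {
    "indistinguishable"
  } else if (obs_est > null$value) {
    "antagonistic"
  } else {
    "synergistic"
  }
  structure(list(call = call, observed = observed, null = null,
                 interval = interval, multiplier = multiplier),
            class = "ms_call")
}

#' @export
print.ms_call <- function(x, ...) {
  cat(sprintf(
    "Interaction call: %s\n  observed combined-arm relative survival %d%% (interval %d%%..%d%%)\n  %s null expectation %d%%\n",
    toupper(x$call), round(100 * x$interval[1] + 100 *
                             (x$interval[2] - x$interval[1]) / 2),
    round(100 * x$interval[1]), round(100 * x$interval[2]),
    x$null$method, round(100 * x$null$value)))
  invisible(x)
}

#' Survival-probability curves over a density grid
#'
#' Evaluates each treatment's predicted survival probability over a grid of
#' conspecific densities, with pointwise bootstrap standard errors (shared
#' coefficient draws across the whole grid).
#'
#' @param fit A survival `ms_fit`.
#' @param densities Density grid (default 0:5).
#' @param B Bootstrap draws.
#' @param seed RNG seed.
#' @return data.frame with columns treatment, density, probability, se.
#' @export
density_curves <- function(fit, densities = 0:5, B = 2000, seed = 1) {
  sc <- survival_coefs(fit)
  draws <- draw_coefs(fit, B, seed)
  out <- list()
  for (tr in names(sc$treatment)) {
    tr_col <- paste0("treatment", tr)
    off <- if (tr_col %in% colnames(draws)) draws[, tr_col] else 0
    p <- inverse_logit(sc$intercept + sc$treatment[[tr]] +
                         sc$density * densities)
    se <- vapply(densities, function(d)
      stats::sd(inverse_logit(draws[, "(Intercept)"] + off +
                                draws[, "density"] * d)), 0)
    out[[tr]] <- data.frame(treatment = tr, density = densities,
                            probability = p, se = se,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
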