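#' Specify an outcome model
#'
#' The family is determined by the outcome: survival is binomial with a logit
#' link, colony size is Poisson with a log link, and log fecundity is Gaussian
#' (ordinary multiple regression on the natural-log scale). Treatment and
#' panel enter as reference-coded categorical effects (control and the first
#' panel are the references); conspecific density is a continuous covariate.
#'
#' @param outcome One of `"survival"`, `"size"`, `"log_fecundity"`.
#' @param terms Main effects, a subset of `c("treatment", "panel", "density")`.
#' @param interactions List of length-2 character vectors naming term pairs,
#'   e.g. `list(c("treatment", "panel"), c("treatment", "density"))`.
#' @return An object of class `ms_spec`.
#' @export
model_spec <- function(outcome = c("survival", "size", "log_fecundity"),
                       terms = c("treatment", "panel", "density"),
                       interactions = list()) {
  outcome <- match.arg(outcome)
  allowed <- c("treatment", "panel", "density")
  if (!all(terms %in% allowed))
    stop("terms must be a subset of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  if (length(interactions) > 0) {
    ok <- vapply(interactions, function(p)
      is.character(p) && length(p) == 2 && all(p %in% terms), logical(1))
    if (!all(ok))
      stop("each interaction must pair two included main-effect terms",
           call. = FALSE)
  }
  family <- switch(outcome,
                   survival = "binomial-logit",
                   size = "poisson-log",
                   log_fecundity = "gaussian-identity")
  structure(list(outcome = outcome, family = family,
                 terms = unique(terms), interactions = interactions),
            class = "ms_spec")
}

spec_formula <- function(spec) {
  lhs <- switch(spec$outcome, survival = "survived", size = "size",
                log_fecundity = "log(fecundity)")
  rhs <- spec$terms
  if (length(spec$interactions) > 0)
    rhs <- c(rhs, vapply(spec$interactions, paste, "", collapse = ":"))
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

spec_family <- function(spec) {
  switch(spec$family,
         "binomial-logit" = stats::binomial("logit"),
         "poisson-log" = stats::poisson("log"),
         "gaussian-identity" = stats::gaussian("identity"))
}

outcome_column <- function(spec) {
  switch(spec$outcome, survival = "survived", size = "size",
         log_fecundity = "fecundity")
}

#' Fit an outcome model by maximum likelihood
#'
#' Fits the generalised linear model described by `spec` via iteratively
#' reweighted least squares (convergence when the deviance change is below
#' 1e-10, at most 100 iterations). Records with a missing outcome are
#' excluded and `n` reflects that; for log fecundity, zero values cannot be
#' log-transformed and are treated as missing with a warning. Reference
#' levels (control treatment, first panel) carry implicit zero coefficients.
#'
#' Complete separation on the logit scale (any |coefficient| > 15) or
#' IRLS non-convergence is flagged in `converged` with a warning; estimates
#' are still returned.
#'
#' @param records Individual-level records (see [read_records()]).
#' @param spec A [model_spec()].
#' @param control Label of the reference treatment; default `"control"` when
#'   present, else the alphabetically first label.
#' @return An object of class `ms_fit` with elements `spec`, `coefficients`,
#'   `std_errors`, `vcov`, `log_likelihood`, `n`, `converged`, plus the
#'   underlying `glm` object.
#' @export
fit_glm <- function(records, spec, control = NULL) {
  stopifnot(inherits(spec, "ms_spec"))
  dat <- as.data.frame(records)
  ycol <- outcome_column(spec)
  if (!ycol %in% names(dat))
    stop("records lack outcome column '", ycol, "'", call. = FALSE)
  if (spec$outcome == "log_fecundity") {
    zero <- !is.na(dat[[ycol]]) & dat[[ycol]] <= 0
    if (any(zero)) {
      warning(sum(zero), " non-positive fecundity value(s) treated as missing",
              call. = FALSE)
      dat[[ycol]][zero] <- NA_real_
    }
  }
  usable <- !is.na(dat[[ycol]])
  for (tm in intersect(spec$terms, c("treatment", "panel", "density")))
    usable <- usable & !is.na(dat[[tm]])
  if ("treatment" %in% spec$terms) {
    # reference level: explicit `control` argument, else "control" if
    # present, else the alphabetically first label; remaining levels sorted
    # so fits are invariant to row order
    lev <- sort(unique(dat$treatment))
    ref <- if (!is.null(control)) control
    else if ("control" %in% lev) "control" else lev[1]
    if (!ref %in% lev)
      stop("control level '", ref, "' not found in records", call. = FALSE)
    lev <- c(ref, setdiff(lev, ref))
    empty <- setdiff(lev, unique(dat$treatment[usable]))
    if (length(empty) > 0)
      stop("no usable records for treatment level(s): ",
           paste(empty, collapse = ", "), call. = FALSE)
    if (length(lev) < 2)
      stop("need >= 2 treatment levels to fit a treatment effect",
           call. = FALSE)
    dat$treatment <- factor(dat$treatment, levels = lev)
  }
  if ("panel" %in% spec$terms)
    dat$panel <- factor(dat$panel, levels = sort(unique(dat$panel)))
  dat <- dat[usable, , drop = FALSE]
  dat <- droplevels(dat)
  if (nrow(dat) == 0) stop("no usable records", call. = FALSE)

  fit <- suppressWarnings(stats::glm(
    spec_formula(spec), family = spec_family(spec), data = dat,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))

  cf <- stats::coef(fit)
  est <- cf[!is.na(cf)]
  V <- stats::vcov(fit)
  V <- V[names(est), names(est), drop = FALSE]
  converged <- isTRUE(fit$converged)
  if (spec$family == "binomial-logit" && any(abs(est) > 15))
    converged <- FALSE
  if (!converged)
    warning("model did not converge cleanly (possible complete separation); ",
            "estimates returned with converged = FALSE", call. = FALSE)

  # map each coefficient to the model term it belongs to
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  term_of <- c("(Intercept)", labels)[asgn + 1L]
  names(term_of) <- colnames(stats::model.matrix(fit))
  term_of <- term_of[names(est)]

  structure(
    list(spec = spec,
         coefficients = est,
         std_errors = sqrt(diag(V)),
         vcov = V,
         log_likelihood = as.numeric(stats::logLik(fit)),
         n_params = length(est),
         n = nrow(dat),
         converged = converged,
         term_of = term_of,
         aliased = names(cf)[is.na(cf)],
         glm = fit),
    class = "ms_fit")
}

#' @export
print.ms_fit <- function(x, ...) {
  cat("GLM fit:", x$spec$outcome, "(", x$spec$family, "), n =", x$n,
      ", logLik =", format(x$log_likelihood, digits = 6),
      if (!x$converged) ", NOT CONVERGED" else "", "\n")
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$std_errors, 4))
  print(tab)
  invisible(x)
}

# names of the estimated coefficients belonging to one model term
term_coef_names <- function(fit, term) {
  hit <- names(fit$term_of)[fit$term_of == term]
  if (length(hit) == 0)
    stop("term '", term, "' not present in fit (available: ",
         paste(setdiff(unique(fit$term_of), "(Intercept)"), collapse = ", "),
         ")", call. = FALSE)
  hit
}

#' Wald test of a fitted model term
#'
#' Tests the joint null that all coefficients of `term` are zero:
#' chi2 = b' V^-1 b over the term's coefficient block, with df equal to the
#' block size (levels - 1 for categorical terms, 1 for density).
#'
#' @param fit An [fit_glm()] result.
#' @param term Term name, e.g. `"treatment"`.
#' @return A data.frame row with `term`, `df`, `chi2`, `p`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "ms_fit"))
  nm <- term_coef_names(fit, term)
  b <- fit$coefficients[nm]
  V <- fit$vcov[nm, nm, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance block for term '", term,
         "'; simplify the model", call. = FALSE))
  chi2 <- drop(t(b) %*% Vi %*% b)
  df <- length(b)
  data.frame(term = term, df = df, chi2 = chi2,
             p = stats::pchisq(chi2, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test of nested fits
#'
#' chi2 = 2 (logLik_full - logLik_reduced), floored at zero; df is the
#' difference in estimated parameter counts. The reduced model's terms and
#' interactions must be a subset of the full model's, on the same outcome and
#' the same records.
#'
#' @param fit_full,fit_reduced [fit_glm()] results.
#' @return A data.frame row with `chi2`, `df`, `p`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "ms_fit"), inherits(fit_reduced, "ms_fit"))
  if (!identical(fit_full$spec$outcome, fit_reduced$spec$outcome))
    stop("fits have different outcomes; not nested", call. = FALSE)
  if (fit_full$n != fit_reduced$n)
    stop("fits use different record sets (n = ", fit_full$n, " vs ",
         fit_reduced$n, ")", call. = FALSE)
  full_terms <- c(fit_full$spec$terms,
                  vapply(fit_full$spec$interactions, paste, "", collapse = ":"))
  red_terms <- c(fit_reduced$spec$terms,
                 vapply(fit_reduced$spec$interactions, paste, "",
                        collapse = ":"))
  if (!all(red_terms %in% full_terms))
    stop("reduced model is not nested in the full model", call. = FALSE)
  df <- fit_full$n_params - fit_reduced$n_params
  if (df < 1)
    stop("degenerate nesting: models have the same parameter count",
         call. = FALSE)
  chi2 <- max(0, 2 * (fit_full$log_likelihood - fit_reduced$log_likelihood))
  data.frame(chi2 = chi2, df = df,
             p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Prune non-significant interactions
#'
#' Each interaction in `spec` is tested by a likelihood-ratio test of the
#' full model (all interactions) against the model omitting that interaction
#' alone. All interactions with p >= `alpha` are then removed jointly and the
#' final model refit. The audit trail records every test. A spec without
#' interactions is returned unchanged with an empty audit trail.
#'
#' @param records Individual-level records.
#' @param spec A [model_spec()] that may include interactions.
#' @param alpha Retention threshold (default 0.05).
#' @return List with `fit` (final [fit_glm()] result), `spec` (final spec)
#'   and `audit` (data.frame: interaction, chi2, df, p, dropped).
#' @export
prune_interactions <- function(records, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "ms_spec"))
  audit <- data.frame(interaction = character(), chi2 = numeric(),
                      df = integer(), p = numeric(), dropped = logical(),
                      stringsAsFactors = FALSE)
  if (length(spec$interactions) == 0)
    return(list(fit = fit_glm(records, spec), spec = spec, audit = audit))
  fit_full <- fit_glm(records, spec)
  keep <- logical(length(spec$interactions))
  for (i in seq_along(spec$interactions)) {
    reduced_spec <- spec
    reduced_spec$interactions <- spec$interactions[-i]
    fit_red <- fit_glm(records, reduced_spec)
    res <- lrt(fit_full, fit_red)
    keep[i] <- res$p < alpha
    audit <- rbind(audit, data.frame(
      interaction = paste(spec$interactions[[i]], collapse = ":"),
      chi2 = res$chi2, df = res$df, p = res$p, dropped = !keep[i],
      stringsAsFactors = FALSE))
  }
  final_spec <- spec
  final_spec$interactions <- spec$interactions[keep]
  final_fit <- if (all(keep)) fit_full else fit_glm(records, final_spec)
  list(fit = final_fit, spec = final_spec, audit = audit)
}
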