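#' Assemble a run configuration
#'
#' Bundles the experiment design, generator parameters (optional — omit when
#' analysing provided data), and analysis settings into one serializable
#' list. A seed is mandatory because every pipeline stage that draws random
#' numbers derives a documented sub-seed from it (stage counters: 1 panel
#' effects, 2 survival, 3 size, 4 fecundity, 5 bootstrap), so adding a later
#' stage never perturbs earlier streams.
#'
#' @param design [experiment_design()] (or plain list of its fields).
#' @param generator [generator_params()] or NULL.
#' @param mode Density mode for simulation.
#' @param reference_density Density for probability conversion (default 3).
#' @param bootstrap_B Parametric-bootstrap draws (default 10000).
#' @param interval_multiplier SE multiplier for the interaction call.
#' @param null_methods Null models to report.
#' @param multiple_label Label of the combined-stressor arm.
#' @param alpha Interaction-pruning threshold.
#' @param seed Master seed (required).
#' @return List of class `ms_config`.
#' @export
run_config <- function(design = experiment_design(),
                       generator = generator_params(seed = seed),
                       mode = "exogenous",
                       reference_density = 3,
                       bootstrap_B = 10000,
                       interval_multiplier = 1,
                       null_methods = c("multiplicative", "additive"),
                       multiple_label = "multiple",
                       alpha = 0.05,
                       seed = NULL) {
  if (is.null(seed) || !is.finite(seed))
    stop("a seed is required in the run configuration", call. = FALSE)
  if (!is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(design = unclass(design),
                 generator = if (!is.null(generator)) unclass(generator),
                 mode = mode,
                 analysis = list(reference_density = reference_density,
                                 bootstrap_B = bootstrap_B,
                                 interval_multiplier = interval_multiplier,
                                 null_methods = null_methods,
                                 multiple_label = multiple_label,
                                 alpha = alpha),
                 seed = as.integer(seed)),
            class = "ms_config")
}

usage_error <- function(msg) {
  stop(structure(class = c("ms_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

data_error <- function(msg) {
  stop(structure(class = c("ms_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

normalize_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$seed) || !is.finite(config$seed))
    usage_error("configuration must contain a seed")
  config
}

config_design <- function(config) {
  do.call(experiment_design, config$design)
}

config_generator <- function(config) {
  if (is.null(config$generator))
    usage_error("configuration has no generator block")
  do.call(generator_params, config$generator)
}

write_run_log <- function(path, lines) {
  writeLines(c(sprintf("multistress %s | %s",
                       as.character(utils::packageVersion("multistress")),
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
               lines), path)
  invisible(path)
}

#' Simulate a dataset from a configuration
#'
#' Writes `records.csv`, a `config.json` snapshot and `run.log` into
#' `out_dir`. Byte-identical output under an identical configuration.
#'
#' @param config An [run_config()] list or path to a config JSON file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the records data.frame.
#' @export
cmd_simulate <- function(config, out_dir) {
  config <- normalize_config(config)
  design <- config_design(config)
  params <- config_generator(config)
  mode <- config$mode %||% "exogenous"
  records <- simulate_experiment(design, params, mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_records(records, file.path(out_dir, "records.csv"))
  write_config(config, file.path(out_dir, "config.json"))
  bp <- attr(records, "beta_panel")
  write_run_log(file.path(out_dir, "run.log"), c(
    "command: simulate",
    paste0("seed: ", config$seed),
    paste0("mode: ", mode),
    paste0("records: ", nrow(records)),
    paste0("panel effects: ",
           paste(sprintf("%s=%.6f", names(bp), bp), collapse = ", "))))
  invisible(records)
}

fit_outcome_or_note <- function(records, outcome, alpha) {
  spec <- model_spec(outcome,
                     terms = c("treatment", "panel", "density"),
                     interactions = list(c("treatment", "panel"),
                                         c("treatment", "density")))
  tryCatch(
    withCallingHandlers(
      prune_interactions(records, spec, alpha = alpha),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) {
      # single-panel or single-block subsets make some terms inestimable;
      # retry without panel, then without interactions, before giving up
      for (alt in list(
        model_spec(outcome, terms = c("treatment", "panel", "density"),
                   interactions = list(c("treatment", "density"))),
        model_spec(outcome, terms = c("treatment", "density"),
                   interactions = list(c("treatment", "density"))),
        model_spec(outcome, terms = c("treatment", "density")))) {
        res <- tryCatch(
          suppressWarnings(prune_interactions(records, alt, alpha = alpha)),
          error = function(e2) NULL)
        if (!is.null(res)) {
          res$note <- paste("model simplified:", conditionMessage(e))
          return(res)
        }
      }
      list(fit = NULL, audit = NULL,
           note = paste("not estimable:", conditionMessage(e)))
    })
}

coef_table <- function(fit, outcome) {
  z <- fit$coefficients / fit$std_errors
  data.frame(outcome = outcome, term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$std_errors),
             p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Analyse a records file
#'
#' Fits the three outcome models (survival, colony size, log fecundity, the
#' latter restricted to records with observed fecundity), prunes
#' non-significant interactions, computes Wald tables, runs the interaction
#' analysis on the survival fit, and writes `report.json`,
#' `coefficients.csv`, `wald.csv`, `density_curves.csv`, `report.txt` and
#' `run.log` to `out_dir`.
#'
#' @param records_path Path to a records CSV (or a records data.frame).
#' @param config An [run_config()] list or path to one.
#' @param out_dir Output directory.
#' @return Invisibly, the report list.
#' @export
cmd_analyze <- function(records_path, config, out_dir) {
  config <- normalize_config(config)
  an <- config$analysis
  records <- if (is.data.frame(records_path)) records_path else
    tryCatch(read_records(records_path),
             error = function(e) data_error(conditionMessage(e)))
  if (nrow(records) == 0) data_error("records file contains no data rows")
  if (all(is.na(records$survived)) ||
      sum(records$survived, na.rm = TRUE) == 0 ||
      sum(records$survived == 0, na.rm = TRUE) == 0)
    data_error("need at least one survivor and one death to fit survival")

  fits <- list(
    survival = fit_outcome_or_note(records, "survival", an$alpha),
    size = fit_outcome_or_note(records, "size", an$alpha),
    fecundity = if (all(is.na(records$fecundity)))
      list(fit = NULL, audit = NULL, note = "not estimable: no fecundity observations")
    else fit_outcome_or_note(records, "log_fecundity", an$alpha))

  coef_tabs <- list(); wald_tabs <- list(); notes <- character()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!is.null(f$note)) notes <- c(notes, paste0(nm, ": ", f$note))
    if (is.null(f$fit)) next
    coef_tabs[[nm]] <- coef_table(f$fit, nm)
    for (tm in f$fit$spec$terms) {
      wt <- tryCatch(wald_test(f$fit, tm), error = function(e) NULL)
      if (!is.null(wt)) wald_tabs[[paste(nm, tm)]] <-
          cbind(outcome = nm, wt, stringsAsFactors = FALSE)
    }
    if (!isTRUE(f$fit$converged))
      notes <- c(notes, paste0(nm, ": fit flagged as non-converged ",
                               "(possible separation)"))
  }
  coefficients <- do.call(rbind, c(coef_tabs, list(make.row.names = FALSE)))
  wald <- do.call(rbind, c(wald_tabs, list(make.row.names = FALSE)))

  sfit <- fits$survival$fit
  if (is.null(sfit)) data_error("survival model could not be fitted")
  sc <- survival_coefs(sfit)
  multiple_label <- an$multiple_label %||% "multiple"
  rs <- relative_survival(sfit, reference_density = an$reference_density,
                          B = an$bootstrap_B,
                          seed = child_seed(config$seed, 5))
  singles <- rs[!(rs$treatment %in% c(sc$control, multiple_label)), ,
                drop = FALSE]
  attr(singles, "draws") <- attr(rs, "draws")[, singles$treatment,
                                              drop = FALSE]
  attr(singles, "control") <- sc$control
  class(singles) <- class(rs)
  observed <- rs[rs$treatment == multiple_label, , drop = FALSE]
  nulls <- list()
  for (m in (an$null_methods %||% "multiplicative")) {
    nulls[[m]] <- switch(m, multiplicative = multiplicative_null(singles),
                         additive = additive_null(singles))
  }
  call <- if (nrow(observed) == 1 && length(nulls) > 0)
    classify_interaction(observed, nulls[[1]],
                         multiplier = an$interval_multiplier %||% 1)
  else NULL

  occupancy <- max(table(records$plate))
  curves <- density_curves(sfit, densities = 0:(occupancy - 1),
                           B = min(an$bootstrap_B, 5000),
                           seed = child_seed(config$seed, 5))

  report <- list(
    n_records = nrow(records),
    coefficients = coefficients,
    wald = wald,
    interaction = list(
      reference_density = an$reference_density,
      relative_survivals = as.data.frame(rs),
      nulls = lapply(nulls, function(x)
        list(method = x$method, value = x$value, se = x$se)),
      call = if (!is.null(call)) call$call else NA_character_,
      interval = if (!is.null(call)) call$interval else NULL),
    audit = lapply(fits, `[[`, "audit"),
    notes = notes,
    provenance = list(seed = config$seed,
                      bootstrap_B = an$bootstrap_B,
                      version =
                        as.character(utils::packageVersion("multistress"))))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  utils::write.csv(coefficients, file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  if (!is.null(wald))
    utils::write.csv(wald, file.path(out_dir, "wald.csv"), row.names = FALSE)
  utils::write.csv(curves, file.path(out_dir, "density_curves.csv"),
                   row.names = FALSE)

  txt <- c(
    sprintf("Records analysed: %d", nrow(records)),
    "",
    "Relative survivals (vs control):",
    sprintf("  %-10s %3d%% +/- %d%%", rs$treatment,
            round(100 * rs$estimate), round(100 * rs$se)),
    "",
    vapply(nulls, function(x)
      sprintf("%s null expectation: %d%%", x$method, round(100 * x$value)),
      ""),
    if (!is.null(call)) sprintf("Interaction call: %s", call$call),
    if (length(notes) > 0) c("", "Notes:", paste(" -", notes)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  write_run_log(file.path(out_dir, "run.log"), c(
    "command: analyze",
    paste0("seed: ", config$seed),
    paste0("records: ", nrow(records)),
    paste0("interaction call: ",
           if (!is.null(call)) call$call else "n/a")))
  invisible(report)
}

#' Run the worked example as a pipeline command
#'
#' @param out_dir Optional directory for `report.json` / `report.txt`.
#' @param seed Bootstrap seed.
#' @return The [worked_example()] result, invisibly printed.
#' @export
cmd_worked_example <- function(out_dir = NULL, seed = 1) {
  we <- worked_example(seed = seed)
  print(we)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(relative_survivals = as.data.frame(we$relative_survivals),
           null = list(method = we$null$method, value = we$null$value),
           additive_null = list(method = "additive",
                                value = we$additive_null$value),
           call = we$call$call, interval = we$call$interval),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::capture.output(print(we),
                          file = file.path(out_dir, "report.txt"))
  }
  invisible(we)
}

#' Parameter-recovery study
#'
#' Simulates `n_reps` datasets in exogenous mode from known coefficients,
#' refits the survival model (treatment + panel + density) to each, and
#' summarises per-coefficient bias and 95% Wald confidence-interval coverage.
#' Panel effects are drawn once (from the master seed) and held fixed across
#' replicates so they are part of the recoverable truth.
#'
#' @param n_reps Number of simulated datasets.
#' @param design Experiment design (default: the full study design).
#' @param params Generator parameters (default published coefficients).
#' @param seed Master seed.
#' @return List with `summary` (per-coefficient mean estimate, truth, bias,
#'   coverage) and `overall_coverage`.
#' @export
recover_parameters <- function(n_reps = 500,
                               design = experiment_design(),
                               params = generator_params(),
                               seed = 1) {
  skel <- generate_design(design)
  panels <- unique(skel$panel)
  if (is.null(params$beta_panel)) {
    p0 <- params
    p0$seed <- as.integer(child_seed(seed, 1))
    params$beta_panel <- resolve_panel_effects(panels, p0)
  }
  truth <- c("(Intercept)" = params$beta_intercept,
             stats::setNames(
               params$beta_treatment[setdiff(names(params$beta_treatment),
                                             design$treatments[1])],
               paste0("treatment",
                      setdiff(names(params$beta_treatment),
                              design$treatments[1]))),
             stats::setNames(params$beta_panel[panels[-1]],
                             paste0("panel", panels[-1])),
             density = params$beta_density)
  spec <- model_spec("survival", terms = c("treatment", "panel", "density"))
  est <- cover <- matrix(NA_real_, nrow = n_reps, ncol = length(truth),
                         dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_reps)) {
    pr <- params
    pr$seed <- as.integer(child_seed(seed, 100 + r))
    rec <- simulate_survival(skel, pr, mode = "exogenous")
    fit <- suppressWarnings(fit_glm(rec, spec))
    nm <- intersect(names(truth), names(fit$coefficients))
    est[r, nm] <- fit$coefficients[nm]
    half <- stats::qnorm(0.975) * fit$std_errors[nm]
    cover[r, nm] <- as.numeric(abs(fit$coefficients[nm] - truth[nm]) <= half)
  }
  summary <- data.frame(
    term = names(truth),
    truth = unname(truth),
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(truth),
    coverage = colMeans(cover, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, overall_coverage = mean(cover, na.rm = TRUE),
       n_reps = n_reps)
}

#' Wald and LRT calibration study under a no-effect simulation
#'
#' Simulates datasets with all treatment effects equal to zero, fits the
#' survival model, and records the rejection rate at `alpha` of (i) the Wald
#' test of the treatment term and (ii) the likelihood-ratio test dropping
#' treatment. Both rates should sit near `alpha` for a calibrated test.
#'
#' @param n_reps Number of replicates.
#' @param design Experiment design; defaults to a single block of the full
#'   design (288 records) to keep runtime modest — the tests' asymptotics are
#'   already comfortable at that size.
#' @param seed Master seed.
#' @param alpha Nominal level.
#' @return List with `wald_rate`, `lrt_rate`, `n_reps`.
#' @export
calibration_study <- function(n_reps = 1000,
                              design = experiment_design(n_blocks = 1),
                              seed = 1, alpha = 0.05) {
  base <- generator_params(seed = 1)
  base$beta_treatment[] <- 0
  skel <- generate_design(design)
  panels <- unique(skel$panel)
  p0 <- base
  p0$seed <- as.integer(child_seed(seed, 1))
  base$beta_panel <- resolve_panel_effects(panels, p0)
  full_spec <- model_spec("survival",
                          terms = c("treatment", "panel", "density"))
  red_spec <- model_spec("survival", terms = c("panel", "density"))
  wald_rej <- lrt_rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    pr <- base
    pr$seed <- as.integer(child_seed(seed, 1000 + r))
    rec <- simulate_survival(skel, pr, mode = "exogenous")
    ff <- suppressWarnings(fit_glm(rec, full_spec))
    fr <- suppressWarnings(fit_glm(rec, red_spec))
    wald_rej[r] <- wald_test(ff, "treatment")$p < alpha
    lrt_rej[r] <- lrt(ff, fr)$p < alpha
  }
  list(wald_rate = mean(wald_rej), lrt_rate = mean(lrt_rej), n_reps = n_reps)
}
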