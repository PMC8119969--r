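#' Ready-made designs for the two reference experiments
#'
#' `design_experiment1()` is the unilateral-punishment design: 98
#' participants, 20 one-shot trials each, half the computer partners
#' cooperate, 400-cent endowment, punishment investments of 1-9 cents with a
#' tenfold deduction. `design_experiment2()` is the symmetric variant with
#' 93 participants in which a cooperating partner who is cheated morally
#' punishes the participant (random 1-9 cent cost, tenfold deduction).
#'
#' @param n_participants override the sample size.
#' @return An [experiment_design()].
#' @export
design_experiment1 <- function(n_participants = 98L) {
  experiment_design(n_participants = n_participants)
}

#' @rdname design_experiment1
#' @export
design_experiment2 <- function(n_participants = 93L) {
  experiment_design(n_participants = n_participants,
                    partner_punishes_unilateral_defection = TRUE)
}

#' Full model-based analysis of a trial table
#'
#' Reproduces the complete analysis pipeline for one experiment: aggregate
#' the trials into the per-condition category table, fit the unconstrained
#' two-condition model (goodness of fit), then test each parameter (`C`,
#' `P_Moral`, `P_Hypocritical`, `P_Antisocial`, `b`) for equality across
#' the framing conditions by a nested delta-G2 test with Cohen's w at the
#' table's total observation count.
#'
#' @param trials trial data frame or path to a trial CSV (see
#'   [read_trials()]).
#' @param experiment_label free-text label echoed in the report.
#' @param conditions optional ordered condition labels.
#' @param ... passed to [fit_mpt()] (e.g. `n_starts`, `start_seed`).
#' @return An object of class `"mpt_report"`: `experiment_label`,
#'   `base_fit`, `comparisons` (ordered list of [compare_nested()] results),
#'   `n_total`, `conditions`.
#' @export
run_paper_analysis <- function(trials, experiment_label = "experiment",
                               conditions = NULL, ...) {
  if (is.character(trials) && length(trials) == 1L) {
    trials <- read_trials(trials)
  }
  table <- aggregate_trials(trials, conditions)
  conds <- unique(table$condition)
  if (length(conds) < 2L) {
    stop("the framing analysis needs at least two conditions; got: ",
         paste(conds, collapse = ", "),
         " (supply both arms in the trial table)", call. = FALSE)
  }
  spec <- model_spec(conds)
  base_fit <- fit_mpt(table, spec, ...)
  comparisons <- lapply(.mpt_param_names, function(p) {
    compare_nested(table, spec, p, ...)
  })
  names(comparisons) <- .mpt_param_names
  structure(list(experiment_label = experiment_label,
                 base_fit = base_fit,
                 comparisons = comparisons,
                 n_total = base_fit$n_total,
                 conditions = conds,
                 package_version =
                   as.character(utils::packageVersion("punishMPT"))),
            class = "mpt_report")
}

#' @export
print.mpt_report <- function(x, ...) {
  cat("==", x$experiment_label, "==\n")
  cat(sprintf("Base model: G2(%d) = %.2f, p = %.3f\n",
              x$base_fit$df, x$base_fit$g2, x$base_fit$p_value))
  for (cond in names(x$base_fit$estimates)) {
    est <- x$base_fit$estimates[[cond]]
    cat("  ", cond, ": ",
        paste(sprintf("%s = %.3f", names(unclass(est)), unclass(est)),
              collapse = ", "), "\n", sep = "")
  }
  cat("Equality tests across conditions (N =", x$n_total, "):\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Machine-readable mirror of the printed report: base-fit statistics and
#' per-condition estimates, then one entry per equality test in the fixed
#' order C, P_Moral, P_Hypocritical, P_Antisocial, b.
#'
#' @param report an [run_paper_analysis()] result.
#' @param path optional file path; when given, JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mpt_report"))
  bf <- report$base_fit
  obj <- list(
    experiment_label = report$experiment_label,
    package_version = report$package_version,
    n_total = bf$n_total,
    base_fit = list(
      g2 = bf$g2, df = bf$df, p_value = bf$p_value,
      converged = bf$converged,
      estimates = lapply(bf$estimates, function(e)
        as.list(unclass(e)[.mpt_param_names])),
      standard_errors = as.list(bf$standard_errors)),
    comparisons = lapply(report$comparisons, function(cmp) list(
      parameter = cmp$parameter_tested,
      delta_g2 = cmp$delta_g2, df = cmp$df,
      p_value = cmp$p_value, w = cmp$w, n_total = cmp$n_total))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a design or agent-parameter configuration file
#'
#' Plain JSON. A design config maps [experiment_design()] argument names to
#' values. A profile config maps each condition label to an object with the
#' five parameter names.
#'
#' @param path JSON file path.
#' @return `read_design_config`: an [experiment_design()];
#'   `read_profiles_config`: named list of [agent_profile()].
#' @export
read_design_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  do.call(experiment_design, cfg)
}

#' @rdname read_design_config
#' @export
read_profiles_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  lapply(cfg, function(p) agent_profile(do.call(mpt_parameters, as.list(p))))
}
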