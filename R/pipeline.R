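#' Evaluate recommendations: Consis versus Inconsis survival contrast
#'
#' The observational evaluation of a recommender: patients whose actual
#' treatment agrees with the recommendation (Consis) are contrasted with
#' those whose treatment does not (Inconsis) on overall survival, with and
#' without stabilized IPTW for Consis-membership given covariates. Reports
#' the multivariate HR, IPTW HR, 5-year ARR and DRMST (plus IPTW variants)
#' with percentile-bootstrap CIs, and classical and IPTW log-rank tests.
#'
#' @param times,events follow-up (months) and event indicators.
#' @param consistency factor from [concordance_grouping()] (levels
#'   \code{Inconsis}, \code{Consis}); the HR is Consis vs Inconsis, so values
#'   below 1 favour following the recommendation.
#' @param features covariates used both as the multivariate adjustment set
#'   and in the propensity model for Consis membership.
#' @param horizon evaluation horizon in months (default 60 = 5 years).
#' @param n_boot bootstrap resamples for ARR/DRMST CIs (default 200).
#' @param conf_level confidence level.
#' @param seed bootstrap seed.
#' @return list of class \code{eval_report}.
#' @export
evaluate_recommendations <- function(times, events, consistency, features,
                                     horizon = 60, n_boot = 200L,
                                     conf_level = 0.95, seed = 1L) {
  g <- as_binary_group(consistency)
  X <- as.matrix(features)
  hr <- weighted_cox_hr(times, events, g, adjustment_covariates = X,
                        conf_level = conf_level)
  ps <- estimate_propensity(X, g)
  w <- compute_iptw_weights(ps)
  hr_iptw <- weighted_cox_hr(times, events, g, weights = w,
                             conf_level = conf_level)

  grid <- default_grid(times, events, horizon)
  km_pair <- function(wts) {
    list(consis = weighted_km(times[g == 1L], events[g == 1L],
                              wts[g == 1L], grid = grid),
         inconsis = weighted_km(times[g == 0L], events[g == 0L],
                                wts[g == 0L], grid = grid))
  }
  unit <- rep(1, length(times))
  km_u <- km_pair(unit); km_w <- km_pair(w)
  point <- c(arr = arr_5yr(km_u$consis, km_u$inconsis, horizon),
             arr_iptw = arr_5yr(km_w$consis, km_w$inconsis, horizon),
             drmst = drmst(km_u$consis, km_u$inconsis, horizon),
             drmst_iptw = drmst(km_w$consis, km_w$inconsis, horizon))

  set.seed(seed)
  n <- length(times)
  bt <- matrix(NA_real_, n_boot, 4L,
               dimnames = list(NULL, names(point)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    gi <- g[idx]
    if (length(unique(gi)) < 2) next
    row <- tryCatch({
      wi <- compute_iptw_weights(estimate_propensity(X[idx, , drop = FALSE], gi))
      gr <- default_grid(times[idx], events[idx], horizon)
      kp <- function(wts) list(
        consis = weighted_km(times[idx][gi == 1L], events[idx][gi == 1L],
                             wts[gi == 1L], grid = gr),
        inconsis = weighted_km(times[idx][gi == 0L], events[idx][gi == 0L],
                               wts[gi == 0L], grid = gr))
      ku <- kp(rep(1, length(idx))); kw <- kp(wi)
      c(arr_5yr(ku$consis, ku$inconsis, horizon),
        arr_5yr(kw$consis, kw$inconsis, horizon),
        drmst(ku$consis, ku$inconsis, horizon),
        drmst(kw$consis, kw$inconsis, horizon))
    }, error = function(e) NULL)
    if (!is.null(row)) bt[b, ] <- row
  }
  alpha <- (1 - conf_level) / 2
  cis <- apply(bt, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
               na.rm = TRUE)

  lr <- weighted_logrank(times, events, g)
  lr_iptw <- weighted_logrank(times, events, g, weights = w)

  structure(list(
    n = n, n_consis = sum(g == 1L), n_inconsis = sum(g == 0L),
    horizon = horizon,
    hr = hr$hr, hr_ci = hr$ci,
    hr_iptw = hr_iptw$hr, hr_iptw_ci = hr_iptw$ci,
    arr = unname(point["arr"]), arr_ci = unname(cis[, "arr"]),
    arr_iptw = unname(point["arr_iptw"]), arr_iptw_ci = unname(cis[, "arr_iptw"]),
    drmst = unname(point["drmst"]), drmst_ci = unname(cis[, "drmst"]),
    drmst_iptw = unname(point["drmst_iptw"]),
    drmst_iptw_ci = unname(cis[, "drmst_iptw"]),
    logrank_p = lr$p, logrank_p_iptw = lr_iptw$p,
    weights = w),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Consis (n=%d) vs Inconsis (n=%d), horizon %g months\n",
              x$n_consis, x$n_inconsis, x$horizon))
  cat(sprintf("  HR %s  IPTW HR %s\n",
              fmt_hr_ci(x$hr, x$hr_ci), fmt_hr_ci(x$hr_iptw, x$hr_iptw_ci)))
  cat(sprintf("  DRMST %.2f (%.2f-%.2f)  IPTW DRMST %.2f (%.2f-%.2f) months\n",
              x$drmst, x$drmst_ci[1], x$drmst_ci[2],
              x$drmst_iptw, x$drmst_iptw_ci[1], x$drmst_iptw_ci[2]))
  cat(sprintf("  ARR %.1f (%.1f-%.1f)  IPTW ARR %.1f (%.1f-%.1f) %%\n",
              x$arr, x$arr_ci[1], x$arr_ci[2],
              x$arr_iptw, x$arr_iptw_ci[1], x$arr_iptw_ci[2]))
  cat(sprintf("  log-rank p %.3g  IPTW log-rank p %.3g\n",
              x$logrank_p, x$logrank_p_iptw))
  invisible(x)
}

fmt_hr_ci <- function(hr, ci) sprintf("%.2f (%.2f-%.2f)", hr, ci[1], ci[2])

#' Run one recommendation phase end to end
#'
#' Orchestrates the full analysis on one treatment contrast: generate (or
#' load) the cohort, split 70/30, optionally grid-search hyperparameters by
#' five-fold cross-validation on the training set, fit the chosen estimator,
#' predict counterfactual curves for the test set, convert to
#' restricted-survival-time ITEs and recommendations, and evaluate the
#' Consis/Inconsis contrast with and without IPTW. All artifacts are written
#' under \code{output_dir} when given.
#'
#' @param config list with fields: \code{generator} (a
#'   [generator_config()]) or \code{cohort_file} + \code{schema};
#'   \code{estimator} one of \code{"balanced"}, \code{"proportional-hazards"},
#'   \code{"survival-forest"}, \code{"oracle"}; \code{spec} (a
#'   [balanced_tlearner_spec()]) or \code{grid} (list of specs to tune);
#'   \code{horizon} (months, default 60); \code{test_fraction} (default 0.3);
#'   \code{seed}; optional \code{output_dir}; optional \code{threshold}
#'   (months of minimum benefit). The \code{"oracle"} estimator recommends by
#'   the sign of the generator's true ITE and requires a generated cohort.
#' @return list: \code{report} (an \code{eval_report}), \code{ite}
#'   (per-patient table on the test set), \code{model}, \code{split},
#'   \code{encoder}, and \code{log} (seed, stage timings, config hash).
#' @export
run_phase <- function(config) {
  cfg <- validate_run_config(config)
  log <- list(seed = cfg$seed, estimator = cfg$estimator,
              config_hash = config_hash(cfg), stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  data <- t_stage("load", {
    if (!is.null(cfg$generator)) generate_cohort(cfg$generator)
    else list(cohort = read_cohort(cfg$cohort_file, cfg$schema), truth = NULL)
  })
  cohort <- data$cohort
  schema <- if (!is.null(cfg$generator)) cfg$generator$covariate_schema else cfg$schema

  split <- t_stage("split",
                   train_test_split(cohort, cfg$test_fraction, cfg$seed))
  enc <- t_stage("encode", encode_covariates(split$train, schema))
  X_train <- enc$features
  X_test <- apply_encoder(enc$encoder, split$test)

  spec <- cfg$spec
  tuning <- NULL
  if (!is.null(cfg$grid) && cfg$estimator == "balanced") {
    tuning <- t_stage("tune", tune_hyperparameters(
      X_train, split$train$arm, split$train$time, split$train$event,
      cfg$grid, n_folds = cfg$n_folds, seed = cfg$seed))
    spec <- tuning$best_spec
  }

  model <- t_stage("fit", switch(
    cfg$estimator,
    "balanced" = fit_balanced_tlearner(X_train, split$train$arm,
                                       split$train$time, split$train$event,
                                       spec, encoder = enc$encoder),
    "proportional-hazards" = fit_benchmark_tlearner(
      "proportional-hazards", X_train, split$train$arm,
      split$train$time, split$train$event, encoder = enc$encoder),
    "survival-forest" = fit_benchmark_tlearner(
      "survival-forest", X_train, split$train$arm,
      split$train$time, split$train$event, encoder = enc$encoder,
      seed = cfg$seed),
    "oracle" = NULL))

  ite_tab <- t_stage("recommend", {
    if (cfg$estimator == "oracle") {
      if (is.null(data$truth))
        stop("the oracle estimator needs a generated cohort with ground truth")
      tr <- data$truth[match(split$test$patient_id, data$truth$patient_id), ]
      out <- data.frame(patient_id = split$test$patient_id,
                        rst_arm1 = NA_real_, rst_arm0 = NA_real_,
                        ite = tr$true_ite60)
      out$recommended_arm <- recommend(out$ite, cfg$threshold)$recommended_arm
      out$consistency <- concordance_grouping(split$test$arm, out$recommended_arm)
      out
    } else {
      grid <- default_grid(split$train$time, split$train$event, cfg$horizon)
      c1 <- predict_survival(model, X_test, 1L, grid)
      c0 <- predict_survival(model, X_test, 0L, grid)
      ite_results(split$test$patient_id, c1, c0, cfg$horizon,
                  actual_arms = split$test$arm, threshold = cfg$threshold)
    }
  })

  report <- t_stage("evaluate", evaluate_recommendations(
    split$test$time, split$test$event, ite_tab$consistency, X_test,
    horizon = cfg$horizon, seed = cfg$seed))

  result <- list(report = report, ite = ite_tab, model = model,
                 tuning = tuning, split = split, encoder = enc$encoder,
                 log = log)
  if (!is.null(cfg$output_dir))
    t_stage("write", write_report(result, cfg$output_dir))
  result
}

validate_run_config <- function(config) {
  defaults <- list(horizon = 60, test_fraction = 0.3, seed = 1L,
                   threshold = 0, n_folds = 5L, estimator = "balanced",
                   spec = NULL, grid = NULL, output_dir = NULL,
                   generator = NULL, cohort_file = NULL, schema = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$generator) && is.null(cfg$cohort_file))
    stop("config needs either `generator` or `cohort_file`", call. = FALSE)
  if (!cfg$estimator %in% c("balanced", "proportional-hazards",
                            "survival-forest", "oracle"))
    stop("unknown estimator: ", cfg$estimator, call. = FALSE)
  if (cfg$estimator == "balanced" && is.null(cfg$spec) && is.null(cfg$grid))
    cfg$spec <- balanced_tlearner_spec(seed = cfg$seed)
  if (!is.null(cfg$covariates)) {
    schema <- if (!is.null(cfg$generator)) cfg$generator$covariate_schema
              else cfg$schema
    missing_cov <- setdiff(cfg$covariates, names(schema))
    if (length(missing_cov))
      stop("config references covariate(s) absent from the schema: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  cfg
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("output_dir"))]
  s <- paste(utils::capture.output(utils::str(keep, digits.d = 10)),
             collapse = "\n")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Load a cohort file with schema validation
#'
#' Thin alias of [read_cohort()] matching the pipeline vocabulary.
#' @param path CSV path.
#' @param schema covariate schema.
#' @export
load_cohort <- function(path, schema = NULL) read_cohort(path, schema)

#' Write pipeline artifacts to a directory
#'
#' Writes the evaluation report as JSON, the per-patient ITE table as CSV,
#' a Table-2-style one-row metrics CSV, a plain-text summary (HRs to 2
#' decimals, percentages to 1), and a machine-readable run log naming the
#' seed and config hash.
#'
#' @param result a [run_phase()] result (or a list with the same fields).
#' @param output_dir directory, created if needed.
#' @param tables optional named list of extra data.frames (e.g. subgroup ATE
#'   or probability-difference tables), each written as \code{<name>.csv};
#'   an empty data.frame yields a header-only file.
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, output_dir, tables = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  r <- result$report
  paths <- character(0)

  report_list <- r[setdiff(names(r), "weights")]
  p <- file.path(output_dir, "eval_report.json")
  jsonlite::write_json(report_list, p, auto_unbox = TRUE, digits = 10)
  paths <- c(paths, p)

  if (!is.null(result$ite)) {
    p <- file.path(output_dir, "ite_results.csv")
    utils::write.csv(result$ite, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  tab <- data.frame(
    HR = fmt_num(r$hr, 2), HR_CI = fmt_ci(r$hr_ci, 2),
    IPTW_HR = fmt_num(r$hr_iptw, 2), IPTW_HR_CI = fmt_ci(r$hr_iptw_ci, 2),
    DRMST = fmt_num(r$drmst, 2), IPTW_DRMST = fmt_num(r$drmst_iptw, 2),
    ARR = fmt_num(r$arr, 1), IPTW_ARR = fmt_num(r$arr_iptw, 1),
    logrank_p = format.pval(r$logrank_p, digits = 3),
    IPTW_logrank_p = format.pval(r$logrank_p_iptw, digits = 3))
  p <- file.path(output_dir, "metrics_table.csv")
  utils::write.csv(tab, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(output_dir, "summary.txt")
  writeLines(utils::capture.output(print(r)), p)
  paths <- c(paths, p)

  if (!is.null(result$log)) {
    p <- file.path(output_dir, "run_log.json")
    jsonlite::write_json(result$log, p, auto_unbox = TRUE, digits = 10)
    paths <- c(paths, p)
  }
  for (nm in names(tables)) {
    p <- file.path(output_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)
fmt_ci <- function(ci, digits)
  paste0(fmt_num(ci[1], digits), "-", fmt_num(ci[2], digits))
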