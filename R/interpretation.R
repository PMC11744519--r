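#' Probability difference of being recommended a treatment
#'
#' The probability that a patient with a given characteristic is recommended
#' arm 1 minus the probability that a patient without it is — a risk
#' difference on the recommendation scale, in percentage points. The
#' IPTW-adjusted variant reweights by a propensity model for the
#' characteristic given the remaining covariates, removing the influence of
#' the other characteristics. Confidence intervals are percentile bootstrap
#' over patients.
#'
#' @param recommendations 0/1 vector of recommended arms.
#' @param characteristic_indicator 0/1 indicator of the characteristic; both
#'   strata must be non-empty.
#' @param adjust_features optional covariate matrix; when supplied the
#'   IPTW-adjusted PD is also computed.
#' @param n_boot bootstrap resamples for the CI (default 500).
#' @param conf_level confidence level.
#' @param seed bootstrap seed.
#' @return list: \code{pd}, \code{ci}, and (when adjusted)
#'   \code{pd_iptw}, \code{ci_iptw}; all in percentage points.
#' @export
probability_difference <- function(recommendations, characteristic_indicator,
                                   adjust_features = NULL, n_boot = 500L,
                                   conf_level = 0.95, seed = 1L) {
  r <- as.numeric(recommendations)
  c1 <- as.integer(characteristic_indicator)
  if (!all(c1 %in% c(0L, 1L)))
    stop("`characteristic_indicator` must be binary", call. = FALSE)
  for (v in 0:1)
    if (!any(c1 == v))
      stop(sprintf("stratum with characteristic = %d is empty", v), call. = FALSE)

  pd_stat <- function(r, c1, w) {
    100 * (sum(w * r * c1) / sum(w * c1) -
             sum(w * r * (1 - c1)) / sum(w * (1 - c1)))
  }
  n <- length(r)
  w1 <- rep(1, n)
  out <- list(pd = pd_stat(r, c1, w1))

  w_adj <- NULL
  if (!is.null(adjust_features)) {
    A <- as.matrix(adjust_features)
    # the propensity is for the characteristic given the *other* covariates:
    # drop columns that are (anti)perfect copies of the indicator itself
    keep <- vapply(seq_len(ncol(A)), function(j) {
      x <- A[, j]
      if (stats::sd(x) == 0) return(FALSE)
      abs(stats::cor(x, c1)) < 0.999
    }, logical(1))
    if (!all(keep))
      warning("dropping adjustment column(s) collinear with the characteristic: ",
              paste(colnames(A)[!keep], collapse = ", "))
    ps <- estimate_propensity(A[, keep, drop = FALSE], c1)
    w_adj <- compute_iptw_weights(ps)
    out$pd_iptw <- pd_stat(r, c1, w_adj)
  }

  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(c1[idx])) < 2) next
    boots[b, 1L] <- pd_stat(r[idx], c1[idx], w1[idx])
    if (!is.null(w_adj)) boots[b, 2L] <- pd_stat(r[idx], c1[idx], w_adj[idx])
  }
  alpha <- (1 - conf_level) / 2
  out$ci <- unname(stats::quantile(boots[, 1L], c(alpha, 1 - alpha), na.rm = TRUE))
  if (!is.null(w_adj))
    out$ci_iptw <- unname(stats::quantile(boots[, 2L], c(alpha, 1 - alpha),
                                          na.rm = TRUE))
  out
}

#' Probability differences for every level of a characteristic
#'
#' One-vs-rest [probability_difference()] per level of a categorical
#' covariate (e.g. tumor subsite), or per band of a banded continuous one.
#'
#' @param recommendations 0/1 recommended arms.
#' @param characteristic factor/character vector.
#' @param adjust_features optional covariates for the IPTW adjustment.
#' @param ... passed to [probability_difference()].
#' @return data.frame keyed by level with PD and CI columns.
#' @export
probability_difference_by_level <- function(recommendations, characteristic,
                                            adjust_features = NULL, ...) {
  lv <- if (is.factor(characteristic)) levels(characteristic)
        else sort(unique(characteristic))
  rows <- lapply(lv, function(l) {
    pd <- tryCatch(
      probability_difference(recommendations,
                             as.integer(characteristic == l),
                             adjust_features = adjust_features, ...),
      error = function(e) {
        warning(sprintf("level '%s' not estimable: %s", l,
                        conditionMessage(e)))
        list(pd = NA_real_, ci = c(NA_real_, NA_real_))
      })
    data.frame(level = l, pd = pd$pd,
               ci_lower = pd$ci[1], ci_upper = pd$ci[2],
               pd_iptw = if (is.null(pd$pd_iptw)) NA_real_ else pd$pd_iptw,
               ci_iptw_lower = if (is.null(pd$ci_iptw)) NA_real_ else pd$ci_iptw[1],
               ci_iptw_upper = if (is.null(pd$ci_iptw)) NA_real_ else pd$ci_iptw[2])
  })
  do.call(rbind, rows)
}

#' Age bands used for probability-difference reporting
#'
#' Default bands: [0, 30), [30, 60], (60, Inf).
#'
#' @param age numeric ages in years.
#' @param breaks interior band edges (default 30 and 60).
#' @return factor with one level per band.
#' @export
age_bands <- function(age, breaks = c(30, 60)) {
  cut(age, c(-Inf, breaks[1] - 1e-9, breaks[2], Inf),
      labels = c(sprintf("<%g", breaks[1]),
                 sprintf("%g-%g", breaks[1], breaks[2]),
                 sprintf(">%g", breaks[2])))
}

#' Mediation decomposition with the actual treatment as mediator
#'
#' Linear-probability-model mediation of the effect of following a
#' recommendation (exposure) on death within the horizon (outcome), treating
#' the actual treatment received as the mediator: the natural direct effect
#' (NDE) is the exposure slope in \code{outcome ~ exposure + mediator +
#' covariates}; the mediator path \code{a} comes from \code{mediator ~
#' exposure + covariates}; the natural indirect effect is \code{NIE = a * b}
#' with \code{b} the mediator slope in the outcome model. For these linear
#' estimators \code{NDE + NIE} equals the total-effect slope of the reduced
#' model exactly. CIs are percentile bootstrap.
#'
#' @param exposure binary (e.g. Consis membership).
#' @param mediator binary actual treatment.
#' @param outcome binary (death within horizon).
#' @param covariates optional baseline covariate matrix.
#' @param n_boot bootstrap resamples (default 200).
#' @param conf_level confidence level.
#' @param seed bootstrap seed.
#' @return list of class \code{mediation_result}: \code{nde}, \code{nie},
#'   \code{total}, their CIs, and the path coefficients \code{a}, \code{b}.
#' @export
mediation_nde_nie <- function(exposure, mediator, outcome, covariates = NULL,
                              n_boot = 200L, conf_level = 0.95, seed = 1L) {
  e <- as.numeric(as_binary_group(exposure))
  m <- as.numeric(mediator)
  y <- as.numeric(outcome)
  X <- if (is.null(covariates)) NULL else as.matrix(covariates)

  const_mediator <- stats::var(m) == 0
  if (const_mediator)
    warning("mediator is constant; NIE is 0 by construction")

  paths <- function(e, m, y, X) {
    D_out <- cbind(1, e, m, X)
    cf_out <- stats::lm.fit(D_out, y)$coefficients
    nde <- cf_out[2L]; b <- cf_out[3L]
    a <- if (stats::var(m) == 0) 0 else {
      D_med <- cbind(1, e, X)
      stats::lm.fit(D_med, m)$coefficients[2L]
    }
    b <- if (is.na(b)) 0 else b
    c(nde = unname(nde), a = unname(a), b = unname(b),
      nie = unname(a * ifelse(is.na(b), 0, b)))
  }
  est <- paths(e, m, y, X)

  set.seed(seed)
  n <- length(y)
  bt <- matrix(NA_real_, n_boot, 3L, dimnames = list(NULL, c("nde", "nie", "total")))
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- tryCatch(paths(e[idx], m[idx], y[idx],
                        if (is.null(X)) NULL else X[idx, , drop = FALSE]),
                  error = function(err) NULL)
    if (!is.null(p)) bt[bb, ] <- c(p["nde"], p["nie"], p["nde"] + p["nie"])
  }
  alpha <- (1 - conf_level) / 2
  qs <- function(col) unname(stats::quantile(bt[, col], c(alpha, 1 - alpha),
                                             na.rm = TRUE))
  structure(list(nde = est[["nde"]], nie = est[["nie"]],
                 total = est[["nde"]] + est[["nie"]],
                 a = est[["a"]], b = est[["b"]],
                 ci_nde = qs("nde"), ci_nie = qs("nie"), ci_total = qs("total")),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("NDE %.4f [%.4f, %.4f]; NIE %.4f [%.4f, %.4f]; total %.4f\n",
              x$nde, x$ci_nde[1], x$ci_nde[2],
              x$nie, x$ci_nie[1], x$ci_nie[2], x$total))
  invisible(x)
}

#' Subgroup average treatment effects
#'
#' Within each subgroup (and for the whole cohort), the hazard ratio of
#' actual treatment 1 versus 0, unweighted and IPTW-weighted with a
#' propensity model for the actual treatment fitted within the subgroup.
#' Opposite-signed subgroup HRs are the signature of a qualitative
#' interaction exploited by a recommender.
#'
#' @param times,events follow-up and event indicators.
#' @param actual_treatment 0/1 treatment received.
#' @param subgroup_labels factor partitioning the cohort (e.g. the
#'   recommended-arm groups).
#' @param features covariates for the IPTW propensity model.
#' @return data.frame with one row per subgroup plus an \code{Overall} row:
#'   HR, CI, IPTW HR, IPTW CI, and an estimability flag.
#' @export
subgroup_ate <- function(times, events, actual_treatment, subgroup_labels,
                         features) {
  sg <- as.factor(subgroup_labels)
  X <- as.matrix(features)
  one_row <- function(name, idx) {
    t_s <- times[idx]; e_s <- events[idx]; a_s <- actual_treatment[idx]
    ok0 <- sum(e_s[a_s == 0]) >= 1; ok1 <- sum(e_s[a_s == 1]) >= 1
    if (!(ok0 && ok1) || length(unique(a_s)) < 2)
      return(data.frame(subgroup = name, n = length(idx), hr = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        hr_iptw = NA_real_, ci_iptw_lower = NA_real_,
                        ci_iptw_upper = NA_real_, estimable = FALSE))
    un <- weighted_cox_hr(t_s, e_s, a_s)
    wts <- tryCatch({
      ps <- estimate_propensity(X[idx, , drop = FALSE], a_s)
      compute_iptw_weights(ps)
    }, error = function(e) rep(1, length(idx)))
    wt <- weighted_cox_hr(t_s, e_s, a_s, weights = wts)
    data.frame(subgroup = name, n = length(idx),
               hr = un$hr, ci_lower = un$ci[1], ci_upper = un$ci[2],
               hr_iptw = wt$hr, ci_iptw_lower = wt$ci[1],
               ci_iptw_upper = wt$ci[2], estimable = TRUE)
  }
  rows <- lapply(levels(sg), function(l) one_row(l, which(sg == l)))
  rows <- c(rows, list(one_row("Overall", seq_along(times))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
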