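#' Fit a propensity model for group membership
#'
#' Logistic regression of a binary group label (here usually membership in
#' the recommendation-consistent group, the "exposure" being weighted) on
#' covariates. Fitted probabilities are clipped away from 0 and 1 so that
#' downstream inverse weights stay finite.
#'
#' @param features numeric covariate matrix or data.frame.
#' @param group_labels binary vector/factor; the second level (or value 1) is
#'   modelled as the "exposed" group.
#' @param clip two probabilities; fitted values are clipped into this range.
#' @return object of class \code{propensity_fit}: coefficients, clipped
#'   fitted probabilities, and the exposure indicator.
#' @export
estimate_propensity <- function(features, group_labels, clip = c(0.01, 0.99)) {
  g <- as_binary_group(group_labels)
  if (length(unique(g)) < 2)
    stop("both groups must be non-empty", call. = FALSE)
  df <- data.frame(..g = g, as.data.frame(features))
  fit <- suppressWarnings(stats::glm(..g ~ ., data = df, family = stats::binomial()))
  p_raw <- stats::fitted(fit)
  if (!fit$converged || any(p_raw < 1e-8) || any(p_raw > 1 - 1e-8))
    if (any(p_raw < 1e-8 | p_raw > 1 - 1e-8))
      stop(paste("propensity model shows (near-)perfect separation;",
                 "remove or coarsen the offending covariate, or regularize"),
           call. = FALSE)
  structure(list(coefficients = stats::coef(fit),
                 probabilities = pmin(pmax(p_raw, clip[1]), clip[2]),
                 exposure = g),
            class = "propensity_fit")
}

as_binary_group <- function(g) {
  if (is.factor(g)) as.integer(g == levels(g)[2L])
  else if (is.logical(g)) as.integer(g)
  else as.integer(g == max(g))
}

#' Stabilized inverse probability of treatment weights
#'
#' Weight \eqn{P(G = g) / P(G = g \mid x)}: the marginal prevalence of the
#' subject's own group over their fitted propensity of being in it. Weights
#' are truncated at the given percentiles (1st/99th by default) to control
#' variance. Mean stabilized weight is approximately 1 within each group.
#'
#' @param fit a [estimate_propensity()] result covering all rows.
#' @param truncate_quantiles lower/upper truncation percentiles (0-1 scale);
#'   \code{NULL} disables truncation.
#' @return numeric vector of positive weights.
#' @export
compute_iptw_weights <- function(fit, truncate_quantiles = c(0.01, 0.99)) {
  stopifnot(inherits(fit, "propensity_fit"))
  g <- fit$exposure
  prev <- mean(g)
  p_own <- ifelse(g == 1L, fit$probabilities, 1 - fit$probabilities)
  prev_own <- ifelse(g == 1L, prev, 1 - prev)
  w <- prev_own / p_own
  if (!is.null(truncate_quantiles)) {
    qs <- stats::quantile(w, truncate_quantiles, names = FALSE)
    w <- pmin(pmax(w, qs[1]), qs[2])
  }
  w
}

#' Weighted Cox hazard ratio with robust confidence interval
#'
#' Weighted partial-likelihood fit of a binary group indicator, optionally
#' adjusted for further covariates ("multivariate HR"), with a robust
#' sandwich variance. At unit weights this is the ordinary (multivariate)
#' Cox model.
#'
#' @param times,events follow-up and event indicators.
#' @param group_labels binary group (the second factor level / value 1 is the
#'   numerator of the HR).
#' @param weights positive per-subject weights (default 1).
#' @param adjustment_covariates optional matrix/data.frame of additional
#'   covariates entered linearly.
#' @param conf_level confidence level (default 0.95).
#' @return list: \code{hr}, \code{ci} (2-vector), \code{log_hr}, \code{se},
#'   \code{p}, and the underlying \code{fit}.
#' @export
weighted_cox_hr <- function(times, events, group_labels, weights = NULL,
                            adjustment_covariates = NULL, conf_level = 0.95) {
  g <- as_binary_group(group_labels)
  if (length(unique(g)) < 2) stop("both groups must be non-empty", call. = FALSE)
  for (gg in 0:1)
    if (sum(events[g == gg]) < 1)
      stop(sprintf("no events in group %d; HR is not estimable", gg), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(times))
  df <- data.frame(time = times, event = events, ..group = g)
  if (!is.null(adjustment_covariates))
    df <- cbind(df, as.data.frame(adjustment_covariates))
  rhs <- paste(sprintf("`%s`", setdiff(names(df), c("time", "event"))),
               collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = df, weights = weights, robust = TRUE,
                         ties = "breslow")
  i <- match("..group", names(stats::coef(fit)))
  b <- unname(stats::coef(fit)[i])
  se <- sqrt(diag(fit$var))[i]   # robust (sandwich) variance
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(b), ci = exp(b + c(-1, 1) * z * se),
       log_hr = unname(b), se = unname(se),
       p = 2 * stats::pnorm(-abs(b / se)), fit = fit)
}

#' Weighted Kaplan-Meier survival curve
#'
#' Product-limit estimator with weighted event and at-risk counts:
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d^w_i / n^w_i)}. Equal weights
#' reproduce the classical Kaplan-Meier estimator exactly.
#'
#' @param times,events follow-up and event indicators.
#' @param weights positive weights (default 1).
#' @param grid optional evaluation grid; defaults to \code{c(0, sorted event
#'   times)}.
#' @return a [survival_curves()] object with one row.
#' @export
weighted_km <- function(times, events, weights = NULL, grid = NULL) {
  n <- length(times)
  if (!n) stop("empty input", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  et <- sort(unique(times[events == 1]))
  surv_at_events <- numeric(length(et))
  s <- 1
  for (k in seq_along(et)) {
    t0 <- et[k]
    dw <- sum(weights[times == t0 & events == 1])
    nw <- sum(weights[times >= t0])
    s <- s * (1 - dw / nw)
    surv_at_events[k] <- s
  }
  if (is.null(grid)) grid <- c(0, et)
  idx <- findInterval(grid + 1e-12, et)
  S <- c(1, surv_at_events)[idx + 1L]
  survival_curves(grid, matrix(pmax(S, 0), nrow = 1L))
}

#' Absolute risk reduction at a fixed horizon
#'
#' \eqn{100 \times (S_{\mathrm{consis}}(t^*) - S_{\mathrm{inconsis}}(t^*))}
#' in percentage points; 60 months (5 years) by default.
#'
#' @param km_consis,km_inconsis single-row [survival_curves()] covering the
#'   horizon.
#' @param horizon months.
#' @return ARR in percentage points.
#' @export
arr_5yr <- function(km_consis, km_inconsis, horizon = 60) {
  s_at <- function(km) {
    if (horizon > max(km$time)) stop("curve does not cover the horizon", call. = FALSE)
    km$surv[1L, findInterval(horizon + 1e-12, km$time[-1L]) + 1L]
  }
  100 * (s_at(km_consis) - s_at(km_inconsis))
}

#' Difference in restricted mean survival time
#'
#' \code{rst(km_consis) - rst(km_inconsis)} over the horizon, in months,
#' using the exact step-function integral of the product-limit curves.
#'
#' @inheritParams arr_5yr
#' @return DRMST in months (bounded by the horizon in magnitude).
#' @export
drmst <- function(km_consis, km_inconsis, horizon = 60) {
  km_rst(km_consis, horizon) - km_rst(km_inconsis, horizon)
}

# exact integral of a right-continuous step survival curve
km_rst <- function(km, horizon) {
  tt <- km$time; s <- km$surv[1L, ]
  if (horizon > max(tt)) stop("curve does not cover the horizon", call. = FALSE)
  keep <- tt < horizon
  t_sub <- c(tt[keep], horizon)
  s_sub <- s[keep]
  sum(diff(t_sub) * s_sub)
}

#' Weighted log-rank test
#'
#' Two-group log-rank chi-square with weighted event and at-risk counts.
#' Weights are normalized to mean 1 first, so the statistic is invariant to
#' rescaling all weights by a constant; unit weights reproduce the classical
#' test (as in \code{survival::survdiff}).
#'
#' @param times,events follow-up and event indicators.
#' @param group_labels binary group.
#' @param weights positive weights (default 1).
#' @return list: \code{statistic} (1 df chi-square), \code{p},
#'   \code{observed} and \code{expected} weighted event counts for group 1.
#' @export
weighted_logrank <- function(times, events, group_labels, weights = NULL) {
  g <- as_binary_group(group_labels)
  if (length(unique(g)) < 2) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(times))
  w <- weights / mean(weights)          # stabilized normalization
  et <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t0 in et) {
    at <- times >= t0
    d_all <- sum(w[times == t0 & events == 1])
    d1 <- sum(w[times == t0 & events == 1 & g == 1L])
    n_all <- sum(w[at]); n1 <- sum(w[at & g == 1L])
    if (n_all <= 0) next
    O1 <- O1 + d1
    E1 <- E1 + d_all * n1 / n_all
    if (n_all > 1)
      V <- V + d_all * (n1 / n_all) * (1 - n1 / n_all) *
        (n_all - d_all) / (n_all - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O1, expected = E1)
}

#' Cause-specific hazard ratio under competing risks
#'
#' Re-codes deaths from causes other than the cause of interest as censoring
#' at their event time, then fits the weighted Cox model of
#' [weighted_cox_hr()] (a marginal structural cause-specific model when IPTW
#' weights are supplied). The input table is not modified.
#'
#' @param times follow-up times.
#' @param causes character vector of causes (NA for censored subjects).
#' @param cause_of_interest the cause whose hazard is contrasted.
#' @param group_labels binary group.
#' @param weights optional weights.
#' @param adjustment_covariates optional extra covariates.
#' @return as [weighted_cox_hr()].
#' @export
cause_specific_hr <- function(times, causes, cause_of_interest, group_labels,
                              weights = NULL, adjustment_covariates = NULL) {
  ev <- as.integer(!is.na(causes) & causes == cause_of_interest)
  g <- as_binary_group(group_labels)
  for (gg in 0:1)
    if (sum(ev[g == gg]) < 1)
      stop(sprintf("no '%s' events in group %d", cause_of_interest, gg),
           call. = FALSE)
  weighted_cox_hr(times, ev, group_labels, weights, adjustment_covariates)
}

#' Random train/test split
#'
#' Simple random split reproducible from the seed; the test size is the
#' rounded fraction of n (e.g. 30% of 7,376 rows gives a 2,213-row test set).
#'
#' @param cohort data.frame.
#' @param test_fraction fraction in (0, 1) assigned to the test set.
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} data.frames.
#' @export
train_test_split <- function(cohort, test_fraction = 0.3, seed = 1L) {
  n <- nrow(cohort)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n)
    stop("split would leave an empty train or test set", call. = FALSE)
  set.seed(seed)
  test_idx <- sample.int(n, n_test)
  list(train = cohort[-test_idx, , drop = FALSE],
       test = cohort[test_idx, , drop = FALSE])
}

#' Standardized mean differences between two groups
#'
#' Balance diagnostic: for each column, the (weighted) mean difference
#' divided by the unweighted pooled standard deviation.
#'
#' @param features numeric matrix.
#' @param group_labels binary group.
#' @param weights optional weights.
#' @return named numeric vector of SMDs.
#' @export
standardized_mean_differences <- function(features, group_labels, weights = NULL) {
  g <- as_binary_group(group_labels)
  X <- as.matrix(features)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  wmean <- function(x, w) sum(w * x) / sum(w)
  apply(X, 2L, function(x) {
    m1 <- wmean(x[g == 1L], weights[g == 1L])
    m0 <- wmean(x[g == 0L], weights[g == 0L])
    s <- sqrt((stats::var(x[g == 1L]) + stats::var(x[g == 0L])) / 2)
    if (s == 0) 0 else (m1 - m0) / s
  })
}
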