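#' Grid-search hyperparameter tuning by k-fold cross-validation
#'
#' For every spec in the grid, trains on k-1 folds and records the Cox +
#' IPM loss on the held-out fold; the spec with the smallest mean validation
#' loss across folds wins. Fold assignment is deterministic given
#' \code{seed}. A grid point whose training fails (e.g. a divergent learning
#' rate) is recorded with infinite loss rather than aborting the search.
#'
#' @param features,arms,times,events training data (see
#'   [fit_balanced_tlearner()]).
#' @param grid a list of [balanced_tlearner_spec()] objects.
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer controlling the fold partition.
#' @return list with \code{best_spec}, \code{best_index}, and \code{report}
#'   (data.frame of per-grid-point, per-fold validation losses).
#' @export
tune_hyperparameters <- function(features, arms, times, events, grid,
                                 n_folds = 5L, seed = 1L) {
  if (!length(grid)) stop("`grid` must be non-empty", call. = FALSE)
  features <- as.matrix(features)
  n <- nrow(features)
  folds <- cv_folds(n, n_folds, seed)

  rows <- list()
  mean_loss <- numeric(length(grid))
  for (g in seq_along(grid)) {
    spec <- grid[[g]]
    losses <- vapply(seq_len(n_folds), function(k) {
      tr <- which(folds != k); va <- which(folds == k)
      fit <- tryCatch(
        fit_balanced_tlearner(
          features[tr, , drop = FALSE], arms[tr], times[tr], events[tr], spec,
          validation = list(features = features[va, , drop = FALSE],
                            arms = arms[va], times = times[va],
                            events = events[va])),
        error = function(e) NULL)
      if (is.null(fit)) Inf else fit$report$best_val_loss
    }, numeric(1))
    mean_loss[g] <- mean(losses)
    rows[[g]] <- data.frame(grid_index = g, fold = seq_len(n_folds),
                            val_loss = losses)
  }
  best <- which.min(mean_loss)
  if (!is.finite(mean_loss[best]))
    stop("every grid point failed to train", call. = FALSE)
  list(best_spec = grid[[best]], best_index = best,
       mean_loss = mean_loss, report = do.call(rbind, rows))
}

#' Deterministic k-fold partition
#'
#' @param n number of rows.
#' @param n_folds number of folds.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return integer vector of fold labels in 1..n_folds.
#' @export
cv_folds <- function(n, n_folds = 5L, seed = 1L) {
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Integrated Brier score with censoring weights
#'
#' Time-averaged squared error of predicted survival probabilities over
#' \code{[0, horizon]}, weighted by the inverse probability of censoring from
#' the Kaplan-Meier estimator of the censoring distribution \eqn{\hat G}:
#' \deqn{BS(t) = \frac{1}{n}\sum_i \frac{\hat S_i(t)^2\,1\{T_i \le t,
#'   \delta_i=1\}}{\hat G(T_i^-)} + \frac{(1-\hat S_i(t))^2\,1\{T_i >
#'   t\}}{\hat G(t)},} integrated over t by the trapezoid rule and divided by
#' the horizon. 0 is perfect; a constant prediction of 1/2 scores 0.25.
#'
#' @param curves a [survival_curves()] object (one row per subject), or any
#'   list with fields \code{time} and \code{surv} (so that unconstrained
#'   predictors, e.g. a constant 1/2 at every time, can be scored).
#' @param times,events observed follow-up and event indicators.
#' @param horizon upper end of integration (months); must not exceed the
#'   maximum observed time.
#' @return scalar IBS in [0, 1].
#' @export
integrated_brier_score <- function(curves, times, events, horizon = 60) {
  stopifnot(is.list(curves), !is.null(curves$time), !is.null(curves$surv))
  if (is.null(dim(curves$surv))) curves$surv <- matrix(curves$surv, nrow = 1L)
  n <- nrow(curves$surv)
  stopifnot(length(times) == n, length(events) == n)
  if (horizon > max(times))
    stop("`horizon` exceeds the maximum observed time", call. = FALSE)

  # KM of the censoring distribution (events reversed)
  gfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G_minus <- stats::stepfun(gfit$time, c(1, gfit$surv), right = TRUE)   # G(t-)
  G_right <- stats::stepfun(gfit$time, c(1, gfit$surv), right = FALSE)  # G(t)
  eval_t <- curves$time[curves$time <= horizon]
  if (max(eval_t) < horizon) eval_t <- c(eval_t, horizon)
  g_at <- G_right(eval_t)
  if (any(g_at <= 0)) {
    warning("censoring survival reaches 0 before the horizon; truncating integration")
    eval_t <- eval_t[g_at > 0]; g_at <- g_at[g_at > 0]
  }
  g_ti <- G_minus(times)

  Smat <- vapply(eval_t, function(t0) {
    idx <- findInterval(t0 + 1e-12, curves$time)
    curves$surv[, idx]
  }, numeric(n))
  if (is.null(dim(Smat))) Smat <- matrix(Smat, nrow = n)

  bs <- vapply(seq_along(eval_t), function(j) {
    t0 <- eval_t[j]; s <- Smat[, j]
    dead <- times <= t0 & events == 1
    alive <- times > t0
    w_dead <- ifelse(dead, 1 / pmax(g_ti, 1e-12), 0)
    w_alive <- ifelse(alive, 1 / g_at[j], 0)
    mean(s^2 * w_dead + (1 - s)^2 * w_alive)
  }, numeric(1))
  upper <- max(eval_t)
  sum(diff(eval_t) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / upper
}
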