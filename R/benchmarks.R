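#' Classical T-learner benchmarks
#'
#' Fits one survival model per treatment arm — a Cox proportional-hazards
#' model (\code{survival::coxph}) or a random survival forest
#' (\code{ranger}) — and wraps the pair behind the same
#' [predict_survival()] contract as the balanced T-learner, so the
#' restricted-survival-time ITE machinery is estimator-agnostic.
#'
#' @param method \code{"proportional-hazards"} or \code{"survival-forest"}.
#' @param features numeric feature matrix.
#' @param arms 0/1 treatment indicator.
#' @param times,events follow-up times (months) and event indicators; each
#'   arm needs >= 2 events.
#' @param encoder optional \code{covariate_encoder} stored with the model.
#' @param num_trees,max_depth forest size and depth (survival forest only;
#'   \code{max_depth = 0} means unlimited).
#' @param seed seed for the forest's bootstrap and split sampling.
#' @return object of class \code{counterfactual_model}.
#' @export
fit_benchmark_tlearner <- function(method = c("proportional-hazards",
                                              "survival-forest"),
                                   features, arms, times, events,
                                   encoder = NULL, num_trees = 200,
                                   max_depth = 0, seed = 1L) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  for (a in 0:1)
    if (sum(events[arms == a]) < 2)
      stop(sprintf("arm %d has fewer than 2 events", a), call. = FALSE)

  if (method == "proportional-hazards") {
    fits <- lapply(0:1, function(a) {
      ia <- arms == a
      df <- data.frame(time = times[ia], event = events[ia], features[ia, , drop = FALSE])
      rhs <- paste(sprintf("`%s`", setdiff(names(df), c("time", "event"))),
                   collapse = " + ")
      survival::coxph(stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
                      data = df, ties = "breslow")
    })
    coefs <- lapply(fits, stats::coef)
    baselines <- lapply(0:1, function(a) {
      ia <- arms == a
      eta <- drop(features[ia, , drop = FALSE] %*% coefs[[a + 1L]])
      breslow_baseline(eta, times[ia], events[ia])
    })
    structure(list(type = "coxph", coefs = coefs, fits = fits,
                   baselines = baselines, encoder = encoder),
              class = "counterfactual_model")
  } else {
    fits <- lapply(0:1, function(a) {
      ia <- arms == a
      df <- data.frame(features[ia, , drop = FALSE])
      ranger::ranger(y = survival::Surv(times[ia], events[ia]), x = df,
                     num.trees = num_trees, max.depth = max_depth,
                     seed = seed + a)
    })
    structure(list(type = "survival_forest", fits = fits,
                   feature_names = colnames(features), encoder = encoder),
              class = "counterfactual_model")
  }
}

# step-interpolate a forest's survival matrix onto a grid (right-continuous)
forest_curves_on_grid <- function(fit, newdata, grid) {
  pr <- stats::predict(fit, data = newdata)
  st <- pr$unique.death.times
  S <- pr$survival
  if (is.null(dim(S))) S <- matrix(S, nrow = nrow(newdata))
  idx <- findInterval(grid + 1e-12, st)
  out <- cbind(1, S)[, idx + 1L, drop = FALSE]
  # guard monotonicity against numeric fuzz
  out <- t(apply(out, 1L, cummin))
  survival_curves(grid, out)
}
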