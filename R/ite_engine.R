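#' Construct a set of per-patient survival curves
#'
#' A \code{survival_curves} object holds one predicted survival function per
#' patient on a common time grid starting at 0. Probabilities must lie in
#' [0, 1], start at 1, and be non-increasing along the grid.
#'
#' @param time numeric grid (months), strictly increasing, first element 0.
#' @param surv numeric matrix, patients in rows, grid points in columns.
#' @return object of class \code{survival_curves}.
#' @export
survival_curves <- function(time, surv) {
  if (is.null(dim(surv))) surv <- matrix(surv, nrow = 1L)
  if (length(time) != ncol(surv))
    stop("`time` length must match columns of `surv`", call. = FALSE)
  if (time[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (any(surv < -1e-12 | surv > 1 + 1e-12))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (any(abs(surv[, 1] - 1) > 1e-12)) stop("S(0) must equal 1", call. = FALSE)
  if (any(matrixStats_rowDiffs(surv) > 1e-10))
    stop("survival curves must be non-increasing", call. = FALSE)
  structure(list(time = as.numeric(time), surv = pmin(pmax(surv, 0), 1)),
            class = "survival_curves")
}

# row-wise diffs without a matrixStats dependency
matrixStats_rowDiffs <- function(m) {
  if (ncol(m) < 2L) return(matrix(0, nrow(m), 0))
  m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
}

#' @export
print.survival_curves <- function(x, ...) {
  cat(sprintf("survival_curves: %d patient(s), grid of %d time points on [0, %.4g] months\n",
              nrow(x$surv), length(x$time), max(x$time)))
  invisible(x)
}

#' Restricted survival time: area under a survival curve
#'
#' Integrates each patient's survival curve over [0, horizon] by the
#' trapezoidal rule, linearly interpolating the final partial interval when
#' the horizon falls between grid points. The result lies in [0, horizon] and
#' is read as expected months alive within the horizon.
#'
#' @param curves a [survival_curves()] object.
#' @param horizon months (> 0); must not exceed the grid's maximum.
#' @return numeric vector of per-patient RSTs (months).
#' @export
rst <- function(curves, horizon = 60) {
  stopifnot(inherits(curves, "survival_curves"))
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  tt <- curves$time
  if (horizon > max(tt) + 1e-9)
    stop("time grid does not cover the horizon", call. = FALSE)
  S <- curves$surv
  keep <- tt < horizon - 1e-12
  t_sub <- c(tt[keep], horizon)
  # interpolated survival at the horizon, per patient
  s_h <- apply(S, 1L, function(s) stats::approx(tt, s, xout = horizon, rule = 2)$y)
  S_sub <- cbind(S[, keep, drop = FALSE], s_h)
  dt <- diff(t_sub)
  mid <- (S_sub[, -1L, drop = FALSE] + S_sub[, -ncol(S_sub), drop = FALSE]) / 2
  drop(mid %*% dt)
}

#' Restricted-survival-time individual treatment effect
#'
#' \code{ite_rst} returns \code{rst(curves1) - rst(curves0)}: the additional
#' months a patient is expected to live within the horizon under arm 1
#' relative to arm 0.
#'
#' @param curves1,curves0 [survival_curves()] under arm 1 and arm 0 for the
#'   same patients.
#' @inheritParams rst
#' @return numeric vector of ITEs in months, each in [-horizon, horizon].
#' @export
ite_rst <- function(curves1, curves0, horizon = 60) {
  if (nrow(curves1$surv) != nrow(curves0$surv))
    stop("curve sets must cover the same patients", call. = FALSE)
  rst(curves1, horizon) - rst(curves0, horizon)
}

#' Per-patient treatment recommendations from ITEs
#'
#' Recommends arm 1 when the ITE is strictly positive and arm 0 otherwise
#' (ties, ITE = 0, go to the reference arm). An optional minimum-benefit
#' threshold (months) raises the bar for recommending arm 1.
#'
#' @param ite numeric vector of ITEs (months), or a data.frame containing an
#'   \code{ite} column.
#' @param threshold minimum benefit (months) needed to recommend arm 1;
#'   default 0.
#' @return list with \code{recommended_arm} (integer vector) and
#'   \code{summary} (counts per recommended arm).
#' @export
recommend <- function(ite, threshold = 0) {
  if (is.data.frame(ite)) ite <- ite$ite
  rec <- as.integer(ite > threshold)
  list(recommended_arm = rec,
       summary = c(`0` = sum(rec == 0L), `1` = sum(rec == 1L)))
}

#' Consistency grouping of actual versus recommended treatment
#'
#' Labels each patient \code{"Consis"} when the treatment actually received
#' equals the recommended arm and \code{"Inconsis"} otherwise. The weighted
#' survival contrast between these groups is the evaluation metric for a
#' recommender on observational data.
#'
#' @param actual_arms,recommended_arms integer vectors of equal length.
#' @return factor with levels \code{Inconsis}, \code{Consis}.
#' @export
concordance_grouping <- function(actual_arms, recommended_arms) {
  if (length(actual_arms) != length(recommended_arms))
    stop("`actual_arms` and `recommended_arms` must have equal length", call. = FALSE)
  factor(ifelse(actual_arms == recommended_arms, "Consis", "Inconsis"),
         levels = c("Inconsis", "Consis"))
}

#' Assemble a per-patient ITE results table
#'
#' @param patient_id identifiers.
#' @param curves1,curves0 per-arm [survival_curves()].
#' @param horizon restriction horizon (months).
#' @param actual_arms optional integer vector; when given, a consistency
#'   column is added.
#' @param threshold minimum-benefit threshold passed to [recommend()].
#' @return data.frame with columns \code{patient_id}, \code{rst_arm1},
#'   \code{rst_arm0}, \code{ite}, \code{recommended_arm} and optionally
#'   \code{consistency}.
#' @export
ite_results <- function(patient_id, curves1, curves0, horizon = 60,
                        actual_arms = NULL, threshold = 0) {
  r1 <- rst(curves1, horizon)
  r0 <- rst(curves0, horizon)
  out <- data.frame(patient_id = patient_id, rst_arm1 = r1, rst_arm0 = r0,
                    ite = r1 - r0)
  out$recommended_arm <- recommend(out$ite, threshold)$recommended_arm
  if (!is.null(actual_arms))
    out$consistency <- concordance_grouping(actual_arms, out$recommended_arm)
  out
}

#' Default integration grid for step-function survival curves
#'
#' Union of the observed event times in both arms with a uniform monthly
#' grid, so Breslow step functions integrate exactly under the trapezoid
#' rule between steps.
#'
#' @param times observed times (months).
#' @param events event indicators.
#' @param horizon months; grid extends to at least the horizon.
#' @return increasing numeric grid starting at 0.
#' @export
default_grid <- function(times, events, horizon = 60) {
  sort(unique(c(seq(0, ceiling(horizon), by = 1),
                times[events == 1 & times <= horizon], horizon)))
}
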