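#' Negative log Cox partial likelihood (Breslow ties), averaged over events
#'
#' The training objective of each risk head. For log-risks \eqn{\eta_j},
#' observed times and event indicators, returns
#' \deqn{-\frac{1}{D}\sum_{i: \delta_i = 1}\Big[\eta_i -
#'   \log \sum_{j: t_j \ge t_i} e^{\eta_j}\Big],}
#' with \eqn{D} the number of events and tied event times sharing the full
#' risk set (Breslow). The loss is invariant to adding a constant to all
#' log-risks; that constant is absorbed by the baseline hazard.
#'
#' @param log_risks numeric vector \eqn{\eta}.
#' @param times positive observed times.
#' @param events 0/1 event indicators; at least one event required.
#' @param gradient logical; when \code{TRUE} the gradient with respect to
#'   \code{log_risks} is attached as attribute \code{"gradient"}.
#' @return scalar loss (with optional gradient attribute).
#' @export
cox_partial_likelihood_loss <- function(log_risks, times, events,
                                        gradient = FALSE) {
  d_total <- sum(events)
  if (d_total < 1)
    stop("Cox partial likelihood is undefined with zero events", call. = FALSE)
  n <- length(log_risks)
  stopifnot(length(times) == n, length(events) == n)

  ord <- order(times)
  eta <- log_risks[ord]; tt <- times[ord]; ev <- events[ord]
  w <- exp(eta)
  # risk-set sums: sum over t_j >= t_i, tie groups share the first index's value
  cs <- rev(cumsum(rev(w)))
  first_of_tie <- match(tt, tt)           # index of first occurrence of each time
  riskset <- cs[first_of_tie]
  loss <- -sum(ev * (eta - log(riskset))) / d_total

  if (gradient) {
    r <- ev / riskset
    a <- cumsum(r)
    # within a tie group every member is at risk for that group's events:
    # use the cumulative value at the group's last index
    last_of_tie <- (n + 1L) - match(tt, rev(tt))
    a <- a[last_of_tie]
    g_sorted <- -(ev - w * a) / d_total
    g <- numeric(n); g[ord] <- g_sorted
    attr(loss, "gradient") <- g
  }
  loss
}

#' Breslow estimator of the baseline cumulative hazard
#'
#' \deqn{\hat H_0(t) = \sum_{t_i \le t} \frac{d_i}{\sum_{j \in R(t_i)}
#'   e^{\eta_j}},} a right-continuous non-decreasing step function starting at
#' 0, where \eqn{d_i} counts events at \eqn{t_i} and \eqn{R(t_i)} is the risk
#' set. Combined with a risk head's log-risks it converts relative hazards
#' into absolute survival curves.
#'
#' @inheritParams cox_partial_likelihood_loss
#' @return list with sorted unique event \code{time}s and the cumulative
#'   \code{hazard} at each (class \code{breslow_baseline}).
#' @export
breslow_baseline <- function(log_risks, times, events) {
  n <- length(log_risks)
  stopifnot(length(times) == n, length(events) == n, all(times > 0))
  ord <- order(times)
  tt <- times[ord]; ev <- events[ord]; w <- exp(log_risks[ord])
  cs <- rev(cumsum(rev(w)))
  first_of_tie <- match(tt, tt)
  riskset <- cs[first_of_tie]
  et <- unique(tt[ev == 1])
  if (!length(et))
    return(structure(list(time = numeric(0), hazard = numeric(0)),
                     class = "breslow_baseline"))
  d <- vapply(et, function(t0) sum(ev[tt == t0]), numeric(1))
  denom <- riskset[match(et, tt)]
  structure(list(time = et, hazard = cumsum(d / denom)),
            class = "breslow_baseline")
}

# evaluate a breslow_baseline at arbitrary times (right-continuous)
eval_baseline <- function(baseline, t) {
  if (!length(baseline$time)) return(rep(0, length(t)))
  idx <- findInterval(t + 1e-12, baseline$time)
  c(0, baseline$hazard)[idx + 1L]
}

#' Survival curves from a baseline hazard and log-risks
#'
#' \eqn{S(t \mid x) = \exp\{-\hat H_0(t)\, e^{\eta(x)}\}} on the requested
#' grid.
#'
#' @param baseline a [breslow_baseline()].
#' @param log_risks per-patient \eqn{\eta}.
#' @param grid time grid starting at 0.
#' @return a [survival_curves()] object.
#' @export
baseline_survival <- function(baseline, log_risks, grid) {
  H <- eval_baseline(baseline, grid)
  S <- exp(-outer(exp(log_risks), H))
  survival_curves(grid, S)
}
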