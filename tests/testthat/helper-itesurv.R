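# Shared fixture builders; everything is generated in code.

# exponential survival curves S(t) = exp(-hazard * t) on a dense monthly grid
exp_curves <- function(hazards, t_max = 120, by = 0.25) {
  grid <- seq(0, t_max, by = by)
  S <- t(vapply(hazards, function(h) exp(-h * grid), numeric(length(grid))))
  survival_curves(grid, S)
}

# two-arm exponential cohort with a known hazard ratio for the group contrast
exp_two_group <- function(n_per, hr, base_rate = 0.02, cens_rate = 0.005,
                          seed = 1) {
  set.seed(seed)
  g <- rep(0:1, each = n_per)
  rate <- base_rate * ifelse(g == 1, hr, 1)
  tte <- stats::rexp(2 * n_per, rate)
  cens <- pmin(stats::rexp(2 * n_per, cens_rate), 180)
  list(time = pmin(tte, cens), event = as.integer(tte <= cens), group = g)
}

# small linear proportional-hazards dataset with separate per-arm coefficients
linear_ph_data <- function(n, beta0, beta1, base_rate = 0.02,
                           cens_rate = 0.008, seed = 1, confounded = TRUE) {
  set.seed(seed)
  p <- length(beta0)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  lp_arm <- if (confounded) 0.6 * X[, 1] else rep(0, n)
  arm <- stats::rbinom(n, 1, stats::plogis(lp_arm))
  eta <- ifelse(arm == 1, drop(X %*% beta1), drop(X %*% beta0))
  tte <- stats::rexp(n, base_rate * exp(eta))
  cens <- pmin(stats::rexp(n, cens_rate), 180)
  list(X = X, arm = arm, time = pmin(tte, cens),
       event = as.integer(tte <= cens), eta0 = drop(X %*% beta0),
       eta1 = drop(X %*% beta1))
}

# fast linear spec for tests that need a correctly specified learner
linear_spec <- function(...) {
  args <- utils::modifyList(
    list(shared_layers = integer(0), head_layers = integer(0), dropout = 0,
         balance_weight = 0, learning_rate = 0.05, batch_size = Inf,
         max_steps = 1200L, patience_steps = 300L, eval_every = 50L,
         l2_weight = 0, seed = 3L),
    list(...))
  do.call(balanced_tlearner_spec, args)
}
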