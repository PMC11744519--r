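test_that("alpha = 0 linear learner recovers per-arm Cox coefficients", {
  d <- linear_ph_data(3000, beta0 = c(0.5, -0.3, 0.2),
                      beta1 = c(0.2, 0.3, -0.4), seed = 7)
  fit <- fit_balanced_tlearner(d$X, d$arm, d$time, d$event, linear_spec())
  for (a in 0:1) {
    w <- drop(fit$params[[paste0("head", a)]][[1]]$W)
    ia <- d$arm == a
    oracle <- coef(survival::coxph(
      survival::Surv(d$time[ia], d$event[ia]) ~ d$X[ia, ], ties = "breslow"))
    expect_lt(max(abs(w - oracle)), 0.15)
  }
  # predicted risk ranks agree with the independent per-arm fits
  eta <- itesurv:::tlearner_predict_eta(fit$params, fit$spec, d$X)
  cox0 <- coef(survival::coxph(
    survival::Surv(d$time[d$arm == 0], d$event[d$arm == 0]) ~
      d$X[d$arm == 0, ], ties = "breslow"))
  expect_gt(cor(eta[[1]], drop(d$X %*% cox0), method = "spearman"), 0.98)
})

test_that("training is deterministic under a fixed seed", {
  d <- linear_ph_data(400, beta0 = c(0.4, -0.2), beta1 = c(0.1, 0.3), seed = 2)
  spec <- linear_spec(max_steps = 200L, patience_steps = 100L)
  f1 <- fit_balanced_tlearner(d$X, d$arm, d$time, d$event, spec)
  f2 <- fit_balanced_tlearner(d$X, d$arm, d$time, d$event, spec)
  expect_identical(f1$report$best_val_loss, f2$report$best_val_loss)
  expect_identical(f1$params, f2$params)
})

test_that("the penalty vanishes on identical arm representations", {
  set.seed(5)
  X <- rbind(diag(3), diag(3))            # arm 0 rows == arm 1 rows
  arms <- rep(0:1, each = 3)
  times <- rep(c(1, 2, 3), 2); events <- rep(1, 6)
  spec0 <- balanced_tlearner_spec(shared_layers = 4L, head_layers = integer(0),
                                  dropout = 0, balance_weight = 0, seed = 9)
  specA <- balanced_tlearner_spec(shared_layers = 4L, head_layers = integer(0),
                                  dropout = 0, balance_weight = 5, seed = 9)
  set.seed(9)
  params <- list(encoder = itesurv:::mlp_init(c(3, 4)),
                 head0 = itesurv:::mlp_init(c(4, 1)),
                 head1 = itesurv:::mlp_init(c(4, 1)))
  l0 <- itesurv:::tlearner_batch(params, X, arms, times, events, spec0)$loss
  lA <- itesurv:::tlearner_batch(params, X, arms, times, events, specA)$loss
  expect_equal(l0, lA, tolerance = 1e-9)
})

test_that("training aborts with diagnostics when the loss diverges", {
  d <- linear_ph_data(200, beta0 = 0.3, beta1 = -0.3, seed = 4)
  spec <- linear_spec(learning_rate = 500, max_steps = 400L,
                      patience_steps = 400L)
  expect_error(fit_balanced_tlearner(d$X, d$arm, d$time, d$event, spec),
               "diverged")
})

test_that("fewer than two events per arm is rejected", {
  d <- linear_ph_data(50, beta0 = 0.3, beta1 = -0.3, seed = 4)
  ev <- d$event; ev[d$arm == 1] <- 0
  expect_error(fit_balanced_tlearner(d$X, d$arm, d$time, ev, linear_spec()),
               "fewer than 2 events")
})

test_that("increasing the balance weight shrinks the representation imbalance", {
  d <- linear_ph_data(600, beta0 = c(0.5, -0.3), beta1 = c(0.2, 0.3),
                      seed = 6, confounded = TRUE)
  pens <- vapply(c(0, 10), function(a) {
    spec <- balanced_tlearner_spec(
      shared_layers = 8L, head_layers = integer(0), dropout = 0,
      balance_weight = a, ipm_kind = "mmd-rbf", learning_rate = 0.01,
      batch_size = Inf, max_steps = 400L, patience_steps = 150L,
      eval_every = 25L, seed = 13)
    fit <- fit_balanced_tlearner(d$X, d$arm, d$time, d$event, spec)
    rep_all <- itesurv:::mlp_forward(fit$params$encoder, d$X,
                                     act_last = TRUE)$out
    as.numeric(ipm_penalty(rep_all[d$arm == 0, ], rep_all[d$arm == 1, ],
                           "mmd-rbf"))
  }, numeric(1))
  expect_lt(pens[2], pens[1])
})

test_that("benchmark T-learners honour the shared prediction contract", {
  d <- linear_ph_data(1200, beta0 = c(0.5, -0.3), beta1 = c(0.2, 0.3), seed = 3)
  grid <- default_grid(d$time, d$event, 60)

  cox <- fit_benchmark_tlearner("proportional-hazards", d$X, d$arm,
                                d$time, d$event)
  rf <- fit_benchmark_tlearner("survival-forest", d$X, d$arm, d$time,
                               d$event, num_trees = 25, seed = 2)
  set.seed(31)
  idx <- sample.int(nrow(d$X), 100)
  for (model in list(cox, rf)) {
    for (a in 0:1) {
      cur <- predict_survival(model, d$X[idx, , drop = FALSE], a, grid)
      expect_s3_class(cur, "survival_curves")   # constructor enforces S(0)=1,
      expect_true(all(diff(cur$time) > 0))      # monotone non-increasing rows
    }
  }
})

test_that("a depth-1 single-tree forest predicts one curve per leaf", {
  d <- linear_ph_data(300, beta0 = c(0.8), beta1 = c(-0.8), seed = 5)
  rf <- fit_benchmark_tlearner("survival-forest", d$X, d$arm, d$time, d$event,
                               num_trees = 1, max_depth = 1, seed = 7)
  grid <- default_grid(d$time, d$event, 60)
  cur <- predict_survival(rf, d$X, 0L, grid)
  expect_lte(nrow(unique(cur$surv)), 2)
})

test_that("proportional-hazards benchmark recovers generator coefficients", {
  cfg <- default_scenario(n_patients = 10000, seed = 17)
  d <- generate_cohort(cfg)
  X <- itesurv:::centre_generator_design(
    itesurv:::generator_design(d$cohort, cfg$covariate_schema))
  fit <- fit_benchmark_tlearner("proportional-hazards", X, d$cohort$arm,
                                d$cohort$time, d$cohort$event)
  expect_lt(max(abs(fit$coefs[[1]] - cfg$main_effects)), 0.1)
  expect_lt(max(abs(fit$coefs[[2]] -
                      (cfg$main_effects + cfg$interaction_effects))), 0.1)
})
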