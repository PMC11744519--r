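test_that("propensity model: null case, 2x2 closed form, duplication invariance", {
  set.seed(1)
  X <- matrix(rnorm(2000), ncol = 1)
  g <- rbinom(2000, 1, 0.5)
  fit <- estimate_propensity(X, g)
  # null model: fitted probabilities concentrate at the prevalence
  expect_lt(abs(mean(fit$probabilities) - 0.5), 0.03)
  expect_gt(mean(abs(fit$probabilities - 0.5) < 0.05), 0.95)

  x <- rbinom(4000, 1, 0.5)
  g2 <- rbinom(4000, 1, plogis(-0.4 + 0.9 * x))
  f2 <- estimate_propensity(matrix(x, ncol = 1), g2)
  tab <- table(x, g2)
  log_or <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  expect_equal(unname(f2$coefficients[2]), log_or, tolerance = 1e-6)

  dup <- estimate_propensity(rbind(X, X), c(g, g))
  expect_equal(unname(dup$coefficients), unname(fit$coefficients),
               tolerance = 1e-6)
})

test_that("perfect separation is reported as an error", {
  x <- c(rep(0, 20), rep(1, 20))
  expect_error(estimate_propensity(matrix(x, ncol = 1), x), "separation")
})

test_that("stabilized weights have the stated arithmetic and bounds", {
  set.seed(2)
  X <- matrix(rnorm(1000), ncol = 1)
  g <- rbinom(1000, 1, 0.5)
  fit <- estimate_propensity(X, g)

  # all probabilities equal to prevalence -> all weights 1
  null_fit <- fit
  null_fit$probabilities <- rep(mean(g), 1000)
  expect_equal(compute_iptw_weights(null_fit, NULL), rep(1, 1000))

  # one exposed subject with propensity 0.25 at prevalence 0.5 -> weight 2
  toy <- structure(list(probabilities = c(0.25, 0.5), exposure = c(1L, 0L)),
                   class = "propensity_fit")   # prevalence 0.5
  w_toy <- compute_iptw_weights(toy, NULL)
  expect_equal(w_toy[1], 2.0)

  w <- compute_iptw_weights(fit)
  expect_true(all(w > 0 & is.finite(w)))
  w_un <- compute_iptw_weights(fit, NULL)
  qs <- quantile(w_un, c(0.01, 0.99), names = FALSE)
  expect_true(all(w >= qs[1] - 1e-12 & w <= qs[2] + 1e-12))
  # mean stabilized weight near 1 within each group
  expect_lt(abs(mean(w_un[g == 1]) - 1), 0.1)
  expect_lt(abs(mean(w_un[g == 0]) - 1), 0.1)
})

test_that("weighted Cox: null case, ground-truth HR, and weight invariances", {
  # two identical copies of the same data -> HR exactly 1
  set.seed(3)
  tt <- rexp(100, 0.05); ev <- rbinom(100, 1, 0.8)
  hr_null <- weighted_cox_hr(c(tt, tt), c(ev, ev), rep(0:1, each = 100))
  expect_equal(hr_null$hr, 1, tolerance = 1e-6)

  d <- exp_two_group(2500, hr = 0.5, seed = 4)
  est <- weighted_cox_hr(d$time, d$event, d$group)
  expect_gt(est$ci[1], 0.4); expect_lt(est$ci[2], 0.65)
  expect_true(est$hr > est$ci[1] && est$hr < est$ci[2])
  expect_lt(log(est$ci[2]) - log(est$ci[1]), 0.2)

  # rescaling all weights leaves the HR unchanged
  w <- runif(length(d$time), 0.5, 2)
  a <- weighted_cox_hr(d$time, d$event, d$group, weights = w)
  b <- weighted_cox_hr(d$time, d$event, d$group, weights = 3 * w)
  expect_equal(a$hr, b$hr, tolerance = 1e-9)

  ev0 <- d$event; ev0[d$group == 1] <- 0
  expect_error(weighted_cox_hr(d$time, ev0, d$group), "no events")
})

test_that("weighted KM reduces to classical KM and handles small cases", {
  set.seed(5)
  tt <- rexp(150, 0.04); ev <- rbinom(150, 1, 0.7)
  km <- weighted_km(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  et <- sort(unique(tt[ev == 1]))
  expect_equal(km$surv[1, -1], summary(sf, times = et)$surv,
               tolerance = 1e-12, ignore_attr = TRUE)

  solo <- weighted_km(5, 1, grid = c(0, 2, 5, 8))
  expect_equal(solo$surv[1, ], c(1, 1, 0, 0))

  # 4-subject weighted case against a hand product over event times
  t4 <- c(1, 2, 3, 4); e4 <- c(1, 1, 0, 1); w4 <- c(2, 1, 1, 3)
  km4 <- weighted_km(t4, e4, w4, grid = c(0, 1, 2, 4))
  hand <- c(1,
            1 - 2 / 7,
            (1 - 2 / 7) * (1 - 1 / 5),
            (1 - 2 / 7) * (1 - 1 / 5) * (1 - 3 / 3))
  expect_equal(km4$surv[1, ], hand, tolerance = 1e-12)
})

test_that("ARR and DRMST follow their defining arithmetic", {
  grid <- seq(0, 70, 1)
  flat <- function(s_end) {
    # linear decline to s_end at t = 60, then flat
    s <- pmax(1 - (1 - s_end) * pmin(grid, 60) / 60, s_end)
    survival_curves(grid, matrix(s, 1))
  }
  a <- flat(0.60); b <- flat(0.45)
  expect_equal(arr_5yr(a, b, 60), 15, tolerance = 1e-9)
  expect_equal(arr_5yr(b, a, 60), -15, tolerance = 1e-9)
  expect_equal(arr_5yr(a, a, 60), 0)
  expect_equal(drmst(a, a, 60), 0)
  expect_lte(abs(drmst(a, b, 60)), 60)

  # KM limits of two exponential arms approach the closed-form DRMST
  set.seed(6)
  n <- 20000
  t1 <- rexp(n, 0.01); t0 <- rexp(n, 0.02)
  k1 <- weighted_km(t1, rep(1, n)); k0 <- weighted_km(t0, rep(1, n))
  expect_equal(drmst(k1, k0, 60), 10.1785, tolerance = 0.4)
})

test_that("weighted log-rank reduces to survdiff and is scale invariant", {
  set.seed(7)
  d <- exp_two_group(120, hr = 0.6, seed = 7)
  lr <- weighted_logrank(d$time, d$event, d$group)
  sd_ <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$group)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-9)

  # identical groups: zero statistic, p = 1
  tt <- rexp(50, 0.05); ev <- rbinom(50, 1, 0.8)
  lr0 <- weighted_logrank(c(tt, tt), c(ev, ev), rep(0:1, each = 50))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  w <- runif(length(d$time), 0.5, 2)
  a <- weighted_logrank(d$time, d$event, d$group, w)
  b <- weighted_logrank(d$time, d$event, d$group, 2 * w)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("cause-specific HRs isolate the affected cause", {
  # single cause present: reduces to the all-cause HR
  d <- exp_two_group(400, hr = 0.6, seed = 8)
  causes <- ifelse(d$event == 1, "primary", NA)
  cs <- cause_specific_hr(d$time, causes, "primary", d$group)
  ac <- weighted_cox_hr(d$time, d$event, d$group)
  expect_equal(cs$hr, ac$hr, tolerance = 1e-12)

  # group affects only cause A; cause B stays near null
  set.seed(9)
  n <- 5000
  g <- rep(0:1, each = n / 2)
  tA <- rexp(n, 0.02 * ifelse(g == 1, 0.5, 1))
  tB <- rexp(n, 0.01)
  cens <- rep(120, n)
  tmin <- pmin(tA, tB, cens)
  cause <- ifelse(tmin == cens, NA, ifelse(tA <= tB, "A", "B"))
  input <- data.frame(t = tmin, cause = cause, g = g)
  before <- input
  hrA <- cause_specific_hr(input$t, input$cause, "A", input$g)
  hrB <- cause_specific_hr(input$t, input$cause, "B", input$g)
  expect_lt(hrA$ci[2], 0.6)
  expect_lt(abs(log(hrB$hr)), 0.15)   # cause-B hazard untouched by the group
  expect_identical(input, before)   # purity: inputs untouched
})

test_that("train/test split sizes and reproducibility", {
  big <- data.frame(id = seq_len(7376))
  sp <- train_test_split(big, 0.3, seed = 1)
  expect_identical(nrow(sp$test), 2213L)
  expect_identical(nrow(sp$train), 5163L)

  small <- data.frame(id = 1:10)
  expect_identical(nrow(train_test_split(small, 0.3, seed = 2)$test), 3L)

  s1 <- train_test_split(big, 0.3, seed = 5)
  s2 <- train_test_split(big, 0.3, seed = 5)
  expect_identical(s1$test$id, s2$test$id)
  expect_error(train_test_split(small, 1.2), "\\(0, 1\\)")
})

test_that("IPTW restores covariate balance under injected confounding", {
  set.seed(10)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
  g <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.6 * X[, 2] + 0.7 * X[, 3]))
  smd_before <- standardized_mean_differences(X, g)
  expect_gt(max(abs(smd_before)), 0.1)
  w <- compute_iptw_weights(estimate_propensity(X, g))
  smd_after <- standardized_mean_differences(X, g, w)
  expect_lt(max(abs(smd_after)), 0.1)
})
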