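test_that("generation is deterministic and respects basic contracts", {
  cfg <- default_scenario(n_patients = 500, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  ch <- a$cohort
  expect_true(all(ch$time > 0))
  expect_true(all(ch$arm %in% 0:1))
  expect_true(all(ch$event %in% 0:1))
  expect_false(anyNA(ch[setdiff(names(ch), "cause")]))
  # events carry a cause, censored rows do not
  expect_true(all(!is.na(ch$cause[ch$event == 1])))
  expect_true(all(is.na(ch$cause[ch$event == 0])))
  expect_true(all(ch$time <= cfg$admin_horizon))
})

test_that("null treatment effect gives identically zero true ITE", {
  cfg <- default_scenario(n_patients = 200, seed = 7,
                          treatment_effect = 0,
                          interaction_effects = rep(0, 6))
  d <- generate_cohort(cfg)
  expect_equal(d$truth$true_ite60, rep(0, 200), tolerance = 1e-10)
})

test_that("zero propensity coefficients give a half/half allocation", {
  cfg <- default_scenario(n_patients = 10000, seed = 3,
                          propensity_intercept = 0,
                          propensity_coefficients = rep(0, 6))
  d <- generate_cohort(cfg)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(d$cohort$arm) - 0.5), 3 * se)
  expect_equal(d$truth$propensity, rep(0.5, 10000))
})

test_that("true RST ITE matches the exponential closed form", {
  # shape 1, scale lambda: hazard e^eta / lambda; pick etas so hazards are
  # 0.01 and 0.02 per month
  truth <- data.frame(eta0 = log(0.02 * 50), eta1 = log(0.01 * 50))
  ite <- true_ite_rst(truth, horizon = 60, shape = 1, scale = 50)
  closed <- (1 - exp(-0.01 * 60)) / 0.01 - (1 - exp(-0.02 * 60)) / 0.02
  expect_equal(ite, closed, tolerance = 1e-3)
  expect_equal(closed, 10.1785, tolerance = 1e-3)

  # identical hazards: zero; swapped arms: sign flip
  same <- data.frame(eta0 = 0.3, eta1 = 0.3)
  expect_equal(true_ite_rst(same, 60, 1.4, 80), 0, tolerance = 1e-12)
  sw <- true_ite_rst(data.frame(eta0 = truth$eta1, eta1 = truth$eta0),
                     60, 1, 50)
  expect_equal(sw, -ite, tolerance = 1e-9)
})

test_that("configuration errors are caught", {
  expect_error(default_scenario(n_patients = 0), "positive")
  expect_error(default_scenario(n_patients = 10, baseline_shape = -1), "positive")
  expect_error(default_scenario(n_patients = 10, censor_rate = -0.1), ">= 0")
  expect_error(default_scenario(n_patients = 10,
                                main_effects = c(1, 2)), "length")
})

test_that("covariate encoding: reference coding, standardization, errors", {
  schema <- list(size = "continuous", site = c("a", "b", "c"))
  df <- data.frame(size = c(1, 2, 3, 10), site = c("a", "b", "c", "b"))
  enc <- encode_covariates(df, schema)
  expect_equal(colnames(enc$features), c("size", "site.b", "site.c"))
  expect_equal(mean(enc$features[, "size"]), 0, tolerance = 1e-9)
  expect_equal(sd(enc$features[, "size"]), 1, tolerance = 1e-9)

  # encoder re-applies the training mean/sd, not the new data's
  new <- data.frame(size = c(100, 200), site = c("a", "c"))
  f2 <- apply_encoder(enc$encoder, new)
  expect_equal(f2[, "size"], (c(100, 200) - mean(df$size)) / sd(df$size))

  expect_error(apply_encoder(enc$encoder,
                             data.frame(size = 1, site = "zz")), "zz")
  expect_error(encode_covariates(data.frame(size = rep(5, 4), site = "a"),
                                 schema), "zero variance")
})

test_that("censoring and per-arm hazard structure are recovered at n = 10,000", {
  cfg <- default_scenario(n_patients = 10000, seed = 21, censor_rate = 0.01,
                          admin_horizon = 1e6)
  d <- generate_cohort(cfg)
  # KM of the censoring distribution should match exponential rate 0.01
  cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = d$cohort)
  at <- c(20, 50, 100)
  km_c <- summary(cf, times = at)$surv
  expect_equal(km_c, exp(-0.01 * at), tolerance = 0.03)

  # correctly specified per-arm Cox fits recover the log-hazard coefficients
  X <- itesurv:::centre_generator_design(
    itesurv:::generator_design(d$cohort, cfg$covariate_schema))
  for (a in 0:1) {
    ia <- d$cohort$arm == a
    cf_a <- coef(survival::coxph(
      survival::Surv(d$cohort$time[ia], d$cohort$event[ia]) ~ X[ia, ],
      ties = "breslow"))
    truth_a <- cfg$main_effects +
      if (a == 1) cfg$interaction_effects else 0
    expect_lt(max(abs(cf_a - truth_a)), 0.1)
  }
})

test_that("lower hazard implies longer restricted survival (sign link)", {
  cfg <- default_scenario(n_patients = 400, seed = 5, baseline_shape = 1)
  d <- generate_cohort(cfg)
  delta <- d$truth$eta1 - d$truth$eta0
  nz <- abs(delta) > 1e-12
  expect_true(all(sign(d$truth$true_ite60[nz]) == -sign(delta[nz])))
})

test_that("cohort and config round-trip through text files", {
  cfg <- default_scenario(n_patients = 60, seed = 9)
  d <- generate_cohort(cfg)
  f <- tempfile(fileext = ".csv")
  write_cohort(d$cohort, f)
  back <- read_cohort(f, cfg$covariate_schema)
  expect_equal(back$time, d$cohort$time, tolerance = 1e-12)
  expect_identical(as.character(back$sex), as.character(d$cohort$sex))
  expect_identical(back$arm, d$cohort$arm)

  fc <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, fc)
  cfg2 <- read_generator_config(fc)
  expect_identical(generate_cohort(cfg2)$cohort$time, d$cohort$time)
})

test_that("cohort file validation flags bad rows and unknown columns", {
  cfg <- default_scenario(n_patients = 10, seed = 2)
  d <- generate_cohort(cfg)
  f <- tempfile(fileext = ".csv")
  bad <- d$cohort; bad$time[3] <- -1
  write_cohort(bad, f)
  expect_error(read_cohort(f), "row")
  extra <- d$cohort; extra$spurious <- 1
  write_cohort(extra, f)
  expect_warning(read_cohort(f, cfg$covariate_schema), "spurious")
})

test_that("month coarsening produces tied integer times", {
  cfg <- default_scenario(n_patients = 300, seed = 8, round_months = TRUE)
  d <- generate_cohort(cfg)
  expect_true(all(d$cohort$time == round(d$cohort$time)))
  expect_true(all(d$cohort$time >= 1))
  expect_gt(sum(duplicated(d$cohort$time)), 0)
})
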