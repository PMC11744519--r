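test_that("probability difference follows its defining arithmetic", {
  rec <- c(rep(1, 80), rep(0, 20), rep(1, 30), rep(0, 70))
  char <- c(rep(1, 100), rep(0, 100))
  pd <- probability_difference(rec, char, n_boot = 50, seed = 1)
  expect_equal(pd$pd, 50)
  expect_true(pd$ci[1] <= pd$pd && pd$pd <= pd$ci[2])

  # antisymmetry under complementing the indicator
  pd_c <- probability_difference(rec, 1 - char, n_boot = 50, seed = 1)
  expect_equal(pd_c$pd, -pd$pd)

  expect_error(probability_difference(rec, rep(1, 200)), "empty")
})

test_that("PD is near zero when recommendations ignore the characteristic", {
  set.seed(2)
  n <- 5000
  rec <- rbinom(n, 1, 0.45)
  char <- rbinom(n, 1, 0.3)
  pd <- probability_difference(rec, char, n_boot = 50, seed = 3)
  expect_lt(abs(pd$pd), 3)
})

test_that("IPTW removes a purely confounded probability difference", {
  set.seed(4)
  n <- 5000
  u <- rnorm(n)                        # confounder drives recommendations
  char <- rbinom(n, 1, plogis(u))      # characteristic proxies u only
  rec <- rbinom(n, 1, plogis(1.2 * u))
  pd <- probability_difference(rec, char, adjust_features = cbind(u = u),
                               n_boot = 50, seed = 5)
  expect_gt(abs(pd$pd), 10)            # confounding visible unadjusted
  expect_lt(abs(pd$pd_iptw), 4)        # gone after weighting on u
})

test_that("per-level PD covers each level one-vs-rest", {
  rec <- rbinom(300, 1, 0.5)
  site <- factor(sample(c("larynx", "tongue", "tonsil"), 300, replace = TRUE))
  tab <- probability_difference_by_level(rec, site, n_boot = 20, seed = 1)
  expect_identical(tab$level, levels(site))
  expect_true(all(abs(tab$pd) <= 100))
})

test_that("age bands split at 30 and 60 with the documented boundaries", {
  b <- age_bands(c(10, 29.9, 30, 45, 60, 60.1, 75))
  expect_identical(as.character(b),
                   c("<30", "<30", "30-60", "30-60", "30-60", ">60", ">60"))
})

test_that("mediation: null path, product-of-coefficients, exact additivity", {
  set.seed(6)
  n <- 5000
  Z <- rnorm(n)
  e <- rbinom(n, 1, 0.5)

  # severed mediator path: NIE tends to zero
  m_null <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 - 0.2 * e + 0.5 * m_null + 0.3 * Z))
  md0 <- mediation_nde_nie(e, m_null, y, covariates = cbind(Z), n_boot = 50,
                           seed = 7)
  expect_lt(abs(md0$nie), 0.01)

  # linear-probability generation with known paths a = 0.4, b = 0.2, c = -0.05
  m <- rbinom(n, 1, 0.3 + 0.4 * e)
  py <- pmin(pmax(0.3 - 0.05 * e + 0.2 * m + 0.05 * Z, 0), 1)
  yy <- rbinom(n, 1, py)
  md <- mediation_nde_nie(e, m, yy, covariates = cbind(Z), n_boot = 50,
                          seed = 8)
  expect_lt(abs(md$nde - (-0.05)), 0.02)
  expect_lt(abs(md$nie - 0.08), 0.02)

  # NDE + NIE equals the reduced-model total-effect slope exactly
  total_slope <- coef(lm(yy ~ e + Z))[["e"]]
  expect_equal(md$total, total_slope, tolerance = 1e-9)

  expect_warning(mediation_nde_nie(e, rep(1, n), yy, n_boot = 10),
                 "constant")
})

test_that("bootstrap NIE interval attains near-nominal coverage", {
  # moderate simulation: true NIE = a * b = 0.4 * 0.2 = 0.08
  n_rep <- 100
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n <- 1000
    e <- rbinom(n, 1, 0.5)
    m <- rbinom(n, 1, 0.3 + 0.4 * e)
    y <- rbinom(n, 1, pmin(pmax(0.3 - 0.05 * e + 0.2 * m, 0), 1))
    md <- mediation_nde_nie(e, m, y, n_boot = 200, seed = r)
    cover[r] <- md$ci_nie[1] <= 0.08 && 0.08 <= md$ci_nie[2]
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("subgroup ATEs: reduction, homogeneity, qualitative interaction", {
  # subgroup = whole cohort equals the overall row
  d <- exp_two_group(600, hr = 0.7, seed = 9)
  X <- matrix(rnorm(1200), ncol = 1)
  tab <- subgroup_ate(d$time, d$event, d$group,
                      rep("all", length(d$time)), X)
  expect_equal(tab$hr[tab$subgroup == "all"],
               tab$hr[tab$subgroup == "Overall"], tolerance = 1e-12)

  # homogeneous effect: subgroup CIs overlap
  set.seed(10)
  n <- 5000
  sgl <- sample(c("g1", "g2"), n, replace = TRUE)
  arm <- rbinom(n, 1, 0.5)
  tte <- rexp(n, 0.02 * ifelse(arm == 1, 0.7, 1))
  ev <- as.integer(tte < 120); tt <- pmin(tte, 120)
  Xh <- matrix(rnorm(n), ncol = 1)
  th <- subgroup_ate(tt, ev, arm, sgl, Xh)
  g1 <- th[th$subgroup == "g1", ]; g2 <- th[th$subgroup == "g2", ]
  expect_true(g1$ci_lower < g2$ci_upper && g2$ci_lower < g1$ci_upper)

  # qualitative interaction with oracle subgroups straddles 1
  cfg <- default_scenario(n_patients = 5000, seed = 11)
  dd <- generate_cohort(cfg)
  sg <- ifelse(dd$truth$true_ite60 > 0, "benefit", "harm")
  Xc <- itesurv:::centre_generator_design(
    itesurv:::generator_design(dd$cohort, cfg$covariate_schema))
  ta <- subgroup_ate(dd$cohort$time, dd$cohort$event, dd$cohort$arm, sg, Xc)
  expect_lt(ta$hr_iptw[ta$subgroup == "benefit"], 1)
  expect_gt(ta$hr_iptw[ta$subgroup == "harm"], 1)
  expect_lt(ta$ci_iptw_upper[ta$subgroup == "benefit"], 1)
  expect_gt(ta$ci_iptw_lower[ta$subgroup == "harm"], 1)
})
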