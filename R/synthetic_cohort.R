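#' Configuration for the synthetic cohort generator
#'
#' Defines a registry-like cohort: covariates, a logistic treatment-assignment
#' (propensity) model, a Weibull proportional-hazards outcome model with
#' treatment-by-covariate interactions, and independent exponential censoring
#' with an administrative cutoff. All times are in months.
#'
#' The linear predictor of the hazard is
#' \deqn{\eta(x, a) = \beta' x + a\,(\gamma + \delta' x),}
#' where \eqn{\beta} are \code{main_effects}, \eqn{\gamma} is
#' \code{treatment_effect}, and \eqn{\delta} are \code{interaction_effects},
#' all on the log-hazard scale. Event times follow a Weibull hazard
#' \eqn{h(t \mid x, a) = (k/\lambda)(t/\lambda)^{k-1} e^{\eta(x,a)}}.
#'
#' @param n_patients positive integer, cohort size.
#' @param seed integer seed; identical config + seed gives a byte-identical
#'   cohort.
#' @param covariate_schema named list; each element is \code{"continuous"} or a
#'   character vector of categorical levels. Coefficient vectors are indexed by
#'   the design columns this schema implies (continuous columns as-is,
#'   categorical levels beyond the first as indicators).
#' @param propensity_intercept,propensity_coefficients log-odds scale
#'   intercept and per-design-column slopes of treatment assignment.
#' @param baseline_shape,baseline_scale Weibull shape \eqn{k > 0} and scale
#'   \eqn{\lambda > 0} (months) of the arm-0 baseline.
#' @param main_effects,treatment_effect,interaction_effects log-hazard
#'   coefficients (see above).
#' @param censor_rate exponential censoring rate per month (>= 0; 0 disables
#'   random censoring).
#' @param admin_horizon administrative censoring time in months (> 0).
#' @param causes optional named numeric vector of cause-of-death probabilities
#'   (summing to 1); when supplied, each event is assigned a cause by an
#'   independent categorical draw.
#' @param round_months logical; when \code{TRUE} observed times are coarsened
#'   to whole months (ceiling, so times stay positive), producing ties like
#'   month-resolution registry data.
#'
#' @return An object of class \code{generator_config}.
#' @seealso [generate_cohort()], [default_scenario()]
#' @export
generator_config <- function(n_patients,
                             seed = 1L,
                             covariate_schema,
                             propensity_intercept = 0,
                             propensity_coefficients,
                             baseline_shape = 1,
                             baseline_scale = 60,
                             main_effects,
                             treatment_effect = 0,
                             interaction_effects,
                             censor_rate = 0.005,
                             admin_horizon = 192,
                             causes = NULL,
                             round_months = FALSE) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("`n_patients` must be a positive count", call. = FALSE)
  if (baseline_shape <= 0 || baseline_scale <= 0)
    stop("Weibull `baseline_shape` and `baseline_scale` must be positive", call. = FALSE)
  if (censor_rate < 0) stop("`censor_rate` must be >= 0", call. = FALSE)
  if (admin_horizon <= 0) stop("`admin_horizon` must be positive", call. = FALSE)
  if (is.null(names(covariate_schema)) || any(!nzchar(names(covariate_schema))))
    stop("`covariate_schema` must be a named list", call. = FALSE)
  p <- length(schema_design_names(covariate_schema))
  for (nm in c("propensity_coefficients", "main_effects", "interaction_effects")) {
    v <- get(nm)
    if (length(v) != p)
      stop(sprintf("`%s` must have length %d (one per design column)", nm, p),
           call. = FALSE)
  }
  if (!is.null(causes)) {
    if (is.null(names(causes)) || abs(sum(causes) - 1) > 1e-8)
      stop("`causes` must be a named probability vector summing to 1", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         covariate_schema = covariate_schema,
         propensity_intercept = propensity_intercept,
         propensity_coefficients = propensity_coefficients,
         baseline_shape = baseline_shape, baseline_scale = baseline_scale,
         main_effects = main_effects, treatment_effect = treatment_effect,
         interaction_effects = interaction_effects,
         censor_rate = censor_rate, admin_horizon = admin_horizon,
         causes = causes, round_months = round_months),
    class = "generator_config")
}

# Design-column names implied by a covariate schema (reference level dropped).
schema_design_names <- function(schema) {
  unlist(lapply(names(schema), function(nm) {
    kind <- schema[[nm]]
    if (identical(kind, "continuous")) nm
    else paste(nm, kind[-1L], sep = ".")
  }), use.names = FALSE)
}

# Raw (unstandardized) design matrix used by the generator's linear predictors.
generator_design <- function(covariates, schema) {
  cols <- lapply(names(schema), function(nm) {
    kind <- schema[[nm]]
    if (identical(kind, "continuous")) {
      m <- matrix(covariates[[nm]], ncol = 1L)
      colnames(m) <- nm
      m
    } else {
      lv <- kind[-1L]
      m <- vapply(lv, function(l) as.numeric(covariates[[nm]] == l),
                  numeric(nrow(covariates)))
      m <- matrix(m, ncol = length(lv),
                  dimnames = list(NULL, paste(nm, lv, sep = ".")))
      m
    }
  })
  do.call(cbind, cols)
}

#' The default heterogeneous-effect scenario
#'
#' A head-and-neck-registry-like scenario: continuous age (years) and tumor
#' size (mm), sex, nodal stage, and an advanced-T indicator. Treatment
#' assignment is confounded (older patients with advanced T disease are more
#' likely to receive arm 1), and the treatment effect contains a qualitative
#' interaction: arm 1 lowers the hazard for advanced-T patients but raises it
#' for the rest, so the true ITE changes sign across that subgroup.
#'
#' @param n_patients cohort size (default 5000).
#' @param seed integer seed.
#' @param ... overrides passed to [generator_config()].
#' @return A \code{generator_config}.
#' @export
default_scenario <- function(n_patients = 5000, seed = 1L, ...) {
  schema <- list(
    age = "continuous",            # years, centred/scaled inside the linear predictor
    tumor_size = "continuous",     # mm
    sex = c("female", "male"),
    n_stage = c("N0", "N1", "N2"),
    t4 = c("no", "yes"))
  # design columns: age, tumor_size, sex.male, n_stage.N1, n_stage.N2, t4.yes
  args <- list(
    n_patients = n_patients, seed = seed, covariate_schema = schema,
    propensity_intercept = -0.3,
    propensity_coefficients = c(0.02, 0.005, 0.2, 0.15, 0.3, 0.8),
    baseline_shape = 1.1, baseline_scale = 90,
    main_effects = c(0.015, 0.008, 0.15, 0.25, 0.5, 0.6),
    treatment_effect = 0.35,
    interaction_effects = c(0, 0, 0, 0, -0.2, -1.1),
    censor_rate = 0.004, admin_horizon = 192,
    causes = c(primary_cancer = 0.6, cardiovascular = 0.2,
               adverse_effect = 0.1, other = 0.1))
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws covariates, assigns treatment from the logistic propensity model,
#' draws Weibull proportional-hazards event times under the assigned arm, and
#' censors with an independent exponential time truncated at the
#' administrative horizon. The returned ground truth records, for every
#' patient, the true propensity, the true log-hazard shift under each arm, and
#' the true restricted-survival-time ITE at the 60-month horizon.
#'
#' Covariates are drawn as: age ~ Normal(60, 10); tumor_size ~ Gamma(mean 35);
#' any other continuous column ~ Normal(0, 1); categorical columns uniformly
#' over their levels (age and tumor_size are recentred in the linear
#' predictors so coefficients act on deviations from a typical patient).
#'
#' @param config a [generator_config()].
#' @return A list with elements \code{cohort} (data.frame: \code{patient_id},
#'   covariates, \code{arm}, \code{time}, \code{event}, optional \code{cause})
#'   and \code{truth} (data.frame: \code{propensity}, \code{eta0},
#'   \code{eta1}, \code{true_ite60}).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  schema <- config$covariate_schema
  set.seed(config$seed)

  covs <- as.data.frame(lapply(names(schema), function(nm) {
    kind <- schema[[nm]]
    if (identical(kind, "continuous")) {
      if (nm == "age") stats::rnorm(n, 60, 10)
      else if (nm == "tumor_size") stats::rgamma(n, shape = 6.125, rate = 0.175)
      else stats::rnorm(n)
    } else {
      factor(sample(kind, n, replace = TRUE), levels = kind)
    }
  }), col.names = names(schema))
  names(covs) <- names(schema)

  X <- generator_design(covs, schema)
  # centre the clinical continuous covariates so coefficients act locally
  X <- centre_generator_design(X)

  lin_ps <- config$propensity_intercept +
    drop(X %*% config$propensity_coefficients)
  ps <- stats::plogis(lin_ps)
  arm <- stats::rbinom(n, 1L, ps)

  eta0 <- drop(X %*% config$main_effects)
  eta1 <- eta0 + config$treatment_effect +
    drop(X %*% config$interaction_effects)
  eta <- ifelse(arm == 1L, eta1, eta0)

  # inverse-CDF draw: S(t) = exp(-(t/lambda)^k e^eta)
  u <- stats::runif(n)
  t_event <- config$baseline_scale * (-log(u) * exp(-eta))^(1 / config$baseline_shape)
  t_event <- pmax(t_event, .Machine$double.eps)

  t_cens <- if (config$censor_rate > 0)
    stats::rexp(n, rate = config$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, config$admin_horizon)

  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  if (config$round_months) time <- pmax(ceiling(time), 1)

  cohort <- data.frame(patient_id = seq_len(n), covs,
                       arm = arm, time = time, event = event)
  if (!is.null(config$causes)) {
    cause <- rep(NA_character_, n)
    idx <- which(event == 1L)
    if (length(idx))
      cause[idx] <- sample(names(config$causes), length(idx), replace = TRUE,
                           prob = config$causes)
    cohort$cause <- cause
  }

  truth <- data.frame(patient_id = seq_len(n), propensity = ps,
                      eta0 = eta0, eta1 = eta1)
  truth$true_ite60 <- true_ite_rst(truth, horizon = 60,
                                   shape = config$baseline_shape,
                                   scale = config$baseline_scale)
  list(cohort = cohort, truth = truth)
}

centre_generator_design <- function(X) {
  if ("age" %in% colnames(X)) X[, "age"] <- X[, "age"] - 60
  if ("tumor_size" %in% colnames(X)) X[, "tumor_size"] <- X[, "tumor_size"] - 35
  X
}

#' True restricted-survival-time ITE under the Weibull model
#'
#' Computes, by adaptive quadrature, the difference of restricted survival
#' times \eqn{\int_0^t S_1(u\mid x)\,du - \int_0^t S_0(u\mid x)\,du} using the
#' generator's true Weibull survival functions
#' \eqn{S_a(u \mid x) = \exp\{-(u/\lambda)^k e^{\eta_a(x)}\}}.
#'
#' @param truth ground-truth data.frame with columns \code{eta0}, \code{eta1}.
#' @param horizon restriction horizon in months (> 0).
#' @param shape,scale Weibull baseline shape and scale of the generator.
#' @return numeric vector of per-patient true ITEs (months).
#' @export
true_ite_rst <- function(truth, horizon, shape, scale) {
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  rst_one <- function(eta) {
    stats::integrate(function(u) exp(-(u / scale)^shape * exp(eta)),
                     lower = 0, upper = horizon,
                     rel.tol = 1e-9, abs.tol = 1e-9)$value
  }
  vapply(seq_len(nrow(truth)),
         function(i) rst_one(truth$eta1[i]) - rst_one(truth$eta0[i]),
         numeric(1))
}

#' Encode cohort covariates as a numeric feature matrix
#'
#' One-hot encodes categorical covariates with the first schema level as the
#' dropped reference, and standardizes continuous covariates using the
#' training rows' mean and standard deviation only. The returned encoder can
#' be re-applied to new data (e.g. a test split) and errors on levels it has
#' not seen.
#'
#' @param cohort a cohort data.frame.
#' @param schema covariate schema (as in [generator_config()]).
#' @return list with \code{features} (numeric matrix) and \code{encoder}
#'   (an object usable with [apply_encoder()]).
#' @export
encode_covariates <- function(cohort, schema) {
  centers <- list(); scales <- list()
  for (nm in names(schema)) {
    if (identical(schema[[nm]], "continuous")) {
      x <- cohort[[nm]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0)
        stop(sprintf("continuous covariate '%s' has zero variance", nm),
             call. = FALSE)
      centers[[nm]] <- mean(x); scales[[nm]] <- s
    }
  }
  encoder <- structure(list(schema = schema, centers = centers, scales = scales),
                       class = "covariate_encoder")
  list(features = apply_encoder(encoder, cohort), encoder = encoder)
}

#' Apply a fitted covariate encoder to new rows
#'
#' @param encoder a \code{covariate_encoder} from [encode_covariates()].
#' @param cohort data.frame containing the schema's covariates.
#' @return numeric feature matrix with the training-time columns.
#' @export
apply_encoder <- function(encoder, cohort) {
  schema <- encoder$schema
  cols <- lapply(names(schema), function(nm) {
    kind <- schema[[nm]]
    if (identical(kind, "continuous")) {
      m <- matrix((cohort[[nm]] - encoder$centers[[nm]]) / encoder$scales[[nm]],
                  ncol = 1L, dimnames = list(NULL, nm))
      m
    } else {
      vals <- as.character(cohort[[nm]])
      bad <- setdiff(unique(vals), kind)
      if (length(bad))
        stop(sprintf("unseen level(s) for covariate '%s': %s",
                     nm, paste(bad, collapse = ", ")), call. = FALSE)
      lv <- kind[-1L]
      m <- vapply(lv, function(l) as.numeric(vals == l), numeric(nrow(cohort)))
      matrix(m, ncol = length(lv),
             dimnames = list(NULL, paste(nm, lv, sep = ".")))
    }
  })
  do.call(cbind, cols)
}

#' Write / read a cohort as delimited text
#'
#' @param cohort cohort data.frame.
#' @param path file path (CSV).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @param schema optional schema; when given, categorical columns are
#'   re-levelled to the schema's level order and basic validity checks run.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "arm", "time", "event")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad))
    stop("non-positive follow-up time at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (!all(df$arm %in% c(0L, 1L)))
    stop("`arm` must be binary 0/1", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("`event` must be binary 0/1", call. = FALSE)
  if (!is.null(schema)) {
    extra <- setdiff(names(df), c(required, "cause", names(schema)))
    if (length(extra)) {
      warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
      df <- df[setdiff(names(df), extra)]
    }
    for (nm in names(schema)) {
      if (!nm %in% names(df))
        stop("cohort file missing covariate '", nm, "'", call. = FALSE)
      if (!identical(schema[[nm]], "continuous"))
        df[[nm]] <- factor(df[[nm]], levels = schema[[nm]])
    }
  }
  if ("cause" %in% names(df)) df$cause[df$cause == ""] <- NA_character_
  df
}

#' Serialize / load a generator configuration
#'
#' Flat key-value YAML; covariate schema and coefficient vectors round-trip.
#'
#' @param config a \code{generator_config}.
#' @param path file path.
#' @export
write_generator_config <- function(config, path) {
  raw <- unclass(config)
  if (!is.null(raw$causes)) raw$causes <- as.list(raw$causes)  # keep names
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$covariate_schema <- lapply(raw$covariate_schema, function(k)
    if (length(k) == 1L && identical(k, "continuous")) "continuous" else as.character(k))
  if (!is.null(raw$causes)) raw$causes <- unlist(raw$causes)
  for (nm in c("propensity_coefficients", "main_effects", "interaction_effects"))
    raw[[nm]] <- as.numeric(unlist(raw[[nm]]))
  do.call(generator_config, raw)
}
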