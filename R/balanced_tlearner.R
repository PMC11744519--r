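#' Specification of a balanced T-learner
#'
#' Architecture and training hyperparameters of the representation-balanced
#' neural T-learner: a shared encoder maps covariates to a representation,
#' two arm-specific risk heads map the representation to a scalar log-risk
#' trained by the Cox partial likelihood on that arm's subjects, and an
#' integral probability metric between the two arms' encoded batches is added
#' with weight \code{balance_weight}. With \code{balance_weight = 0} the loss
#' is exactly the sum of the two heads' Cox losses (an unbalanced neural
#' T-learner).
#'
#' @param shared_layers integer widths of the encoder's hidden layers
#'   (\code{integer(0)} = identity encoder).
#' @param head_layers integer widths of each risk head's hidden layers
#'   (\code{integer(0)} = linear head).
#' @param dropout dropout fraction in [0, 1) applied to hidden activations
#'   during training (inverted dropout).
#' @param balance_weight IPM penalty weight \eqn{\alpha \ge 0}.
#' @param ipm_kind \code{"wasserstein-sinkhorn"} or \code{"mmd-rbf"}.
#' @param epsilon Sinkhorn entropic regularization.
#' @param sinkhorn_iters Sinkhorn iteration cap used inside training batches
#'   (the solver exits early on convergence).
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (>= 2); \code{Inf} trains full-batch.
#' @param max_steps maximum number of gradient steps.
#' @param patience_steps early stopping: training stops when the validation
#'   loss has not improved for this many steps.
#' @param eval_every validation-loss evaluation period (steps).
#' @param l2_weight L2 weight decay coefficient.
#' @param val_fraction fraction of the data held out for early stopping when
#'   no explicit validation set is given.
#' @param seed integer seed controlling initialization, batching and dropout.
#' @return object of class \code{tlearner_spec}.
#' @export
balanced_tlearner_spec <- function(shared_layers = c(16L, 16L),
                                   head_layers = 8L,
                                   dropout = 0.1,
                                   balance_weight = 1,
                                   ipm_kind = c("wasserstein-sinkhorn", "mmd-rbf"),
                                   epsilon = 0.1,
                                   sinkhorn_iters = 100L,
                                   learning_rate = 0.01,
                                   batch_size = 256,
                                   max_steps = 3000L,
                                   patience_steps = 1000L,
                                   eval_every = 25L,
                                   l2_weight = 1e-4,
                                   val_fraction = 0.2,
                                   seed = 1L) {
  ipm_kind <- match.arg(ipm_kind)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must lie in [0, 1)", call. = FALSE)
  if (balance_weight < 0) stop("`balance_weight` must be >= 0", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (is.finite(batch_size) && batch_size < 2) stop("`batch_size` must be >= 2", call. = FALSE)
  if (l2_weight < 0) stop("`l2_weight` must be >= 0", call. = FALSE)
  structure(list(shared_layers = as.integer(shared_layers),
                 head_layers = as.integer(head_layers),
                 dropout = dropout, balance_weight = balance_weight,
                 ipm_kind = ipm_kind, epsilon = epsilon,
                 sinkhorn_iters = as.integer(sinkhorn_iters),
                 learning_rate = learning_rate, batch_size = batch_size,
                 max_steps = as.integer(max_steps),
                 patience_steps = as.integer(patience_steps),
                 eval_every = as.integer(eval_every),
                 l2_weight = l2_weight, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "tlearner_spec")
}

## ---- minimal MLP with manual backprop ------------------------------------

mlp_init <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(i) {
    s <- sqrt(6 / (dims[i] + dims[i + 1L]))
    list(W = matrix(stats::runif(dims[i] * dims[i + 1L], -s, s),
                    dims[i], dims[i + 1L]),
         b = numeric(dims[i + 1L]))
  })
}

# act_last: apply ReLU (+ dropout) after the final layer too
mlp_forward <- function(layers, X, act_last, dropout = 0, training = FALSE) {
  caches <- vector("list", length(layers))
  h <- X
  for (i in seq_along(layers)) {
    Z <- sweep(h %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    activated <- i < length(layers) || act_last
    A <- if (activated) pmax(Z, 0) else Z
    mask <- NULL
    if (activated && training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(A), 1L, 1 - dropout) / (1 - dropout),
                     nrow(A), ncol(A))
      A <- A * mask
    }
    caches[[i]] <- list(input = h, Z = Z, mask = mask, activated = activated)
    h <- A
  }
  list(out = h, caches = caches)
}

mlp_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    cc <- caches[[i]]
    if (!is.null(cc$mask)) d <- d * cc$mask
    if (cc$activated) d <- d * (cc$Z > 0)
    grads[[i]] <- list(W = crossprod(cc$input, d), b = colSums(d))
    d <- tcrossprod(d, layers[[i]]$W)
  }
  list(grads = grads, dX = d)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(layers, grads, state, lr, t, l2 = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    gW <- grads[[i]]$W + l2 * layers[[i]]$W
    gb <- grads[[i]]$b
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gW
    st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

## ---- loss over a (mini-)batch --------------------------------------------

# Forward + (optionally) backward of the balanced T-learner loss on a batch.
# Returns the total loss; when `update` the parameter gradients are returned.
tlearner_batch <- function(params, X, arms, times, events, spec,
                           training = FALSE, gradient = FALSE) {
  has_encoder <- length(params$encoder) > 0L
  enc <- if (has_encoder)
    mlp_forward(params$encoder, X, act_last = TRUE,
                dropout = spec$dropout, training = training)
  else list(out = X, caches = NULL)
  rep_all <- enc$out

  i0 <- which(arms == 0L); i1 <- which(arms == 1L)
  z0 <- rep_all[i0, , drop = FALSE]; z1 <- rep_all[i1, , drop = FALSE]

  h0 <- mlp_forward(params$head0, z0, act_last = FALSE,
                    dropout = spec$dropout, training = training)
  h1 <- mlp_forward(params$head1, z1, act_last = FALSE,
                    dropout = spec$dropout, training = training)
  eta0 <- drop(h0$out); eta1 <- drop(h1$out)

  loss <- 0
  d_eta0 <- numeric(length(i0)); d_eta1 <- numeric(length(i1))
  if (length(i0) && sum(events[i0]) > 0) {
    l0 <- cox_partial_likelihood_loss(eta0, times[i0], events[i0], gradient = gradient)
    loss <- loss + as.numeric(l0)
    if (gradient) d_eta0 <- attr(l0, "gradient")
  }
  if (length(i1) && sum(events[i1]) > 0) {
    l1 <- cox_partial_likelihood_loss(eta1, times[i1], events[i1], gradient = gradient)
    loss <- loss + as.numeric(l1)
    if (gradient) d_eta1 <- attr(l1, "gradient")
  }

  dz0_ipm <- NULL; dz1_ipm <- NULL
  if (spec$balance_weight > 0 && length(i0) && length(i1)) {
    pen <- ipm_penalty(z0, z1, kind = spec$ipm_kind, epsilon = spec$epsilon,
                       gradient = gradient, n_iter = spec$sinkhorn_iters)
    loss <- loss + spec$balance_weight * as.numeric(pen)
    if (gradient) {
      dz0_ipm <- spec$balance_weight * attr(pen, "grad0")
      dz1_ipm <- spec$balance_weight * attr(pen, "grad1")
    }
  }
  if (!gradient) return(list(loss = loss))

  b0 <- mlp_backward(params$head0, h0$caches, matrix(d_eta0, ncol = 1L))
  b1 <- mlp_backward(params$head1, h1$caches, matrix(d_eta1, ncol = 1L))
  dRep <- matrix(0, nrow(rep_all), ncol(rep_all))
  dRep[i0, ] <- b0$dX
  dRep[i1, ] <- b1$dX
  if (!is.null(dz0_ipm)) dRep[i0, ] <- dRep[i0, ] + dz0_ipm
  if (!is.null(dz1_ipm)) dRep[i1, ] <- dRep[i1, ] + dz1_ipm
  enc_grads <- if (has_encoder)
    mlp_backward(params$encoder, enc$caches, dRep)$grads else NULL
  list(loss = loss, grads = list(encoder = enc_grads,
                                 head0 = b0$grads, head1 = b1$grads))
}

## ---- fitting --------------------------------------------------------------

#' Fit the balanced neural T-learner
#'
#' Minimizes \deqn{\mathrm{CoxLoss}_0 + \mathrm{CoxLoss}_1 + \alpha\,
#' \mathrm{IPM}(\Phi(X_0), \Phi(X_1))} by mini-batch Adam, where \eqn{\Phi}
#' is the shared encoder and each Cox loss is the negative log partial
#' likelihood of that arm's risk head on that arm's subjects. Training early
#' stops when the validation loss (computed without dropout, with the IPM
#' term) has not improved for \code{patience_steps} gradient steps; the
#' parameters at the best validation loss are kept. Per-arm Breslow baseline
#' cumulative hazards are then estimated on each arm's training subjects at
#' the final parameters.
#'
#' @param features numeric matrix of encoded covariates (see
#'   [encode_covariates()]).
#' @param arms 0/1 treatment indicator.
#' @param times positive follow-up times (months).
#' @param events 0/1 event indicators; each arm needs >= 2 events.
#' @param spec a [balanced_tlearner_spec()].
#' @param validation optional list with elements \code{features},
#'   \code{arms}, \code{times}, \code{events} used for early stopping;
#'   when \code{NULL}, a fraction \code{spec$val_fraction} of the rows is
#'   held out.
#' @param encoder optional \code{covariate_encoder} stored with the model so
#'   that prediction can start from raw cohort rows.
#' @return object of class \code{counterfactual_model}.
#' @export
fit_balanced_tlearner <- function(features, arms, times, events, spec,
                                  validation = NULL, encoder = NULL) {
  stopifnot(inherits(spec, "tlearner_spec"))
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(arms) == n, length(times) == n, length(events) == n)
  for (a in 0:1)
    if (sum(events[arms == a]) < 2)
      stop(sprintf("arm %d has fewer than 2 events", a), call. = FALSE)

  set.seed(spec$seed)
  if (is.null(validation)) {
    n_val <- max(2L, round(spec$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    # both arms must appear with events in the validation set; resample a few
    # times if the draw is degenerate (tiny-n corner)
    tries <- 0L
    while ((sum(events[val_idx][arms[val_idx] == 0L]) < 1 ||
            sum(events[val_idx][arms[val_idx] == 1L]) < 1) && tries < 20L) {
      val_idx <- sample.int(n, n_val); tries <- tries + 1L
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    validation <- list(features = features[val_idx, , drop = FALSE],
                       arms = arms[val_idx], times = times[val_idx],
                       events = events[val_idx])
    features <- features[tr_idx, , drop = FALSE]
    arms <- arms[tr_idx]; times <- times[tr_idx]; events <- events[tr_idx]
    n <- length(tr_idx)
  }

  p <- ncol(features)
  rep_dim <- if (length(spec$shared_layers)) spec$shared_layers[length(spec$shared_layers)] else p
  params <- list(
    encoder = if (length(spec$shared_layers))
      mlp_init(c(p, spec$shared_layers)) else list(),
    head0 = mlp_init(c(rep_dim, spec$head_layers, 1L)),
    head1 = mlp_init(c(rep_dim, spec$head_layers, 1L)))
  state <- list(encoder = if (length(params$encoder)) adam_init(params$encoder) else list(),
                head0 = adam_init(params$head0), head1 = adam_init(params$head1))

  bs <- min(spec$batch_size, n)
  val_loss <- function(pp)
    tlearner_batch(pp, validation$features, validation$arms,
                   validation$times, validation$events, spec)$loss

  best <- list(loss = Inf, params = params, step = 0L)
  trace <- numeric(0)
  for (step in seq_len(spec$max_steps)) {
    idx <- if (bs >= n) seq_len(n) else sample.int(n, bs)
    out <- tlearner_batch(params, features[idx, , drop = FALSE], arms[idx],
                          times[idx], events[idx], spec,
                          training = TRUE, gradient = TRUE)
    if (!is.finite(out$loss))
      stop(sprintf("training diverged at step %d (loss = %s); lower the learning rate",
                   step, format(out$loss)), call. = FALSE)
    if (length(params$encoder)) {
      up <- adam_update(params$encoder, out$grads$encoder, state$encoder,
                        spec$learning_rate, step, spec$l2_weight)
      params$encoder <- up$layers; state$encoder <- up$state
    }
    up0 <- adam_update(params$head0, out$grads$head0, state$head0,
                       spec$learning_rate, step, spec$l2_weight)
    params$head0 <- up0$layers; state$head0 <- up0$state
    up1 <- adam_update(params$head1, out$grads$head1, state$head1,
                       spec$learning_rate, step, spec$l2_weight)
    params$head1 <- up1$layers; state$head1 <- up1$state

    if (step %% spec$eval_every == 0L || step == spec$max_steps) {
      vl <- val_loss(params)
      trace <- c(trace, vl)
      if (is.finite(vl) && vl < best$loss - 1e-9)
        best <- list(loss = vl, params = params, step = step)
      if (step - best$step >= spec$patience_steps) break
    }
  }
  params <- best$params

  # per-arm Breslow baselines on each arm's own training subjects
  eta_all <- tlearner_predict_eta(params, spec, features)
  baselines <- lapply(0:1, function(a) {
    ia <- which(arms == a)
    breslow_baseline(eta_all[[a + 1L]][ia], times[ia], events[ia])
  })

  structure(list(type = "balanced_tlearner", params = params, spec = spec,
                 baselines = baselines, encoder = encoder,
                 report = list(best_val_loss = best$loss,
                               best_step = best$step,
                               n_steps = length(trace) * spec$eval_every,
                               val_trace = trace)),
            class = "counterfactual_model")
}

# per-arm log-risks for all rows (no dropout)
tlearner_predict_eta <- function(params, spec, features) {
  rep_all <- if (length(params$encoder))
    mlp_forward(params$encoder, features, act_last = TRUE)$out else features
  list(drop(mlp_forward(params$head0, rep_all, act_last = FALSE)$out),
       drop(mlp_forward(params$head1, rep_all, act_last = FALSE)$out))
}

#' @export
print.counterfactual_model <- function(x, ...) {
  cat(sprintf("counterfactual_model (%s)\n", x$type))
  if (!is.null(x$report$best_val_loss))
    cat(sprintf("  best validation loss %.4f at step %d\n",
                x$report$best_val_loss, x$report$best_step))
  invisible(x)
}

#' Predict counterfactual survival curves
#'
#' Applies the fitted model's arm-specific risk score and Breslow baseline:
#' \eqn{\hat S_a(t \mid x) = \exp\{-\hat H_{0,a}(t) e^{\eta_a(x)}\}}.
#'
#' @param model a \code{counterfactual_model}.
#' @param features encoded feature matrix (or a raw cohort data.frame when
#'   the model stores a covariate encoder).
#' @param arm 0 or 1: which potential-outcome curve to predict.
#' @param grid time grid starting at 0 (months).
#' @return a [survival_curves()] object, one row per input row.
#' @export
predict_survival <- function(model, features, arm, grid) {
  stopifnot(inherits(model, "counterfactual_model"), arm %in% c(0L, 1L))
  if (is.data.frame(features)) {
    if (is.null(model$encoder))
      stop("model stores no covariate encoder; supply an encoded matrix", call. = FALSE)
    features <- apply_encoder(model$encoder, features)
  }
  if (model$type == "survival_forest") {
    X <- as.matrix(features)
    colnames(X) <- model$feature_names
    return(forest_curves_on_grid(model$fits[[arm + 1L]], data.frame(X), grid))
  }
  eta <- switch(model$type,
    "balanced_tlearner" =
      tlearner_predict_eta(model$params, model$spec, as.matrix(features))[[arm + 1L]],
    "coxph" = drop(as.matrix(features) %*% model$coefs[[arm + 1L]]),
    stop("unknown model type: ", model$type))
  baseline_survival(model$baselines[[arm + 1L]], eta, grid)
}
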