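#' Q-learning model parameters
#'
#' The four-parameter Q-learning choice model: learning rate `alpha` scales
#' the value update of the selected spout, forgetting rate `zeta` decays the
#' value of the unselected spout, inverse temperature `beta` sets how
#' strongly choices exploit the value difference (low beta = stochastic,
#' exploratory choice), and `bias` is an additive side bias toward the
#' right spout (the reference spout; flipping the convention only flips the
#' sign of `bias`).
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param zeta Forgetting rate in \[0, 1\].
#' @param beta Inverse temperature, >= 0.
#' @param bias Additive bias, unbounded.
#' @return An object of class `q_params`.
#' @export
q_params <- function(alpha, zeta, beta, bias = 0) {
  v <- c(alpha = alpha, zeta = zeta, beta = beta, bias = bias)
  if (any(!is.finite(v))) stop("parameters must be finite", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (zeta < 0 || zeta > 1) stop("zeta must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(as.list(v), class = "q_params")
}

#' @export
print.q_params <- function(x, ...) {
  cat(sprintf("<q_params> alpha=%.4g zeta=%.4g beta=%.4g bias=%.4g\n",
              x$alpha, x$zeta, x$beta, x$bias))
  invisible(x)
}

#' One Q-value update
#'
#' Applies the value recursion for a single non-timeout trial: the chosen
#' spout moves toward the reward outcome by `alpha`, the unchosen spout
#' decays by `1 - zeta`. With rewards in \{0, 1\} and initial values in
#' \[0, 1\], both values stay in \[0, 1\].
#'
#' @param state Numeric vector `c(q_left, q_right)`.
#' @param choice `"L"` or `"R"` (timeouts must be filtered out upstream).
#' @param rewarded Logical (or 0/1) reward outcome.
#' @param params A [q_params()].
#' @return Updated `c(q_left, q_right)`.
#' @examples
#' q_update(c(0.5, 0.2), "L", TRUE, q_params(0.4, 0.1, 2))  # -> c(0.7, 0.18)
#' @export
q_update <- function(state, choice, rewarded, params) {
  stopifnot(length(state) == 2L, all(is.finite(state)))
  if (!choice %in% c("L", "R")) {
    stop("timeout trials cannot update values; filter them first",
         call. = FALSE)
  }
  R <- as.numeric(rewarded)
  qL <- state[[1]]; qR <- state[[2]]
  if (choice == "L") {
    qL <- qL + params$alpha * (R - qL)
    qR <- (1 - params$zeta) * qR
  } else {
    qR <- qR + params$alpha * (R - qR)
    qL <- (1 - params$zeta) * qL
  }
  c(q_left = qL, q_right = qR)
}

#' Softmax choice probability
#'
#' Probability of choosing the right (reference) spout:
#' `plogis(beta * (q_right - q_left) + bias)`. The left-spout probability is
#' the complement.
#'
#' @inheritParams q_update
#' @return `P(choose right)`, a scalar in (0, 1).
#' @export
choice_prob <- function(state, params) {
  stopifnot(length(state) == 2L, all(is.finite(state)))
  stats::plogis(params$beta * (state[[2]] - state[[1]]) + params$bias)
}

# Prepare concatenated per-trial arrays for the C++ forward pass. Timeout
# trials are dropped entirely (no likelihood, no value update); Q-values
# reset at each session boundary.
.qlearn_arrays <- function(sessions) {
  if (inherits(sessions, "data.frame")) sessions <- split_sessions(sessions)
  if (length(sessions) == 0L) stop("no sessions supplied", call. = FALSE)
  keep <- lapply(sessions, function(s) s[s$choice != "timeout", , drop = FALSE])
  ns <- vapply(keep, nrow, 1L)
  if (sum(ns) == 0L) stop("no non-timeout trials", call. = FALSE)
  list(
    choice = unlist(lapply(keep, function(s) as.integer(s$choice == "R")),
                    use.names = FALSE),
    rewarded = unlist(lapply(keep, function(s) as.integer(s$rewarded)),
                      use.names = FALSE),
    session = rep.int(seq_along(keep), ns),
    sessions = keep)
}

#' Mean negative log-likelihood of observed choices
#'
#' Runs the value recursion forward over each session (values reset to
#' `(0, 0)` per session) and scores each non-timeout trial's observed choice
#' under the softmax policy. Timeout trials contribute nothing and trigger
#' no value update.
#'
#' @param sessions A stacked session-log data frame or list of session
#'   data frames (one mouse/epoch).
#' @param params A [q_params()].
#' @return Mean negative log-likelihood per included trial (nats).
#' @export
session_nll <- function(sessions, params) {
  a <- .qlearn_arrays(sessions)
  res <- qlearn_forward(a$choice, a$rewarded, a$session,
                        rep(TRUE, length(a$choice)),
                        params$alpha, params$zeta, params$beta, params$bias)
  res$nll
}

# NLL and gradient on the unconstrained optimizer scale:
# theta = (logit alpha, logit zeta, softplus^-1 beta, bias).
.nll_grad_theta <- function(theta, a, in_train) {
  alpha <- stats::plogis(theta[1]); zeta <- stats::plogis(theta[2])
  beta <- log1p(exp(theta[3])); bias <- theta[4]
  res <- qlearn_forward(a$choice, a$rewarded, a$session, in_train,
                        alpha, zeta, beta, bias)
  jac <- c(alpha * (1 - alpha), zeta * (1 - zeta), stats::plogis(theta[3]), 1)
  list(nll = res$nll, grad = res$grad * jac)
}

.theta_from_params <- function(p) {
  clamp <- function(x) min(max(x, 1e-6), 1 - 1e-6)
  c(stats::qlogis(clamp(p$alpha)), stats::qlogis(clamp(p$zeta)),
    log(expm1(max(p$beta, 1e-6))), p$bias)
}

.params_from_theta <- function(theta) {
  q_params(alpha = stats::plogis(theta[1]), zeta = stats::plogis(theta[2]),
           beta = log1p(exp(theta[3])), bias = theta[4])
}

#' Fitting configuration
#'
#' Defaults mirror the reference procedure: full-batch gradient descent with
#' step size 0.1 for 10,000 iterations on a 75% training split, the split
#' taken over each session's 4 contiguous trial-quarters.
#'
#' @param learn_rate Optimizer step size.
#' @param n_iters Gradient-descent iteration count.
#' @param train_fraction Fraction of each session's quarters used for
#'   training; must lie in (0, 1). With the default 0.75, exactly 3 of 4
#'   quarters train and 1 is held out.
#' @param seed Integer seed governing the train/held-out split.
#' @param refine If `TRUE`, polish the gradient-descent solution with BFGS
#'   using the analytic gradient.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(learn_rate = 0.1, n_iters = 10000L,
                       train_fraction = 0.75, seed = 1L, refine = TRUE) {
  stopifnot(learn_rate > 0, n_iters >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(learn_rate = learn_rate, n_iters = as.integer(n_iters),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 refine = isTRUE(refine)),
            class = "fit_config")
}

# Assign each session's non-timeout trials to 4 contiguous quarters and mark
# a seeded random 3 of 4 as training.
.train_mask <- function(a, train_fraction, seed) {
  n_quarters <- 4L
  n_train_q <- round(train_fraction * n_quarters)
  stopifnot(n_train_q >= 1, n_train_q < n_quarters)
  set.seed(seed)
  masks <- lapply(a$sessions, function(s) {
    n <- nrow(s)
    qtr <- ceiling(seq_len(n) / n * n_quarters)
    qtr[qtr < 1L] <- 1L
    train_q <- sample.int(n_quarters, n_train_q)
    qtr %in% train_q
  })
  unlist(masks, use.names = FALSE)
}

#' Fit the Q-learning model to one mouse/epoch by maximum likelihood
#'
#' Splits each session into 4 contiguous trial-quarters, trains on a seeded
#' random 3 of them (75%), and minimizes the mean training negative
#' log-likelihood by full-batch gradient descent on transformed parameters
#' (logistic for `alpha` and `zeta`, softplus for `beta`, identity for
#' `bias`), optionally polished by BFGS. Values are propagated over all
#' trials in order during both training and evaluation. Held-out accuracy is
#' the fraction of held-out non-timeout trials on which the
#' higher-probability spout under the fitted parameters matches the observed
#' choice; a tie at exactly 0.5 counts as incorrect.
#'
#' @param sessions Stacked session-log data frame or list of sessions
#'   (pool one mouse and one epoch per fit).
#' @param config A [fit_config()].
#' @param init Optional [q_params()] starting point.
#' @return A list of class `q_fit`: `params`, `train_nll`,
#'   `heldout_accuracy`, `converged`, `trace` (training loss per iteration),
#'   `n_trials`.
#' @export
fit_q <- function(sessions, config = fit_config(), init = NULL) {
  a <- .qlearn_arrays(sessions)
  in_train <- .train_mask(a, config$train_fraction, config$seed)
  if (is.null(init)) init <- q_params(0.5, 0.2, 1, 0)
  theta <- .theta_from_params(init)

  one_choice <- length(unique(a$choice)) == 1L
  trace <- numeric(config$n_iters)
  converged <- FALSE
  for (i in seq_len(config$n_iters)) {
    st <- .nll_grad_theta(theta, a, in_train)
    if (!is.finite(st$nll)) {
      stop("non-finite loss during optimization at iteration ", i,
           call. = FALSE)
    }
    trace[i] <- st$nll
    theta <- theta - config$learn_rate * st$grad
    if (i > 100L && abs(trace[i - 100L] - trace[i]) < 1e-9) {
      converged <- TRUE
      trace <- trace[seq_len(i)]
      break
    }
  }
  if (config$refine) {
    opt <- stats::optim(theta,
                        fn = function(th) .nll_grad_theta(th, a, in_train)$nll,
                        gr = function(th) .nll_grad_theta(th, a, in_train)$grad,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (opt$value <= trace[length(trace)]) {
      theta <- opt$par
      trace <- c(trace, opt$value)
      converged <- converged || opt$convergence == 0
    }
  }

  params <- .params_from_theta(theta)
  final <- qlearn_forward(a$choice, a$rewarded, a$session, in_train,
                          params$alpha, params$zeta, params$beta, params$bias)
  held <- !in_train
  pred_right <- final$p_right > 0.5  # tie at 0.5 counted as incorrect
  acc <- mean((pred_right == (a$choice == 1L))[held] & final$p_right[held] != 0.5)

  structure(list(params = params, train_nll = final$nll,
                 heldout_accuracy = acc,
                 converged = converged && !one_choice,
                 weakly_identified = one_choice,
                 trace = trace, n_trials = length(a$choice),
                 seed = config$seed),
            class = "q_fit")
}

#' @export
print.q_fit <- function(x, ...) {
  cat(sprintf(
    "<q_fit> alpha=%.3f zeta=%.3f beta=%.3f bias=%.3f | train NLL %.4f | held-out acc %.3f (%d trials)\n",
    x$params$alpha, x$params$zeta, x$params$beta, x$params$bias,
    x$train_nll, x$heldout_accuracy, x$n_trials))
  invisible(x)
}

#' Serialize a fit as JSON
#'
#' @param fit A `q_fit`.
#' @param mouse_id,epoch Annotations stored alongside the parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_q_fit <- function(fit, path, mouse_id = "m0", epoch = "habituation") {
  obj <- list(mouse_id = mouse_id, epoch = epoch,
              alpha = fit$params$alpha, zeta = fit$params$zeta,
              beta = fit$params$beta, bias = fit$params$bias,
              train_nll = fit$train_nll,
              heldout_accuracy = fit$heldout_accuracy,
              n_trials = fit$n_trials, seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a Q-learning agent on the bandit task
#'
#' The agent chooses via [choice_prob()], updates values via [q_update()]
#' (reset to `(0, 0)` at each session start), and the environment follows
#' [run_session()] semantics.
#'
#' @param params A [q_params()].
#' @param task A [task_config()].
#' @param n_sessions Number of sessions to simulate.
#' @param seed Integer seed.
#' @param mouse_id,epoch,first_day Session annotations.
#' @return A stacked `session_log` data frame.
#' @export
simulate_agent <- function(params, task, n_sessions = 1L, seed = 1L,
                           mouse_id = "m0", epoch = "habituation",
                           first_day = 0L) {
  set.seed(seed)
  logs <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    q <- c(0, 0)
    # feed the previous trial's outcome back into the agent's values, then
    # sample the next choice from the softmax policy
    log <- run_session(task, function(info) {
      if (!is.na(info$prev_choice) && info$prev_choice != "timeout") {
        q <<- q_update(q, info$prev_choice, info$prev_rewarded, params)
      }
      if (stats::runif(1) < choice_prob(q, params)) "R" else "L"
    }, mouse_id = mouse_id, session_id = sprintf("s%03d", s),
       epoch = epoch, day = first_day + s - 1L)
    logs[[s]] <- log
  }
  out <- do.call(rbind, logs)
  class(out) <- c("session_log", "data.frame")
  out
}
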