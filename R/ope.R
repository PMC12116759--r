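# Off-policy evaluation: fitted-Q evaluation, empirical behaviour returns,
# percentile-bootstrap confidence intervals, max-lower-bound selection.

new_ope_result <- function(mean_value, ci, n_episodes, n_bootstrap, method) {
  structure(list(mean_value = mean_value, ci_low = ci[1], ci_high = ci[2],
                 n_episodes = n_episodes, n_bootstrap = n_bootstrap,
                 method = method), class = "ope_result")
}

#' @export
print.ope_result <- function(x, ...) {
  cat(sprintf("%s policy value: %.4f [%.4f, %.4f] (%d episodes, %d resamples)\n",
              x$method, x$mean_value, x$ci_low, x$ci_high,
              x$n_episodes, x$n_bootstrap))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `n_resamples` times and returns the
#' percentile interval of the resampled means. Deterministic under `seed`.
#'
#' @param values Numeric vector (at least one value).
#' @param n_resamples Number of bootstrap resamples (default 10,000).
#' @param level Coverage (default 0.95).
#' @param seed Integer seed.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_resamples = 10000, level = 0.95,
                         seed = 1L) {
  if (!length(values)) stop("no values to bootstrap", call. = FALSE)
  local_seed(seed)
  n <- length(values)
  chunk <- max(1L, min(n_resamples, floor(5e6 / n)))
  means <- numeric(n_resamples)
  done_n <- 0L
  while (done_n < n_resamples) {
    m <- min(chunk, n_resamples - done_n)
    draws <- matrix(sample(values, n * m, replace = TRUE), nrow = n)
    means[done_n + seq_len(m)] <- colMeans(draws)
    done_n <- done_n + m
  }
  a <- (1 - level) / 2
  unname(stats::quantile(means, c(a, 1 - a)))
}

#' Empirical discounted returns of the behaviour policy
#'
#' Per-episode discounted return of the logged data,
#' `sum_t gamma^t r_t`, with mean and percentile-bootstrap confidence
#' interval. Since the logged data are on-policy for the treating clinicians,
#' the empirical mean is an unbiased estimate of the behaviour policy value.
#'
#' @param dataset A `transition_dataset`.
#' @param gamma Discount factor.
#' @param n_bootstrap Bootstrap resamples for the CI.
#' @param seed Seed for the bootstrap.
#' @return List with `returns` (per episode) and `result` (an `ope_result`).
#' @export
behavior_returns <- function(dataset, gamma = 0.67, n_bootstrap = 10000,
                             seed = 1L) {
  returns <- vapply(dataset$episodes, function(idx) {
    sum(gamma^(seq_along(idx) - 1L) * dataset$rewards[idx])
  }, numeric(1))
  ci <- bootstrap_ci(returns, n_bootstrap, seed = seed)
  list(returns = returns,
       result = new_ope_result(mean(returns), ci, length(returns),
                               n_bootstrap, "empirical"))
}

as_policy_fn <- function(policy) {
  if (inherits(policy, "policy_artifact")) {
    function(states) as.numeric(recommend_dose(policy, states))
  } else if (is.function(policy)) {
    policy
  } else {
    stop("policy must be a policy_artifact or a function of the state matrix",
         call. = FALSE)
  }
}

#' Fitted-Q evaluation of a dosing policy
#'
#' Estimates the discounted value of a fixed policy from logged transitions
#' by iterated Bellman regressions: an evaluation critic `Q(s, a)` (plain
#' MLP) is fit by stochastic gradient steps towards the Bellman target
#' `reward + gamma * (1 - done) * Q_target(s', pi(s'))`, with the target network
#' hard-synced every `target_update` steps. The per-episode value is
#' `Q(s0, pi(s0))` at the episode's first state; the policy value is its
#' mean over episodes with a percentile-bootstrap confidence interval.
#'
#' @param dataset A `transition_dataset` to evaluate on.
#' @param policy A `policy_artifact` or a function mapping a matrix of
#'   normalized states to doses in `[0, action_max]`.
#' @param gamma Discount factor.
#' @param hidden Hidden widths of the evaluation critic.
#' @param lr Adam learning rate.
#' @param steps Gradient steps.
#' @param batch_size Batch size.
#' @param target_update Steps between target-network syncs.
#' @param action_max Dose cap (for input scaling).
#' @param n_bootstrap Bootstrap resamples.
#' @param seed Integer seed.
#' @param engine `"cpp"` (compiled regression step, default) or `"r"`
#'   (autodiff reference; identical gradients, slower).
#' @return List with `result` (an `ope_result`, method `"fqe"`), `values`
#'   (per-episode), and `critic` (fitted parameters).
#' @export
fqe_evaluate <- function(dataset, policy, gamma = 0.67,
                         hidden = c(256, 256), lr = 3e-4, steps = 2000,
                         batch_size = 256, target_update = 100,
                         action_max = 10, n_bootstrap = 10000, seed = 1L,
                         engine = c("cpp", "r")) {
  stopifnot(inherits(dataset, "transition_dataset"))
  engine <- match.arg(engine)
  policy_fn <- as_policy_fn(policy)
  local_seed(seed)
  n <- length(dataset$actions)
  d <- ncol(dataset$states)
  a2 <- policy_fn(dataset$next_states)
  if (any(a2 < 0 | a2 > action_max)) {
    stop("policy returned doses outside [0, action_max]", call. = FALSE)
  }
  x_all <- cbind(dataset$states, dataset$actions / action_max)
  x2_all <- cbind(dataset$next_states, a2 / action_max)

  params <- init_mlp(d + 1L, c(hidden, 1L))
  target <- params
  opt <- adam_init(params, lr = lr)
  B <- min(batch_size, n)
  for (step in seq_len(steps)) {
    idx <- sample.int(n, B, replace = TRUE)
    qt <- mlp_infer(x2_all[idx, , drop = FALSE], target)
    y <- dataset$rewards[idx] +
      gamma * as.numeric(!dataset$done[idx]) * as.numeric(qt)
    if (engine == "cpp") {
      res <- .fqe_step_cpp(params, x_all[idx, , drop = FALSE], y)
      loss_val <- res$loss
      grads <- res$grads
    } else {
      wp <- wrap_params(params)
      pred <- mlp_forward(x_all[idx, , drop = FALSE], wp)
      loss <- ad_mean(ad_square(ad_addc(pred, -matrix(y, ncol = 1L))))
      ad_backward(loss)
      loss_val <- loss$value[1]
      grads <- grads_of(wp)
    }
    if (!is.finite(loss_val)) {
      stop(sprintf("FQE loss diverged at step %d (%.4g)", step, loss_val),
           call. = FALSE)
    }
    upd <- adam_step(params, grads, opt)
    params <- upd$params
    opt <- upd$state
    if (step %% target_update == 0L) target <- params
  }

  s0_idx <- vapply(dataset$episodes, `[`, integer(1), 1L)
  s0 <- dataset$states[s0_idx, , drop = FALSE]
  a0 <- policy_fn(s0)
  values <- as.numeric(mlp_infer(cbind(s0, a0 / action_max), params))
  ci <- bootstrap_ci(values, n_bootstrap, seed = seed)
  list(result = new_ope_result(mean(values), ci, length(values), n_bootstrap,
                               "fqe"),
       values = values, critic = params)
}

#' Select the model with the highest confidence lower bound
#'
#' Given off-policy evaluation results for several candidate models, returns
#' the index of the one with the maximal lower bound of the 95% CI of its
#' estimated return; ties resolve to the lowest index.
#'
#' @param results A list of `ope_result` objects.
#' @return Integer index of the winner.
#' @export
select_best <- function(results) {
  if (!length(results)) stop("no results to select from", call. = FALSE)
  lows <- vapply(results, function(r) r$ci_low, numeric(1))
  which.max(lows)
}

#' Multi-seed training and model selection
#'
#' The model-development protocol: for each of `n_models` seeds, subsample
#' 80% of the training patients, train an agent on them, and evaluate the
#' resulting policy on the held-out test set with fitted-Q evaluation; the
#' final model is the one with the highest lower 95% confidence bound of its
#' estimated return. Seeds are `config$seed + 0:(n_models-1)`, so the whole
#' protocol is reproducible from one seed.
#'
#' @param train_data,test_data `transition_dataset`s (patient-disjoint).
#' @param n_models Number of independently trained models.
#' @param config Base [agent_config()]; each model gets its own seed.
#' @param subsample_frac Training-patient subsample fraction (default 0.80).
#' @param fqe_args List of overrides passed to [fqe_evaluate()].
#' @param engine Training engine, see [train_dcql()].
#' @param verbose Print per-model progress.
#' @return List with `best` (the selected `policy_artifact`), `best_index`,
#'   `results` (per-model `ope_result`s) and `leaderboard` (data.frame).
#' @export
multiseed_protocol <- function(train_data, test_data, n_models = 5,
                               config = agent_config(),
                               subsample_frac = 0.80, fqe_args = list(),
                               engine = c("cpp", "r"), verbose = FALSE) {
  stopifnot(n_models >= 1)
  engine <- match.arg(engine)
  artifacts <- vector("list", n_models)
  results <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    seed_i <- config$seed + i - 1L
    cfg_i <- config
    cfg_i$seed <- seed_i
    ids <- subsample_patients(unique(train_data$patient_id),
                              frac = subsample_frac, seed = seed_i)
    sub <- subset_transitions(train_data, ids)
    artifacts[[i]] <- train_dcql(sub, cfg_i, engine = engine)
    fqe <- do.call(fqe_evaluate, c(
      list(dataset = test_data, policy = artifacts[[i]],
           gamma = config$discount, seed = seed_i),
      fqe_args))
    results[[i]] <- fqe$result
    if (verbose) {
      message(sprintf("model %d/%d (seed %d): FQE %.4f [%.4f, %.4f]",
                      i, n_models, seed_i, fqe$result$mean_value,
                      fqe$result$ci_low, fqe$result$ci_high))
    }
  }
  best <- select_best(results)
  leaderboard <- data.frame(
    model = seq_len(n_models),
    seed = config$seed + seq_len(n_models) - 1L,
    mean_value = vapply(results, function(r) r$mean_value, numeric(1)),
    ci_low = vapply(results, function(r) r$ci_low, numeric(1)),
    ci_high = vapply(results, function(r) r$ci_high, numeric(1)),
    selected = seq_len(n_models) == best
  )
  list(best = artifacts[[best]], best_index = best, results = results,
       leaderboard = leaderboard)
}
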