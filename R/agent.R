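#' Configuration of the conservative distributional Q-learning agent
#'
#' Hyperparameters of the continuous-action conservative Q-learning (CQL)
#' agent with an implicit-quantile (IQN) critic. Published settings: discount
#' 0.67 (a three-hour effective horizon, `1/(1-gamma)`), batches of 256,
#' actor/critic learning rates 1e-4 and 3e-4, three 512-unit hidden layers
#' and dropout 0.1. The remaining knobs (conservatism weight, quantile sample
#' counts, embedding dimension, Huber threshold, target sync rate,
#' out-of-distribution action samples, entropy weight, sampling temperature)
#' are implementation choices following the CQL and IQN reference
#' formulations, all exposed here.
#'
#' @param discount Discount factor gamma in (0, 1).
#' @param batch_size Transitions per gradient step.
#' @param actor_lr,critic_lr Adam learning rates.
#' @param hidden_layers Integer vector of hidden widths (>= 2 layers).
#' @param dropout_p Dropout probability on hidden activations in training.
#' @param cql_alpha Weight of the conservative penalty; 0 disables it.
#' @param n_quantile_samples Quantile fractions sampled per transition for
#'   the online critic (and the same number for the distributional Bellman
#'   target).
#' @param quantile_embed_dim Dimension of the cosine embedding of tau.
#' @param huber_kappa Huber threshold of the quantile regression loss.
#' @param n_ood_action_samples Uniform actions in `[0, action_max]` sampled
#'   per state for the conservative term.
#' @param n_actor_action_samples Actor-sampled actions added to the
#'   conservative term's comparison set.
#' @param n_cql_quantile_samples Quantile samples used when collapsing the
#'   critic to an expected Q (conservative term and actor objective).
#' @param target_sync_rate Polyak rate for the target critic.
#' @param gradient_steps Number of gradient steps.
#' @param seed Integer seed; all training randomness derives from it.
#' @param return_sampling_temperature Softmax temperature of return-weighted
#'   transition sampling; `Inf` gives uniform sampling.
#' @param entropy_coeff Weight of the actor's entropy bonus.
#' @param action_max Dose cap in units.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(discount = 0.67,
                         batch_size = 256,
                         actor_lr = 1e-4,
                         critic_lr = 3e-4,
                         hidden_layers = c(512, 512, 512),
                         dropout_p = 0.1,
                         cql_alpha = 5.0,
                         n_quantile_samples = 8,
                         quantile_embed_dim = 64,
                         huber_kappa = 1.0,
                         n_ood_action_samples = 10,
                         n_actor_action_samples = 4,
                         n_cql_quantile_samples = 4,
                         target_sync_rate = 0.005,
                         gradient_steps = 5000,
                         seed = 1L,
                         return_sampling_temperature = 1.0,
                         entropy_coeff = 0.05,
                         action_max = 10) {
  stopifnot(discount > 0, discount < 1,
            batch_size >= 1, actor_lr > 0, critic_lr > 0,
            length(hidden_layers) >= 2, all(hidden_layers >= 1),
            dropout_p >= 0, dropout_p < 1,
            cql_alpha >= 0, n_quantile_samples >= 1,
            quantile_embed_dim >= 1, huber_kappa > 0,
            n_ood_action_samples >= 1, n_actor_action_samples >= 0,
            n_cql_quantile_samples >= 1,
            target_sync_rate > 0, target_sync_rate <= 1,
            gradient_steps >= 1,
            return_sampling_temperature > 0,
            entropy_coeff >= 0, action_max > 0)
  structure(as.list(environment()), class = "agent_config")
}

#' @export
print.agent_config <- function(x, ...) {
  cat(sprintf(
    "CQL+IQN agent config: gamma %.2f, batch %d, lr %g/%g, hidden [%s]\n",
    x$discount, x$batch_size, x$actor_lr, x$critic_lr,
    paste(x$hidden_layers, collapse = ", ")))
  cat(sprintf("  cql_alpha %g, %d quantile samples, %d+%d OOD actions, %d steps\n",
              x$cql_alpha, x$n_quantile_samples, x$n_ood_action_samples,
              x$n_actor_action_samples, x$gradient_steps))
  invisible(x)
}

# ---- networks --------------------------------------------------------------

init_critic <- function(d_state, cfg) {
  h <- cfg$hidden_layers
  L <- length(h)
  base_sizes <- c(d_state + 1L, h[seq_len(L - 1L)])
  list(
    base = lapply(seq_len(L - 1L), function(i) {
      init_dense(base_sizes[i], base_sizes[i + 1L])
    }),
    tau = init_dense(cfg$quantile_embed_dim, h[L - 1L]),
    head = list(init_dense(h[L - 1L], h[L]), init_dense(h[L], 1L))
  )
}

init_actor <- function(d_state, cfg) {
  init_mlp(d_state, c(cfg$hidden_layers, 2L))
}

cosine_embed <- function(taus, d_embed) {
  cos(outer(taus, seq_len(d_embed) - 1L) * pi)
}

# Critic forward pass on the autodiff graph.
# s: matrix or node (n x d); a: vector, matrix or node (n x 1, units);
# taus: length n*k vector, k fractions per tiled row. Returns an n x k node.
critic_graph <- function(wp, s, a, taus, n, k, cfg, train = FALSE) {
  a_node <- if (is_ad(a)) a else ad_const(matrix(a, ncol = 1L))
  s_node <- if (is_ad(s)) s else ad_const(s)
  x <- ad_cbind(s_node, ad_scale(a_node, 1 / cfg$action_max))
  dmask <- function(nr, nc) {
    if (!train || cfg$dropout_p <= 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1L, 1 - cfg$dropout_p), nr) /
      (1 - cfg$dropout_p)
  }
  for (layer in wp$base) {
    x <- ad_dense(x, layer$W, layer$b, relu = TRUE,
                  drop_mask = dmask(nrow(x$value), ncol(layer$W$value)))
  }
  if (k > 1L) x <- ad_repeat_rows(x, k)
  phi <- ad_dense(ad_const(cosine_embed(taus, cfg$quantile_embed_dim)),
                  wp$tau$W, wp$tau$b, relu = TRUE)
  h <- ad_mul(x, phi)
  h <- ad_dense(h, wp$head[[1]]$W, wp$head[[1]]$b, relu = TRUE,
                drop_mask = dmask(nrow(h$value), ncol(wp$head[[1]]$W$value)))
  z <- ad_dense(h, wp$head[[2]]$W, wp$head[[2]]$b)
  ad_col_to_mat(z, n, k)
}

# Plain inference version: params are raw matrices; returns an n x k matrix.
critic_infer <- function(params, s, a, taus, k, cfg) {
  s <- as_mat(s)
  n <- nrow(s)
  x <- cbind(s, matrix(a, ncol = 1L) / cfg$action_max)
  for (layer in params$base) {
    x <- pmax(sweep(x %*% layer$W, 2L, layer$b, "+"), 0)
  }
  if (k > 1L) x <- x[rep(seq_len(n), each = k), , drop = FALSE]
  phi <- pmax(sweep(cosine_embed(taus, cfg$quantile_embed_dim) %*%
                      params$tau$W, 2L, params$tau$b, "+"), 0)
  h <- x * phi
  h <- pmax(sweep(h %*% params$head[[1]]$W, 2L, params$head[[1]]$b, "+"), 0)
  z <- sweep(h %*% params$head[[2]]$W, 2L, params$head[[2]]$b, "+")
  matrix(z, n, k, byrow = TRUE)
}

# Actor heads from raw network output: mean and bounded log-sd in z-space.
actor_heads_infer <- function(params, s) {
  out <- mlp_infer(s, params)
  list(mu = out[, 1L], log_std = 2 * tanh(out[, 2L]) - 1)
}

squash_action <- function(z, action_max) action_max / 2 * (tanh(z) + 1)

# Numeric (no-graph) action sample from the current actor.
actor_sample_infer <- function(params, s, cfg, deterministic = FALSE) {
  heads <- actor_heads_infer(params, s)
  z <- if (deterministic) heads$mu else {
    heads$mu + exp(heads$log_std) * stats::rnorm(length(heads$mu))
  }
  squash_action(z, cfg$action_max)
}

# ---- training --------------------------------------------------------------

episode_sampling_weights <- function(dataset, gamma, temperature) {
  returns <- vapply(dataset$episodes, function(idx) {
    sum(gamma^(seq_along(idx) - 1L) * dataset$rewards[idx])
  }, numeric(1))
  if (!length(returns) || all(!is.finite(returns))) {
    warning("no usable episode returns; falling back to uniform sampling",
            call. = FALSE)
    return(rep(1 / length(dataset$actions), length(dataset$actions)))
  }
  w_ep <- if (is.infinite(temperature)) {
    rep(1, length(returns))
  } else {
    exp((returns - max(returns)) / temperature)
  }
  w <- numeric(length(dataset$actions))
  for (e in seq_along(dataset$episodes)) {
    w[dataset$episodes[[e]]] <- w_ep[e]
  }
  w / sum(w)
}

#' Train the conservative distributional Q-learning agent
#'
#' Offline training on a transition dataset. The critic is an implicit
#' quantile network over (state, dose) pairs fit by quantile-regression Huber
#' loss against distributional Bellman targets from a Polyak-averaged target
#' critic, plus a conservative penalty `cql_alpha * (logsumexp of expected Q
#' over sampled out-of-distribution doses - expected Q at the logged dose)`.
#' The actor is a squashed-Gaussian policy over `[0, action_max]` maximizing
#' the critic's expected value with an entropy bonus. Batches are sampled
#' with per-transition probability proportional to the softmax of their
#' episode's discounted return. All randomness derives from `config$seed`.
#'
#' @param dataset A `transition_dataset` from [build_transitions()].
#' @param config An [agent_config()].
#' @param verbose Print progress every 500 steps.
#' @param engine `"cpp"` (compiled gradient step, default) or `"r"` (the
#'   autodiff reference implementation; identical gradients at
#'   `dropout_p = 0`, but slower).
#' @return An object of class `policy_artifact`: actor and critic parameters,
#'   the config, normalization statistics and feature names of the training
#'   data, and a training log.
#' @export
train_dcql <- function(dataset, config = agent_config(), verbose = FALSE,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(dataset, "transition_dataset"),
            inherits(config, "agent_config"))
  n_tr <- length(dataset$actions)
  if (n_tr == 0L) stop("empty dataset", call. = FALSE)
  d <- ncol(dataset$states)
  cfg <- config
  local_seed(cfg$seed)

  actor <- init_actor(d, cfg)
  critic <- init_critic(d, cfg)
  target <- critic
  opt_a <- adam_init(actor, lr = cfg$actor_lr)
  opt_c <- adam_init(critic, lr = cfg$critic_lr)

  w <- episode_sampling_weights(dataset, cfg$discount,
                                cfg$return_sampling_temperature)
  cumw <- cumsum(w)
  cumw <- cumw / cumw[n_tr]

  B <- min(cfg$batch_size, n_tr)
  log_every <- max(50L, cfg$gradient_steps %/% 100L)
  log_rows <- list()

  for (step in seq_len(cfg$gradient_steps)) {
    idx <- findInterval(stats::runif(B), cumw) + 1L
    res <- dcql_step(critic, target, actor, dataset, idx, cfg, engine)

    upd <- adam_step(critic, res$critic_grads, opt_c)
    critic <- upd$params
    opt_c <- upd$state
    upd <- adam_step(actor, res$actor_grads, opt_a)
    actor <- upd$params
    opt_a <- upd$state
    target <- polyak(target, critic, cfg$target_sync_rate)

    if (!is.finite(res$critic_loss) || !is.finite(res$actor_loss)) {
      stop(sprintf(
        "non-finite loss at step %d (critic %.4g, td %.4g, cql %.4g, actor %.4g)",
        step, res$critic_loss, res$td_loss, res$cql_loss, res$actor_loss),
        call. = FALSE)
    }
    if (step %% log_every == 0L || step == 1L) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, critic_loss = res$critic_loss, td_loss = res$td_loss,
        cql_loss = res$cql_loss, actor_loss = res$actor_loss)
      if (verbose && step %% 500L == 0L) {
        message(sprintf("step %d: critic %.4f (td %.4f, cql %.4f) actor %.4f",
                        step, res$critic_loss, res$td_loss, res$cql_loss,
                        res$actor_loss))
      }
    }
  }

  structure(list(
    actor = actor, critic = critic, target_critic = target,
    config = cfg, norm_stats = dataset$norm_stats,
    feature_names = dataset$feature_names,
    log = do.call(rbind, log_rows)
  ), class = "policy_artifact")
}

#' @export
print.policy_artifact <- function(x, ...) {
  cat(sprintf("Trained dosing policy: %d features, hidden [%s], seed %d\n",
              length(x$feature_names),
              paste(x$config$hidden_layers, collapse = ", "), x$config$seed))
  if (!is.null(x$log) && nrow(x$log)) {
    tail1 <- x$log[nrow(x$log), ]
    cat(sprintf("  final losses: critic %.4f (td %.4f, cql %.4f), actor %.4f\n",
                tail1$critic_loss, tail1$td_loss, tail1$cql_loss,
                tail1$actor_loss))
  }
  invisible(x)
}

check_state_matrix <- function(artifact, state) {
  d <- length(artifact$feature_names)
  if (is.null(dim(state))) {
    if (length(state) != d) {
      stop(sprintf("state has %d features; artifact expects %d",
                   length(state), d), call. = FALSE)
    }
    state <- matrix(state, nrow = 1L)
  } else if (ncol(state) != d) {
    stop(sprintf("state has %d columns; artifact expects %d",
                 ncol(state), d), call. = FALSE)
  }
  cn <- colnames(state)
  if (!is.null(cn) && !identical(cn, artifact$feature_names)) {
    if (!setequal(cn, artifact$feature_names)) {
      stop("state feature names do not match the artifact", call. = FALSE)
    }
    state <- state[, artifact$feature_names, drop = FALSE]
  }
  state
}

#' Recommend an integer insulin dose
#'
#' Deterministic recommendation: the actor's mean action, clipped to
#' `[0, action_max]` and rounded half-up to the nearest integer unit.
#'
#' @param artifact A `policy_artifact` from [train_dcql()].
#' @param state Normalized feature vector (or matrix of rows) matching the
#'   artifact's feature names.
#' @return Integer dose(s) in `0:action_max`.
#' @export
recommend_dose <- function(artifact, state) {
  stopifnot(inherits(artifact, "policy_artifact"))
  state <- check_state_matrix(artifact, state)
  amax <- artifact$config$action_max
  a <- actor_sample_infer(artifact$actor, state, artifact$config,
                          deterministic = TRUE)
  as.integer(floor(clip(a, 0, amax) + 0.5))
}

#' Evaluate critic return quantiles
#'
#' Returns the critic's estimated return quantiles for a (state, dose) pair
#' at the requested quantile fractions; averaging over many uniform fractions
#' approximates the expected Q value.
#'
#' @param artifact A `policy_artifact`.
#' @param state Normalized feature vector.
#' @param action Dose in units.
#' @param taus Quantile fractions in (0, 1).
#' @return A data.frame with columns `tau` and `value`.
#' @export
critic_quantiles <- function(artifact, state, action, taus) {
  stopifnot(inherits(artifact, "policy_artifact"))
  if (any(taus <= 0) || any(taus >= 1)) {
    stop("taus must lie strictly inside (0, 1)", call. = FALSE)
  }
  state <- check_state_matrix(artifact, state)
  if (nrow(state) != 1L) stop("one state at a time", call. = FALSE)
  z <- critic_infer(artifact$critic, state, action, taus, length(taus),
                    artifact$config)
  data.frame(tau = taus, value = as.numeric(z))
}

#' Wrap a trained artifact as a simulator rollout policy
#'
#' Produces a `function(history, patient)` suitable for [rollout_policy()]:
#' at each hour it assembles the artifact's state features from the raw
#' trajectory history (glucose lags/deltas backfilled exactly as in
#' [engineer_glucose_features()]), normalizes them with the artifact's
#' training statistics and returns the recommended integer dose. Hours
#' before the first glucose measurement receive dose 0.
#'
#' @param artifact A `policy_artifact`.
#' @return A policy function for the simulator.
#' @export
policy_from_artifact <- function(artifact) {
  stopifnot(inherits(artifact, "policy_artifact"))
  feats <- artifact$feature_names
  stats <- artifact$norm_stats
  force(artifact)
  function(history, patient) {
    t_now <- nrow(history)
    g_obs <- history$glucose[!is.na(history$glucose)]
    if (!length(g_obs)) return(0)
    g0 <- g_obs[1]
    gl <- function(k) {
      i <- t_now - k
      if (i >= 1 && !is.na(history$glucose[i])) history$glucose[i] else g0
    }
    g_now <- if (is.na(history$glucose[t_now])) g0 else history$glucose[t_now]
    lags <- c(gl(1), gl(2), gl(3), gl(4))
    prev_dose <- if (t_now > 1) history$insulin[t_now - 1L] else 0
    derived <- c(
      glucose_lag1 = lags[1], glucose_lag2 = lags[2],
      glucose_lag3 = lags[3], glucose_lag4 = lags[4],
      glucose_delta1 = g_now - lags[1], glucose_delta2 = lags[1] - lags[2],
      glucose_delta3 = lags[2] - lags[3], glucose_delta4 = lags[3] - lags[4],
      insulin_lag1 = prev_dose,
      delta_insulin_ratio = (g_now - lags[1]) / max(prev_dose, 0.1)
    )
    raw <- numeric(length(feats))
    names(raw) <- feats
    for (f in feats) {
      raw[f] <- if (f %in% names(derived)) {
        derived[[f]]
      } else if (f %in% names(history)) {
        v <- history[[f]][t_now]
        if (is.na(v)) {
          vv <- history[[f]][!is.na(history[[f]])]
          if (length(vv)) vv[length(vv)] else
            (stats$min[[f]] + stats$max[[f]]) / 2
        } else v
      } else if (f %in% names(patient)) {
        patient[[f]]
      } else {
        (stats$min[[f]] + stats$max[[f]]) / 2
      }
    }
    rng <- stats$max[feats] - stats$min[feats]
    x <- clip((raw - stats$min[feats]) / rng, 0, 1)
    as.numeric(recommend_dose(artifact, x))
  }
}
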