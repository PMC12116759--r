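# Shared fixtures and independent oracles, all built in code.

# ---- tabular MDP oracle ----------------------------------------------------

# Random episodic tabular MDP: n_s states, doses `actions` (in units),
# per-step continuation probability `cont_prob` (absorbing termination),
# uniform-random behaviour policy for logging.
random_tabular_mdp <- function(n_s = 4, actions = c(0, 1, 2),
                               cont_prob = 0.9, seed = 1) {
  set.seed(seed)
  n_a <- length(actions)
  P <- array(0, dim = c(n_s, n_a, n_s))
  for (s in seq_len(n_s)) {
    for (a in seq_len(n_a)) {
      w <- rexp(n_s)
      P[s, a, ] <- w / sum(w)
    }
  }
  R <- matrix(runif(n_s * n_a, -1, 0.2), n_s, n_a)
  list(n_s = n_s, actions = actions, P = P, R = R, cont_prob = cont_prob)
}

# Exact value of a deterministic policy (state -> action index) by solving
# the linear system V = R_pi + gamma * cont * P_pi V.
dp_policy_value <- function(mdp, policy_idx, gamma) {
  n_s <- mdp$n_s
  P_pi <- t(vapply(seq_len(n_s), function(s) mdp$P[s, policy_idx[s], ],
                   numeric(n_s)))
  R_pi <- vapply(seq_len(n_s), function(s) mdp$R[s, policy_idx[s]],
                 numeric(1))
  solve(diag(n_s) - gamma * mdp$cont_prob * P_pi, R_pi)
}

# Log episodes from the uniform behaviour policy and package them as a
# transition_dataset with one-hot state features.
log_tabular_episodes <- function(mdp, n_episodes = 150, max_len = 30,
                                 seed = 1, start_state = 1L) {
  set.seed(seed)
  n_s <- mdp$n_s
  n_a <- length(mdp$actions)
  rows <- list()
  for (e in seq_len(n_episodes)) {
    s <- start_state
    for (t in seq_len(max_len)) {
      a <- sample.int(n_a, 1)
      r <- mdp$R[s, a]
      s2 <- sample.int(n_s, 1, prob = mdp$P[s, a, ])
      done <- runif(1) > mdp$cont_prob || t == max_len
      rows[[length(rows) + 1L]] <- c(e, t, s, a, r, s2, done)
      s <- s2
      if (done) break
    }
  }
  m <- do.call(rbind, rows)
  onehot <- function(s) {
    out <- matrix(0, length(s), n_s)
    out[cbind(seq_along(s), s)] <- 1
    colnames(out) <- paste0("s", seq_len(n_s))
    out
  }
  pid <- sprintf("E%04d", m[, 1])
  structure(list(
    states = onehot(m[, 3]),
    actions = mdp$actions[m[, 4]],
    rewards = m[, 5],
    next_states = onehot(m[, 6]),
    done = as.logical(m[, 7]),
    patient_id = pid,
    hour = m[, 2],
    glucose = rep(150, nrow(m)),
    glucose_next = rep(150, nrow(m)),
    feature_names = paste0("s", seq_len(n_s)),
    norm_stats = list(min = stats::setNames(rep(0, n_s), paste0("s", 1:n_s)),
                      max = stats::setNames(rep(1, n_s), paste0("s", 1:n_s)),
                      features = paste0("s", seq_len(n_s))),
    episodes = split(seq_len(nrow(m)), pid)[unique(pid)]
  ), class = "transition_dataset")
}

# Policy function over one-hot states from an action-index map.
tabular_policy_fn <- function(mdp, policy_idx) {
  function(states) {
    s <- max.col(states)
    mdp$actions[policy_idx[s]]
  }
}

# ---- tiny agent fixtures ---------------------------------------------------

# Contextual bandit: constant state, integer doses with known best dose.
make_bandit_dataset <- function(doses = 0:5, best = 2, n_per = 40,
                                good = 0.2, bad = -1, d = 3) {
  a <- rep(doses, each = n_per)
  n <- length(a)
  states <- matrix(0.5, n, d)
  colnames(states) <- paste0("f", seq_len(d))
  pid <- sprintf("B%04d", seq_len(n))
  structure(list(
    states = states, actions = as.numeric(a),
    rewards = ifelse(a == best, good, bad),
    next_states = states, done = rep(TRUE, n),
    patient_id = pid, hour = rep(0L, n),
    glucose = rep(150, n), glucose_next = rep(150, n),
    feature_names = colnames(states),
    norm_stats = list(
      min = stats::setNames(rep(0, d), colnames(states)),
      max = stats::setNames(rep(1, d), colnames(states)),
      features = colnames(states)),
    episodes = split(seq_len(n), pid)[unique(pid)]
  ), class = "transition_dataset")
}

# Self-looping chain with constant reward, for the discount sanity check.
make_chain_dataset <- function(n_episodes = 30, len = 40, reward = 0.2,
                               d = 3) {
  n <- n_episodes * len
  states <- matrix(0.5, n, d)
  colnames(states) <- paste0("f", seq_len(d))
  pid <- rep(sprintf("C%03d", seq_len(n_episodes)), each = len)
  structure(list(
    states = states, actions = rep(0, n), rewards = rep(reward, n),
    next_states = states,
    done = rep(c(rep(FALSE, len - 1), TRUE), n_episodes),
    patient_id = pid, hour = rep(seq_len(len) - 1L, n_episodes),
    glucose = rep(150, n), glucose_next = rep(150, n),
    feature_names = colnames(states),
    norm_stats = list(
      min = stats::setNames(rep(0, d), colnames(states)),
      max = stats::setNames(rep(1, d), colnames(states)),
      features = colnames(states)),
    episodes = split(seq_len(n), pid)[unique(pid)]
  ), class = "transition_dataset")
}

# Small agent config for fast tests.
test_agent_config <- function(...) {
  defaults <- list(hidden_layers = c(32, 32), batch_size = 128,
                   quantile_embed_dim = 16, n_quantile_samples = 8,
                   n_cql_quantile_samples = 2, n_ood_action_samples = 8,
                   n_actor_action_samples = 2, cql_alpha = 1,
                   actor_lr = 1e-3, critic_lr = 3e-3, dropout_p = 0,
                   return_sampling_temperature = Inf, gradient_steps = 1500,
                   seed = 7)
  do.call(agent_config, utils::modifyList(defaults, list(...)))
}

# Monte-Carlo value of a rolled-out cohort under the shaped reward.
mc_cohort_value <- function(cohort, gamma = 0.67) {
  sp <- split(cohort$trajectories, cohort$trajectories$patient_id)
  vals <- vapply(sp, function(p) {
    g <- p$glucose
    a <- p$insulin
    ok <- which(!is.na(g))
    if (length(ok) < 2) return(NA_real_)
    r <- shaped_reward(pmin(pmax(g[ok][-1], 20), 600),
                       a[ok][-length(ok)])
    sum(gamma^(seq_along(r) - 1) * r)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# The deterministic sliding scale as a rollout policy function.
sliding_scale_rollout_policy <- function(history, patient) {
  g <- history$glucose[nrow(history)]
  if (is.na(g)) return(0)
  sliding_scale_policy(max(g, 21))
}
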