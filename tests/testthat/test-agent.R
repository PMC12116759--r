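test_that("training is deterministic under the seed", {
  ds <- make_bandit_dataset()
  cfg <- test_agent_config(gradient_steps = 120)
  a1 <- train_dcql(ds, cfg)
  a2 <- train_dcql(ds, cfg)
  probe <- matrix(runif(50 * 3), 50, 3)
  expect_identical(recommend_dose(a1, probe), recommend_dose(a2, probe))
  expect_identical(a1$actor, a2$actor)
  cfg2 <- test_agent_config(gradient_steps = 120, seed = 8)
  a3 <- train_dcql(ds, cfg2)
  expect_false(identical(a1$actor, a3$actor))
})

test_that("the trained policy recovers the enumerable bandit optimum", {
  ds <- make_bandit_dataset(doses = 0:5, best = 2)
  art <- train_dcql(ds, test_agent_config())
  expect_equal(recommend_dose(art, rep(0.5, 3)), 2L)
  # the critic agrees: expected Q peaks at the rewarded dose among the
  # doses present in the data
  q <- vapply(0:5, function(a) {
    mean(critic_quantiles(art, rep(0.5, 3), a, seq(0.05, 0.95, 0.05))$value)
  }, numeric(1))
  expect_equal(which.max(q) - 1L, 2L)
})

test_that("recommendations are integers in 0..10 with half-up rounding", {
  ds <- make_bandit_dataset()
  art <- train_dcql(ds, test_agent_config(gradient_steps = 60))
  probe <- matrix(runif(200 * 3), 200, 3)
  rec <- recommend_dose(art, probe)
  expect_true(all(rec %in% 0:10))
  expect_type(rec, "integer")
  # force the actor mean to a known value and check the rounding rule:
  # squashed mean a = 5 * (tanh(mu) + 1)
  for (target in c(2.5, 2.49, 9.999)) {
    art2 <- art
    nl <- length(art2$actor)
    art2$actor[[nl]]$W[] <- 0
    art2$actor[[nl]]$b[1, 1] <- atanh(target / 5 - 1)
    expect_equal(recommend_dose(art2, rep(0.5, 3)),
                 as.integer(floor(target + 0.5)))
  }
  expect_error(recommend_dose(art, rep(0.5, 7)), "features")
})

test_that("critic quantiles behave like a return distribution", {
  # degenerate bandit: single action, constant reward 0.2; conservatism
  # off so the distributional regression is tested in isolation
  ds <- make_bandit_dataset(doses = 2, best = 2, n_per = 120)
  art <- train_dcql(ds, test_agent_config(gradient_steps = 2000,
                                          cql_alpha = 0))
  qq <- critic_quantiles(art, rep(0.5, 3), 2, seq(0.1, 0.9, 0.1))
  expect_true(all(abs(qq$value - 0.2) < 0.05))
  # Monte-Carlo consistency of the tau average
  set.seed(1)
  m64 <- mean(critic_quantiles(art, rep(0.5, 3), 2, runif(64))$value)
  m256 <- mean(critic_quantiles(art, rep(0.5, 3), 2, runif(256))$value)
  expect_lt(abs(m64 - m256), 0.05)
  expect_error(critic_quantiles(art, rep(0.5, 3), 2, c(0.5, 1)), "inside")
})

test_that("the critic learns a two-point return distribution's spread", {
  # same dose rewarded -1 or 0.2 with equal probability
  a <- rep(2, 240)
  rew <- rep(c(-1, 0.2), 120)
  states <- matrix(0.5, 240, 3)
  colnames(states) <- paste0("f", 1:3)
  pid <- sprintf("B%04d", seq_len(240))
  ds <- structure(list(
    states = states, actions = a, rewards = rew, next_states = states,
    done = rep(TRUE, 240), patient_id = pid, hour = rep(0L, 240),
    glucose = rep(150, 240), glucose_next = rep(150, 240),
    feature_names = colnames(states),
    norm_stats = list(min = c(f1 = 0, f2 = 0, f3 = 0),
                      max = c(f1 = 1, f2 = 1, f3 = 1),
                      features = colnames(states)),
    episodes = split(seq_len(240), pid)[unique(pid)]
  ), class = "transition_dataset")
  art <- train_dcql(ds, test_agent_config(gradient_steps = 2500))
  q25 <- mean(critic_quantiles(art, rep(0.5, 3), 2, rep(0.25, 8))$value)
  q75 <- mean(critic_quantiles(art, rep(0.5, 3), 2, rep(0.75, 8))$value)
  expect_lt(q25, q75)
})

test_that("conservatism pushes unsupported doses below supported ones", {
  ds <- make_bandit_dataset(doses = 0:2, best = 1, n_per = 60)
  cfg_cql <- test_agent_config(gradient_steps = 1200, cql_alpha = 2)
  cfg_abl <- test_agent_config(gradient_steps = 1200, cql_alpha = 0)
  art_cql <- train_dcql(ds, cfg_cql)
  art_abl <- train_dcql(ds, cfg_abl)
  expected_q <- function(art, a) {
    mean(critic_quantiles(art, rep(0.5, 3), a, seq(0.05, 0.95, 0.05))$value)
  }
  q8_cql <- expected_q(art_cql, 8)
  q8_abl <- expected_q(art_abl, 8)
  best_in_data <- max(vapply(0:2, function(a) expected_q(art_cql, a),
                             numeric(1)))
  expect_lte(q8_cql, best_in_data)
  expect_lte(q8_cql, q8_abl)
})

test_that("long-horizon value matches the geometric series", {
  # every step pays 0.2 regardless of action, so the value of the logged
  # behaviour is 0.2 / (1 - 0.67); mild conservatism keeps bootstrapping
  # off-data actions from inflating the estimate
  ds <- make_chain_dataset(reward = 0.2)
  cfg <- test_agent_config(gradient_steps = 3000, cql_alpha = 0.1,
                           target_sync_rate = 0.01)
  art <- train_dcql(ds, cfg)
  v <- mean(critic_quantiles(art, rep(0.5, 3), 0,
                             seq(0.05, 0.95, 0.05))$value)
  expect_lt(abs(v - 0.2 / (1 - 0.67)), 0.1)
})

test_that("return-weighted sampling interpolates uniform to greedy", {
  ds <- make_chain_dataset(n_episodes = 4, len = 5, reward = 0.1)
  ds$rewards[ds$episodes[[4]]] <- 0.2   # one clearly better episode
  w_unif <- insulinrl:::episode_sampling_weights(ds, 0.67, Inf)
  expect_equal(w_unif, rep(1 / 20, 20))
  set.seed(1)
  draws <- sample.int(20, 1e5, replace = TRUE, prob = w_unif)
  freq <- tabulate(draws, 20) / 1e5
  expect_true(all(abs(freq - 1 / 20) < 0.02))
  w_sharp <- insulinrl:::episode_sampling_weights(ds, 0.67, 0.01)
  expect_gt(sum(w_sharp[ds$episodes[[4]]]), 0.999)
  w_mid <- insulinrl:::episode_sampling_weights(ds, 0.67, 1)
  expect_gt(sum(w_mid[ds$episodes[[4]]]), 0.25)
  expect_lt(sum(w_mid[ds$episodes[[4]]]), 0.999)
})

test_that("non-finite rewards abort training with diagnostics", {
  ds <- make_bandit_dataset()
  ds$rewards[1] <- NaN
  expect_error(train_dcql(ds, test_agent_config(gradient_steps = 50)),
               "non-finite loss")
})

test_that("empty datasets and bad configs are rejected", {
  expect_error(agent_config(discount = 1.2))
  expect_error(agent_config(hidden_layers = 32))
  ds <- make_bandit_dataset()
  ds$actions <- numeric(0)
  expect_error(train_dcql(ds, test_agent_config()), "empty")
})

test_that("artifact rollout policies reproduce pipeline feature engineering", {
  co <- simulate_cohort(sim_config(n_patients = 40, seed = 31))
  mdp <- build_mdp(co, seed = 31)
  art <- train_dcql(mdp$train, test_agent_config(gradient_steps = 150))
  pol <- policy_from_artifact(art)
  # the wrapped policy must agree with recommend_dose on logged states
  ds <- mdp$test
  i <- ds$episodes[[1]][3]
  direct <- recommend_dose(art, ds$states[i, ])
  ro <- rollout_policy(pol, sim_config(n_patients = 3, seed = 31))
  expect_true(all(ro$trajectories$insulin %in% 0:10))
  expect_true(is.numeric(direct))
})
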