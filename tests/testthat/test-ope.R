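test_that("discounted episode returns match hand-computed sums", {
  ds <- make_chain_dataset(n_episodes = 1, len = 3, reward = 1)
  br <- behavior_returns(ds, gamma = 0.67, n_bootstrap = 100)
  expect_equal(br$returns[[1]], 1 + 0.67 + 0.67^2)
  expect_equal(br$returns[[1]], 2.1189)
  ds1 <- make_chain_dataset(n_episodes = 1, len = 1, reward = -0.37)
  expect_equal(behavior_returns(ds1, n_bootstrap = 50)$returns[[1]], -0.37)
  ds24 <- make_chain_dataset(n_episodes = 1, len = 24, reward = 0.2)
  expect_equal(behavior_returns(ds24, gamma = 0.67,
                                n_bootstrap = 50)$returns[[1]],
               0.2 * (1 - 0.67^24) / (1 - 0.67))
  expect_equal(behavior_returns(ds24, gamma = 0.67,
                                n_bootstrap = 50)$returns[[1]],
               0.6060, tolerance = 1e-4)
})

test_that("bootstrap CI is degenerate for constant data and seeded", {
  ci <- bootstrap_ci(rep(3.5, 20), n_resamples = 500, seed = 1)
  expect_equal(ci, c(3.5, 3.5))
  ci1 <- bootstrap_ci(rnorm(50), n_resamples = 2000, seed = 9)
  set.seed(42)  # unrelated global state must not matter
  ci2 <- bootstrap_ci(rnorm(50), n_resamples = 2000, seed = 9)
  expect_false(identical(ci1, ci2))  # different data
  x <- rnorm(50)
  expect_identical(bootstrap_ci(x, 2000, seed = 9),
                   bootstrap_ci(x, 2000, seed = 9))
  expect_error(bootstrap_ci(numeric(0)), "no values")
})

test_that("bootstrap CI matches exhaustive enumeration on three points", {
  # data {0, 0, 1}: all 27 equally likely resamples have known means
  x <- c(0, 0, 1)
  grid <- expand.grid(1:3, 1:3, 1:3)
  exact_means <- apply(grid, 1, function(idx) mean(x[idx]))
  # inverse CDF of the exact (discrete) resample-mean distribution
  inv_cdf <- function(p) {
    tab <- table(exact_means) / length(exact_means)
    vals <- as.numeric(names(tab))
    vals[which(cumsum(tab) >= p)[1]]
  }
  ci <- bootstrap_ci(x, n_resamples = 1e5, seed = 3)
  expect_equal(ci[1], inv_cdf(0.025), tolerance = 0.05)
  expect_equal(ci[2], inv_cdf(0.975), tolerance = 0.05)
  # CI brackets the sample mean for symmetric data
  y <- seq(-1, 1, length.out = 21)
  ciy <- bootstrap_ci(y, 2000, seed = 2)
  expect_lte(ciy[1], mean(y))
  expect_gte(ciy[2], mean(y))
})

test_that("bootstrap CI width shrinks like one over root n", {
  set.seed(11)
  x4 <- rnorm(2000)
  x1 <- x4[1:500]
  w1 <- diff(bootstrap_ci(x1, 4000, seed = 5))
  w4 <- diff(bootstrap_ci(x4, 4000, seed = 5))
  expect_lt(abs(w1 / w4 - 2), 2 * 0.25)
})

test_that("model selection maximizes the CI lower bound with first-index ties", {
  mk <- function(lo) {
    structure(list(mean_value = lo + 0.5, ci_low = lo, ci_high = lo + 1,
                   n_episodes = 10, n_bootstrap = 100, method = "fqe"),
              class = "ope_result")
  }
  expect_equal(select_best(list(mk(-1.2), mk(-0.9), mk(-1.0))), 2)
  expect_equal(select_best(list(mk(-0.5))), 1)
  expect_equal(select_best(list(mk(-0.9), mk(-0.9))), 1)
  expect_error(select_best(list()), "no results")
})

test_that("FQE matches exact dynamic programming on a small tabular MDP", {
  mdp <- random_tabular_mdp(n_s = 3, actions = c(0, 1), seed = 4)
  policy_idx <- c(2L, 1L, 2L)
  gamma <- 0.67
  exact <- dp_policy_value(mdp, policy_idx, gamma)
  ds <- log_tabular_episodes(mdp, n_episodes = 200, seed = 5)
  fqe <- fqe_evaluate(ds, tabular_policy_fn(mdp, policy_idx), gamma = gamma,
                      hidden = c(32, 32), lr = 1e-3, steps = 1200,
                      batch_size = 128, n_bootstrap = 200, seed = 6)
  expect_lt(abs(fqe$result$mean_value - exact[1]), 0.05)
})

test_that("FQE of the behaviour policy agrees with its empirical return", {
  # deterministic behaviour: episodes are on-policy for it
  mdp <- random_tabular_mdp(n_s = 3, actions = c(0, 1, 2), seed = 7)
  policy_idx <- c(1L, 3L, 2L)
  set.seed(8)
  # log under the SAME deterministic policy
  rows <- list()
  for (e in 1:200) {
    s <- 1L
    for (t in 1:30) {
      a <- policy_idx[s]
      s2 <- sample.int(3, 1, prob = mdp$P[s, a, ])
      done <- runif(1) > mdp$cont_prob || t == 30
      rows[[length(rows) + 1]] <- c(e, t, s, a, mdp$R[s, a], s2, done)
      s <- s2
      if (done) break
    }
  }
  m <- do.call(rbind, rows)
  onehot <- function(s) {
    out <- matrix(0, length(s), 3)
    out[cbind(seq_along(s), s)] <- 1
    colnames(out) <- paste0("s", 1:3)
    out
  }
  pid <- sprintf("E%04d", m[, 1])
  ds <- structure(list(
    states = onehot(m[, 3]), actions = mdp$actions[m[, 4]],
    rewards = m[, 5], next_states = onehot(m[, 6]),
    done = as.logical(m[, 7]), patient_id = pid, hour = m[, 2],
    glucose = rep(150, nrow(m)), glucose_next = rep(150, nrow(m)),
    feature_names = paste0("s", 1:3),
    norm_stats = list(min = c(s1 = 0, s2 = 0, s3 = 0),
                      max = c(s1 = 1, s2 = 1, s3 = 1),
                      features = paste0("s", 1:3)),
    episodes = split(seq_len(nrow(m)), pid)[unique(pid)]
  ), class = "transition_dataset")
  emp <- behavior_returns(ds, gamma = 0.67, n_bootstrap = 200)
  fqe <- fqe_evaluate(ds, tabular_policy_fn(mdp, policy_idx), gamma = 0.67,
                      hidden = c(32, 32), lr = 1e-3, steps = 1200,
                      batch_size = 128, n_bootstrap = 200, seed = 2)
  expect_lt(abs(fqe$result$mean_value - emp$result$mean_value), 0.05)
})

test_that("single-transition episodes reduce FQE to the immediate reward", {
  ds <- make_bandit_dataset(doses = 2, best = 2, n_per = 100)
  fqe <- fqe_evaluate(ds, function(states) rep(2, nrow(states)),
                      gamma = 0.67, hidden = c(16, 16), lr = 3e-3,
                      steps = 600, batch_size = 64, n_bootstrap = 100,
                      seed = 1)
  expect_lt(abs(fqe$result$mean_value - 0.2), 0.05)
})

test_that("FQE rejects policies that leave the dose range", {
  ds <- make_bandit_dataset()
  expect_error(
    fqe_evaluate(ds, function(states) rep(12, nrow(states)), steps = 10),
    "outside")
})

test_that("the multi-seed protocol is reproducible and selects by lower bound", {
  co <- simulate_cohort(sim_config(n_patients = 60, seed = 13))
  mdp <- build_mdp(co, seed = 13)
  cfg <- test_agent_config(gradient_steps = 200, batch_size = 64)
  fqe_args <- list(hidden = c(16, 16), steps = 200, batch_size = 64,
                   n_bootstrap = 200)
  p1 <- multiseed_protocol(mdp$train, mdp$test, n_models = 2, config = cfg,
                           fqe_args = fqe_args)
  p2 <- multiseed_protocol(mdp$train, mdp$test, n_models = 2, config = cfg,
                           fqe_args = fqe_args)
  expect_identical(p1$leaderboard, p2$leaderboard)
  expect_equal(p1$best_index, select_best(p1$results))
  lows <- p1$leaderboard$ci_low
  expect_true(all(lows[p1$best_index] >= lows))
  # single-model degenerate case
  p3 <- multiseed_protocol(mdp$train, mdp$test, n_models = 1, config = cfg,
                           fqe_args = fqe_args)
  expect_equal(p3$best_index, 1)
})

test_that("compiled and autodiff FQE engines produce identical fits", {
  mdp <- random_tabular_mdp(n_s = 3, actions = c(0, 1), seed = 4)
  ds <- log_tabular_episodes(mdp, n_episodes = 60, seed = 5)
  pol <- tabular_policy_fn(mdp, c(2L, 1L, 2L))
  f_cpp <- fqe_evaluate(ds, pol, hidden = c(16, 16), steps = 300,
                        batch_size = 64, n_bootstrap = 100, seed = 3,
                        engine = "cpp")
  f_r <- fqe_evaluate(ds, pol, hidden = c(16, 16), steps = 300,
                      batch_size = 64, n_bootstrap = 100, seed = 3,
                      engine = "r")
  expect_equal(f_cpp$result$mean_value, f_r$result$mean_value,
               tolerance = 1e-10)
  expect_equal(f_cpp$values, f_r$values, tolerance = 1e-10)
})
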