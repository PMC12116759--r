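test_that("time in range uses the closed 70-180 interval", {
  expect_equal(time_in_range(c(100, 150, 170)), 1.0)
  expect_equal(time_in_range(c(65, 100, 200, 150)), 0.5)
  expect_equal(time_in_range(c(70, 180)), 1.0)
  expect_equal(time_in_range(c(69.9, 180.1)), 0)
  expect_error(time_in_range(numeric(0)), "empty")
  # invariant under reordering
  g <- runif(50, 40, 300)
  expect_equal(time_in_range(g), time_in_range(rev(g)))
})

test_that("cumulative difference is an exact signed sum", {
  expect_equal(cumulative_difference(c(1, 2), c(1, 2)), 0)
  expect_equal(cumulative_difference(c(2, 3, 1), c(1, 1, 1)), 3)
  expect_equal(cumulative_difference(c(0, 0), c(2, 3)), -5)
  expect_error(cumulative_difference(1:3, 1:2), "equal length")
  set.seed(1)
  m <- runif(100, 0, 10)
  o <- runif(100, 0, 10)
  expect_equal(cumulative_difference(m, o), sum(m - o), tolerance = 1e-12)
})

test_that("agreement rate counts exact matches only", {
  expect_equal(agreement_rate(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(agreement_rate(c(1, 2, 3, 4), c(1, 2, 0, 0)), 0.5)
  expect_error(agreement_rate(numeric(0), numeric(0)), "no timesteps")
  expect_error(agreement_rate(1:3, 1:4), "equal length")
  m <- sample(0:10, 60, replace = TRUE)
  o <- sample(0:10, 60, replace = TRUE)
  p <- sample(60)
  expect_equal(agreement_rate(m, o), agreement_rate(m[p], o[p]))
})

fixed_policy_comparison <- function(deltas, tirs, glucose = 150) {
  n <- length(deltas)
  structure(list(
    timesteps = data.frame(patient_id = sprintf("P%d", seq_len(n)),
                           hour = 0, glucose = glucose,
                           model_dose = 2, observed_dose = 2),
    patients = data.frame(patient_id = sprintf("P%d", seq_len(n)),
                          delta = deltas, tir = tirs,
                          mean_glucose = glucose, n_hours = 24,
                          agreement = 1)
  ), class = "policy_comparison")
}

test_that("TIR-by-difference bins report hand-computed means, omitting empties", {
  comp <- fixed_policy_comparison(deltas = c(0, 0, 5, 5),
                                  tirs = c(1, 1, 0.5, 0.5))
  tab <- tir_by_difference(comp, n_bootstrap = 50)
  expect_equal(nrow(tab), 2)  # only two occupied bins reported
  near_zero <- tab[tab$bin == "[-2,2)", ]
  expect_equal(near_zero$mean_tir, 1.0)
  expect_equal(near_zero$n, 2)
  plus5 <- tab[tab$bin == "[5,10)", ]
  expect_equal(plus5$mean_tir, 0.5)
  # all-delta-zero cohort: a single bin holding every patient
  comp0 <- fixed_policy_comparison(deltas = rep(0, 5), tirs = rep(0.8, 5))
  tab0 <- tir_by_difference(comp0, n_bootstrap = 50)
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$n, 5)
})

test_that("dose-by-glucose bins report the right means", {
  comp <- structure(list(
    timesteps = data.frame(
      patient_id = "P1", hour = 0:5,
      glucose = c(60, 90, 120, 160, 190, 260),
      model_dose = c(0, 0, 1, 2, 3, 6),
      observed_dose = c(0, 1, 2, 2, 2, 4)),
    patients = data.frame(patient_id = "P1", delta = 1, tir = 0.5,
                          mean_glucose = 150, n_hours = 6, agreement = 0.5)
  ), class = "policy_comparison")
  tab <- dose_by_glucose(comp, n_bootstrap = 50)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$mean_model_dose[tab$bin == "[140,180)"], 2)
  expect_equal(tab$mean_observed_dose[tab$bin == "[70,100)"], 1)
  # constant doses everywhere: every occupied bin reports that constant
  comp$timesteps$model_dose <- 2
  comp$timesteps$observed_dose <- 2
  tab2 <- dose_by_glucose(comp, n_bootstrap = 50)
  expect_true(all(tab2$mean_model_dose == 2))
  expect_true(all(tab2$mean_observed_dose == 2))
})

test_that("a policy compared with itself shows identity everywhere", {
  co <- simulate_cohort(sim_config(n_patients = 30, seed = 17))
  mdp <- build_mdp(co, seed = 17)
  self_policy <- function(states) mdp$test$actions
  comp <- compare_policies(self_policy, mdp$test)
  expect_equal(comp$timesteps$model_dose, comp$timesteps$observed_dose)
  expect_true(all(comp$patients$delta == 0))
  expect_equal(agreement_rate(comp$timesteps$model_dose,
                              comp$timesteps$observed_dose), 1.0)
  tab <- dose_by_glucose(comp, n_bootstrap = 50)
  expect_equal(tab$mean_model_dose, tab$mean_observed_dose)
})

test_that("disagreement deciles summarize hand-built extremes", {
  model <- c(rep(0, 10), rep(10, 10))
  observed <- rep(0, 20)
  feats <- data.frame(glucose = c(rep(100, 10), rep(250, 10)))
  out <- disagreement_deciles(model, observed, feats)
  expect_equal(out$mean_abs_difference[out$decile == "bottom"], 0)
  expect_equal(out$mean_abs_difference[out$decile == "top"], 10)
  expect_equal(out$mean_glucose[out$decile == "top"], 250)
  # constant disagreement: both extremes identical
  out2 <- disagreement_deciles(rep(3, 20), rep(1, 20))
  expect_equal(out2$mean_abs_difference[1], out2$mean_abs_difference[2])
  # ordering by construction
  set.seed(2)
  m <- sample(0:10, 200, replace = TRUE)
  o <- sample(0:10, 200, replace = TRUE)
  out3 <- disagreement_deciles(m, o)
  expect_gte(out3$mean_abs_difference[out3$decile == "top"],
             out3$mean_abs_difference[out3$decile == "bottom"])
  expect_error(disagreement_deciles(1:5, 1:5), "at least 10")
})

test_that("MAE is symmetric, zero on identity, and compares schemes", {
  expect_equal(mae_vs_reference(c(1, 2), c(1, 2))$mae, 0)
  expect_equal(mae_vs_reference(c(2, 4), c(1, 1))$mae, 2)
  expect_equal(mae_vs_reference(c(1, 1), c(2, 4))$mae, 2)
  out <- mae_vs_reference(c(2, 4, 2, 4), c(1, 1, 1, 1),
                          other = c(1, 1, 2, 1))
  expect_equal(out$mae_other, mean(c(0, 0, 1, 0)))
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_error(mae_vs_reference(1:3, 1:2), "equal length")
})

test_that("permutation importance isolates the features a policy uses", {
  co <- simulate_cohort(sim_config(n_patients = 30, seed = 19))
  mdp <- build_mdp(co, seed = 19)
  ds <- mdp$test
  # constant policy: nothing matters
  const_pol <- function(states) rep(2, nrow(states))
  imp0 <- permutation_importance(const_pol, ds, n_repeats = 2, seed = 1)
  expect_true(all(imp0$score == 0))
  # a policy that reads only the glucose column
  g_col <- which(ds$feature_names == "glucose")
  glu_pol <- function(states) round(states[, g_col] * 10)
  imp <- permutation_importance(glu_pol, ds, n_repeats = 3, seed = 1)
  expect_equal(imp$feature[1], "glucose")
  expect_gt(imp$score[1], max(imp$score[-1]))
  expect_true(all(imp$score[imp$feature != "glucose"] == 0))
  # seeded repeatability
  imp2 <- permutation_importance(glu_pol, ds, n_repeats = 3, seed = 1)
  expect_identical(imp, imp2)
})
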