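test_that("run configuration validates blocks, keys and values", {
  expect_error(run_config(list(bogus = list())), "unknown config block")
  expect_error(run_config(list(agent = list(nonsense = 1))), "unknown key")
  # invalid values are rejected before any computation
  expect_error(run_config(list(agent = list(discount = 1.2))))
  expect_error(run_config(list(sim = list(n_patients = 0))), "positive")
  cfg <- run_config(list(seed = 9, sim = list(n_patients = 25)))
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$sim$n_patients, 25)
  expect_equal(cfg$sim$seed, 9)
  expect_equal(cfg$agent$seed, 9)
})

test_that("run configuration round-trips through YAML", {
  path <- file.path(tempdir(), "cfg.yaml")
  yaml::write_yaml(list(seed = 4, sim = list(n_patients = 12),
                        agent = list(gradient_steps = 50)), path)
  cfg <- run_config(path)
  expect_equal(cfg$sim$n_patients, 12)
  expect_equal(cfg$agent$gradient_steps, 50)
})

test_that("cohorts round-trip through CSV", {
  co <- simulate_cohort(sim_config(n_patients = 8, seed = 2))
  dir <- file.path(tempdir(), "cohort_rt")
  write_trajectories(co, dir)
  back <- read_trajectories(dir)
  expect_equal(back$trajectories$glucose, co$trajectories$glucose)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_error(read_trajectories(file.path(tempdir(), "nope")), "missing")
})

test_that("policy artifacts round-trip through JSON exactly", {
  ds <- make_bandit_dataset()
  art <- train_dcql(ds, test_agent_config(gradient_steps = 80))
  path <- file.path(tempdir(), "art", "artifact.json")
  save_artifact(art, path)
  back <- load_artifact(path)
  probe <- matrix(runif(60), 20, 3)
  expect_identical(recommend_dose(art, probe), recommend_dose(back, probe))
  expect_equal(back$config$discount, art$config$discount)
  expect_equal(back$norm_stats$min, art$norm_stats$min)
  expect_error(load_artifact(file.path(tempdir(), "absent.json")), "no artifact")
})

test_that("transition datasets round-trip through JSON", {
  co <- simulate_cohort(sim_config(n_patients = 10, seed = 3))
  mdp <- build_mdp(co, seed = 3)
  path <- file.path(tempdir(), "ds.json")
  insulinrl:::write_dataset(mdp$test, path)
  back <- insulinrl:::read_dataset(path)
  expect_equal(back$states, mdp$test$states, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$actions, mdp$test$actions)
  expect_equal(back$rewards, mdp$test$rewards)
  expect_equal(names(back$episodes), names(mdp$test$episodes))
})

test_that("the CLI wraps the stage functions and validates its arguments", {
  out_dir <- file.path(tempdir(), "cli_sim")
  expect_message(
    insulinrl:::cli_main(c("simulate", "--n", "6", "--seed", "2",
                           "--out", out_dir)),
    "wrote cohort")
  expect_true(file.exists(file.path(out_dir, "trajectories.csv")))
  expect_true(file.exists(file.path(out_dir, "patients.csv")))
  pre_dir <- file.path(tempdir(), "cli_pre")
  expect_message(
    insulinrl:::cli_main(c("preprocess", "--data", out_dir,
                           "--out", pre_dir, "--seed", "2")),
    "wrote transition")
  expect_true(file.exists(file.path(pre_dir, "train.json")))
  expect_error(insulinrl:::cli_main(c("evaluate", "--data", "x.json")),
               "--policy")
  expect_error(insulinrl:::cli_main(c("frobnicate")), "unknown command")
  expect_error(insulinrl:::cli_main(c("simulate", "oops")), "unexpected")
})

test_that("end-to-end runs are reproducible byte for byte", {
  base <- list(
    seed = 3,
    sim = list(n_patients = 40),
    agent = list(hidden_layers = c(16, 16), gradient_steps = 120,
                 batch_size = 64, quantile_embed_dim = 8,
                 n_ood_action_samples = 4, n_actor_action_samples = 1,
                 n_cql_quantile_samples = 2, cql_alpha = 1,
                 dropout_p = 0),
    ope = list(n_models = 1, fqe_hidden = c(16, 16), fqe_steps = 120,
               fqe_batch_size = 64, n_bootstrap = 200),
    analysis = list(n_bootstrap = 100)
  )
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  r1 <- run_end_to_end(run_config(c(base, list(output_dir = d1))),
                       verbose = FALSE)
  r2 <- run_end_to_end(run_config(c(base, list(output_dir = d2))),
                       verbose = FALSE)
  expect_identical(readLines(file.path(d1, "leaderboard.csv")),
                   readLines(file.path(d2, "leaderboard.csv")))
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  # the output directory carries everything needed to reproduce the run
  expect_true(file.exists(file.path(d1, "config.yaml")))
  expect_true(file.exists(file.path(d1, "best_model", "artifact.json")))
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(rep$seed, 3)
  expect_true(!is.null(rep$package_version))
  expect_equal(unlist(rep$model_seeds), 3)
})

test_that("cohorts round-trip through Parquet", {
  co <- simulate_cohort(sim_config(n_patients = 5, seed = 4))
  dir <- file.path(tempdir(), "cohort_pq")
  write_trajectories(co, dir, format = "parquet")
  back <- read_trajectories(dir)
  expect_equal(back$trajectories$glucose, co$trajectories$glucose)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
})
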