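#' Configuration for the synthetic post-cardiac-surgery cohort
#'
#' Parameters of the virtual ICU glucose-insulin cohort generator. The
#' generator emulates the structure of hourly post-cardiac-surgery
#' trajectories: 24-hour episodes starting at the first glucose measurement,
#' endogenous stress-driven hyperglycemia decaying over the episode,
#' linear-Gaussian glucose dynamics under hourly regular-insulin boluses from
#' a sliding-scale behaviour policy, sporadic dextrose events, injected
#' feature missingness, and a small fraction of patients carrying each
#' exclusion flag.
#'
#' @param n_patients Number of patients to simulate.
#' @param horizon Episode length in hours (default 24).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param diabetic_fraction Fraction of patients with diabetes.
#' @param stress_drive_range Interval (mg/dL per hour) from which each
#'   patient's initial endogenous hyperglycemic drive is drawn uniformly;
#'   the drive decays geometrically by `drive_decay` per hour.
#' @param drive_decay Per-hour geometric decay of the stress drive.
#' @param insulin_sensitivity_range Interval (mg/dL drop per unit) from which
#'   each patient's insulin sensitivity is drawn uniformly.
#' @param noise_sd SD (mg/dL) of the Gaussian hourly glucose innovation.
#' @param dextrose_event_rate Probability per hour of a dextrose event
#'   (adds 20-45 mg/dL).
#' @param carryover Fraction of the previous hour's dose still acting in the
#'   current hour (IV regular insulin acts fast; most effect is within-hour).
#' @param omission_prob Probability that a sliding-scale dose is skipped.
#' @param jitter_prob Probability that the administered dose deviates by
#'   one unit from the sliding-scale dose.
#' @param missingness_rates Named list mapping dynamic feature names to the
#'   probability that an hourly value is recorded missing.
#' @param flag_rates Named list with elements `died_within_24h`,
#'   `ambiguous_meds`, `no_glucose_3h`, `other_insulin`: per-patient
#'   probabilities of each exclusion flag.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100,
                       horizon = 24,
                       seed = 1L,
                       diabetic_fraction = 0.15,
                       stress_drive_range = c(0, 11),
                       drive_decay = 0.9,
                       insulin_sensitivity_range = c(4, 12),
                       noise_sd = 12,
                       dextrose_event_rate = 0.04,
                       carryover = 0.3,
                       omission_prob = 0.12,
                       jitter_prob = 0.15,
                       missingness_rates = default_missingness(),
                       flag_rates = list(died_within_24h = 0.02,
                                         ambiguous_meds = 0.03,
                                         no_glucose_3h = 0.02,
                                         other_insulin = 0.03)) {
  if (!is.numeric(n_patients) || n_patients <= 0) {
    stop("n_patients must be positive", call. = FALSE)
  }
  stopifnot(horizon >= 2,
            diabetic_fraction >= 0, diabetic_fraction <= 1,
            length(stress_drive_range) == 2L,
            stress_drive_range[1] >= 0,
            diff(stress_drive_range) >= 0,
            length(insulin_sensitivity_range) == 2L,
            insulin_sensitivity_range[1] > 0,
            diff(insulin_sensitivity_range) >= 0,
            noise_sd >= 0, dextrose_event_rate >= 0,
            carryover >= 0, carryover <= 1,
            omission_prob >= 0, omission_prob <= 1,
            jitter_prob >= 0, jitter_prob <= 1,
            drive_decay > 0, drive_decay <= 1)
  rates <- unlist(missingness_rates)
  if (length(rates) && (any(rates < 0) || any(rates > 1))) {
    stop("missingness_rates must be probabilities", call. = FALSE)
  }
  fr <- unlist(flag_rates)
  stopifnot(all(fr >= 0), all(fr <= 1))
  structure(list(
    n_patients = as.integer(n_patients), horizon = as.integer(horizon),
    seed = as.integer(seed), diabetic_fraction = diabetic_fraction,
    stress_drive_range = stress_drive_range, drive_decay = drive_decay,
    insulin_sensitivity_range = insulin_sensitivity_range,
    noise_sd = noise_sd, dextrose_event_rate = dextrose_event_rate,
    carryover = carryover, omission_prob = omission_prob,
    jitter_prob = jitter_prob, missingness_rates = missingness_rates,
    flag_rates = flag_rates
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort config: %d patients x %d h (seed %d)\n",
              x$n_patients, x$horizon, x$seed))
  cat(sprintf("  stress drive %g-%g mg/dL/h (decay %g), sensitivity %g-%g mg/dL/U\n",
              x$stress_drive_range[1], x$stress_drive_range[2], x$drive_decay,
              x$insulin_sensitivity_range[1], x$insulin_sensitivity_range[2]))
  cat(sprintf("  noise sd %g, dextrose rate %g/h, omission %g, jitter %g\n",
              x$noise_sd, x$dextrose_event_rate, x$omission_prob, x$jitter_prob))
  invisible(x)
}

#' Default per-feature missingness rates
#'
#' Labs are recorded less often than vitals; lactate exceeds the 30%
#' drop threshold by design so the feature-drop rule is exercised.
#'
#' @return Named list of probabilities.
#' @export
default_missingness <- function() {
  list(heart_rate = 0.03, resp_rate = 0.03, sbp = 0.03, dbp = 0.03,
       map = 0.03, temp_c = 0.08, spo2 = 0.03,
       wbc = 0.15, creatinine = 0.15, potassium = 0.15, hemoglobin = 0.15,
       lactate = 0.35, sofa = 0.05)
}

#' Column dictionary of the trajectory table
#'
#' One row per feature: its name, whether it is static (patient-level) or
#' dynamic (hourly), and how hourly duplicates are aggregated when binning
#' (doses are summed; measurements are averaged).
#'
#' @return A data.frame with columns `feature`, `kind`, `agg`.
#' @export
trajectory_schema <- function() {
  dynamic <- c("glucose", "insulin", "heart_rate", "resp_rate", "sbp", "dbp",
               "map", "temp_c", "spo2", "wbc", "creatinine", "lactate",
               "potassium", "hemoglobin", "sofa", "on_vasopressor",
               "vasopressor_dose", "mech_vent")
  static <- c("age", "sex", "weight", "bmi", "diabetes_type", "surgery_cabg",
              "surgery_valve", "htn", "chf", "copd", "esrd", "prior_mi",
              "elixhauser")
  data.frame(
    feature = c(dynamic, static),
    kind = c(rep("dynamic", length(dynamic)), rep("static", length(static))),
    agg = c(ifelse(dynamic == "insulin", "sum", "mean"),
            rep("static", length(static))),
    stringsAsFactors = FALSE
  )
}

#' Sliding-scale insulin behaviour policy
#'
#' The deterministic reactive step function used as the behaviour policy of
#' the simulated hospitals: no insulin below 150 mg/dL, then increasing doses
#' per 40-mg/dL band (1, 2, 3, 4, 6, 8 units), capped at 10 units from
#' 390 mg/dL upward. Monotone non-decreasing in glucose.
#'
#' @param glucose Glucose values in mg/dL (vectorized).
#' @return Integer doses in units.
#' @export
#' @examples
#' sliding_scale_policy(c(120, 155, 190, 400))
sliding_scale_policy <- function(glucose) {
  if (!is.numeric(glucose) || any(!is.finite(glucose)) || any(glucose <= 0)) {
    stop("glucose must be positive and finite", call. = FALSE)
  }
  steps <- c(1, 2, 3, 4, 6, 8, 10)
  band <- floor((glucose - 150) / 40) + 1
  band <- pmin(pmax(band, 0), length(steps))
  out <- numeric(length(glucose))
  treat <- band >= 1
  out[treat] <- steps[band[treat]]
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw static covariates, latent dynamics parameters, and exclusion flags for
# n patients. Severity (stress drive) is reflected in SOFA, vasopressor use
# and vitals so that learnable severity proxies exist in the state.
draw_patients <- function(config) {
  n <- config$n_patients
  drive0 <- stats::runif(n, config$stress_drive_range[1],
                         config$stress_drive_range[2])
  diabetes <- stats::rbinom(n, 1L, config$diabetic_fraction)
  # type 1 is rare among cardiac-surgery admissions
  diabetes_type <- ifelse(diabetes == 1L,
                          ifelse(stats::runif(n) < 0.04, 1L, 2L), 0L)
  drive0 <- drive0 + 3 * diabetes
  sens <- stats::runif(n, config$insulin_sensitivity_range[1],
                       config$insulin_sensitivity_range[2])
  sens <- sens * ifelse(diabetes == 1L, 0.7, 1)
  g0 <- stats::rnorm(n, 125 + 30 * diabetes, 26)
  g0 <- clip(g0, 80, 400)

  age <- clip(round(stats::rnorm(n, 67, 11.5)), 18, 95)
  sex <- stats::rbinom(n, 1L, 0.71)  # 1 = male
  height <- stats::rnorm(n, 165 + 12 * sex, 8)
  weight <- clip(stats::rnorm(n, 84, 17), 45, 180)
  bmi <- round(weight / (height / 100)^2, 1)
  surgery_cabg <- stats::rbinom(n, 1L, 0.71)
  surgery_valve <- ifelse(surgery_cabg == 1L,
                          stats::rbinom(n, 1L, 0.25),
                          stats::rbinom(n, 1L, 0.85))
  htn <- stats::rbinom(n, 1L, 0.62)
  chf <- stats::rbinom(n, 1L, 0.27)
  copd <- stats::rbinom(n, 1L, 0.05)
  esrd <- stats::rbinom(n, 1L, 0.02)
  prior_mi <- stats::rbinom(n, 1L, 0.29)
  elixhauser <- pmax(0L, stats::rpois(n, 2) +
                       2L * (htn + chf + copd + esrd + prior_mi + diabetes))
  admission_sofa <- clip(round(1 + drive0 / 2.5 + stats::rpois(n, 2)), 0, 20)
  on_vasopressor <- as.integer(drive0 + stats::rnorm(n, 0, 2) > 11)
  vent_hours <- pmin(config$horizon,
                     stats::rpois(n, 5) + 3L * on_vasopressor + 2L)

  fr <- config$flag_rates
  died_within_24h <- stats::rbinom(n, 1L, fr$died_within_24h)
  ambiguous_meds <- stats::rbinom(n, 1L, fr$ambiguous_meds)
  no_glucose_3h <- stats::rbinom(n, 1L, fr$no_glucose_3h)
  other_insulin <- stats::rbinom(n, 1L, fr$other_insulin)
  first_glucose_hour <- ifelse(
    no_glucose_3h == 1L,
    4L + stats::rbinom(n, 2L, 0.5),
    sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.88, 0.08, 0.04))
  )
  death_hour <- ifelse(died_within_24h == 1L,
                       sample(6:23, n, replace = TRUE), NA_integer_)

  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, weight = weight, bmi = bmi,
    diabetes_type = diabetes_type, surgery_cabg = surgery_cabg,
    surgery_valve = surgery_valve, htn = htn, chf = chf, copd = copd,
    esrd = esrd, prior_mi = prior_mi, elixhauser = elixhauser,
    admission_sofa = admission_sofa,
    died_within_24h = died_within_24h, ambiguous_meds = ambiguous_meds,
    no_glucose_3h = no_glucose_3h, other_insulin = other_insulin,
    first_glucose_hour = first_glucose_hour, death_hour = death_hour,
    sim_drive0 = drive0, sim_sensitivity = sens, sim_baseline_glucose = g0,
    sim_on_vasopressor = on_vasopressor, sim_vent_hours = vent_hours,
    stringsAsFactors = FALSE
  )
}

# Simulate one patient's hourly rows. `policy` NULL means the jittered
# sliding-scale behaviour policy; otherwise a function(history_df) -> dose
# evaluated on the complete (unjittered) history.
simulate_patient_rows <- function(pat, config, policy = NULL) {
  horizon <- config$horizon
  last_hour <- if (!is.na(pat$death_hour)) min(pat$death_hour, horizon - 1L) else horizon - 1L
  hours <- 0:last_hour
  nh <- length(hours)

  g <- numeric(nh)
  a <- numeric(nh)
  g[1] <- pat$sim_baseline_glucose
  drive <- pat$sim_drive0 * config$drive_decay^hours

  hr <- 70 + 1.2 * drive + stats::rnorm(nh, 0, 6)
  map <- 75 - 0.6 * drive + stats::rnorm(nh, 0, 5)
  sbp <- map * 1.45 + stats::rnorm(nh, 0, 5)
  dbp <- map * 0.78 + stats::rnorm(nh, 0, 4)
  temp_c <- 36.8 + 0.02 * drive + stats::rnorm(nh, 0, 0.25)
  spo2 <- clip(97 + stats::rnorm(nh, 0, 1.3), 85, 100)
  resp <- 14 + 0.25 * drive + stats::rnorm(nh, 0, 2)
  wbc <- pmax(2, 10 + 0.35 * pat$sim_drive0 + stats::rnorm(nh, 0, 1.5))
  creat <- pmax(0.3, 0.9 + 2.5 * pat$esrd + stats::rnorm(nh, 0, 0.15))
  lact <- pmax(0.4, 1.4 + 0.12 * drive + stats::rnorm(nh, 0, 0.4))
  potassium <- 4.2 + stats::rnorm(nh, 0, 0.3)
  hgb <- pmax(6, 10.5 + stats::rnorm(nh, 0, 0.8))
  sofa <- clip(pat$admission_sofa + cumsum(sample(c(-1L, 0L, 1L), nh, TRUE,
                                                  prob = c(0.08, 0.86, 0.06))),
               0, 24)
  vaso_dose <- ifelse(pat$sim_on_vasopressor == 1L,
                      pmax(0, 0.05 + 0.01 * drive + stats::rnorm(nh, 0, 0.02)), 0)
  mech_vent <- as.integer(hours < pat$sim_vent_hours)

  rows <- data.frame(
    patient_id = pat$patient_id, hour = hours, glucose = NA_real_,
    insulin = 0, heart_rate = hr, resp_rate = resp, sbp = sbp, dbp = dbp,
    map = map, temp_c = temp_c, spo2 = spo2, wbc = wbc, creatinine = creat,
    lactate = lact, potassium = potassium, hemoglobin = hgb, sofa = sofa,
    on_vasopressor = as.integer(vaso_dose > 0), vasopressor_dose = vaso_dose,
    mech_vent = mech_vent, stringsAsFactors = FALSE
  )

  for (t in seq_len(nh)) {
    gt <- g[t]
    rows$glucose[t] <- gt
    if (hours[t] < pat$first_glucose_hour) {
      rows$glucose[t] <- NA_real_
      dose <- 0
    } else if (is.null(policy)) {
      dose <- sliding_scale_policy(max(gt, 21))
      if (gt < 90) dose <- 0  # clinicians hold insulin near hypoglycemia
      if (dose > 0 && stats::runif(1) < config$jitter_prob) {
        # dose deviations from protocol: mostly +/-1, occasional larger bolus
        dose <- clip(dose + sample(c(-1, 1, 2, 4), 1L,
                                   prob = c(0.35, 0.35, 0.2, 0.1)), 0, 10)
      }
      if (stats::runif(1) < config$omission_prob) dose <- 0
    } else {
      dose <- policy(rows[seq_len(t), , drop = FALSE], pat)
      if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) ||
          dose < 0 || dose > 10) {
        stop("policy must return a single dose in [0, 10]", call. = FALSE)
      }
    }
    a[t] <- dose
    rows$insulin[t] <- dose
    if (t < nh) {
      eff <- pat$sim_sensitivity * (a[t] + config$carryover * if (t > 1) a[t - 1] else 0)
      dex <- if (stats::runif(1) < config$dextrose_event_rate) stats::runif(1, 20, 45) else 0
      rescue <- if (g[t] < 70 && stats::runif(1) < 0.9) stats::runif(1, 25, 40) else 0
      g[t + 1] <- clip(g[t] + drive[t] - eff + dex + rescue +
                         stats::rnorm(1, 0, config$noise_sd),
                       GLUCOSE_RANGE[1], GLUCOSE_RANGE[2])
    }
  }
  rows
}

inject_missingness <- function(trajectories, rates) {
  for (feat in names(rates)) {
    if (!feat %in% names(trajectories)) next
    miss <- stats::runif(nrow(trajectories)) < rates[[feat]]
    trajectories[[feat]][miss] <- NA_real_
  }
  trajectories
}

#' Simulate a synthetic post-cardiac-surgery cohort
#'
#' Generates hourly glucose-insulin trajectories under the jittered
#' sliding-scale behaviour policy, together with a static patient table
#' carrying demographics, comorbidities, exclusion flags and the latent
#' simulation parameters (columns prefixed `sim_`, never used as model
#' features). Glucose follows
#' `G[t+1] = clip(G[t] + drive[t] - sens * (a[t] + carryover * a[t-1]) +
#' dextrose + rescue + noise, 20, 600)`. Feature missingness is injected at
#' the configured per-feature rates. Identical seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort` with elements `trajectories` (patient-hour
#'   data.frame), `patients` (static table) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 5, seed = 1))
#' head(cohort$trajectories)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed)
  patients <- draw_patients(config)
  traj <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    simulate_patient_rows(patients[i, ], config)
  }))
  traj <- inject_missingness(traj, config$missingness_rates)
  rownames(traj) <- NULL
  structure(list(trajectories = traj, patients = patients, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tr <- x$trajectories
  obs <- tr$glucose[!is.na(tr$glucose)]
  cat(sprintf("Synthetic cohort: %d patients, %d patient-hours\n",
              nrow(x$patients), nrow(tr)))
  cat(sprintf("  glucose median %.0f mg/dL; mean hourly insulin %.2f U\n",
              stats::median(obs), mean(tr$insulin, na.rm = TRUE)))
  invisible(x)
}

#' Roll out a dosing policy in the simulator
#'
#' Generates trajectories under a supplied policy instead of the sliding
#' scale, for ground-truth Monte-Carlo policy evaluation. No dose jitter,
#' omissions or feature missingness are applied, and exclusion-flag patients
#' are simulated like the rest (filtering is an analysis choice).
#'
#' @param policy A function taking the patient's raw trajectory history (a
#'   data.frame of rows up to and including the current hour, current-hour
#'   insulin not yet set) and returning a dose in `[0, 10]`. See
#'   [policy_from_artifact()] for wrapping a trained agent.
#' @param config A [sim_config()]; its patient-population parameters are
#'   reused so rollouts are comparable with [simulate_cohort()] output under
#'   the same seed.
#' @param n_patients,seed Optional overrides of the config values.
#' @return A `cohort` list, as [simulate_cohort()] but without missingness.
#' @export
rollout_policy <- function(policy, config = sim_config(),
                           n_patients = config$n_patients,
                           seed = config$seed) {
  stopifnot(is.function(policy), inherits(config, "sim_config"))
  config$n_patients <- as.integer(n_patients)
  config$seed <- as.integer(seed)
  local_seed(config$seed)
  patients <- draw_patients(config)
  traj <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    simulate_patient_rows(patients[i, ], config, policy = policy)
  }))
  rownames(traj) <- NULL
  structure(list(trajectories = traj, patients = patients, config = config),
            class = "cohort")
}
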