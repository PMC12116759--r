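# Descriptive policy analyses: time in range, cumulative dose differences,
# dose-by-glucose profiles, agreement/disagreement and feature importance.

#' Time in range
#'
#' Fraction of hourly glucose values inside the closed interval
#' `[70, 180]` mg/dL. The interval is closed because hypoglycemia and
#' hyperglycemia are defined as `<70` and `>180`, so the boundary values are
#' in range.
#'
#' @param glucose Numeric vector of hourly glucose values (mg/dL).
#' @param range Closed interval bounds, default `c(70, 180)`.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' time_in_range(c(65, 100, 200, 150))  # 0.5
time_in_range <- function(glucose, range = c(70, 180)) {
  glucose <- glucose[!is.na(glucose)]
  if (!length(glucose)) stop("empty glucose series", call. = FALSE)
  mean(glucose >= range[1] & glucose <= range[2])
}

#' Cumulative dosing difference
#'
#' Sum over the episode of model-recommended minus observed insulin doses:
#' positive when the model recommends more insulin than was administered.
#'
#' @param model_doses,observed_doses Aligned hourly dose vectors.
#' @return The cumulative difference in units.
#' @export
cumulative_difference <- function(model_doses, observed_doses) {
  if (length(model_doses) != length(observed_doses)) {
    stop("dose vectors must have equal length", call. = FALSE)
  }
  sum(model_doses - observed_doses)
}

#' Exact agreement rate between model and observed doses
#'
#' Fraction of patient-hours where the administered dose equals the model's
#' (integer, post-rounding) recommendation exactly.
#'
#' @inheritParams cumulative_difference
#' @return Fraction in `[0, 1]`.
#' @export
agreement_rate <- function(model_doses, observed_doses) {
  if (length(model_doses) != length(observed_doses)) {
    stop("dose vectors must have equal length", call. = FALSE)
  }
  if (!length(model_doses)) stop("no timesteps", call. = FALSE)
  mean(model_doses == observed_doses)
}

#' Compare a policy with the observed behaviour on a transition dataset
#'
#' Evaluates the policy's recommendation at every logged state and assembles
#' the per-timestep and per-patient comparison tables that the other
#' analyses consume. Per patient the episode's TIR and mean glucose use all
#' hourly glucose values (each transition's state plus the final
#' next-state).
#'
#' @param policy A `policy_artifact` or a function mapping a matrix of
#'   normalized states to doses.
#' @param dataset A `transition_dataset`.
#' @return An object of class `policy_comparison`: list with `timesteps`
#'   (patient_id, hour, glucose, model_dose, observed_dose) and `patients`
#'   (patient_id, delta, tir, mean_glucose, n_hours, agreement).
#' @export
compare_policies <- function(policy, dataset) {
  stopifnot(inherits(dataset, "transition_dataset"))
  policy_fn <- as_policy_fn(policy)
  model <- policy_fn(dataset$states)
  ts <- data.frame(
    patient_id = dataset$patient_id,
    hour = dataset$hour,
    glucose = dataset$glucose,
    model_dose = model,
    observed_dose = dataset$actions,
    stringsAsFactors = FALSE
  )
  pats <- lapply(names(dataset$episodes), function(pid) {
    idx <- dataset$episodes[[pid]]
    g_all <- c(dataset$glucose[idx], dataset$glucose_next[idx[length(idx)]])
    data.frame(
      patient_id = pid,
      delta = cumulative_difference(model[idx], dataset$actions[idx]),
      tir = time_in_range(g_all),
      mean_glucose = mean(g_all),
      n_hours = length(g_all),
      agreement = agreement_rate(model[idx], dataset$actions[idx]),
      stringsAsFactors = FALSE
    )
  })
  structure(list(timesteps = ts, patients = do.call(rbind, pats)),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat(sprintf(
    "Policy comparison: %d patients, %d patient-hours, agreement %.1f%%\n",
    nrow(x$patients), nrow(x$timesteps),
    100 * agreement_rate(x$timesteps$model_dose, x$timesteps$observed_dose)))
  cat(sprintf("  mean cumulative difference %.2f U, mean TIR %.3f\n",
              mean(x$patients$delta), mean(x$patients$tir)))
  invisible(x)
}

#' TIR and mean glucose by cumulative dosing difference
#'
#' Bins patients by the cumulative difference between model-recommended and
#' observed insulin over the episode, and reports mean TIR and mean glucose
#' per bin with percentile-bootstrap confidence intervals. Empty bins are
#' omitted.
#'
#' @param comparison A `policy_comparison` from [compare_policies()].
#' @param breaks Bin edges for the cumulative difference (units); the
#'   default's central bin `[-2, 2)` is the "model agrees" bin.
#' @param n_bootstrap,seed Bootstrap settings for the per-bin CIs.
#' @return A data.frame: bin, n, mean_tir (with CI), mean_glucose (with CI).
#' @export
tir_by_difference <- function(comparison,
                              breaks = c(-Inf, -15, -10, -5, -2, 2, 5, 10,
                                         15, Inf),
                              n_bootstrap = 1000, seed = 1L) {
  stopifnot(inherits(comparison, "policy_comparison"))
  pats <- comparison$patients
  bin <- cut(pats$delta, breaks = breaks, right = FALSE)
  out <- lapply(levels(bin), function(lv) {
    rows <- pats[which(bin == lv), , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    tir_ci <- bootstrap_ci(rows$tir, n_bootstrap, seed = seed)
    glu_ci <- bootstrap_ci(rows$mean_glucose, n_bootstrap, seed = seed)
    data.frame(bin = lv, n = nrow(rows),
               mean_tir = mean(rows$tir),
               tir_low = tir_ci[1], tir_high = tir_ci[2],
               mean_glucose = mean(rows$mean_glucose),
               glucose_low = glu_ci[1], glucose_high = glu_ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean insulin dose by glucose range
#'
#' Average model-recommended and observed doses within glucose bins, with
#' percentile-bootstrap confidence intervals.
#'
#' @param comparison A `policy_comparison`.
#' @param breaks Glucose bin edges in mg/dL (default `<70`, `[70,100)`,
#'   `[100,140)`, `[140,180)`, `[180,200)`, `[200,250)`, `>=250`).
#' @param n_bootstrap,seed Bootstrap settings.
#' @return A data.frame with per-bin means and CIs for both dose series.
#' @export
dose_by_glucose <- function(comparison,
                            breaks = c(-Inf, 70, 100, 140, 180, 200, 250,
                                       Inf),
                            n_bootstrap = 1000, seed = 1L) {
  stopifnot(inherits(comparison, "policy_comparison"))
  ts <- comparison$timesteps
  bin <- cut(ts$glucose, breaks = breaks, right = FALSE)
  out <- lapply(levels(bin), function(lv) {
    rows <- ts[which(bin == lv), , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    m_ci <- bootstrap_ci(rows$model_dose, n_bootstrap, seed = seed)
    o_ci <- bootstrap_ci(rows$observed_dose, n_bootstrap, seed = seed)
    data.frame(bin = lv, n = nrow(rows),
               mean_model_dose = mean(rows$model_dose),
               model_low = m_ci[1], model_high = m_ci[2],
               mean_observed_dose = mean(rows$observed_dose),
               observed_low = o_ci[1], observed_high = o_ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Characterize the largest and smallest model-clinician disagreements
#'
#' Splits patient-hours into deciles of the absolute difference between
#' model-recommended and observed doses and summarizes the top and bottom
#' deciles: mean glucose, mean doses, and the mean of every supplied
#' feature.
#'
#' @param model_doses,observed_doses Aligned hourly doses (>= 10 timesteps).
#' @param features Optional data.frame/matrix of per-timestep features to
#'   summarize alongside.
#' @return A data.frame with one row per decile extreme (`bottom`, `top`).
#' @export
disagreement_deciles <- function(model_doses, observed_doses,
                                 features = NULL) {
  if (length(model_doses) != length(observed_doses)) {
    stop("dose vectors must have equal length", call. = FALSE)
  }
  n <- length(model_doses)
  if (n < 10L) stop("need at least 10 timesteps", call. = FALSE)
  ad <- abs(model_doses - observed_doses)
  decile <- ceiling(rank(ad, ties.method = "first") / n * 10)
  summarize <- function(which_rows, label) {
    row <- data.frame(
      decile = label, n = length(which_rows),
      mean_abs_difference = mean(ad[which_rows]),
      mean_model_dose = mean(model_doses[which_rows]),
      mean_observed_dose = mean(observed_doses[which_rows]),
      stringsAsFactors = FALSE
    )
    if (!is.null(features)) {
      fm <- as.data.frame(features)[which_rows, , drop = FALSE]
      for (col in names(fm)) {
        row[[paste0("mean_", col)]] <- mean(as.numeric(fm[[col]]),
                                            na.rm = TRUE)
      }
    }
    row
  }
  rbind(summarize(which(decile == 1L), "bottom"),
        summarize(which(decile == 10L), "top"))
}

#' Mean absolute error between two dosing schemes
#'
#' MAE of the candidate doses against a reference scheme over all aligned
#' patient-hours; optionally compares the candidate's absolute errors with a
#' second scheme's by two-sample t test (as when two dosing policies are
#' judged against the same reference).
#'
#' @param candidate,reference Aligned hourly dose vectors.
#' @param other Optional second candidate to compare against the same
#'   reference.
#' @return List with `mae`, and when `other` is given `mae_other` and
#'   `p_value` of the t test between the two absolute-error vectors.
#' @export
mae_vs_reference <- function(candidate, reference, other = NULL) {
  if (length(candidate) != length(reference)) {
    stop("dose vectors must have equal length", call. = FALSE)
  }
  err <- abs(candidate - reference)
  out <- list(mae = mean(err))
  if (!is.null(other)) {
    if (length(other) != length(reference)) {
      stop("dose vectors must have equal length", call. = FALSE)
    }
    err2 <- abs(other - reference)
    out$mae_other <- mean(err2)
    out$p_value <- stats::t.test(err, err2)$p.value
  }
  out
}

#' Permutation importance of state features for the recommended dose
#'
#' For each feature, permutes its column across states and measures the mean
#' absolute change in the recommended dose, averaged over `n_repeats`
#' seeded permutations; features are returned ranked by score. A
#' model-agnostic stand-in for coalitional attribution: it measures how much
#' the recommendation relies on each feature, not credit shares.
#'
#' @param artifact A `policy_artifact` (or policy function plus
#'   `feature_names` attribute).
#' @param dataset A `transition_dataset` whose states are probed.
#' @param n_repeats Permutations per feature.
#' @param seed Integer seed.
#' @return A data.frame (feature, score) sorted by decreasing score.
#' @export
permutation_importance <- function(artifact, dataset, n_repeats = 5,
                                   seed = 1L) {
  stopifnot(inherits(dataset, "transition_dataset"))
  policy_fn <- as_policy_fn(artifact)
  local_seed(seed)
  states <- dataset$states
  base <- policy_fn(states)
  n <- nrow(states)
  scores <- vapply(seq_len(ncol(states)), function(j) {
    mean(vapply(seq_len(n_repeats), function(rep) {
      perm <- states
      perm[, j] <- perm[sample.int(n), j]
      mean(abs(policy_fn(perm) - base))
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = dataset$feature_names, score = scores,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
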