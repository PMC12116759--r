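# Preprocessing pipeline: exclusion filters, hourly alignment, imputation,
# feature engineering, normalization, transition construction and splitting.

EXCLUSION_FLAGS <- c("died_within_24h", "ambiguous_meds", "no_glucose_3h",
                     "other_insulin")

#' Apply cohort exclusion filters
#'
#' Removes patients flagged as having died within the first 24 h, carrying
#' ambiguous medication records, lacking a glucose measurement within the
#' first three hours, or having received other short-acting insulins
#' (aspart, lispro, NPH, 70/30 mixes). A patient with several flags is
#' tallied once, under the first matching criterion in that fixed order.
#'
#' @param trajectories Patient-hour data.frame with a `patient_id` column.
#' @param patients Static patient table carrying the four flag columns.
#' @return A list with filtered `trajectories` and `patients`, and `tally`,
#'   a named integer vector of patients removed per criterion.
#' @export
apply_exclusions <- function(trajectories, patients) {
  missing_cols <- setdiff(EXCLUSION_FLAGS, names(patients))
  if (length(missing_cols)) {
    stop("patient table lacks exclusion flag column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tally <- stats::setNames(integer(length(EXCLUSION_FLAGS)), EXCLUSION_FLAGS)
  excluded <- rep(FALSE, nrow(patients))
  for (flag in EXCLUSION_FLAGS) {
    hit <- patients[[flag]] == 1L & !excluded
    tally[flag] <- sum(hit)
    excluded <- excluded | hit
  }
  keep_ids <- patients$patient_id[!excluded]
  list(
    trajectories = trajectories[trajectories$patient_id %in% keep_ids, ,
                                drop = FALSE],
    patients = patients[!excluded, , drop = FALSE],
    tally = tally
  )
}

#' Align trajectories to hourly bins anchored at the first glucose
#'
#' Bins time-stamped rows into 1-hour intervals (doses summed, measurements
#' averaged, per the schema), retains only the first `horizon` hours of raw
#' data, and re-indexes hours so that hour 0 is the first available glucose
#' measurement. If a numeric `time` column is present it is floored to hours;
#' otherwise the integer `hour` column is used as-is. Patients without any
#' glucose measurement are dropped with a warning.
#'
#' @param trajectories Patient-hour (or time-stamped) data.frame.
#' @param schema Aggregation schema, see [trajectory_schema()].
#' @param horizon Raw observation window in hours (default 24).
#' @return Hourly data.frame with re-indexed `hour` starting at 0.
#' @export
align_and_bin <- function(trajectories, schema = trajectory_schema(),
                          horizon = 24) {
  df <- trajectories
  if ("time" %in% names(df) && !("hour" %in% names(df))) {
    df$hour <- floor(df$time)
    df$time <- NULL
  }
  stopifnot("hour" %in% names(df), "patient_id" %in% names(df),
            "glucose" %in% names(df))
  df <- df[df$hour >= 0 & df$hour < horizon, , drop = FALSE]

  feat_cols <- setdiff(names(df), c("patient_id", "hour"))
  agg_of <- stats::setNames(schema$agg, schema$feature)
  key <- interaction(df$patient_id, df$hour, drop = TRUE)
  if (anyDuplicated(key)) {
    aggregated <- lapply(feat_cols, function(col) {
      fun <- if (identical(agg_of[[col]], "sum")) {
        function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
      } else {
        function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      }
      as.numeric(tapply(df[[col]], key, fun))
    })
    # tapply returns values in key-level order; rebuild ids/hours from levels
    lev <- levels(key)
    split_ids <- sub("\\.[^.]*$", "", lev)
    split_hours <- as.numeric(sub("^.*\\.", "", lev))
    out <- data.frame(patient_id = split_ids, hour = split_hours,
                      stringsAsFactors = FALSE)
    for (i in seq_along(feat_cols)) out[[feat_cols[i]]] <- aggregated[[i]]
    df <- out
  }
  df <- df[order(df$patient_id, df$hour), , drop = FALSE]

  pieces <- lapply(split(df, df$patient_id), function(p) {
    obs <- which(!is.na(p$glucose))
    if (!length(obs)) return(NULL)
    p <- p[p$hour >= p$hour[obs[1]], , drop = FALSE]
    p$hour <- p$hour - p$hour[1]
    p
  })
  dropped <- vapply(pieces, is.null, TRUE)
  if (any(dropped)) {
    warning(sum(dropped), " patient(s) without any glucose measurement dropped",
            call. = FALSE)
  }
  out <- do.call(rbind, pieces[!dropped])
  rownames(out) <- NULL
  out
}

#' Drop high-missingness features and impute the rest
#'
#' Features whose missingness over the training split's patient-hours exceeds
#' `threshold` (strictly) are dropped. Remaining gaps are forward-filled
#' within each patient; leading gaps that forward fill cannot reach are
#' imputed by k-nearest-neighbour regression (Euclidean distance over the
#' fully observed features, standardized by training min/max; donors are
#' training-split rows only, so no information leaks from the test split).
#'
#' @param hourly Hourly table from [align_and_bin()] (optionally merged with
#'   static covariates).
#' @param train_ids Patient ids constituting the training split; missingness
#'   rates and k-NN donors are computed from these patients only. Defaults to
#'   all patients.
#' @param threshold Missingness fraction above which a feature is dropped.
#' @param k Number of neighbours for k-NN imputation.
#' @return List with `table` (imputed), `dropped` (feature names removed) and
#'   `missing_rates` (training-split missingness per feature).
#' @export
handle_missingness <- function(hourly, train_ids = unique(hourly$patient_id),
                               threshold = 0.30, k = 5) {
  feat_cols <- setdiff(names(hourly), c("patient_id", "hour"))
  train_rows <- hourly$patient_id %in% train_ids
  if (!any(train_rows)) stop("no training rows", call. = FALSE)

  rates <- vapply(feat_cols, function(col) {
    mean(is.na(hourly[[col]][train_rows]))
  }, numeric(1))
  dropped <- feat_cols[rates > threshold]
  keep <- setdiff(feat_cols, dropped)
  df <- hourly[c("patient_id", "hour", keep)]

  # forward fill within patient
  ord <- order(df$patient_id, df$hour)
  df <- df[ord, , drop = FALSE]
  pid <- df$patient_id
  new_patient <- c(TRUE, pid[-1] != pid[-length(pid)])
  for (col in keep) {
    x <- df[[col]]
    if (!anyNA(x)) next
    # last-observation-carried-forward, reset at patient boundaries
    run_start <- cumsum(new_patient)
    filled <- stats::ave(x, run_start, FUN = function(v) {
      i <- seq_along(v)
      i[is.na(v)] <- NA
      i <- cummax_na(i)
      ifelse(is.na(i), NA, v[i])
    })
    df[[col]] <- filled
  }

  # k-NN for leading gaps, donors from the training split
  still_missing <- vapply(keep, function(col) anyNA(df[[col]]), TRUE)
  if (any(still_missing)) {
    complete_cols <- keep[vapply(keep, function(col) !anyNA(df[[col]]), TRUE)]
    if (!length(complete_cols)) {
      stop("k-NN imputation needs at least one fully observed feature",
           call. = FALSE)
    }
    train_mask <- df$patient_id %in% train_ids
    ref <- as.matrix(df[train_mask, complete_cols, drop = FALSE])
    rng_lo <- apply(ref, 2L, min)
    rng <- pmax(apply(ref, 2L, max) - rng_lo, 1e-12)
    ref_std <- sweep(sweep(ref, 2L, rng_lo), 2L, rng, "/")
    for (col in keep[still_missing]) {
      miss_idx <- which(is.na(df[[col]]))
      donor_ok <- which(train_mask & !is.na(df[[col]]))
      if (!length(donor_ok)) {
        stop("feature '", col, "' has no observed training values; ",
             "it should have been dropped by the missingness rule",
             call. = FALSE)
      }
      donors_std <- ref_std[match(donor_ok, which(train_mask)), , drop = FALSE]
      donor_vals <- df[[col]][donor_ok]
      q_std <- sweep(sweep(as.matrix(df[miss_idx, complete_cols, drop = FALSE]),
                           2L, rng_lo), 2L, rng, "/")
      kk <- min(k, nrow(donors_std))
      for (j in seq_along(miss_idx)) {
        d2 <- colSums((t(donors_std) - q_std[j, ])^2)
        nn <- order(d2)[seq_len(kk)]
        df[[col]][miss_idx[j]] <- mean(donor_vals[nn])
      }
    }
  }
  rownames(df) <- NULL
  list(table = df, dropped = dropped, missing_rates = rates)
}

# cummax that propagates over NA (last non-NA index)
cummax_na <- function(i) {
  out <- i
  last <- NA_integer_
  for (j in seq_along(i)) {
    if (!is.na(i[j])) last <- i[j]
    out[j] <- last
  }
  out
}

#' Add glucose-history features
#'
#' Appends, per patient-hour: the prior four hours of glucose
#' (`glucose_lag1` ... `glucose_lag4`, backfilled with the earliest observed
#' glucose where history is shorter), the hourly glucose changes over the
#' same window (`glucose_delta1` = current minus previous, etc.), and the
#' change-to-insulin ratio `glucose_delta1 / max(dose, 0.1)`, where the dose
#' is the insulin administered during the hour over which the change was
#' measured (the previous row's action) and the 0.1 floor guards undosed
#' hours.
#'
#' @param hourly Imputed hourly table with `glucose` and `insulin` columns.
#' @return The table with seven appended feature columns.
#' @export
engineer_glucose_features <- function(hourly) {
  stopifnot(all(c("glucose", "insulin") %in% names(hourly)))
  df <- hourly[order(hourly$patient_id, hourly$hour), , drop = FALSE]
  pieces <- lapply(split(df, df$patient_id), function(p) {
    g <- p$glucose
    n <- length(g)
    lag_k <- function(k) c(rep(g[1], min(k, n)), g[seq_len(max(0, n - k))])
    l1 <- lag_k(1); l2 <- lag_k(2); l3 <- lag_k(3); l4 <- lag_k(4)
    p$glucose_lag1 <- l1
    p$glucose_lag2 <- l2
    p$glucose_lag3 <- l3
    p$glucose_lag4 <- l4
    p$glucose_delta1 <- g - l1
    p$glucose_delta2 <- l1 - l2
    p$glucose_delta3 <- l2 - l3
    p$glucose_delta4 <- l3 - l4
    prev_dose <- c(0, p$insulin[seq_len(max(0, n - 1))])
    p$insulin_lag1 <- prev_dose
    p$delta_insulin_ratio <- p$glucose_delta1 / pmax(prev_dose, 0.1)
    p
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Min-max normalization to the unit interval
#'
#' Scales each feature to `[0, 1]` using per-feature minima and maxima
#' computed on the training split; values outside the training range are
#' clipped. Features constant on the training split are dropped.
#'
#' @param table Feature table (patient-hour rows).
#' @param stats Normalization statistics from a previous call (training
#'   split); if `NULL`, computed from `table` rows belonging to `train_ids`.
#' @param train_ids Patient ids used to compute statistics when `stats` is
#'   `NULL`.
#' @param exclude Columns never normalized: identifiers, and `insulin`,
#'   which is the action, is kept in raw units rather than entering the
#'   state (past doses reach the state via `insulin_lag1` and the
#'   change-to-insulin ratio).
#' @return List with `table` (normalized, plus an untouched `glucose_raw`
#'   column for reward computation), `stats` (list with `min`, `max`,
#'   `features`), and `dropped_constant`.
#' @export
normalize_features <- function(table, stats = NULL,
                               train_ids = unique(table$patient_id),
                               exclude = c("patient_id", "hour", "insulin")) {
  if (!"glucose_raw" %in% names(table)) table$glucose_raw <- table$glucose
  exclude <- intersect(exclude, names(table))
  feat_cols <- setdiff(names(table), c(exclude, "glucose_raw"))
  dropped <- character(0)
  if (is.null(stats)) {
    train_rows <- table$patient_id %in% train_ids
    if (!any(train_rows)) stop("no training rows for stats", call. = FALSE)
    mins <- vapply(feat_cols, function(c) min(table[[c]][train_rows]), 0)
    maxs <- vapply(feat_cols, function(c) max(table[[c]][train_rows]), 0)
    constant <- maxs - mins <= 0
    dropped <- feat_cols[constant]
    feat_cols <- feat_cols[!constant]
    stats <- list(min = mins[!constant], max = maxs[!constant],
                  features = feat_cols)
  } else {
    unknown <- setdiff(stats$features, names(table))
    if (length(unknown)) {
      stop("normalization stats refer to unknown feature(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    feat_cols <- stats$features
  }
  out <- table[c(exclude, "glucose_raw", feat_cols)]
  for (col in feat_cols) {
    rng <- stats$max[[col]] - stats$min[[col]]
    out[[col]] <- clip((table[[col]] - stats$min[[col]]) / rng, 0, 1)
  }
  list(table = out, stats = stats, dropped_constant = dropped)
}

#' Build a transition dataset from a normalized hourly table
#'
#' For each patient and each consecutive hour pair `(t, t+1)`: the state is
#' the normalized feature vector at `t`; the action is the insulin dose at
#' `t` clipped to `[0, 10]`; the reward is the shaped reward of the glucose
#' observed at `t+1` (the action's consequence) minus the quadratic dose
#' penalty; the next state is the feature vector at `t+1`; the final pair of
#' the episode is flagged done. Single-hour patients contribute no
#' transitions and are skipped with a warning. The terminal hour's own action
#' has no observed consequence and contributes no transition.
#'
#' @param normalized Result of [normalize_features()] (list with `table` and
#'   `stats`), or the normalized table itself plus `stats`.
#' @param params [reward_params()] used for the shaped reward.
#' @param stats Normalization statistics (when `normalized` is a bare table).
#' @param action_max Dose cap in units (default 10).
#' @return An object of class `transition_dataset`: list with matrices
#'   `states`, `next_states`, vectors `actions`, `rewards`, `done`,
#'   `patient_id`, `hour`, the `feature_names`, `norm_stats` and `episodes`
#'   (a list of row-index vectors, one per patient, in temporal order).
#' @export
build_transitions <- function(normalized, params = reward_params(),
                              stats = NULL, action_max = 10) {
  if (is.list(normalized) && !is.data.frame(normalized) &&
      all(c("table", "stats") %in% names(normalized))) {
    tab <- normalized$table
    stats <- normalized$stats
  } else {
    tab <- normalized
    if (is.null(stats)) stop("stats required with a bare table", call. = FALSE)
  }
  feat_cols <- stats$features
  tab <- tab[order(tab$patient_id, tab$hour), , drop = FALSE]
  pieces <- split(tab, tab$patient_id)
  n_single <- 0L
  states <- list(); next_states <- list()
  actions <- list(); rewards <- list(); done <- list()
  pids <- list(); hours <- list(); glus <- list(); glus_next <- list()
  for (p in pieces) {
    n <- nrow(p)
    if (n < 2L) {
      n_single <- n_single + 1L
      next
    }
    feats <- as.matrix(p[feat_cols])
    idx_t <- seq_len(n - 1L)
    if (is.null(p$insulin)) stop("insulin column required", call. = FALSE)
    a <- clip(p$insulin, 0, action_max)[idx_t]
    states[[length(states) + 1L]] <- feats[idx_t, , drop = FALSE]
    next_states[[length(next_states) + 1L]] <- feats[idx_t + 1L, , drop = FALSE]
    actions[[length(actions) + 1L]] <- a
    rewards[[length(rewards) + 1L]] <-
      shaped_reward(p$glucose_raw[idx_t + 1L], a, params)
    done[[length(done) + 1L]] <- c(rep(FALSE, n - 2L), TRUE)
    pids[[length(pids) + 1L]] <- p$patient_id[idx_t]
    hours[[length(hours) + 1L]] <- p$hour[idx_t]
    glus[[length(glus) + 1L]] <- p$glucose_raw[idx_t]
    glus_next[[length(glus_next) + 1L]] <- p$glucose_raw[idx_t + 1L]
  }
  if (n_single > 0L) {
    warning(n_single, " single-hour patient(s) skipped", call. = FALSE)
  }
  if (!length(states)) stop("no transitions could be built", call. = FALSE)
  st <- do.call(rbind, states)
  pid_vec <- unlist(pids, use.names = FALSE)
  ds <- structure(list(
    states = st,
    actions = unlist(actions, use.names = FALSE),
    rewards = unlist(rewards, use.names = FALSE),
    next_states = do.call(rbind, next_states),
    done = unlist(done, use.names = FALSE),
    patient_id = pid_vec,
    hour = unlist(hours, use.names = FALSE),
    glucose = unlist(glus, use.names = FALSE),
    glucose_next = unlist(glus_next, use.names = FALSE),
    feature_names = feat_cols,
    norm_stats = stats,
    episodes = split(seq_len(nrow(st)), pid_vec)[unique(pid_vec)]
  ), class = "transition_dataset")
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transition_dataset <- function(x, ...) {
  cat(sprintf("Transition dataset: %d transitions, %d episodes, %d features\n",
              length(x$actions), length(x$episodes), ncol(x$states)))
  cat(sprintf("  reward range [%.3f, %.3f]; dose range [%g, %g] U\n",
              min(x$rewards), max(x$rewards), min(x$actions), max(x$actions)))
  invisible(x)
}

#' Subset a transition dataset by patient
#'
#' @param dataset A `transition_dataset`.
#' @param patient_ids Patients to keep.
#' @return A `transition_dataset` restricted to those patients.
#' @export
subset_transitions <- function(dataset, patient_ids) {
  keep <- dataset$patient_id %in% patient_ids
  if (!any(keep)) stop("no transitions for the requested patients", call. = FALSE)
  idx <- which(keep)
  out <- dataset
  out$states <- dataset$states[idx, , drop = FALSE]
  out$next_states <- dataset$next_states[idx, , drop = FALSE]
  for (f in c("actions", "rewards", "done", "patient_id", "hour",
              "glucose", "glucose_next")) {
    out[[f]] <- dataset[[f]][idx]
  }
  pid <- out$patient_id
  out$episodes <- split(seq_along(idx), pid)[unique(pid)]
  out
}

#' Patient-level train/test split
#'
#' Splits patient ids into training and test sets at the patient level so no
#' patient contributes to both. Deterministic under `seed`.
#'
#' @param patient_ids Character vector of patient ids (or a
#'   `transition_dataset`, whose patients are used).
#' @param train_frac Fraction of patients assigned to training (default 0.85).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_patients <- function(patient_ids, train_frac = 0.85, seed = 1L) {
  if (inherits(patient_ids, "transition_dataset")) {
    patient_ids <- unique(patient_ids$patient_id)
  }
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  ids <- unique(patient_ids)
  local_seed(seed)
  n_train <- round(train_frac * length(ids))
  train <- sort(sample(ids, n_train))
  list(train = train, test = sort(setdiff(ids, train)))
}

#' Subsample training patients without replacement
#'
#' Draws `floor(frac * n)` of the training patients, used to give each model
#' of the multi-seed protocol a distinct training subset.
#'
#' @param patient_ids Training patient ids.
#' @param frac Subsample fraction (default 0.80).
#' @param seed Integer seed.
#' @return Character vector of sampled ids.
#' @export
subsample_patients <- function(patient_ids, frac = 0.80, seed = 1L) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  ids <- unique(patient_ids)
  local_seed(seed)
  sort(sample(ids, floor(frac * length(ids))))
}

#' End-to-end preprocessing of a simulated or imported cohort
#'
#' Convenience wrapper chaining [apply_exclusions()], [align_and_bin()],
#' static-covariate merging, [handle_missingness()],
#' [engineer_glucose_features()], [normalize_features()] (training-split
#' statistics only) and [build_transitions()], with a patient-level
#' [split_patients()] in between.
#'
#' @param cohort A `cohort` list (`trajectories`, `patients`) as produced by
#'   [simulate_cohort()] or [read_trajectories()].
#' @param train_frac Training fraction for the patient split.
#' @param seed Seed for the split.
#' @param params [reward_params()].
#' @param threshold,k Missingness parameters, see [handle_missingness()].
#' @param horizon Hours retained per patient.
#' @return List with `train` and `test` `transition_dataset`s, `split`,
#'   `exclusion_tally`, `dropped_features` and `norm_stats`.
#' @export
build_mdp <- function(cohort, train_frac = 0.85, seed = 1L,
                      params = reward_params(), threshold = 0.30, k = 5,
                      horizon = 24) {
  filt <- apply_exclusions(cohort$trajectories, cohort$patients)
  hourly <- align_and_bin(filt$trajectories, horizon = horizon)
  static_cols <- trajectory_schema()
  static_cols <- static_cols$feature[static_cols$kind == "static"]
  static_cols <- intersect(static_cols, names(filt$patients))
  hourly <- merge(hourly, filt$patients[c("patient_id", static_cols)],
                  by = "patient_id", sort = FALSE)
  hourly <- hourly[order(hourly$patient_id, hourly$hour), , drop = FALSE]

  split <- split_patients(unique(hourly$patient_id), train_frac, seed)
  imp <- handle_missingness(hourly, train_ids = split$train,
                            threshold = threshold, k = k)
  eng <- engineer_glucose_features(imp$table)
  norm <- normalize_features(eng, train_ids = split$train)
  tab <- norm$table
  train_tab <- tab[tab$patient_id %in% split$train, , drop = FALSE]
  test_tab <- tab[tab$patient_id %in% split$test, , drop = FALSE]
  list(
    train = build_transitions(list(table = train_tab, stats = norm$stats),
                              params = params),
    test = build_transitions(list(table = test_tab, stats = norm$stats),
                             params = params),
    split = split,
    exclusion_tally = filt$tally,
    dropped_features = c(imp$dropped, norm$dropped_constant),
    norm_stats = norm$stats
  )
}
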