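#' Glycemic reward parameters
#'
#' Bundles the constants of the piecewise glycemic reward and the quadratic
#' dose penalty. The reward plateaus at `plateau_reward` on
#' `[plateau_low, plateau_high)` mg/dL, falls linearly towards `floor_reward`
#' on either side, and sits at the floor below `hypo_cut` and at or above
#' `hyper_floor_cut`. The penalty subtracts `penalty_coeff * dose^2` from the
#' glycemic reward.
#'
#' @param hypo_cut Glucose (mg/dL) below which the reward is the floor.
#' @param plateau_low,plateau_high Bounds (mg/dL) of the maximum-reward band.
#' @param hyper_floor_cut Glucose (mg/dL) at and above which the reward is the
#'   floor again.
#' @param plateau_reward Reward inside the plateau band (dimensionless).
#' @param floor_reward Minimum reward (dimensionless).
#' @param rise_slope,rise_intercept Linear segment on
#'   `[hypo_cut, plateau_low)`, reward = `rise_slope * x + rise_intercept`.
#' @param fall_slope,fall_intercept Linear segment on
#'   `[plateau_high, hyper_floor_cut)`.
#' @param penalty_coeff Coefficient of the quadratic dose penalty
#'   (per squared insulin unit).
#'
#' @return An object of class `reward_params`.
#' @export
#' @examples
#' p <- reward_params()
#' glycemic_reward(160, p)
reward_params <- function(hypo_cut = 70,
                          plateau_low = 140,
                          plateau_high = 180,
                          hyper_floor_cut = 220,
                          plateau_reward = 0.2,
                          floor_reward = -1,
                          rise_slope = 3 / 175,
                          rise_intercept = -2.2,
                          fall_slope = -0.03,
                          fall_intercept = 5.6,
                          penalty_coeff = 0.001) {
  stopifnot(hypo_cut < plateau_low, plateau_low < plateau_high,
            plateau_high < hyper_floor_cut,
            floor_reward < plateau_reward,
            penalty_coeff >= 0)
  structure(list(
    hypo_cut = hypo_cut, plateau_low = plateau_low,
    plateau_high = plateau_high, hyper_floor_cut = hyper_floor_cut,
    plateau_reward = plateau_reward, floor_reward = floor_reward,
    rise_slope = rise_slope, rise_intercept = rise_intercept,
    fall_slope = fall_slope, fall_intercept = fall_intercept,
    penalty_coeff = penalty_coeff
  ), class = "reward_params")
}

#' @export
print.reward_params <- function(x, ...) {
  cat("Glycemic reward parameters\n")
  cat(sprintf("  plateau: +%.2g on [%g, %g) mg/dL; floor %.2g below %g and at/above %g\n",
              x$plateau_reward, x$plateau_low, x$plateau_high,
              x$floor_reward, x$hypo_cut, x$hyper_floor_cut))
  cat(sprintf("  dose penalty: %g * dose^2\n", x$penalty_coeff))
  invisible(x)
}

# Physiologic plausibility gate shared by the reward and the simulator:
# values outside this range are data errors, not extreme physiology.
GLUCOSE_RANGE <- c(20, 600)

check_glucose <- function(glucose) {
  if (!is.numeric(glucose) || length(glucose) == 0L) {
    stop("glucose must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(glucose))) {
    stop("glucose must be finite", call. = FALSE)
  }
  if (any(glucose < GLUCOSE_RANGE[1] | glucose > GLUCOSE_RANGE[2])) {
    stop(sprintf("glucose outside the plausible range [%g, %g] mg/dL",
                 GLUCOSE_RANGE[1], GLUCOSE_RANGE[2]), call. = FALSE)
  }
  invisible(glucose)
}

#' Piecewise glycemic reward
#'
#' Five-branch reward of the hourly glucose level: a plateau of `+0.2` on
#' 140-180 mg/dL, linear descent to `-1` towards 70 mg/dL on the low side and
#' towards 220 mg/dL on the high side, and `-1` beyond. Branch membership uses
#' half-open intervals (`70 <= x < 140`, etc.). Continuous at every boundary.
#'
#' @param glucose Glucose values in mg/dL. Must be finite and within the
#'   plausible range 20-600 mg/dL; anything else is treated as a data error.
#' @param params A [reward_params()] object.
#' @return Reward values, same length as `glucose`, in
#'   `[floor_reward, plateau_reward]`.
#' @export
#' @examples
#' glycemic_reward(c(60, 105, 160, 200, 250))
glycemic_reward <- function(glucose, params = reward_params()) {
  check_glucose(glucose)
  x <- glucose
  r <- numeric(length(x))
  lo <- x < params$hypo_cut
  rise <- x >= params$hypo_cut & x < params$plateau_low
  flat <- x >= params$plateau_low & x < params$plateau_high
  fall <- x >= params$plateau_high & x < params$hyper_floor_cut
  hi <- x >= params$hyper_floor_cut
  r[lo] <- params$floor_reward
  r[rise] <- params$rise_slope * x[rise] + params$rise_intercept
  r[flat] <- params$plateau_reward
  r[fall] <- params$fall_slope * x[fall] + params$fall_intercept
  r[hi] <- params$floor_reward
  r
}

#' Quadratic insulin dose penalty
#'
#' Penalises large boluses to discourage overcorrection:
#' `penalty_coeff * dose^2`.
#'
#' @param dose Insulin dose(s) in units, non-negative.
#' @inheritParams glycemic_reward
#' @return Non-negative penalties, same length as `dose`.
#' @export
#' @examples
#' action_penalty(c(0, 4, 10))
action_penalty <- function(dose, params = reward_params()) {
  if (!is.numeric(dose) || any(!is.finite(dose))) {
    stop("dose must be finite numeric", call. = FALSE)
  }
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  params$penalty_coeff * dose^2
}

#' Shaped reward: glycemic reward minus dose penalty
#'
#' The per-transition reward used to build the decision process: the glycemic
#' reward of the glucose observed after the action, minus the quadratic
#' penalty of the dose taken.
#'
#' @param glucose Glucose in mg/dL observed as the consequence of the dose.
#' @param dose Insulin dose in units (recycled against `glucose`).
#' @inheritParams glycemic_reward
#' @return Shaped rewards.
#' @export
#' @examples
#' shaped_reward(160, 0)   # 0.2
#' shaped_reward(160, 10)  # 0.1
shaped_reward <- function(glucose, dose, params = reward_params()) {
  glycemic_reward(glucose, params) - action_penalty(dose, params)
}
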