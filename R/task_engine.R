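# Adjusting-amount delay-discounting task: configuration, simulated agents,
# staircase administration, indifference-point extraction, choice-log scoring.

#' Task configuration for the adjusting-amount procedure
#'
#' Describes one administration of the adjusting-amount ("staircase") delay
#' discounting task: a fixed larger-later reward (LLR) is pitted against an
#' immediate amount that titrates toward the participant's indifference point
#' at each of several delays.
#'
#' The adjustment schedule is a binary search: the first immediate offer is
#' `start_fraction * llr_amount`; after each choice the offer moves down (if
#' the immediate option was chosen) or up (if the delayed option was chosen)
#' by a step that starts at `start_fraction * llr_amount / 2` and halves after
#' every trial. The indifference point is the hypothetical next offer after
#' the final adjustment.
#'
#' @param llr_amount Larger-later reward in dollars. Default 100.
#' @param delays Delays in days at which staircases are run, strictly
#'   increasing and positive. Default `c(1, 7, 30, 182, 365)`.
#' @param trials_per_delay Number of binary choices per staircase (>= 1).
#'   Default 6.
#' @param start_fraction First immediate offer as a fraction of `llr_amount`,
#'   in (0, 1). Default 0.5 ("$50 now or $100 later").
#' @param tie_rule What a deterministic (zero-noise) agent does when the
#'   immediate offer exactly equals the discounted value of the LLR:
#'   `"prefer_delayed"` (default) or `"prefer_immediate"`.
#' @return An object of class `dd_task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$delays
#' @export
task_config <- function(llr_amount = 100,
                        delays = c(1, 7, 30, 182, 365),
                        trials_per_delay = 6L,
                        start_fraction = 0.5,
                        tie_rule = c("prefer_delayed", "prefer_immediate")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(is.numeric(llr_amount), length(llr_amount) == 1L, llr_amount > 0)
  if (!is.numeric(delays) || length(delays) < 1L || any(delays <= 0) ||
      is.unsorted(delays, strictly = TRUE)) {
    stop("`delays` must be a strictly increasing vector of positive day counts",
         call. = FALSE)
  }
  trials_per_delay <- as.integer(trials_per_delay)
  stopifnot(length(trials_per_delay) == 1L, trials_per_delay >= 1L)
  stopifnot(is.numeric(start_fraction), length(start_fraction) == 1L,
            start_fraction > 0, start_fraction < 1)
  structure(
    list(llr_amount = llr_amount, delays = as.numeric(delays),
         trials_per_delay = trials_per_delay, start_fraction = start_fraction,
         tie_rule = tie_rule),
    class = "dd_task_config"
  )
}

#' Simulated choice agent
#'
#' A synthetic respondent used by the cohort generator. The agent values the
#' delayed reward with a hyperbolic discount function `V = A / (1 + k D)` and
#' chooses via a logistic (softmax) rule with temperature
#' `noise_temperature`; temperature 0 gives a deterministic threshold
#' responder. The parametric form is a generator modelling choice, not an
#' assumption of any scoring or analysis code.
#'
#' @param k Hyperbolic discount rate per day, >= 0.
#' @param noise_temperature Choice noise temperature in dollars, >= 0.
#' @return An object of class `dd_agent`.
#' @examples
#' a <- dd_agent(k = 0.05)
#' @export
dd_agent <- function(k, noise_temperature = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  stopifnot(is.numeric(noise_temperature), length(noise_temperature) == 1L,
            noise_temperature >= 0)
  structure(list(k = k, noise_temperature = noise_temperature),
            class = "dd_agent")
}

#' Hyperbolic present value of a delayed amount
#'
#' `V = A / (1 + k D)`; equals `A` when `k = 0` or `delay = 0`. Vectorised
#' over its arguments.
#'
#' @param amount Delayed amount(s), >= 0.
#' @param k Discount rate(s) per day, >= 0.
#' @param delay Delay(s) in days, >= 0.
#' @return Present value(s), same length as the recycled inputs.
#' @examples
#' hyperbolic_value(100, 0.05, 30)  # 40
#' @export
hyperbolic_value <- function(amount, k, delay) {
  if (any(amount < 0) || any(k < 0) || any(delay < 0)) {
    stop("amount, k and delay must all be non-negative", call. = FALSE)
  }
  amount / (1 + k * delay)
}

#' Simulate one binary choice
#'
#' With temperature 0 the agent chooses the immediate amount iff it exceeds
#' the hyperbolic value of the LLR (ties resolved by `config$tie_rule`); with
#' temperature > 0 it chooses the immediate amount with probability
#' `plogis((immediate - value) / temperature)`.
#'
#' @param agent A [dd_agent()].
#' @param immediate Immediate offer, in `(0, llr_amount)`.
#' @param delay Delay in days.
#' @param config A [task_config()].
#' @return `TRUE` if the immediate amount was chosen.
#' @export
simulate_choice <- function(agent, immediate, delay, config = task_config()) {
  stopifnot(inherits(agent, "dd_agent"), inherits(config, "dd_task_config"))
  if (immediate <= 0 || immediate >= config$llr_amount) {
    stop("immediate offer must lie strictly between 0 and the LLR amount",
         call. = FALSE)
  }
  value <- hyperbolic_value(config$llr_amount, agent$k, delay)
  if (agent$noise_temperature == 0) {
    if (immediate == value) {
      return(config$tie_rule == "prefer_immediate")
    }
    return(immediate > value)
  }
  stats::runif(1) < stats::plogis((immediate - value) / agent$noise_temperature)
}

# Vectorised staircase over agents at one delay. k, temp: equal-length
# vectors. Returns list(offers = n x trials matrix, choices = n x trials
# logical matrix, ip = numeric n). Stochastic draws consume the R RNG stream
# only for temp > 0 rows (one uniform per agent-trial, drawn for all rows to
# keep the stream layout independent of the temperature pattern).
staircase_batch <- function(k, temp, delay, config) {
  n <- length(k)
  tpd <- config$trials_per_delay
  llr <- config$llr_amount
  offers <- matrix(NA_real_, n, tpd)
  choices <- matrix(NA, n, tpd)
  offer <- rep(config$start_fraction * llr, n)
  step <- config$start_fraction * llr / 2
  value <- hyperbolic_value(llr, k, delay)
  eps <- llr * 1e-12
  for (t in seq_len(tpd)) {
    offers[, t] <- offer
    u <- stats::runif(n)
    det <- if (config$tie_rule == "prefer_immediate") offer >= value
           else offer > value
    noisy <- u < stats::plogis((offer - value) / temp)
    chose_imm <- ifelse(temp > 0, noisy, det)
    choices[, t] <- chose_imm
    offer <- offer + ifelse(chose_imm, -step, step)
    offer <- pmin(pmax(offer, eps), llr - eps)
    step <- step / 2
  }
  list(offers = offers, choices = choices, ip = offer)
}

#' Run one adjusting-amount staircase
#'
#' Administers `config$trials_per_delay` binary choices at a single delay,
#' titrating the immediate offer by binary search (see [task_config()]), and
#' returns the trial log together with the indifference point (the offer
#' after the final adjustment). Offers are clamped to `(0, llr_amount)`.
#'
#' @inheritParams simulate_choice
#' @param participant_id Identifier recorded in the trial log.
#' @return A list with `trials` (a data.frame with columns `participant_id`,
#'   `delay_days`, `trial_index`, `immediate_amount`, `chose_immediate`) and
#'   `indifference_point`.
#' @examples
#' run_adjusting_staircase(dd_agent(k = 0.05), delay = 30)$indifference_point
#' @export
run_adjusting_staircase <- function(agent, delay, config = task_config(),
                                    participant_id = "agent") {
  stopifnot(inherits(agent, "dd_agent"), inherits(config, "dd_task_config"))
  res <- staircase_batch(agent$k, agent$noise_temperature, delay, config)
  trials <- data.frame(
    participant_id = participant_id,
    delay_days = delay,
    trial_index = seq_len(config$trials_per_delay),
    immediate_amount = as.numeric(res$offers[1, ]),
    chose_immediate = as.logical(res$choices[1, ]),
    stringsAsFactors = FALSE
  )
  list(trials = trials, indifference_point = res$ip[1])
}

#' Indifference-point profile
#'
#' One participant's indifference points at each configured delay, plus the
#' LLR they were measured against.
#'
#' @param participant_id Identifier.
#' @param delays Delays in days (strictly increasing).
#' @param points Indifference points in dollars, one per delay, each in
#'   `[0, llr_amount]`.
#' @param llr_amount Larger-later reward.
#' @return An object of class `dd_profile`.
#' @export
dd_profile <- function(participant_id, delays, points, llr_amount = 100) {
  stopifnot(length(delays) == length(points), llr_amount > 0)
  if (is.unsorted(delays, strictly = TRUE)) {
    stop("profile delays must be strictly increasing", call. = FALSE)
  }
  if (any(points < 0) || any(points > llr_amount)) {
    stop("indifference points must lie in [0, llr_amount]", call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, delays = as.numeric(delays),
         points = as.numeric(points), llr_amount = llr_amount),
    class = "dd_profile"
  )
}

#' @export
print.dd_profile <- function(x, ...) {
  cat("<dd_profile>", x$participant_id, "LLR", x$llr_amount, "\n")
  print(stats::setNames(x$points, paste0(x$delays, "d")))
  invisible(x)
}

#' Run the full adjusting-amount task for one agent
#'
#' One staircase per configured delay, administered in the order the delays
#' appear in the configuration (ascending by default).
#'
#' @inheritParams run_adjusting_staircase
#' @return A list with `profile` (a [dd_profile()]) and `trials` (the
#'   concatenated choice log across delays).
#' @examples
#' run_full_task(dd_agent(k = 0))$profile$points  # all 99.21875
#' @export
run_full_task <- function(agent, config = task_config(),
                          participant_id = "agent") {
  runs <- lapply(config$delays, function(d) {
    run_adjusting_staircase(agent, d, config, participant_id)
  })
  profile <- dd_profile(
    participant_id, config$delays,
    vapply(runs, `[[`, numeric(1), "indifference_point"),
    config$llr_amount
  )
  list(profile = profile,
       trials = do.call(rbind, lapply(runs, `[[`, "trials")))
}

#' Score a recorded choice log by replaying the staircase
#'
#' Re-derives indifference points from a per-trial choice log by replaying
#' the adjustment rule, verifying at every trial that the recorded offer
#' matches the offer the rule implies. Logs with missing trials, unknown
#' delays, or offers inconsistent with the adjustment schedule raise a
#' structured validation error (condition class `dd_log_error`) naming the
#' delay and trial.
#'
#' @param trials Data frame of one participant's trials with columns
#'   `delay_days`, `trial_index`, `immediate_amount`, `chose_immediate`
#'   (logical or 0/1), and optionally `participant_id`.
#' @param config The [task_config()] under which the log was produced.
#' @return A [dd_profile()].
#' @export
score_choice_log <- function(trials, config = task_config()) {
  stopifnot(is.data.frame(trials), inherits(config, "dd_task_config"))
  need <- c("delay_days", "trial_index", "immediate_amount", "chose_immediate")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop(dd_log_error(sprintf("choice log missing columns: %s",
                              paste(miss, collapse = ", "))))
  }
  pid <- if ("participant_id" %in% names(trials)) {
    u <- unique(trials$participant_id)
    if (length(u) != 1L) {
      stop(dd_log_error("choice log contains more than one participant"))
    }
    u
  } else "unknown"
  llr <- config$llr_amount
  tol <- llr * 1e-9
  points <- vapply(config$delays, function(d) {
    sub <- trials[trials$delay_days == d, , drop = FALSE]
    if (nrow(sub) != config$trials_per_delay) {
      stop(dd_log_error(sprintf(
        "delay %s: expected %d trials, found %d", format(d),
        config$trials_per_delay, nrow(sub)), delay = d))
    }
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    if (!identical(as.integer(sub$trial_index),
                   seq_len(config$trials_per_delay))) {
      stop(dd_log_error(sprintf("delay %s: trial indices are not 1..%d",
                                format(d), config$trials_per_delay), delay = d))
    }
    offer <- config$start_fraction * llr
    step <- config$start_fraction * llr / 2
    eps <- llr * 1e-12
    for (t in seq_len(config$trials_per_delay)) {
      if (abs(sub$immediate_amount[t] - offer) > tol) {
        stop(dd_log_error(sprintf(
          "delay %s trial %d: recorded offer %.6f inconsistent with replayed offer %.6f",
          format(d), t, sub$immediate_amount[t], offer), delay = d, trial = t))
      }
      chose_imm <- as.logical(sub$chose_immediate[t])
      if (is.na(chose_imm)) {
        stop(dd_log_error(sprintf("delay %s trial %d: missing choice",
                                  format(d), t), delay = d, trial = t))
      }
      offer <- offer + if (chose_imm) -step else step
      offer <- min(max(offer, eps), llr - eps)
      step <- step / 2
    }
    offer
  }, numeric(1))
  extra <- setdiff(unique(trials$delay_days), config$delays)
  if (length(extra)) {
    stop(dd_log_error(sprintf("log contains unconfigured delays: %s",
                              paste(extra, collapse = ", "))))
  }
  dd_profile(pid, config$delays, points, llr)
}

dd_log_error <- function(msg, delay = NULL, trial = NULL) {
  structure(
    class = c("dd_log_error", "error", "condition"),
    list(message = msg, call = NULL, delay = delay, trial = trial)
  )
}
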