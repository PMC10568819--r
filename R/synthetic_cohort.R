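# Synthetic parent-child dyad generator with known latent truth.
#
# Marginal defaults are calibrated to the study population the package
# targets (families seeking paediatric weight management): household income
# mean $84,459 (SD $55,134), parent education 15.0 (2.2) years, Medicaid
# 20.7%, parent age 41.4 (7.3), child age 9.4 (1.8) within 6-12, parent BMI
# 37.1 (7.9), child ~60% over the reference median BMI. Discount rates are
# log-normal; a latent scarcity composite drives parent (and optionally
# child) log-k, and high-choice-noise agents produce non-systematic
# profiles mechanistically.

#' Configuration for the synthetic dyad cohort generator
#'
#' All knobs of the generator, with defaults giving the cohort the marginal
#' structure described above. Effect sizes `gamma_parent` / `gamma_child`
#' are the slopes of member log-k on the standardized family scarcity
#' composite (positive = more scarcity, steeper discounting).
#'
#' @param n_families Number of parent-child dyads. Default 452.
#' @param income_mean,income_sd Household income moments; incomes are drawn
#'   log-normal moment-matched to these. Defaults 84459 / 55134.
#' @param education_mean,education_sd Parent education years. 15.0 / 2.2.
#' @param medicaid_rate Baseline Medicaid probability (modulated downward
#'   with income). Default 0.207.
#' @param minority_rate Baseline family minority probability (modulated with
#'   income); the child shares the family indicator. Default 0.346.
#' @param parent_age_mean,parent_age_sd Parent age, years. 41.4 / 7.3.
#' @param child_age_mean,child_age_sd Child age, years, truncated to
#'   `child_age_range`. 9.4 / 1.8.
#' @param child_age_range Closed interval for child ages. Default `c(6, 12)`.
#' @param child_male_rate,parent_male_rate Sex marginals. 0.479 / 0.141.
#' @param gamma_parent,gamma_child Scarcity-to-log-k slopes. Defaults 0.5
#'   (parents) and 0 (children): scarcity steepens parent but not child
#'   discounting.
#' @param logk_parent_mean,logk_child_mean Baseline log discount rates;
#'   defaults `log(0.005)` and `log(0.02)` (children discount more steeply).
#' @param logk_sd Residual SD of log-k. Default 1.5.
#' @param family_k_cor Fraction of the parent's log-k residual inherited by
#'   the child (within-family resemblance). Default 0.3.
#' @param nonsys_rate_child,nonsys_rate_parent Baseline probabilities of
#'   designating a member a non-systematic (high-noise) responder. Defaults
#'   0.42 / 0.19, emulating the child > parent non-systematic excess.
#' @param nonsys_scarcity_slope Logit slope of the designation probability
#'   on the scarcity composite (scarcer families more often non-systematic).
#'   Default 0.5.
#' @param temp_systematic Range of choice-noise temperatures (dollars) for
#'   ordinary responders. Default `c(0.2, 1.5)`.
#' @param temp_nonsystematic Range for designated non-systematic responders:
#'   large relative to the $100 stakes, so their choices approach coin flips
#'   and QC failure is likely. Default `c(50, 300)`.
#' @param seed Integer seed; every generator draw derives from it.
#' @return Object of class `dd_synth_config` (a named list).
#' @export
synthetic_config <- function(n_families = 452L,
                             income_mean = 84459, income_sd = 55134,
                             education_mean = 15.0, education_sd = 2.2,
                             medicaid_rate = 0.207,
                             minority_rate = 0.346,
                             parent_age_mean = 41.4, parent_age_sd = 7.3,
                             child_age_mean = 9.4, child_age_sd = 1.8,
                             child_age_range = c(6, 12),
                             child_male_rate = 0.479,
                             parent_male_rate = 0.141,
                             gamma_parent = 0.5, gamma_child = 0,
                             logk_parent_mean = log(0.005),
                             logk_child_mean = log(0.02),
                             logk_sd = 1.5,
                             family_k_cor = 0.3,
                             nonsys_rate_child = 0.42,
                             nonsys_rate_parent = 0.19,
                             nonsys_scarcity_slope = 0.5,
                             temp_systematic = c(0.2, 1.5),
                             temp_nonsystematic = c(50, 300),
                             seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$medicaid_rate, cfg$minority_rate, cfg$nonsys_rate_child,
             cfg$nonsys_rate_parent, cfg$child_male_rate, cfg$parent_male_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rate parameters must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  if (cfg$child_age_range[1] < 6 || cfg$child_age_range[2] > 12 ||
      diff(cfg$child_age_range) <= 0) {
    stop("child_age_range must be a non-empty interval within [6, 12]",
         call. = FALSE)
  }
  if (cfg$income_mean <= 0 || cfg$income_sd <= 0 || cfg$logk_sd < 0) {
    stop("income moments must be positive; logk_sd must be >= 0",
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "dd_synth_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic parent-child cohort with latent truth
#'
#' Draws `n_families` dyads. Per family: a log-normal income, education and
#' Medicaid/minority indicators correlated with it, and a standardized
#' scarcity composite `z_sc` built from -log-income, Medicaid and
#' -education; then parent log-k = baseline + `gamma_parent * z_sc` + noise
#' and child log-k = baseline_child + `gamma_child * z_sc` + inherited
#' parent residual + noise. Non-systematic responder designations and choice
#' noise temperatures are assigned per member. Latent truth columns (`log_k`,
#' `k`, `scarcity_z`, `designated_nonsystematic`, `noise_temperature`) are
#' retained so recovery can be tested.
#'
#' @param config A [synthetic_config()].
#' @return Data frame, two rows per family (`member_role` parent/child),
#'   with demographics, anthropometrics (height/weight), and latent truth.
#'   Attribute `truth` records the generating `gamma_parent`/`gamma_child`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "dd_synth_config"))
  set.seed(config$seed)
  n <- config$n_families

  # family-level economics
  s2 <- log(1 + (config$income_sd / config$income_mean)^2)
  mu <- log(config$income_mean) - s2 / 2
  income <- stats::rlnorm(n, mu, sqrt(s2))
  z_linc <- as.numeric(scale(log(income)))
  educ <- config$education_mean +
    config$education_sd * (0.4 * z_linc + sqrt(1 - 0.16) * stats::rnorm(n))
  educ <- pmin(pmax(educ, 6), 24)
  medicaid <- stats::rbinom(n, 1,
    stats::plogis(stats::qlogis(config$medicaid_rate) - 0.8 * z_linc))
  minority <- stats::rbinom(n, 1,
    stats::plogis(stats::qlogis(config$minority_rate) - 0.5 * z_linc))
  family_size <- pmax(2, round(stats::rnorm(n, 4.5, 1.2)))

  raw_sc <- -z_linc + (medicaid - mean(medicaid)) / max(stats::sd(medicaid), 1e-8) -
    as.numeric(scale(educ))
  z_sc <- if (stats::sd(raw_sc) > 0) as.numeric(scale(raw_sc)) else raw_sc * 0

  # latent discounting
  parent_resid <- stats::rnorm(n, 0, config$logk_sd)
  child_resid <- config$family_k_cor * parent_resid +
    sqrt(max(0, 1 - config$family_k_cor^2)) * stats::rnorm(n, 0, config$logk_sd)
  logk_p <- config$logk_parent_mean + config$gamma_parent * z_sc + parent_resid
  logk_c <- config$logk_child_mean + config$gamma_child * z_sc + child_resid

  # demographics per member
  age_p <- rtrunc_norm(n, config$parent_age_mean, config$parent_age_sd, 18, 80)
  age_c <- rtrunc_norm(n, config$child_age_mean, config$child_age_sd,
                       config$child_age_range[1], config$child_age_range[2])
  sex_p <- ifelse(stats::rbinom(n, 1, config$parent_male_rate) == 1,
                  "male", "female")
  sex_c <- ifelse(stats::rbinom(n, 1, config$child_male_rate) == 1,
                  "male", "female")
  race <- ifelse(minority == 1,
                 sample(c("Black", "Multiracial", "Asian", "Other"), n,
                        replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
                 "White")
  ethnicity <- ifelse(minority == 1 & stats::rbinom(n, 1, 0.3) == 1,
                      "Hispanic/Latino", "not Hispanic/Latino")
  insurance <- ifelse(medicaid == 1, "Medicaid",
                      sample(c("Private", "Medicare", "Other"), n,
                             replace = TRUE, prob = c(0.85, 0.05, 0.10)))

  # anthropometrics: parent BMI ~ 37.1 (7.9) floored at 25 (eligibility);
  # child drawn as percent over the reference median (~60% +/- 27)
  ref <- synthetic_lms_reference()
  bmi_p <- pmax(25, stats::rnorm(n, 37.1, 7.9))
  ht_p <- ifelse(sex_p == "male", stats::rnorm(n, 177, 7),
                 stats::rnorm(n, 163, 6.5))
  wt_p <- bmi_p * (ht_p / 100)^2
  age_c_months <- round(age_c * 12)
  med_c <- ref$M[match(paste(sex_c, age_c_months),
                       paste(ref$sex, ref$age_months))]
  pct_c <- pmax(15, stats::rnorm(n, 59.6, 27.3))
  bmi_c <- med_c * (1 + pct_c / 100)
  ht_c <- pmax(95, stats::rnorm(n, 85 + 6.0 * age_c, 5))
  wt_c <- bmi_c * (ht_c / 100)^2

  # non-systematic designation and choice noise
  p_ns_p <- stats::plogis(stats::qlogis(config$nonsys_rate_parent) +
                            config$nonsys_scarcity_slope * z_sc)
  p_ns_c <- stats::plogis(stats::qlogis(config$nonsys_rate_child) +
                            config$nonsys_scarcity_slope * z_sc)
  ns_p <- stats::rbinom(n, 1, p_ns_p)
  ns_c <- stats::rbinom(n, 1, p_ns_c)
  draw_temp <- function(ns) {
    lo <- ifelse(ns == 1, config$temp_nonsystematic[1], config$temp_systematic[1])
    hi <- ifelse(ns == 1, config$temp_nonsystematic[2], config$temp_systematic[2])
    stats::runif(length(ns), lo, hi)
  }
  temp_p <- draw_temp(ns_p)
  temp_c <- draw_temp(ns_c)

  fam <- sprintf("F%04d", seq_len(n))
  member_df <- function(role, pid_suffix, age, sex, ht, wt, logk, ns, temp) {
    data.frame(
      family_id = fam,
      participant_id = paste0(fam, pid_suffix),
      member_role = role,
      age = age, sex = sex,
      age_months = round(age * 12),
      height_cm = ht, weight_kg = wt,
      race = race, ethnicity = ethnicity, insurance = insurance,
      income = income, education_years = educ, family_size = family_size,
      scarcity_z = z_sc,
      log_k = logk, k = exp(logk),
      designated_nonsystematic = ns,
      noise_temperature = temp,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    member_df("parent", "-P", age_p, sex_p, ht_p, wt_p, logk_p, ns_p, temp_p),
    member_df("child", "-C", age_c, sex_c, ht_c, wt_c, logk_c, ns_c, temp_c)
  )
  out <- out[order(out$family_id, out$member_role, decreasing = c(FALSE, TRUE),
                   method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(gamma_parent = config$gamma_parent,
                             gamma_child = config$gamma_child,
                             config = config)
  out
}

#' Generate per-trial choice logs for a synthetic cohort
#'
#' Runs every participant through the adjusting-amount task as a hyperbolic
#' agent with their latent `k` and `noise_temperature` (non-systematic
#' designees carry temperatures high enough that QC failure is likely).
#' Draws derive from `config$seed + 1` so cohort generation and task
#' administration use disjoint streams.
#'
#' @param cohort Output of [generate_cohort()].
#' @param task A [task_config()].
#' @param config The [synthetic_config()] used for the cohort (source of the
#'   seed).
#' @return List with `trials` (long per-trial choice log: `participant_id`,
#'   `member_role`, `delay_days`, `trial_index`, `immediate_amount`,
#'   `chose_immediate`) and `profiles` (long indifference-point table).
#' @export
generate_raw_choices <- function(cohort, task = task_config(),
                                 config = synthetic_config()) {
  stopifnot(is.data.frame(cohort),
            all(c("participant_id", "member_role", "k", "noise_temperature")
                %in% names(cohort)))
  set.seed(config$seed + 1L)
  n <- nrow(cohort)
  tpd <- task$trials_per_delay
  trial_blocks <- vector("list", length(task$delays))
  points <- matrix(NA_real_, n, length(task$delays))
  for (j in seq_along(task$delays)) {
    d <- task$delays[j]
    res <- staircase_batch(cohort$k, cohort$noise_temperature, d, task)
    points[, j] <- res$ip
    trial_blocks[[j]] <- data.frame(
      participant_id = rep(cohort$participant_id, each = tpd),
      member_role = rep(cohort$member_role, each = tpd),
      delay_days = d,
      trial_index = rep(seq_len(tpd), n),
      immediate_amount = as.vector(t(res$offers)),
      chose_immediate = as.integer(as.vector(t(res$choices))),
      stringsAsFactors = FALSE
    )
  }
  profiles <- data.frame(
    participant_id = rep(cohort$participant_id, times = length(task$delays)),
    member_role = rep(cohort$member_role, times = length(task$delays)),
    delay_days = rep(task$delays, each = n),
    indifference_point = as.vector(points),
    stringsAsFactors = FALSE
  )
  list(trials = do.call(rbind, trial_blocks), profiles = profiles)
}

#' Generate and score a cohort in one vectorised pass
#'
#' Convenience wrapper for simulation studies: draws a cohort
#' ([generate_cohort()]), administers the adjusting-amount task to every
#' member (same draws as [generate_raw_choices()] — the RNG stream is
#' `config$seed + 1`), and appends the ordinal AUC and the systematic-QC
#' flag without materialising per-trial logs.
#'
#' @inheritParams generate_raw_choices
#' @return The cohort data frame plus columns `auc_ord` and `systematic`
#'   (0/1); the `truth` attribute is carried over.
#' @export
simulate_scored_cohort <- function(config = synthetic_config(),
                                   task = task_config()) {
  cohort <- generate_cohort(config)
  set.seed(config$seed + 1L)
  pts <- matrix(NA_real_, nrow(cohort), length(task$delays))
  for (j in seq_along(task$delays)) {
    pts[, j] <- staircase_batch(cohort$k, cohort$noise_temperature,
                                task$delays[j], task)$ip
  }
  truth <- attr(cohort, "truth")
  cohort$auc_ord <- auc_ordinal_matrix(pts, task$llr_amount)
  cohort$systematic <- as.integer(qc_matrix(pts, task$llr_amount)$systematic)
  attr(cohort, "truth") <- truth
  cohort
}

#' Check interaction recovery against the generator's latent truth
#'
#' Fits the stacked mixed model of the ordinal AUC on the scarcity composite,
#' member and their interaction, and compares the interaction with the
#' generating effect difference. With the member dummy parent = 0 / child = 1
#' and outcome AUC (which falls as log-k rises), the interaction's expected
#' sign equals `sign(gamma_parent - gamma_child)`.
#'
#' @param scored Participant table holding `family_id`, `member_role`,
#'   `auc_ord` and the truth columns `scarcity_z`, `log_k` (e.g. pipeline
#'   output joined back to the cohort).
#' @param truth List with `gamma_parent` and `gamma_child` (e.g.
#'   `attr(cohort, "truth")`).
#' @param alpha Significance level for the interaction Wald test. Default
#'   0.05.
#' @return List with the interaction `estimate`, `se`, `p`, the generating
#'   `truth_diff = gamma_parent - gamma_child`, `sign_recovered`, and
#'   `significant`.
#' @export
recover_parameters <- function(scored, truth, alpha = 0.05) {
  if (!all(c("scarcity_z", "log_k") %in% names(scored))) {
    stop("latent truth columns (scarcity_z, log_k) are absent", call. = FALSE)
  }
  if (is.null(truth$gamma_parent) || is.null(truth$gamma_child)) {
    stop("truth must contain gamma_parent and gamma_child", call. = FALSE)
  }
  d <- scored[, c("family_id", "member_role", "auc_ord", "scarcity_z")]
  names(d)[names(d) == "member_role"] <- "member"
  mod <- fit_stacked_hlm(d, "scarcity_z")
  est <- mod$interaction$estimate
  diff <- truth$gamma_parent - truth$gamma_child
  list(estimate = est, se = mod$interaction$se, p = mod$interaction$p,
       truth_diff = diff,
       sign_recovered = if (diff == 0) NA else sign(est) == sign(diff),
       significant = mod$interaction$p < alpha,
       model = mod)
}
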