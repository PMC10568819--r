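# Synthetic dyad generator: determinism, marginal calibration, latent
# structure, round-trip with the task engine.

test_that("generation is reproducible from (config, seed) and configs validate", {
  cfg <- synthetic_config(n_families = 120, seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(synthetic_config(n_families = 120, seed = 34))
  expect_false(identical(a$income, c2$income))
  expect_error(synthetic_config(medicaid_rate = 1.4), "\\[0, 1\\]")
  expect_error(synthetic_config(n_families = 0), ">= 1")
  expect_error(synthetic_config(child_age_range = c(4, 12)), "within \\[6, 12\\]")
})

test_that("marginals converge to the configured moments (n = 10^4, 3 SE)", {
  cfg <- synthetic_config(n_families = 10000, seed = 77)
  co <- generate_cohort(cfg)
  par <- co[co$member_role == "parent", ]
  chi <- co[co$member_role == "child", ]
  n <- nrow(par)
  se <- function(s) 3 * s / sqrt(n)
  expect_lt(abs(mean(par$income) - cfg$income_mean), se(cfg$income_sd))
  expect_lt(abs(sd(par$income) - cfg$income_sd), 3000)
  expect_lt(abs(mean(par$education_years) - cfg$education_mean),
            se(cfg$education_sd))
  expect_lt(abs(mean(par$age) - cfg$parent_age_mean), se(cfg$parent_age_sd))
  # truncation to [6, 12] pulls the child age mean slightly below 9.4
  expect_gt(mean(chi$age), 9.1); expect_lt(mean(chi$age), 9.5)
  expect_true(all(chi$age >= 6 & chi$age <= 12))
  expect_lt(abs(mean(par$insurance == "Medicaid") - cfg$medicaid_rate), 0.03)
  expect_lt(abs(mean(par$sex == "male") - cfg$parent_male_rate), se(0.5))
  expect_lt(abs(mean(chi$sex == "male") - cfg$child_male_rate), se(0.5))
  # scarcity composite is standardized and drives parent log-k at gamma_parent
  expect_equal(mean(par$scarcity_z), 0, tolerance = 1e-8)
  expect_equal(sd(par$scarcity_z), 1, tolerance = 1e-8)
  slope <- coef(lm(par$log_k ~ par$scarcity_z))[2]
  expect_lt(abs(slope - cfg$gamma_parent), 3 * cfg$logk_sd / sqrt(n))
})

test_that("null cohort shows no income-discounting association", {
  cfg <- synthetic_config(n_families = 2000, gamma_parent = 0,
                          gamma_child = 0, nonsys_scarcity_slope = 0,
                          seed = 55)
  sc <- simulate_scored_cohort(cfg)
  par <- sc[sc$member_role == "parent", ]
  expect_lt(abs(cor(par$income, par$auc_ord)), 0.05)
})

test_that("latent k and scored AUC are strictly negatively associated for
           zero-noise agents", {
  cfg <- synthetic_config(n_families = 150, seed = 9,
                          temp_systematic = c(0, 0), temp_nonsystematic = c(0, 0))
  sc <- simulate_scored_cohort(cfg)
  ord <- order(sc$k)
  expect_true(all(diff(sc$auc_ord[ord]) <= 0))
  expect_lt(cor(sc$k, sc$auc_ord, method = "spearman"), -0.95)
  # deterministic agents produce monotone profiles: criterion 1 never fires,
  # so the only QC failures are flat profiles of near-zero discounters
  raw <- generate_raw_choices(co <- generate_cohort(cfg), task_config(), cfg)
  qc <- qc_report(raw$profiles)
  expect_true(all(qc$criterion1_violations == ""))
  expect_identical(qc$systematic == 0,
                   qc$criterion2_violation == 1)
})

test_that("choice logs round-trip through score_choice_log and match
           simulate_scored_cohort", {
  cfg <- synthetic_config(n_families = 25, seed = 14)
  co <- generate_cohort(cfg)
  raw <- generate_raw_choices(co, task_config(), cfg)
  sc <- simulate_scored_cohort(cfg)
  for (id in sample(co$participant_id, 8)) {
    sub <- raw$trials[raw$trials$participant_id == id, ]
    prof <- score_choice_log(sub, task_config())
    long <- raw$profiles[raw$profiles$participant_id == id, ]
    long <- long[order(long$delay_days), ]
    expect_identical(prof$points, long$indifference_point)
    expect_equal(auc_ordinal(prof)$auc_ord,
                 sc$auc_ord[sc$participant_id == id])
  }
})

test_that("non-systematic designation: children exceed parents and QC pass
           rates land near the intended split", {
  cfg <- synthetic_config(n_families = 2000, seed = 70)
  sc <- simulate_scored_cohort(cfg)
  rates <- tapply(sc$systematic, sc$member_role, mean)
  expect_gt(rates[["parent"]], rates[["child"]])
  expect_gt(rates[["parent"]], 0.70); expect_lt(rates[["parent"]], 0.90)
  expect_gt(rates[["child"]], 0.50); expect_lt(rates[["child"]], 0.75)
  # designated high-noise responders mostly fail QC
  expect_lt(mean(sc$systematic[sc$designated_nonsystematic == 1]), 0.3)
})

test_that("recover_parameters reports sign and significance; demands truth", {
  cfg <- synthetic_config(n_families = 2000, gamma_parent = -0.3,
                          gamma_child = 0, seed = 101)
  sc <- simulate_scored_cohort(cfg)
  rec <- recover_parameters(sc[sc$systematic == 1, ], attr(sc, "truth"))
  expect_true(rec$sign_recovered)
  expect_equal(rec$truth_diff, -0.3)
  no_truth <- sc[, setdiff(names(sc), "scarcity_z")]
  expect_error(recover_parameters(no_truth, attr(sc, "truth")), "truth columns")
  expect_error(recover_parameters(sc, list()), "gamma_parent")
})
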