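# Correlation screens, stacked mixed model, BH-FDR.

test_that("pearson_r: worked values, point-biserial identity, errors", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), ">= 3")
  # point-biserial: Pearson on a 0/1 dummy equals the dedicated formula
  set.seed(31)
  g <- rbinom(200, 1, 0.4)
  y <- rnorm(200) + 0.5 * g
  r <- pearson_r(g, y)$r
  n1 <- sum(g); n0 <- sum(1 - g); n <- length(g)
  rpb <- (mean(y[g == 1]) - mean(y[g == 0])) /
    (sd(y) * sqrt((n - 1) / n)) * sqrt(n1 * n0 / n^2)
  expect_equal(r, rpb, tolerance = 1e-12)
  # p-value matches cor.test
  ct <- cor.test(g, y)
  expect_equal(pearson_r(g, y)$p, ct$p.value, tolerance = 1e-10)
})

test_that("bh_fdr: step-up examples, monotonicity, subset property,
           agreement with p.adjust", {
  expect_identical(bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.1),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(0.9, 6)), rep(FALSE, 6))
  expect_identical(bh_fdr(0.05, q = 0.1), TRUE)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:50) {
    p <- runif(40)^2
    f10 <- bh_fdr(p, 0.10)
    # oracle: flags iff BH-adjusted p-value <= q
    expect_identical(f10, p.adjust(p, "BH") <= 0.10)
    # q = 0.05 flags are a subset of q = 0.10 flags
    expect_true(all(bh_fdr(p, 0.05) <= f10))
    # lowering one p-value never unflags anything
    j <- sample(40, 1)
    p2 <- p; p2[j] <- p2[j] / 2
    expect_true(all(f10 <= bh_fdr(p2, 0.10)))
  }
  expect_identical(bh_fdr(c(0.01, NA, 0.5)), c(TRUE, NA, FALSE))
})

test_that("stacked model recovers null and known slope differences", {
  set.seed(41)
  null_rows <- make_stacked(500, b_parent = 0.1, b_child = 0.1)
  m0 <- fit_stacked_hlm(null_rows, "x")
  expect_lt(abs(m0$interaction$estimate), 2 * m0$interaction$se)
  eff_rows <- make_stacked(500, b_parent = -0.2, b_child = 0)
  m1 <- fit_stacked_hlm(eff_rows, "x")
  # member dummy is child = 1, so the interaction is child minus parent slope
  expect_lt(abs(m1$interaction$estimate - 0.2), 2 * m1$interaction$se)
  expect_lt(m1$interaction$p, 0.05)
  expect_true(all(m1$coefficients$p >= 0 & m1$coefficients$p <= 1))
  expect_equal(m1$n_families, 500)
})

test_that("stacked model degrades to OLS when between-family variance is zero", {
  set.seed(5150)
  rows <- make_stacked(300, b_parent = 0.1, b_child = 0.1, tau = 0)
  m <- fit_stacked_hlm(rows, "x")
  expect_true(m$singular)  # variance estimate on the boundary
  ols <- fit_stacked_hlm(rows, "x", random_intercept = FALSE)
  expect_equal(m$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("stacked model input contracts", {
  rows <- make_stacked(50)
  expect_error(fit_stacked_hlm(rows[rows$member == "parent", ], "x"),
               "both parent and child")
  expect_error(fit_stacked_hlm(rows[rows$family_id == rows$family_id[1], ], "x"),
               ">= 2 families")
  rows$cst <- 1
  expect_error(fit_stacked_hlm(rows, "cst"), "does not vary")
  dup <- rbind(rows, rows[1, ])
  expect_error(fit_stacked_hlm(dup, "x"), "one parent and one child")
  # covariate variant returns the same interaction term label
  mc <- fit_stacked_hlm(make_stacked(200, b_parent = -0.2), "x",
                        with_covariates = TRUE)
  expect_match(mc$interaction$term, "member_child")
  expect_equal(nrow(mc$coefficients), 7)  # int, x, member, 3 covs, interaction
})

test_that("results battery: parent-only effect surfaces; FDR across 54 tests", {
  run <- run_pipeline(list(n_families = 600, gamma_parent = 1.0,
                           gamma_child = 0),
                      mode = "synthetic", out_dir = tempfile(), seed = 88)
  res <- run$results
  expect_equal(res$m, 54L)  # 9 predictors x 2 samples x (2 cors + 1 interaction)
  inc_par <- res$correlations[res$correlations$predictor == "income" &
                                res$correlations$role == "parent", ]
  inc_chi <- res$correlations[res$correlations$predictor == "income" &
                                res$correlations$role == "child", ]
  expect_true(all(inc_par$r > 0))
  expect_true(all(abs(inc_chi$r) < abs(inc_par$r)))
  inc_int <- res$interactions[res$interactions$predictor == "income", ]
  expect_true(any(inc_int$fdr_flag))
})

test_that("empty predictor list yields empty tables", {
  out <- build_results_tables(data.frame(family_id = "f", member_role = "parent",
                                         auc_ord = 0.5, systematic = 1),
                              character(0))
  expect_equal(nrow(out$correlations), 0)
  expect_equal(nrow(out$interactions), 0)
  expect_equal(out$m, 0L)
})
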