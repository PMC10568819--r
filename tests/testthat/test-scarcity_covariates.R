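# Income tertile-style split and covariate dummy coding.

test_that("income categories: median +/- one SD band, boundaries inside", {
  x <- c(50e3, 80e3, 110e3, 70e3, 90e3, 75e3, 85e3)
  med <- median(x); s <- sd(x)
  cat <- categorize_income(x)
  expect_identical(as.character(cat),
                   ifelse(x < med - s, "low",
                          ifelse(x > med + s, "high", "median")))
  # every input gets exactly one category
  expect_false(anyNA(cat))
  # boundary value is 'median' (strict inequalities)
  y <- c(0, 100, 200)  # median 100, sd 100; 0 == median - sd
  expect_identical(as.character(categorize_income(y))[1], "median")
})

test_that("income categories are location/scale equivariant and handle
           degenerate spread", {
  set.seed(12)
  x <- rlnorm(200, 11, 0.5)
  base <- categorize_income(x)
  expect_identical(categorize_income(x + 12345), base)
  expect_identical(categorize_income(x * 3.2), base)
  expect_warning(all_med <- categorize_income(rep(5e4, 10)), "zero income spread")
  expect_true(all(all_med == "median"))
  expect_error(categorize_income(numeric(0)), "at least two")
  expect_true(is.na(categorize_income(c(1e5, NA, 9e4, 8e4))[2]))
})

test_that("covariate coding: Medicaid dichotomy, minority rule, sex codes", {
  out <- encode_covariates("White", "not Hispanic/Latino", "Private", "male")
  expect_identical(unlist(out), c(medicaid = 0L, minority = 0L, sex_code = 1L))
  out <- encode_covariates("Black", "not Hispanic/Latino", "Medicaid", "female")
  expect_identical(unlist(out), c(medicaid = 1L, minority = 1L, sex_code = 2L))
  # any non-Medicaid insurance codes 0, including single-payer systems
  out <- encode_covariates("White", "not Hispanic/Latino",
                           "Universal Health Care (Canada)", "female")
  expect_identical(out$medicaid, 0L)
  expect_identical(encode_covariates("White", "Hispanic/Latino", "Medicare",
                                     "male")$minority, 1L)
  # refused race with no Hispanic/Latino ethnicity is indeterminate
  expect_true(is.na(encode_covariates("Refused", "not Hispanic/Latino",
                                      "Private", "male")$minority))
  expect_identical(encode_covariates("Refused", "Hispanic/Latino",
                                     "Private", "male")$minority, 1L)
})

test_that("unrecognised categories raise a validation error naming the vocabulary", {
  expect_error(encode_covariates("Martian", "not Hispanic/Latino", "Private",
                                 "male"), "allowed: Asian")
  expect_error(encode_covariates("White", "maybe", "Private", "male"),
               "ethnicity")
  expect_error(encode_covariates("White", "not Hispanic/Latino", "HMO",
                                 "male"), "insurance")
  # custom minority predicate is honoured
  strict <- function(race, ethnicity) as.integer(race != "White" &
                                                   ethnicity == "Hispanic/Latino")
  expect_identical(encode_covariates("Black", "not Hispanic/Latino", "Private",
                                     "male", minority_rule = strict)$minority, 0L)
})
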