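# Coding of economic-scarcity indicators and demographic covariates.

# Closed category vocabularies for the demographics questionnaire.
RACE_LEVELS <- c("Asian", "Black", "Multiracial", "Native", "Other",
                 "Refused", "White")
ETHNICITY_LEVELS <- c("Hispanic/Latino", "not Hispanic/Latino")
INSURANCE_LEVELS <- c("Private", "Medicare", "Medicaid", "Veterans",
                      "Universal Health Care (Canada)", "Supplementary",
                      "Other")

#' Categorise household incomes into low / median / high
#'
#' Splits a vector of incomes about its own median using the sample standard
#' deviation as the band half-width: low iff `income < median(x) - sd(x)`,
#' high iff `income > median(x) + sd(x)`, and median otherwise (boundary
#' values fall in the median band). Centre and spread are computed from the
#' supplied vector itself (missing values ignored for the thresholds and
#' propagated in the output).
#'
#' @param incomes Numeric vector of annual household incomes (>= 2 finite
#'   values required).
#' @return Factor with levels `low`, `median`, `high`, same length as
#'   `incomes`.
#' @examples
#' table(categorize_income(c(20e3, 50e3, 80e3, 81e3, 82e3, 150e3)))
#' @export
categorize_income <- function(incomes) {
  x <- incomes[is.finite(incomes)]
  if (length(x) < 2L) {
    stop("categorize_income needs at least two finite incomes", call. = FALSE)
  }
  ctr <- stats::median(x)
  spread <- stats::sd(x)
  if (spread == 0) {
    warning("zero income spread; all incomes categorised as 'median'",
            call. = FALSE)
  }
  out <- rep(NA_character_, length(incomes))
  ok <- is.finite(incomes)
  out[ok] <- ifelse(incomes[ok] < ctr - spread, "low",
                    ifelse(incomes[ok] > ctr + spread, "high", "median"))
  factor(out, levels = c("low", "median", "high"))
}

#' Code demographic covariates for analysis
#'
#' Produces the dummy/numeric codings the analysis consumes:
#' * `medicaid`: 1 iff insurance type is `"Medicaid"`, else 0 (all other
#'   insurance categories, including Medicare, code 0).
#' * `minority`: 1 iff race is not `"White"` OR ethnicity is
#'   `"Hispanic/Latino"`; `"Refused"` race propagates as `NA`.
#' * `sex_code`: male = 1, female = 2.
#'
#' Unrecognised race/ethnicity/insurance/sex values raise a validation error
#' listing the allowed vocabulary. Vectorised over rows.
#'
#' @param race,ethnicity,insurance,sex Character vectors (recycled to a
#'   common length). Allowed race values: Asian, Black, Multiracial, Native,
#'   Other, Refused, White; ethnicity: Hispanic/Latino, not Hispanic/Latino;
#'   insurance: Private, Medicare, Medicaid, Veterans, Universal Health Care
#'   (Canada), Supplementary, Other; sex: male, female.
#' @param minority_rule Function `(race, ethnicity) -> 0/1/NA` implementing
#'   the minority indicator; the default is the conventional reading above.
#' @return Data frame with columns `medicaid`, `minority`, `sex_code`.
#' @examples
#' encode_covariates("White", "not Hispanic/Latino", "Private", "male")
#' @export
encode_covariates <- function(race, ethnicity, insurance, sex,
                              minority_rule = default_minority_rule) {
  n <- max(length(race), length(ethnicity), length(insurance), length(sex))
  race <- rep_len(race, n); ethnicity <- rep_len(ethnicity, n)
  insurance <- rep_len(insurance, n); sex <- rep_len(sex, n)
  check_vocab(race, RACE_LEVELS, "race")
  check_vocab(ethnicity, ETHNICITY_LEVELS, "ethnicity")
  check_vocab(insurance, INSURANCE_LEVELS, "insurance")
  check_vocab(sex, c("male", "female"), "sex")
  data.frame(
    medicaid = as.integer(insurance == "Medicaid"),
    minority = minority_rule(race, ethnicity),
    sex_code = ifelse(sex == "male", 1L, 2L)
  )
}

#' @rdname encode_covariates
#' @export
default_minority_rule <- function(race, ethnicity) {
  out <- as.integer(race != "White" | ethnicity == "Hispanic/Latino")
  out[race == "Refused" & ethnicity != "Hispanic/Latino"] <- NA_integer_
  out
}

check_vocab <- function(x, allowed, what) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad)) {
    stop(sprintf("unrecognised %s value(s) %s; allowed: %s", what,
                 paste(sQuote(bad), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
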