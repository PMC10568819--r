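# Anthropometric scoring: BMI, percent over reference-median BMI, and LMS
# z-scores against a user-supplied growth reference table.

#' Body mass index
#'
#' @param weight_kg Weight in kilograms, > 0. Vectorised.
#' @param height_cm Height in centimetres, > 0. Vectorised.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(80, 200)  # 20
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive and finite", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' Percent over the reference-median BMI
#'
#' `100 * (bmi - median_bmi) / median_bmi`: 0 at the reference median,
#' negative below it. For adults the age-20 reference median for the
#' participant's sex is used as a proxy (see [lookup_reference()]).
#'
#' @param bmi Observed BMI. Vectorised.
#' @param median_bmi Age/sex reference median BMI, > 0. Vectorised.
#' @return Percent over (or under, negative) the reference median.
#' @export
percent_over_median_bmi <- function(bmi, median_bmi) {
  if (any(!is.finite(median_bmi)) || any(median_bmi <= 0)) {
    stop("median_bmi must be positive and finite", call. = FALSE)
  }
  100 * (bmi - median_bmi) / median_bmi
}

#' Look up an LMS reference row
#'
#' Retrieves the L (Box-Cox power), M (median) and S (coefficient of
#' variation) parameters for a participant from a growth reference table.
#' Children are matched to the nearest tabulated age in months; adults
#' (`role = "parent"`) always use the terminal age-20 row (240 months) for
#' their sex, regardless of actual age, as the adult proxy.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_months Age in months (used only for children).
#' @param role `"parent"` or `"child"`.
#' @param table Reference data frame with columns `sex`, `age_months`, `L`,
#'   `M`, `S`, such as [synthetic_lms_reference()].
#' @param adult_age_months Row used for adults. Default 240.
#' @param max_gap_months A child lookup fails if the nearest tabulated age is
#'   farther than this. Default 6.
#' @return One-row data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @export
lookup_reference <- function(sex, age_months, role = c("child", "parent"),
                             table, adult_age_months = 240,
                             max_gap_months = 6) {
  role <- match.arg(role)
  stopifnot(is.data.frame(table),
            all(c("sex", "age_months", "L", "M", "S") %in% names(table)))
  if (!sex %in% table$sex) {
    stop(sprintf("reference table has no rows for sex '%s'", sex),
         call. = FALSE)
  }
  sub <- table[table$sex == sex, , drop = FALSE]
  target <- if (role == "parent") adult_age_months else age_months
  gap <- abs(sub$age_months - target)
  i <- which.min(gap)
  if (gap[i] > max_gap_months) {
    stop(sprintf(
      "reference table for sex '%s' does not cover age %s months (nearest row: %s)",
      sex, format(target), format(sub$age_months[i])), call. = FALSE)
  }
  sub[i, c("sex", "age_months", "L", "M", "S"), drop = FALSE]
}

#' LMS z-score
#'
#' Standard LMS (Box-Cox) transform: `((bmi / M)^L - 1) / (L * S)` for
#' `L != 0`, and the limiting form `log(bmi / M) / S` for `L = 0`. `bmi = M`
#' maps to z = 0.
#'
#' @param bmi Observed BMI, > 0. Vectorised.
#' @param L,M,S LMS parameters (scalars or vectors recycled against `bmi`);
#'   `M > 0`, `S > 0`. A one-row data frame from [lookup_reference()] may be
#'   passed as `L`.
#' @return z-score(s).
#' @examples
#' lms_z(22, L = 1, M = 20, S = 0.1)  # 1
#' @export
lms_z <- function(bmi, L, M = NULL, S = NULL) {
  if (is.data.frame(L)) {
    row <- L
    L <- row$L; M <- row$M; S <- row$S
  }
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be positive and finite", call. = FALSE)
  }
  stopifnot(all(M > 0), all(S > 0))
  n <- max(length(bmi), length(L), length(M), length(S))
  bmi <- rep_len(bmi, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  # log branch also used for |L| below 1e-6: the power form loses relative
  # accuracy ~ L (log(bmi/M))^2 / 2 there, and the series limit is exact
  ifelse(abs(L) < 1e-6, log(bmi / M) / S, ((bmi / M)^L - 1) / (L * S))
}

#' Synthetic LMS growth reference table
#'
#' A smooth, synthetic stand-in for a pediatric BMI-for-age growth reference
#' (it is NOT real growth-chart data): for each sex, rows every month from 24
#' to 240 months with a logistic-shaped median rising from ~15.5 to ~22-23
#' kg/m^2, a mild negative skew power L, and S around 0.10-0.13. Shaped like
#' the real thing so that lookup and z-scoring code paths are fully
#' exercised; do not use for clinical scoring.
#'
#' @return Data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @export
synthetic_lms_reference <- function() {
  age <- 24:240
  build <- function(sex, m_adult) {
    frac <- (age - 24) / (240 - 24)
    M <- 15.5 + (m_adult - 15.5) * stats::plogis(6 * (frac - 0.55)) /
      stats::plogis(6 * 0.45)
    data.frame(sex = sex, age_months = age,
               L = -2 + 0.8 * frac,
               M = M,
               S = 0.10 + 0.03 * frac,
               stringsAsFactors = FALSE)
  }
  rbind(build("male", 23.0), build("female", 21.7))
}

#' Anthropometric scores for a cohort table
#'
#' @param data Data frame with columns `participant_id`, `member_role`
#'   (`"parent"`/`"child"`), `sex` (`"male"`/`"female"`), `age_months`,
#'   `weight_kg`, `height_cm`.
#' @param reference LMS reference table; default [synthetic_lms_reference()].
#' @return `data` plus columns `bmi`, `pct_over_median`, `zbmi`.
#' @export
score_anthropometrics <- function(data, reference = synthetic_lms_reference()) {
  need <- c("participant_id", "member_role", "sex", "age_months",
            "weight_kg", "height_cm")
  stopifnot(all(need %in% names(data)))
  bmi <- compute_bmi(data$weight_kg, data$height_cm)
  rows <- lapply(seq_len(nrow(data)), function(i) {
    lookup_reference(data$sex[i], data$age_months[i],
                     role = data$member_role[i], table = reference)
  })
  ref <- do.call(rbind, rows)
  data$bmi <- bmi
  data$pct_over_median <- percent_over_median_bmi(bmi, ref$M)
  data$zbmi <- lms_z(bmi, ref$L, ref$M, ref$S)
  data
}
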