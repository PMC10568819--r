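# Discounting summary measures: ordinal AUC (primary) and the traditional
# delay-weighted AUC (secondary, for comparison only).

#' Ordinal area under the discounting curve
#'
#' Normalises indifference points by the LLR and integrates them by the
#' trapezoid rule over equally spaced ordinal delay ranks mapped to
#' `[0, 1]` — rank i at `(i - 1) / (n - 1)`. Because the x-axis uses ranks,
#' the measure is invariant to the numeric delay values given their order and
#' does not up-weight long delays the way the traditional AUC does. It ranges
#' from 0 (maximum discounting: all points at 0) to 1 (no discounting: all
#' points at the LLR).
#'
#' With `include_origin = TRUE` an implicit point (delay rank 0, value 1) is
#' prepended and rank i maps to `i / n`; under that convention the attainable
#' minimum is `1 / (2 n)` rather than 0, which is why the origin is excluded
#' by default.
#'
#' @param profile A [dd_profile()] (complete; LLR > 0).
#' @param include_origin Prepend the (0, 1) origin point. Default `FALSE`.
#' @return A list of class `dd_auc` with `participant_id`, `auc_ord`,
#'   `n_delays`, `include_origin`.
#' @examples
#' p <- dd_profile("x", c(1, 7, 30, 182, 365), c(90, 70, 50, 30, 10), 100)
#' auc_ordinal(p)$auc_ord  # 0.5
#' @export
auc_ordinal <- function(profile, include_origin = FALSE) {
  stopifnot(inherits(profile, "dd_profile"))
  y <- profile$points / profile$llr_amount
  n <- length(y)
  if (n < 2L || anyNA(y)) {
    stop("auc_ordinal needs a complete profile over >= 2 delays", call. = FALSE)
  }
  if (include_origin) {
    x <- (0:n) / n
    y <- c(1, y)
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
  }
  auc <- sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
  structure(
    list(participant_id = profile$participant_id, auc_ord = auc,
         n_delays = n, include_origin = include_origin),
    class = "dd_auc"
  )
}

# Vectorised ordinal AUC over a points matrix (rows = participants, columns =
# delays in ascending order), origin excluded.
auc_ordinal_matrix <- function(points, llr) {
  n <- ncol(points)
  y <- points / llr
  w <- rep(1 / (n - 1), n)
  w[c(1L, n)] <- w[c(1L, n)] / 2
  as.numeric(y %*% w)
}

#' Traditional delay-weighted area under the discounting curve
#'
#' The classical AUC with the x-axis given by the actual delays normalised by
#' the maximum delay. Long delays dominate the integral; provided only for
#' comparison against [auc_ordinal()].
#'
#' @inheritParams auc_ordinal
#' @return The traditional AUC, a number in `[0, 1]`.
#' @export
auc_traditional <- function(profile) {
  stopifnot(inherits(profile, "dd_profile"))
  y <- profile$points / profile$llr_amount
  x <- profile$delays / max(profile$delays)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2) / (x[length(x)] - x[1L])
}
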