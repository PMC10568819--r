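# Systematic-responding quality control for indifference-point profiles.

#' Classify a profile as systematic or non-systematic
#'
#' Applies the standard two-criterion consistency check to an
#' indifference-point profile:
#'
#' * Criterion 1: any indifference point exceeding its predecessor by
#'   strictly more than `c1_frac` of the LLR (default 20%) is a violation,
#'   recorded per adjacent delay pair.
#' * Criterion 2: the last indifference point must be below the first by at
#'   least `c2_frac` of the LLR (default 10%); a first-minus-last difference
#'   strictly below that bound is a violation.
#'
#' A profile is systematic iff no enabled criterion is violated. Both
#' criteria can be toggled to reproduce single-criterion variants.
#'
#' @param profile A [dd_profile()] over at least two delays.
#' @param c1_frac Criterion-1 bound as a fraction of the LLR. Default 0.20.
#' @param c2_frac Criterion-2 bound as a fraction of the LLR. Default 0.10.
#' @param use_c1,use_c2 Enable/disable each criterion. Both `TRUE` by default.
#' @return A list of class `dd_qc` with `participant_id`, `systematic`,
#'   `criterion1_violations` (integer indices j such that the rise from point
#'   j-1 to point j violates criterion 1; empty when none), and
#'   `criterion2_violation` (logical).
#' @examples
#' p <- dd_profile("x", c(1, 7, 30, 182, 365), c(90, 70, 50, 30, 10), 100)
#' classify_systematic(p)$systematic  # TRUE
#' @export
classify_systematic <- function(profile, c1_frac = 0.20, c2_frac = 0.10,
                                use_c1 = TRUE, use_c2 = TRUE) {
  stopifnot(inherits(profile, "dd_profile"))
  y <- profile$points
  if (length(y) < 2L || anyNA(y)) {
    stop("classify_systematic needs a complete profile over >= 2 delays",
         call. = FALSE)
  }
  llr <- profile$llr_amount
  rises <- diff(y)
  c1_idx <- which(rises > c1_frac * llr) + 1L
  c2_bad <- (y[1L] - y[length(y)]) < c2_frac * llr
  systematic <- (!use_c1 || length(c1_idx) == 0L) && (!use_c2 || !c2_bad)
  structure(
    list(participant_id = profile$participant_id,
         systematic = systematic,
         criterion1_violations = c1_idx,
         criterion2_violation = c2_bad),
    class = "dd_qc"
  )
}

# Vectorised QC over a points matrix (rows = participants, cols = delays in
# order). Returns a data.frame; used by the pipeline for whole-cohort runs.
qc_matrix <- function(points, llr, c1_frac = 0.20, c2_frac = 0.10) {
  stopifnot(is.matrix(points), ncol(points) >= 2L)
  rises <- points[, -1L, drop = FALSE] - points[, -ncol(points), drop = FALSE]
  c1 <- rowSums(rises > c1_frac * llr) > 0
  c2 <- (points[, 1L] - points[, ncol(points)]) < c2_frac * llr
  data.frame(criterion1_violation = c1, criterion2_violation = c2,
             systematic = !c1 & !c2)
}

#' QC report for a long-format profile table
#'
#' @param profiles Data frame with columns `participant_id`, `delay_days`,
#'   `indifference_point`, and optionally `member_role` (carried through).
#' @param llr_amount Larger-later reward the points were measured against.
#' @inheritParams classify_systematic
#' @return One row per participant: `participant_id`, `member_role` (if
#'   present), `systematic` (0/1), `criterion1_violations` (semicolon-joined
#'   adjacent-pair labels such as `"2-3"`), `criterion2_violation` (0/1).
#' @export
qc_report <- function(profiles, llr_amount = 100,
                      c1_frac = 0.20, c2_frac = 0.10) {
  stopifnot(all(c("participant_id", "delay_days", "indifference_point")
                %in% names(profiles)))
  split_idx <- split(seq_len(nrow(profiles)), profiles$participant_id)
  rows <- lapply(split_idx, function(i) {
    sub <- profiles[i, , drop = FALSE]
    sub <- sub[order(sub$delay_days), , drop = FALSE]
    pr <- dd_profile(sub$participant_id[1L], sub$delay_days,
                     sub$indifference_point, llr_amount)
    qc <- classify_systematic(pr, c1_frac, c2_frac)
    out <- data.frame(
      participant_id = qc$participant_id,
      systematic = as.integer(qc$systematic),
      criterion1_violations = paste(
        sprintf("%d-%d", qc$criterion1_violations - 1L,
                qc$criterion1_violations),
        collapse = ";"),
      criterion2_violation = as.integer(qc$criterion2_violation),
      stringsAsFactors = FALSE
    )
    if ("member_role" %in% names(sub)) out$member_role <- sub$member_role[1L]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
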