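# Correlation screens, stacked parent-child mixed models with interaction,
# and Benjamini-Hochberg FDR control.

#' Pearson product-moment correlation with two-sided p-value
#'
#' Standard Pearson r and the t-based two-sided p-value. When one vector is a
#' 0/1 dummy this is the point-biserial correlation. Pairs with missing
#' values are dropped listwise.
#'
#' @param x,y Numeric vectors of equal length; after listwise deletion at
#'   least 3 pairs and nonzero variance in both are required.
#' @return List with `r`, `p`, `n`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson_r needs >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) == 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Fit the stacked parent-child model with a predictor-by-member interaction
#'
#' Parent and child rows are stacked (one row per family member) and the
#' discounting outcome is regressed on the predictor, a member dummy
#' (parent = 0, child = 1), and their interaction, with a family-level random
#' intercept for the within-family nesting (REML via \pkg{lme4}). The Wald
#' z p-value on the interaction term tests whether the predictor-outcome
#' relationship differs between parents and children. The covariate variant
#' adds age, sex code (male 1 / female 2) and minority main effects.
#'
#' With `random_intercept = FALSE` the same fixed effects are fit by ordinary
#' least squares (sensitivity path). When the estimated between-family
#' variance is zero the mixed fit degrades to the OLS coefficients.
#'
#' @param rows Data frame with columns `family_id`, `member`
#'   (`"parent"`/`"child"`), `auc_ord`, the predictor column, and — for the
#'   covariate variant — `age`, `sex_code`, `minority`. At most one parent
#'   and one child row per family.
#' @param predictor Name of the predictor column.
#' @param with_covariates Add age, sex and minority main effects.
#' @param random_intercept Include the family random intercept. Default
#'   `TRUE`.
#' @return Object of class `dd_model`: list with `coefficients` (data frame
#'   with `term`, `estimate`, `se`, `z`, `p`), `interaction` (the
#'   predictor-by-member row), `n_families`, `n_rows`, `converged`,
#'   `singular`, `predictor`, `with_covariates`.
#' @export
fit_stacked_hlm <- function(rows, predictor, with_covariates = FALSE,
                            random_intercept = TRUE) {
  stopifnot(is.data.frame(rows),
            all(c("family_id", "member", "auc_ord", predictor) %in% names(rows)))
  if (!all(rows$member %in% c("parent", "child"))) {
    stop("`member` must be 'parent' or 'child'", call. = FALSE)
  }
  dup <- duplicated(rows[, c("family_id", "member")])
  if (any(dup)) {
    stop("at most one parent and one child row per family", call. = FALSE)
  }
  covs <- if (with_covariates) c("age", "sex_code", "minority") else character()
  use <- c("family_id", "member", "auc_ord", predictor, covs)
  stopifnot(all(use %in% names(rows)))
  d <- rows[stats::complete.cases(rows[, use]), use, drop = FALSE]
  d$member_child <- as.integer(d$member == "child")
  if (length(unique(d$member_child)) < 2L) {
    stop("stacked model needs both parent and child rows", call. = FALSE)
  }
  if (length(unique(d$family_id)) < 2L) {
    stop("stacked model needs >= 2 families", call. = FALSE)
  }
  if (stats::sd(d[[predictor]]) == 0) {
    stop("predictor does not vary", call. = FALSE)
  }
  rhs <- paste(c(sprintf("`%s` * member_child", predictor),
                 sprintf("`%s`", covs)), collapse = " + ")
  converged <- TRUE; singular <- FALSE
  if (random_intercept) {
    fml <- stats::as.formula(
      paste("auc_ord ~", rhs, "+ (1 | family_id)"))
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        if (grepl("rank deficient", conditionMessage(m))) {
          invokeRestart("muffleMessage")
        }
      })
    singular <- lme4::isSingular(fit)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  } else {
    fml <- stats::as.formula(paste("auc_ord ~", rhs))
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  }
  z <- est / se
  coef_tab <- data.frame(term = rownames(sm), estimate = unname(est),
                         se = unname(se), z = unname(z),
                         p = unname(2 * stats::pnorm(-abs(z))),
                         stringsAsFactors = FALSE)
  int_term <- grep(":member_child$", coef_tab$term, value = TRUE)
  interaction <- if (length(int_term) == 1L) {
    coef_tab[coef_tab$term == int_term, , drop = FALSE]
  } else {
    # rank-deficient designs (tiny samples, collinear predictors) can drop
    # the interaction column; surface an NA row rather than a 0-row frame
    data.frame(term = "dropped", estimate = NA_real_, se = NA_real_,
               z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  }
  structure(
    list(coefficients = coef_tab,
         interaction = interaction,
         n_families = length(unique(d$family_id)), n_rows = nrow(d),
         converged = converged, singular = singular,
         predictor = predictor, with_covariates = with_covariates,
         random_intercept = random_intercept, fit = fit),
    class = "dd_model"
  )
}

#' @export
print.dd_model <- function(x, ...) {
  cat(sprintf("<dd_model> auc_ord ~ %s * member%s | %d rows, %d families%s\n",
              x$predictor,
              if (x$with_covariates) " + age + sex + minority" else "",
              x$n_rows, x$n_families,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg FDR flags
#'
#' Standard step-up procedure at rate `q`: sort the p-values ascending, find
#' the largest rank i with `p_(i) <= i q / m`, and flag everything with rank
#' at most i. `NA` p-values are never flagged and do not count toward m.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param q Target false-discovery rate. Default 0.10.
#' @return Logical vector of flags, aligned with `pvals`.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.1)
#' @export
bh_fdr <- function(pvals, q = 0.10) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  out <- rep(NA, length(pvals))
  out[ok] <- FALSE
  if (m > 0L) {
    ord <- order(p)
    below <- p[ord] <= seq_len(m) * q / m
    if (any(below)) {
      k <- max(which(below))
      flag <- logical(m)
      flag[ord[seq_len(k)]] <- TRUE
      out[ok] <- flag
    }
  }
  out
}

#' Correlation and interaction battery over a coded cohort
#'
#' For each predictor, within each sample (`all` = every scored participant;
#' `systematic` = participants whose own profile passed QC) computes the
#' parent and child zero-order Pearson/point-biserial correlations of the
#' predictor with the ordinal AUC, and the interaction p-value from the
#' stacked mixed model ([fit_stacked_hlm()]). Benjamini-Hochberg flags are
#' then assigned across the whole battery (2 correlations + 1 interaction
#' per predictor per sample; 9 predictors x 2 samples = 54 tests with the
#' default roster).
#'
#' @param dataset One row per participant with columns `family_id`,
#'   `member_role`, `auc_ord`, `systematic` (0/1), the predictor columns,
#'   and `age`, `sex_code`, `minority` if `with_covariates = TRUE`.
#' @param predictors Character vector of predictor column names.
#' @param q FDR rate across the battery. Default 0.10.
#' @param with_covariates Use the covariate-adjusted stacked model.
#' @return List with `correlations` (predictor x sample x role r/p table),
#'   `interactions` (predictor x sample interaction estimate/p), `m` (number
#'   of tests the FDR controlled), and `models` (the fitted `dd_model`s).
#' @export
build_results_tables <- function(dataset, predictors, q = 0.10,
                                 with_covariates = FALSE) {
  stopifnot(all(c("family_id", "member_role", "auc_ord", "systematic")
                %in% names(dataset)))
  if (length(predictors) == 0L) {
    return(list(correlations = data.frame(), interactions = data.frame(),
                m = 0L, models = list()))
  }
  stopifnot(all(predictors %in% names(dataset)))
  samples <- list(
    all = dataset,
    systematic = dataset[dataset$systematic == 1, , drop = FALSE]
  )
  cor_rows <- list(); int_rows <- list(); models <- list()
  for (s in names(samples)) {
    d <- samples[[s]]
    for (pred in predictors) {
      for (role in c("parent", "child")) {
        sub <- d[d$member_role == role, , drop = FALSE]
        res <- tryCatch(pearson_r(sub[[pred]], sub$auc_ord),
                        error = function(e) list(r = NA_real_, p = NA_real_,
                                                 n = sum(stats::complete.cases(
                                                   sub[, c(pred, "auc_ord")]))))
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          sample = s, predictor = pred, role = role,
          r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
      }
      stacked <- d[, c("family_id", "member_role", "auc_ord", pred,
                       intersect(c("age", "sex_code", "minority"), names(d))),
                   drop = FALSE]
      names(stacked)[names(stacked) == "member_role"] <- "member"
      mod <- tryCatch(
        fit_stacked_hlm(stacked, pred, with_covariates = with_covariates),
        error = function(e) NULL)
      models[[paste(s, pred, sep = ".")]] <- mod
      int_rows[[length(int_rows) + 1L]] <- data.frame(
        sample = s, predictor = pred,
        estimate = if (is.null(mod)) NA_real_ else mod$interaction$estimate,
        se = if (is.null(mod)) NA_real_ else mod$interaction$se,
        p = if (is.null(mod)) NA_real_ else mod$interaction$p,
        n_families = if (is.null(mod)) NA_integer_ else mod$n_families,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cor_rows)
  interactions <- do.call(rbind, int_rows)
  all_p <- c(correlations$p, interactions$p)
  flags <- bh_fdr(all_p, q = q)
  correlations$fdr_flag <- flags[seq_len(nrow(correlations))]
  interactions$fdr_flag <- flags[nrow(correlations) + seq_len(nrow(interactions))]
  list(correlations = correlations, interactions = interactions,
       m = sum(!is.na(all_p)), models = models)
}
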