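#' Partial eta-squared from F or t statistics
#'
#' `etap2_from_f()` computes F·df1 / (F·df1 + df2); `etap2_from_t()`
#' computes t² / (t² + df), the two standard identities for effect sizes
#' of ANOVA effects and single-df contrasts.
#'
#' @param f,t test statistic.
#' @param df1,df2,df degrees of freedom.
#' @return partial eta-squared in `[0, 1)`.
#' @examples
#' etap2_from_t(4.86, 619)        # ~0.037
#' etap2_from_f(13.06, 2, 620)    # ~0.04
#' @export
etap2_from_f <- function(f, df1, df2) (f * df1) / (f * df1 + df2)

#' @rdname etap2_from_f
#' @export
etap2_from_t <- function(t, df) t^2 / (t^2 + df)

#' Bonferroni multiple-testing plans
#'
#' `multiple_testing_plan()` fixes the per-test threshold for a family of
#' tests at `alpha / family_size`. `follow_up_plan()` builds the plan for
#' pairwise dominance-vs-balanced follow-up contrasts after `k_significant`
#' omnibus tests survived: the strict Bonferroni threshold is
#' `alpha / (2 k)`; the conventional rounded thresholds 0.01 (k = 3) and
#' 0.0125 (k = 2) are carried alongside and used for flagging by default.
#'
#' @param family_size number of tests in the family.
#' @param alpha family-wise error level (default 0.05).
#' @param k_significant number of omnibus-significant outcomes.
#' @param use one of `"printed"` (conventional threshold; default) or
#'   `"strict"`.
#' @return list of class `mt_plan` with `family_size`, `alpha`,
#'   `threshold`, and for follow-up plans also `strict_threshold`.
#' @export
multiple_testing_plan <- function(family_size, alpha = 0.05) {
  if (family_size < 1) stop_validation("family_size must be >= 1")
  structure(list(family_size = family_size, alpha = alpha,
                 threshold = alpha / family_size),
            class = "mt_plan")
}

#' @rdname multiple_testing_plan
#' @export
follow_up_plan <- function(k_significant, alpha = 0.05,
                           use = c("printed", "strict")) {
  use <- match.arg(use)
  family <- 2L * k_significant
  strict <- alpha / family
  printed <- switch(as.character(k_significant), "3" = 0.01, "2" = 0.0125, strict)
  structure(list(family_size = family, alpha = alpha,
                 threshold = if (use == "printed") printed else strict,
                 printed_threshold = printed, strict_threshold = strict),
            class = "mt_plan")
}

# z-score a model column, mapping degenerate/structural errors to the
# offending column name
z_col <- function(x, name) {
  tryCatch(standardize(x),
           empdiseq_degenerate_error = function(e)
             stop_degenerate("zero-variance predictor: %s", name),
           empdiseq_structural_error = function(e)
             stop_structural("predictor %s: %s", name, conditionMessage(e)))
}

#' Regression of autism traits on disequilibrium magnitude
#'
#' Ordinary least squares with every variable z-scored (sex coded
#' male = 0 / female = 1 before standardization), so coefficients are
#' standardized betas. Two predictor rosters mirror the two published
#' specifications: `spec = "total"` uses disequilibrium magnitude plus the
#' instrument's total empathy score, `spec = "components"` replaces the
#' total with the raw CE and EE composites. Sex and age are always
#' included as covariates.
#'
#' @param data scored cohort with `sex`, `age`, the outcome and empathy
#'   columns for the instrument.
#' @param profile an [ed_profile()] for the same cohort (supplies
#'   `ed_magnitude`); rows are matched by `id`.
#' @param spec `"total"` or `"components"`.
#' @param outcome outcome column (default `"aq_total"`).
#' @return object of class `ed_regression`: `coefficients` data.frame
#'   (term, beta, se, t, p), `n`, `r_squared`, `spec`, `instrument`.
#' @export
regress_aq <- function(data, profile, spec = c("total", "components"),
                       outcome = "aq_total") {
  spec <- match.arg(spec)
  instrument <- as.character(profile$instrument[1])
  require_columns(data, c("id", "sex", "age", outcome), "cohort")
  d <- merge(data, profile[c("id", "ed_magnitude")], by = "id")
  if (instrument == "combined") {
    # combined-track empathy covariates: per-instrument standardized
    # components averaged, matching the combined disequilibrium recipe
    iri <- ee_ce_from_battery(d, "iri")
    eq <- ee_ce_from_battery(d, "eq")
    comp <- data.frame(ce = (standardize(iri$ce) + standardize(eq$ce)) / 2,
                       ee = (standardize(iri$ee) + standardize(eq$ee)) / 2)
    d$.combined_total <- comp$ce + comp$ee
    total_col <- ".combined_total"
  } else {
    comp <- ee_ce_from_battery(d, instrument)
    total_col <- paste0(instrument, "_total")
  }
  d$.ce <- comp$ce
  d$.ee <- comp$ee
  if (spec == "total") require_columns(d, total_col, "cohort")
  keep_cols <- c(outcome, "ed_magnitude",
                 if (spec == "total") total_col else c(".ce", ".ee"),
                 "sex", "age")
  d <- d[stats::complete.cases(d[keep_cols]), , drop = FALSE]
  n <- nrow(d)
  if (n < 20) stop_structural("need at least 20 complete cases, have %d", n)

  empathy <- if (spec == "total") {
    stats::setNames(list(d[[total_col]]), "empathy_total")
  } else {
    list(ce = d$.ce, ee = d$.ee)
  }
  pred_list <- c(list(ed_magnitude = d$ed_magnitude), empathy,
                 list(sex = sex_indicator(d$sex), age = d$age))
  X <- vapply(names(pred_list),
              function(nm) z_col(pred_list[[nm]], nm), numeric(n))
  y <- z_col(d[[outcome]], outcome)

  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
    stop_collinear("rank-deficient design; collinear column(s): %s",
                   paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]  # drop intercept (0 by construction)
  structure(list(
    coefficients = data.frame(term = colnames(X),
                              beta = unname(co[, 1]), se = unname(co[, 2]),
                              t = unname(co[, 3]), p = unname(co[, 4])),
    n = n, r_squared = sm$r.squared, spec = spec,
    instrument = instrument, outcome = outcome
  ), class = "ed_regression")
}

#' @export
print.ed_regression <- function(x, ...) {
  cat(sprintf("Standardized OLS: %s ~ ed_magnitude + %s + sex + age  [%s, n = %d, R2 = %.3f]\n",
              x$outcome,
              if (x$spec == "total") "empathy_total" else "ce + ee",
              x$instrument, x$n, x$r_squared))
  co <- x$coefficients
  co$beta <- round(co$beta, 3); co$se <- round(co$se, 3)
  co$t <- round(co$t, 2); co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  invisible(x)
}

# merge cohort with profile groups, validate three non-empty groups
group_frame <- function(data, profile, outcome) {
  require_columns(data, c("id", "sex", outcome), "cohort")
  data <- data[setdiff(names(data), "group")]  # the profile's labels are authoritative
  d <- merge(data, profile[c("id", "group")], by = "id")
  d <- d[stats::complete.cases(d[c(outcome, "sex", "group")]), , drop = FALSE]
  sizes <- table(factor(d$group, levels = ED_GROUP_LEVELS))
  if (any(sizes == 0)) {
    stop_structural("empty dominance group(s): %s",
                    paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  d$group <- stats::relevel(factor(d$group, levels = ED_GROUP_LEVELS),
                            ref = "balanced")
  d$sex01 <- sex_indicator(d$sex)
  d
}

#' One-way ANCOVA across dominance groups
#'
#' Tests the three-group effect on an outcome adjusting for sex: the F
#' statistic is the sex-adjusted group effect from comparing
#' `outcome ~ sex` against `outcome ~ sex + group` (df1 = 2,
#' df2 = n − 4), with partial eta-squared from F·df1/(F·df1 + df2).
#'
#' @inheritParams regress_aq
#' @param outcome outcome column, e.g. `"aq_total"`, `"tas20_total"`,
#'   `"sq_total"` or any subscale column.
#' @return object of class `ed_anova`: `f`, `df1`, `df2`, `p`,
#'   `eta_p_sq`, `outcome`, `n`.
#' @export
group_anova <- function(data, profile, outcome) {
  d <- group_frame(data, profile, outcome)
  y <- d[[outcome]]
  fit0 <- stats::lm(y ~ sex01, data = d)
  fit1 <- stats::lm(y ~ sex01 + group, data = d)
  an <- stats::anova(fit0, fit1)
  f <- an$F[2]; df1 <- an$Df[2]; df2 <- fit1$df.residual
  structure(list(f = f, df1 = df1, df2 = df2,
                 p = an$`Pr(>F)`[2],
                 eta_p_sq = etap2_from_f(f, df1, df2),
                 outcome = outcome, n = nrow(d)),
            class = "ed_anova")
}

#' @export
print.ed_anova <- function(x, ...) {
  cat(sprintf("ANCOVA %s ~ group + sex: F(%d, %d) = %.2f, p = %.3g, etap2 = %.4f (n = %d)\n",
              x$outcome, x$df1, x$df2, x$f, x$p, x$eta_p_sq, x$n))
  invisible(x)
}

#' Dominance-vs-balanced planned contrast
#'
#' The sex-adjusted difference between one dominance group and the balanced
#' group, taken from the full three-group linear model
#' `outcome ~ group + sex` (estimated marginal group-mean difference, model
#' residual df). Partial eta-squared is t²/(t² + df).
#'
#' @inheritParams group_anova
#' @param dominance which dominance group to contrast against balanced:
#'   `"ee"` or `"ce"`.
#' @param plan optional [multiple_testing_plan()]/[follow_up_plan()] used
#'   to set the significance flag.
#' @return object of class `ed_contrast`: `label`, `estimate`, `se`, `t`,
#'   `df`, `p`, `eta_p_sq`, `threshold`, `significant`.
#' @export
group_contrast <- function(data, profile, outcome, dominance = c("ee", "ce"),
                           plan = NULL) {
  dominance <- match.arg(dominance)
  d <- group_frame(data, profile, outcome)
  y <- d[[outcome]]
  fit <- stats::lm(y ~ group + sex01, data = d)
  term <- paste0("group", if (dominance == "ee") "EE-dominant" else "CE-dominant")
  co <- summary(fit)$coefficients
  est <- co[term, "Estimate"]; se <- co[term, "Std. Error"]
  tval <- co[term, "t value"]; df <- fit$df.residual
  p <- co[term, "Pr(>|t|)"]
  thr <- if (!is.null(plan)) plan$threshold else NA_real_
  structure(list(
    label = sprintf("%s-dominant vs balanced", toupper(dominance)),
    outcome = outcome, estimate = est, se = se, t = tval, df = df, p = p,
    eta_p_sq = etap2_from_t(tval, df),
    threshold = thr,
    significant = if (!is.null(plan)) p < thr else NA
  ), class = "ed_contrast")
}

#' @export
print.ed_contrast <- function(x, ...) {
  cat(sprintf("Contrast %s [%s]: t(%d) = %.2f, p = %.3g, etap2 = %.4f%s\n",
              x$label, x$outcome, x$df, x$t, x$p, x$eta_p_sq,
              if (!is.na(x$significant))
                sprintf(" [%s at %.4g]",
                        if (x$significant) "significant" else "n.s.", x$threshold)
              else ""))
  invisible(x)
}

#' Goodness-of-fit chi-square on a group's sex composition
#'
#' Pearson chi-square (df = 1, no continuity correction) comparing a
#' group's observed male/female counts against the counts expected under a
#' reference female share (typically the whole sample's).
#'
#' @param m,f observed male and female counts.
#' @param expected_female_share expected proportion of females in (0, 1).
#' @return object of class `ed_gof`: `observed`, `expected`, `statistic`,
#'   `df`, `p`.
#' @examples
#' sex_gof(65, 47, 0.56)  # chi-square ~8.95
#' @export
sex_gof <- function(m, f, expected_female_share) {
  if (m + f <= 0) stop_structural("need at least one observation")
  if (expected_female_share <= 0 || expected_female_share >= 1) {
    stop_degenerate("expected_female_share must be strictly inside (0, 1)")
  }
  ht <- stats::chisq.test(c(m = m, f = f),
                          p = c(1 - expected_female_share, expected_female_share))
  structure(list(observed = c(m = m, f = f),
                 expected = unname(ht$expected),
                 expected_female_share = expected_female_share,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value),
            class = "ed_gof")
}

#' @export
print.ed_gof <- function(x, ...) {
  cat(sprintf("Sex GOF: observed m = %d, f = %d vs %.0f%% female: chi-square(%d) = %.2f, p = %.3g\n",
              x$observed["m"], x$observed["f"], 100 * x$expected_female_share,
              x$df, x$statistic, x$p))
  invisible(x)
}
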