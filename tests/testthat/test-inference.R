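test_that("partial eta-squared identities reproduce reported effect sizes", {
  expect_equal(round(etap2_from_t(4.86, 619), 3), 0.037)
  expect_equal(round(etap2_from_f(13.06, 2, 620), 2), 0.04)
  expect_equal(etap2_from_f(0, 2, 100), 0)
  # single-df equivalence: t^2 = F implies identical effect sizes
  set.seed(1)
  tt <- rnorm(20, sd = 3); df <- sample(50:500, 20)
  expect_equal(etap2_from_t(tt, df), etap2_from_f(tt^2, 1, df))
})

test_that("Bonferroni plans carry both printed and strict thresholds", {
  expect_equal(multiple_testing_plan(3)$threshold, 0.05 / 3)
  p3 <- follow_up_plan(3)
  expect_equal(p3$threshold, 0.01)
  expect_equal(p3$strict_threshold, 0.05 / 6)
  p2 <- follow_up_plan(2)
  expect_equal(p2$threshold, 0.0125)
  expect_equal(p2$strict_threshold, 0.0125)
  expect_equal(follow_up_plan(1)$threshold, 0.025)
  expect_equal(follow_up_plan(3, use = "strict")$threshold, 0.05 / 6)
})

test_that("an outcome equal to disequilibrium magnitude regresses to beta one", {
  coh <- make_cohort(n = 80, seed = 41)
  prof <- ed_profile(coh, "iri")
  coh$aq_total <- prof$ed_magnitude[match(coh$id, prof$id)]
  # lm warns about the (intended) perfect fit
  expect_warning(r <- regress_aq(coh, prof, spec = "total"), "perfect fit")
  co <- r$coefficients
  expect_equal(co$beta[co$term == "ed_magnitude"], 1, tolerance = 1e-10)
  expect_equal(co$beta[co$term != "ed_magnitude"], rep(0, 3), tolerance = 1e-8)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})

test_that("standardized betas match the normal-equations oracle on a 30-row table", {
  coh <- make_cohort(n = 30, seed = 42)
  prof <- ed_profile(coh, "iri")
  for (sp in c("total", "components")) {
    r <- regress_aq(coh, prof, spec = sp)
    d <- merge(coh, prof[c("id", "ed_magnitude")], by = "id")
    cols <- if (sp == "total") list(d$ed_magnitude, d$iri_total)
            else list(d$ed_magnitude, d$iri_ce, d$iri_ee)
    X <- vapply(c(cols, list(as.numeric(d$sex == "f"), d$age)),
                oracle_standardize, numeric(nrow(d)))
    o <- oracle_ols(X, oracle_standardize(d$aq_total))
    expect_equal(r$coefficients$beta, unname(o$beta[-1]), tolerance = 1e-8)
    expect_equal(r$coefficients$se, unname(o$se[-1]), tolerance = 1e-8)
    expect_equal(r$coefficients$p, unname(o$p[-1]), tolerance = 1e-8)
  }
})

test_that("standardized betas are invariant to affine rescaling of inputs", {
  coh <- make_cohort(n = 100, seed = 43)
  prof <- ed_profile(coh, "iri")
  r1 <- regress_aq(coh, prof, spec = "total")
  coh2 <- coh
  coh2$aq_total <- 100 + 3 * coh2$aq_total
  coh2$iri_total <- coh2$iri_total / 7
  coh2$age <- coh2$age * 12     # months instead of years
  r2 <- regress_aq(coh2, prof, spec = "total")
  expect_equal(r2$coefficients$beta, r1$coefficients$beta, tolerance = 1e-10)
})

test_that("regression rejects collinear and degenerate designs", {
  coh <- make_cohort(n = 60, seed = 44)
  prof <- ed_profile(coh, "iri")
  coh$age <- coh$iri_total          # exact collinearity
  expect_error(regress_aq(coh, prof, "total"),
               class = "empdiseq_collinearity_error")
  coh2 <- make_cohort(n = 60, seed = 44)
  coh2$age <- 25                    # zero variance
  expect_error(regress_aq(coh2, ed_profile(coh2, "iri"), "total"),
               regexp = "age", class = "empdiseq_degenerate_error")
  expect_error(regress_aq(coh2[1:10, ], ed_profile(coh2, "iri"), "total"),
               class = "empdiseq_structural_error")
})

test_that("identical group distributions yield a zero omnibus F", {
  d <- data.frame(id = 1:12,
                  sex = rep(c("m", "m", "f", "f"), 3),
                  y = rep(c(1, 2, 3, 4), 3))
  prof <- data.frame(id = 1:12, instrument = "iri",
                     group = factor(rep(levels(assign_groups(0)), each = 4),
                                    levels = levels(assign_groups(0))))
  a <- group_anova(d, prof, "y")
  expect_equal(a$f, 0, tolerance = 1e-12)
  expect_equal(a$eta_p_sq, 0, tolerance = 1e-12)
  expect_equal(c(a$df1, a$df2), c(2, 12 - 4))
})

test_that("omnibus F matches the explicit sum-of-squares oracle", {
  fix <- make_group_fixture(n_per = 4, seed = 51)
  prof <- as_fake_profile(fix)
  a <- group_anova(fix, prof, "y")
  o <- oracle_group_f(fix$y, fix$group, as.numeric(fix$sex == "f"))
  expect_equal(a$f, o$f, tolerance = 1e-8)
  expect_equal(a$p, o$p, tolerance = 1e-8)
  expect_equal(c(a$df1, a$df2), c(o$df1, o$df2))
  expect_equal(a$eta_p_sq, etap2_from_f(o$f, o$df1, o$df2))
  expect_error(group_anova(fix[fix$group != "balanced", ], prof, "y"),
               class = "empdiseq_structural_error")
})

test_that("contrasts match the model-covariance oracle and emmeans", {
  fix <- make_group_fixture(n_per = 5, seed = 52)
  prof <- as_fake_profile(fix)
  ct_ee <- group_contrast(fix, prof, "y", "ee")
  ct_ce <- group_contrast(fix, prof, "y", "ce")

  # oracle: dummy-coded three-group model solved by normal equations;
  # the dominance-vs-balanced difference is the dummy coefficient
  X <- cbind(ee = as.numeric(fix$group == "EE-dominant"),
             ce = as.numeric(fix$group == "CE-dominant"),
             sex = as.numeric(fix$sex == "f"))
  o <- oracle_ols(X, fix$y)
  expect_equal(ct_ee$t, unname(o$t["ee"]), tolerance = 1e-8)
  expect_equal(ct_ce$t, unname(o$t["ce"]), tolerance = 1e-8)
  expect_equal(ct_ee$df, o$df)
  expect_equal(ct_ee$eta_p_sq, etap2_from_t(ct_ee$t, ct_ee$df))
  expect_equal(ct_ee$p, unname(o$p["ee"]), tolerance = 1e-8)

  # independent cross-check against the estimated-marginal-means workflow
  fit <- lm(y ~ group + sex, data = transform(fix, sex = factor(sex)))
  em <- emmeans::emmeans(fit, "group")
  pairs_tab <- as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                               ref = "balanced", adjust = "none"))
  expect_equal(ct_ee$t,
               pairs_tab$t.ratio[grepl("EE-dominant", pairs_tab$contrast)],
               tolerance = 1e-8)
  expect_equal(ct_ce$t,
               pairs_tab$t.ratio[grepl("CE-dominant", pairs_tab$contrast)],
               tolerance = 1e-8)
})

test_that("contrast of identical groups is exactly zero", {
  fix <- make_group_fixture(n_per = 4, seed = 53)
  fix$y <- rep(c(5, 6, 7, 8), 3)  # same values in every group
  ct <- group_contrast(fix, as_fake_profile(fix), "y", "ee")
  expect_equal(ct$t, 0, tolerance = 1e-12)
  expect_equal(ct$eta_p_sq, 0, tolerance = 1e-12)
})

test_that("contrast significance flags follow the plan threshold", {
  fix <- make_group_fixture(n_per = 30, seed = 54)
  fix$y[fix$group == "EE-dominant"] <- fix$y[fix$group == "EE-dominant"] + 5
  ct <- group_contrast(fix, as_fake_profile(fix), "y", "ee",
                       plan = follow_up_plan(3))
  expect_true(ct$significant)
  expect_equal(ct$threshold, 0.01)
})

test_that("sex goodness-of-fit reproduces the hand chi-square", {
  g <- sex_gof(65, 47, 0.56)
  expect_equal(g$statistic, oracle_gof(65, 47, 0.56), tolerance = 1e-8)
  expect_equal(g$df, 1)
  expect_equal(g$p, pchisq(g$statistic, 1, lower.tail = FALSE))
  # observed exactly at expectation
  expect_equal(sex_gof(44, 56, 0.56)$statistic, 0)
  # label symmetry: swapping cells and shares leaves the statistic alone
  set.seed(55)
  for (i in 1:20) {
    m <- sample(10:200, 1); f <- sample(10:200, 1); p <- runif(1, 0.1, 0.9)
    expect_equal(sex_gof(m, f, p)$statistic, sex_gof(f, m, 1 - p)$statistic,
                 tolerance = 1e-12)
  }
  expect_error(sex_gof(0, 0, 0.5), class = "empdiseq_structural_error")
  expect_error(sex_gof(10, 10, 1), class = "empdiseq_degenerate_error")
})

test_that("the full battery flags a planted EE-dominance elevation and only that", {
  cfg <- simulation_config(n = 800, beta_edmag_aq = 0, sex_ed_shift = 0,
                           group_offsets = list("EE-dominant" = c(aq_total = 4)))
  coh <- generate_cohort(cfg, seed = 61)
  bat <- run_full_battery(coh, "iri")
  expect_true(bat$omnibus_significant[["aq_total"]])
  ee <- bat$contrasts[["aq_total.ee"]]
  ce <- bat$contrasts[["aq_total.ce"]]
  expect_true(ee$significant)
  expect_gt(ee$t, 0)
  expect_false(isTRUE(ce$significant))
  # report renders the starred omnibus row
  rep_lines <- render_report(bat)
  expect_true(any(grepl("aq_total.*\\*", rep_lines)))
})

test_that("the battery refuses an empty cohort and labels stage errors", {
  expect_error(run_full_battery(data.frame(), "iri"),
               class = "empdiseq_structural_error")
  coh <- make_cohort(n = 100, seed = 62)
  coh$age <- 30  # zero-variance covariate breaks the regression stage
  expect_error(run_full_battery(coh, "iri"), "stage regression",
               class = "empdiseq_structural_error")
})
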