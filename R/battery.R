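#' Run the full inference battery for one instrument track
#'
#' Executes, in order: both regression specifications of autism traits on
#' disequilibrium magnitude; sex-adjusted omnibus ANCOVAs across dominance
#' groups for each available autism-related outcome under a Bonferroni plan
#' (alpha / number of outcomes); dominance-vs-balanced follow-up contrasts
#' for the omnibus-significant outcomes only, under the follow-up plan; and
#' a sex-composition goodness-of-fit test per group against the analyzed
#' cohort's female share (or an override).
#'
#' @param data scored cohort: `id`, `sex`, `age`, instrument composites and
#'   the outcome totals (`aq_total`, and `tas20_total`/`sq_total` when
#'   available).
#' @param instrument `"iri"`, `"eq"` or `"combined"`.
#' @param scheme a [grouping_scheme()].
#' @param outcomes outcome columns for the omnibus family; defaults to
#'   whichever of `aq_total`, `tas20_total`, `sq_total` are present.
#' @param alpha family-wise error level (default 0.05).
#' @param expected_female_share reference female share for the sex
#'   goodness-of-fit tests; default recomputed from the analyzed cohort.
#' @param follow_up_threshold `"printed"` (conventional rounded Bonferroni
#'   values) or `"strict"` (exact alpha / family size); both are reported.
#' @return object of class `ed_battery`: profile, group summary,
#'   regressions, omnibus tests, contrasts, goodness-of-fit results, and
#'   the plans used.
#' @export
run_full_battery <- function(data, instrument = c("iri", "eq", "combined"),
                             scheme = grouping_scheme(),
                             outcomes = NULL, alpha = 0.05,
                             expected_female_share = NULL,
                             follow_up_threshold = c("printed", "strict")) {
  instrument <- match.arg(instrument)
  follow_up_threshold <- match.arg(follow_up_threshold)
  if (is.null(data) || nrow(data) == 0) stop_structural("empty cohort")
  require_columns(data, c("id", "sex", "age", "aq_total"), "cohort")

  profile <- if (instrument == "combined") combine_ed(data, scheme)
             else ed_profile(data, instrument, scheme)

  if (is.null(outcomes)) {
    outcomes <- intersect(c("aq_total", "tas20_total", "sq_total"), names(data))
  }

  regressions <- lapply(c("total", "components"), function(sp) {
    tryCatch(regress_aq(data, profile, spec = sp),
             empdiseq_error = function(e) {
               stop_structural("stage regression[%s]: %s", sp, conditionMessage(e))
             })
  })
  names(regressions) <- c("total", "components")

  omnibus_plan <- multiple_testing_plan(length(outcomes), alpha)
  omnibus <- lapply(outcomes, function(oc) {
    tryCatch(group_anova(data, profile, oc),
             empdiseq_error = function(e)
               stop_structural("stage omnibus[%s]: %s", oc, conditionMessage(e)))
  })
  names(omnibus) <- outcomes
  sig <- vapply(omnibus, function(a) a$p < omnibus_plan$threshold, logical(1))

  contrasts <- list()
  fu_plan <- NULL
  if (any(sig)) {
    fu_plan <- follow_up_plan(sum(sig), alpha, use = follow_up_threshold)
    for (oc in outcomes[sig]) {
      for (dom in c("ee", "ce")) {
        contrasts[[paste(oc, dom, sep = ".")]] <-
          group_contrast(data, profile, oc, dominance = dom, plan = fu_plan)
      }
    }
  }

  summary_tab <- group_summary(data, profile)
  share <- expected_female_share %||%
    mean(sex_indicator(data$sex[data$id %in% profile$id]))
  gof <- lapply(seq_len(nrow(summary_tab)), function(i) {
    sex_gof(summary_tab$m[i], summary_tab$f[i], share)
  })
  names(gof) <- summary_tab$group

  structure(list(
    instrument = instrument, n = nrow(profile),
    scheme = scheme, profile = profile, group_summary = summary_tab,
    regressions = regressions,
    omnibus = omnibus, omnibus_plan = omnibus_plan, omnibus_significant = sig,
    contrasts = contrasts, follow_up = fu_plan,
    sex_gof = gof, expected_female_share = share
  ), class = "ed_battery")
}

#' Render a battery report as text
#'
#' Produces the human-readable summary of a full battery run: regressions,
#' omnibus ANCOVAs with their Bonferroni threshold, follow-up contrasts
#' with partial eta-squared, and per-group sex goodness-of-fit rows.
#' Significant tests are starred against their family threshold
#' (`"*p < <threshold>"` convention). Missing stages are reported
#' explicitly rather than silently omitted.
#'
#' @param battery an `ed_battery` (or a partial list of its stages).
#' @return character vector of report lines.
#' @export
render_report <- function(battery) {
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  star <- function(p, thr) if (is.finite(thr) && p < thr) " *" else ""

  add("== Empathic disequilibrium analysis: %s track (n = %s) ==",
      toupper(battery$instrument %||% "?"), battery$n %||% "?")

  if (is.null(battery$group_summary)) {
    add("[stage missing] group summary")
  } else {
    add("-- Dominance groups (tau = %g, %s basis) --",
        battery$scheme$tau, battery$scheme$basis)
    s <- battery$group_summary
    for (i in seq_len(nrow(s))) {
      add("  %-12s n = %3d (m = %3d, f = %3d)  total %6.2f +/- %5.2f  age %5.2f +/- %4.2f",
          s$group[i], s$n[i], s$m[i], s$f[i],
          s$total_mean[i], s$total_sd[i], s$age_mean[i], s$age_sd[i])
    }
  }

  if (is.null(battery$regressions)) {
    add("[stage missing] regressions")
  } else {
    add("-- Standardized regressions predicting AQ --")
    for (r in battery$regressions) {
      add("  spec '%s' (n = %d, R2 = %.3f):", r$spec, r$n, r$r_squared)
      for (i in seq_len(nrow(r$coefficients))) {
        co <- r$coefficients[i, ]
        add("    %-14s beta = %6.3f  se = %.3f  p = %.3g", co$term, co$beta, co$se, co$p)
      }
    }
  }

  if (is.null(battery$omnibus)) {
    add("[stage missing] omnibus ANCOVAs")
  } else {
    add("-- Omnibus ANCOVAs (group effect, sex-adjusted; *p < %.3g) --",
        battery$omnibus_plan$threshold)
    for (a in battery$omnibus) {
      add("  %-12s F(%d, %d) = %6.2f  p = %.3g  etap2 = %.4f%s",
          a$outcome, a$df1, a$df2, a$f, a$p, a$eta_p_sq,
          star(a$p, battery$omnibus_plan$threshold))
    }
  }

  if (length(battery$contrasts %||% list()) == 0) {
    add("-- Follow-up contrasts: none (no omnibus-significant outcome) --")
  } else {
    add("-- Follow-up contrasts vs balanced (*p < %.4g; strict %.4g) --",
        battery$follow_up$threshold, battery$follow_up$strict_threshold)
    for (ct in battery$contrasts) {
      add("  %-12s %-24s t(%d) = %6.2f  p = %.3g  etap2 = %.4f%s",
          ct$outcome, ct$label, ct$df, ct$t, ct$p, ct$eta_p_sq,
          star(ct$p, ct$threshold))
    }
  }

  if (is.null(battery$sex_gof)) {
    add("[stage missing] sex goodness-of-fit")
  } else {
    add("-- Sex composition vs %.1f%% female --", 100 * battery$expected_female_share)
    for (g in names(battery$sex_gof)) {
      x <- battery$sex_gof[[g]]
      add("  %-12s m = %3d, f = %3d  chi-square(%d) = %5.2f  p = %.3g%s",
          g, x$observed["m"], x$observed["f"], x$df, x$statistic, x$p,
          star(x$p, 0.05))
    }
  }
  lines
}

#' @export
print.ed_battery <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Serialize a battery to a plain list for JSON output
#'
#' @param battery an `ed_battery`.
#' @return nested list of plain vectors suitable for `jsonlite`.
#' @export
battery_to_list <- function(battery) {
  list(
    instrument = battery$instrument,
    n = battery$n,
    scheme = list(tau = battery$scheme$tau, basis = battery$scheme$basis),
    group_summary = battery$group_summary,
    regressions = lapply(battery$regressions, function(r) {
      list(spec = r$spec, n = r$n, r_squared = r$r_squared,
           coefficients = r$coefficients)
    }),
    omnibus = lapply(battery$omnibus, function(a) {
      list(outcome = a$outcome, f = a$f, df1 = a$df1, df2 = a$df2,
           p = a$p, eta_p_sq = a$eta_p_sq,
           significant = a$p < battery$omnibus_plan$threshold)
    }),
    omnibus_threshold = battery$omnibus_plan$threshold,
    follow_up = if (!is.null(battery$follow_up)) {
      list(threshold = battery$follow_up$threshold,
           strict_threshold = battery$follow_up$strict_threshold)
    },
    contrasts = lapply(battery$contrasts, function(ct) {
      list(outcome = ct$outcome, label = ct$label, t = ct$t, df = ct$df,
           p = ct$p, eta_p_sq = ct$eta_p_sq, significant = ct$significant)
    }),
    expected_female_share = battery$expected_female_share,
    sex_gof = lapply(battery$sex_gof, function(x) {
      list(m = unname(x$observed["m"]), f = unname(x$observed["f"]),
           statistic = x$statistic, df = x$df, p = x$p)
    })
  )
}
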