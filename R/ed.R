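#' Sample-standardize a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1
#' (denominator n − 1). `NA`s are ignored when computing the moments and
#' propagate through the result.
#'
#' @param x numeric vector with at least two non-missing values and
#'   nonzero variance.
#' @return z-score vector of the same length.
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  n <- sum(!is.na(x))
  if (n < 2) stop_structural("standardize() needs at least 2 non-missing values")
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop_degenerate("standardize() needs nonzero sample variance")
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Empathic disequilibrium from standardized components
#'
#' The disequilibrium statistic is the standardized cognitive-empathy score
#' minus the standardized emotional-empathy score, so one unit is one
#' standard deviation of difference: positive values mean CE-dominance,
#' negative values EE-dominance. Its magnitude (absolute value) measures
#' the size of the imbalance regardless of direction.
#'
#' @param z_ce,z_ee standardized CE and EE scores (finite numerics,
#'   equal length).
#' @return data.frame with columns `ed` and `ed_magnitude`.
#' @examples
#' compute_ed(0.5, -0.5)  # ed = 1, magnitude = 1
#' @export
compute_ed <- function(z_ce, z_ee) {
  if (length(z_ce) != length(z_ee)) {
    stop_structural("z_ce and z_ee must have equal length")
  }
  if (!all(is.finite(z_ce)) || !all(is.finite(z_ee))) {
    stop_validation("compute_ed() requires finite z-scores (drop incomplete rows first)")
  }
  ed <- z_ce - z_ee
  data.frame(ed = ed, ed_magnitude = abs(ed))
}

#' Dominance-grouping scheme
#'
#' Defines how disequilibrium scores are cut into EE-dominant, balanced and
#' CE-dominant groups. With the default basis, `tau` is expressed in raw
#' disequilibrium units (one unit = one SD of difference between the
#' standardized components). With `basis = "ed_sd"`, `tau` is expressed in
#' standard deviations of the cohort's own disequilibrium distribution,
#' whose SD is sqrt(2 (1 − r)) for component correlation r, i.e. below 1
#' for positively correlated components. Boundary values land in the
#' dominance groups (CE-dominant iff ed ≥ τ, EE-dominant iff ed ≤ −τ).
#'
#' @param tau positive threshold (default 1).
#' @param basis `"raw"` (default) or `"ed_sd"`.
#' @return object of class `grouping_scheme`.
#' @export
grouping_scheme <- function(tau = 1, basis = c("raw", "ed_sd")) {
  basis <- match.arg(basis)
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop_validation("tau must be a single positive number")
  }
  structure(list(tau = tau, basis = basis), class = "grouping_scheme")
}

ED_GROUP_LEVELS <- c("EE-dominant", "balanced", "CE-dominant")

#' Assign dominance groups
#'
#' Partitions disequilibrium scores into the three dominance groups with
#' inclusive boundaries: CE-dominant iff `ed >= tau`, EE-dominant iff
#' `ed <= -tau`, balanced strictly in between.
#'
#' @param ed numeric vector of disequilibrium scores.
#' @param scheme a [grouping_scheme()].
#' @return factor with levels `EE-dominant`, `balanced`, `CE-dominant`.
#' @export
assign_groups <- function(ed, scheme = grouping_scheme()) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  if (length(ed) == 0) stop_structural("empty cohort")
  tau <- scheme$tau
  if (scheme$basis == "ed_sd") tau <- tau * stats::sd(ed, na.rm = TRUE)
  g <- ifelse(ed >= tau, "CE-dominant", ifelse(ed <= -tau, "EE-dominant", "balanced"))
  factor(g, levels = ED_GROUP_LEVELS)
}

#' Build per-participant disequilibrium profiles for one instrument
#'
#' Standardizes the instrument's raw CE and EE composites over the analysis
#' sample, computes disequilibrium and its magnitude, and assigns dominance
#' groups. Participants with a missing component are omitted (and listed in
#' the `"dropped"` attribute), so standardization always happens within the
#' per-instrument analysis sample.
#'
#' @param data scored cohort with `id` and the instrument's CE/EE
#'   composites (see [ee_ce_from_battery()]).
#' @inheritParams ee_ce_from_battery
#' @param scheme a [grouping_scheme()].
#' @return data.frame of class `ed_profile` with columns
#'   `id`, `instrument`, `z_ce`, `z_ee`, `ed`, `ed_magnitude`, `group`.
#' @export
ed_profile <- function(data, instrument = c("iri", "eq"),
                       scheme = grouping_scheme()) {
  instrument <- match.arg(instrument)
  require_columns(data, "id", "cohort")
  comp <- ee_ce_from_battery(data, instrument)
  keep <- stats::complete.cases(comp)
  dropped <- data$id[!keep]
  comp <- comp[keep, , drop = FALSE]
  if (nrow(comp) < 2) stop_structural("fewer than 2 complete cases on '%s'", instrument)
  z_ce <- standardize(comp$ce)
  z_ee <- standardize(comp$ee)
  ed <- compute_ed(z_ce, z_ee)
  out <- data.frame(id = data$id[keep], instrument = instrument,
                    z_ce = z_ce, z_ee = z_ee,
                    ed = ed$ed, ed_magnitude = ed$ed_magnitude,
                    group = assign_groups(ed$ed, scheme))
  attr(out, "dropped") <- dropped
  class(out) <- c("ed_profile", class(out))
  out
}

#' Combined-instrument disequilibrium profile
#'
#' Builds a single disequilibrium profile from both instruments by
#' averaging their standardized CE scores (and likewise EE), re-standardizing
#' the averages over the cohort, and differencing. Averaging on the
#' standardized scale keeps the incommensurable raw IRI and EQ scales from
#' dominating each other; `average = "raw"` averages raw composites instead.
#' Participants missing either instrument are omitted and logged in the
#' `"dropped"` attribute.
#'
#' @param data scored cohort with both instruments' composites and `id`.
#' @param scheme a [grouping_scheme()].
#' @param average `"standardized"` (default) or `"raw"`.
#' @return an `ed_profile` data.frame with `instrument = "combined"`.
#' @export
combine_ed <- function(data, scheme = grouping_scheme(),
                       average = c("standardized", "raw")) {
  average <- match.arg(average)
  require_columns(data, "id", "cohort")
  iri <- ee_ce_from_battery(data, "iri")
  eq <- ee_ce_from_battery(data, "eq")
  keep <- stats::complete.cases(iri) & stats::complete.cases(eq)
  dropped <- data$id[!keep]
  if (sum(keep) < 2) stop_structural("fewer than 2 complete cases on both instruments")
  iri <- iri[keep, , drop = FALSE]
  eq <- eq[keep, , drop = FALSE]
  if (average == "standardized") {
    ce_avg <- (standardize(iri$ce) + standardize(eq$ce)) / 2
    ee_avg <- (standardize(iri$ee) + standardize(eq$ee)) / 2
  } else {
    ce_avg <- (iri$ce + eq$ce) / 2
    ee_avg <- (iri$ee + eq$ee) / 2
  }
  z_ce <- standardize(ce_avg)
  z_ee <- standardize(ee_avg)
  ed <- compute_ed(z_ce, z_ee)
  out <- data.frame(id = data$id[keep], instrument = "combined",
                    z_ce = z_ce, z_ee = z_ee,
                    ed = ed$ed, ed_magnitude = ed$ed_magnitude,
                    group = assign_groups(ed$ed, scheme))
  attr(out, "dropped") <- dropped
  class(out) <- c("ed_profile", class(out))
  out
}

#' Concordantly grouped sub-cohort
#'
#' Restricts to participants whose dominance-group assignment agrees across
#' two profiles (typically IRI- and EQ-derived). Participants present in
#' only one profile are omitted and logged.
#'
#' @param profile_a,profile_b two [ed_profile()] data.frames sharing ids.
#' @return data.frame with `id`, `group`, and both profiles' `ed` columns
#'   (`ed_a`, `ed_b`); attribute `"counts"` tabulates the concordant groups,
#'   attribute `"dropped"` lists non-matching or unmatched ids.
#' @export
concordant_subset <- function(profile_a, profile_b) {
  m <- merge(profile_a[c("id", "ed", "group")], profile_b[c("id", "ed", "group")],
             by = "id", suffixes = c("_a", "_b"))
  unmatched <- c(setdiff(profile_a$id, m$id), setdiff(profile_b$id, m$id))
  same <- m$group_a == m$group_b
  out <- data.frame(id = m$id[same], group = m$group_a[same],
                    ed_a = m$ed_a[same], ed_b = m$ed_b[same])
  attr(out, "counts") <- table(factor(out$group, levels = ED_GROUP_LEVELS))
  attr(out, "dropped") <- c(unmatched, m$id[!same])
  out
}

#' Dominance-group summary table
#'
#' Per-group sample size, sex counts, and mean/SD of the instrument's total
#' empathy score and of age, in the layout of a cohort-characteristics
#' table.
#'
#' @param data scored cohort with `id`, `sex`, `age` and the instrument
#'   total column named `<instrument>_total` (for combined profiles no
#'   total is summarized).
#' @param profile an [ed_profile()].
#' @return data.frame, one row per group.
#' @export
group_summary <- function(data, profile) {
  require_columns(data, c("id", "sex", "age"), "cohort")
  m <- merge(data, profile[c("id", "group")], by = "id")
  m$sex <- normalize_sex(m$sex)
  total_col <- paste0(profile$instrument[1], "_total")
  rows <- lapply(ED_GROUP_LEVELS, function(g) {
    d <- m[m$group == g, , drop = FALSE]
    data.frame(group = g, n = nrow(d),
               m = sum(d$sex == "m"), f = sum(d$sex == "f"),
               total_mean = if (total_col %in% names(d)) mean(d[[total_col]]) else NA_real_,
               total_sd = if (total_col %in% names(d)) stats::sd(d[[total_col]]) else NA_real_,
               age_mean = mean(d$age), age_sd = stats::sd(d$age))
  })
  do.call(rbind, rows)
}
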