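SIM_VARS <- c("iri_ce", "iri_ee", "eq_ce", "eq_ee", "eq_rest",
              "aq_total", "tas20_total", "sq_total", "age")

# which latent components make up each reported measure
SIM_MEASURES <- list(
  iri = c("iri_ce", "iri_ee"),
  eq = c("eq_ce", "eq_ee", "eq_rest"),
  aq = "aq_total", tas20 = "tas20_total", sq = "sq_total", age = "age"
)

# plausible ranges used by the rounded-and-clipped discretization policy
SIM_RANGES <- list(
  iri_ce = c(14, 70), iri_ee = c(14, 70),
  eq_ce = c(0, 22), eq_ee = c(0, 22), eq_rest = c(0, 36),
  aq_total = c(0, 50), tas20_total = c(20, 100), sq_total = c(0, 80),
  age = c(18, Inf)
)

#' Simulation configuration for a calibrated synthetic cohort
#'
#' Fixes the generative model of the synthetic cohort: a multivariate
#' normal over the latent traits `{IRI-CE, IRI-EE, EQ-CE, EQ-EE, EQ-rest,
#' AQ, TAS-20, SQ, age}` (EQ-rest collects the scored EQ items outside the
#' CE/emotional-reactivity factors, so that EQ total = CE + EE + rest),
#' plus Bernoulli sex, an effect block, and a discretization policy.
#'
#' Default moments reproduce the reference cohort of 671 young adults (56%
#' female, age 24.5 ± 2.5): AQ 19.19 ± 4.44, TAS-20 41.67 ± 11.91,
#' SQ 27.9 ± 11.05, EQ-CE 11.8 ± 4.06, EQ-EE 12.59 ± 4.53, IRI-CE/EE and
#' EQ-rest chosen so the composite totals match IRI 94.46 ± 11.47 and
#' EQ 43.07 ± 10.41. Default correlation targets are the measure-level
#' matrix (EQ–IRI 0.47, EQ–AQ −0.28, EQ–TAS −0.49, EQ–SQ 0.05,
#' IRI–AQ 0.05, IRI–TAS −0.17, IRI–SQ −0.13, AQ–TAS 0.30, AQ–SQ 0.01,
#' TAS–SQ −0.14) plus the within-instrument CE–EE correlations
#' (0.365 IRI, 0.43 EQ); unspecified cells default to 0.
#'
#' The effect block injects, on the standardized scale, a disequilibrium-
#' magnitude effect on AQ (`beta_edmag_aq`, default 0.12, sourced from
#' `effect_instrument`), optional standardized sex and age effects on AQ,
#' a male-minus-female disequilibrium shift (`sex_ed_shift`, in SD units,
#' default 0.5 — calibrated so simulated group sex ratios qualitatively
#' match the reference cohort), and optional additive group offsets.
#'
#' @param n cohort size (default 671).
#' @param female_share proportion of females in (0, 1), default 0.56.
#' @param means,sds named numeric vectors overriding latent means/SDs
#'   (names among `r toString(SIM_VARS)`).
#' @param measure_cors named numeric vector of measure-level correlation
#'   targets, names like `"eq.iri"`.
#' @param ce_ee_cors named vector with the within-instrument CE–EE
#'   correlations, `c(iri = , eq = )`.
#' @param rest_cor correlation of EQ-rest with the EQ CE/EE factors
#'   (calibration constant, default 0.3).
#' @param beta_edmag_aq standardized effect of disequilibrium magnitude on
#'   AQ (default 0.12).
#' @param beta_sex_aq,beta_age_aq standardized sex/age effects on AQ
#'   (default 0).
#' @param sex_ed_shift male-minus-female disequilibrium shift in SD units
#'   (default 0.5).
#' @param effect_instrument instrument whose disequilibrium drives the
#'   injected effects (`"iri"` or `"eq"`).
#' @param group_offsets optional named list
#'   `list("EE-dominant" = c(aq_total = ...), ...)` of raw-scale additive
#'   offsets applied by dominance group of the effect instrument.
#' @param discretize `"continuous"` (default) or `"rounded"` (round and
#'   clip scores to instrument ranges).
#' @param seed default seed used by [generate_cohort()] when none is given.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n = 671, female_share = 0.56,
                              means = NULL, sds = NULL,
                              measure_cors = NULL, ce_ee_cors = NULL,
                              rest_cor = 0.3,
                              beta_edmag_aq = 0.12,
                              beta_sex_aq = 0, beta_age_aq = 0,
                              sex_ed_shift = 0.5,
                              effect_instrument = c("iri", "eq"),
                              group_offsets = list(),
                              discretize = c("continuous", "rounded"),
                              seed = 1L) {
  effect_instrument <- match.arg(effect_instrument)
  discretize <- match.arg(discretize)
  if (n < 2) stop_validation("n must be >= 2")
  if (female_share <= 0 || female_share >= 1) {
    stop_validation("female_share must be strictly inside (0, 1)")
  }

  # IRI composite SDs: printed subscale SDs (PT 4.21, F 5.06, EC 4.17,
  # PD 4.03) combined with a 0.3 within-pair correlation, then rescaled so
  # the IRI total SD hits its printed 11.47 given the 0.365 CE-EE
  # correlation.
  sd_iri_ce0 <- sqrt(4.21^2 + 5.06^2 + 2 * 0.3 * 4.21 * 5.06)
  sd_iri_ee0 <- sqrt(4.17^2 + 4.03^2 + 2 * 0.3 * 4.17 * 4.03)
  lam <- 11.47 / sqrt(sd_iri_ce0^2 + sd_iri_ee0^2 +
                        2 * 0.365 * sd_iri_ce0 * sd_iri_ee0)
  # EQ-rest SD: solve var(eq_total) = 10.41^2 given the printed factor SDs,
  # the 0.43 CE-EE correlation, and rest_cor against both factors.
  cov_ce_ee <- 0.43 * 4.06 * 4.53
  b <- 2 * rest_cor * (4.06 + 4.53)
  c0 <- 4.06^2 + 4.53^2 + 2 * cov_ce_ee - 10.41^2
  sd_rest <- (-b + sqrt(b^2 - 4 * c0)) / 2

  def_means <- c(iri_ce = 25.13 + 23.91, iri_ee = 25.58 + 19.84,
                 eq_ce = 11.8, eq_ee = 12.59,
                 eq_rest = 43.07 - 11.8 - 12.59,
                 aq_total = 19.19, tas20_total = 41.67, sq_total = 27.9,
                 age = 24.5)
  def_sds <- c(iri_ce = lam * sd_iri_ce0, iri_ee = lam * sd_iri_ee0,
               eq_ce = 4.06, eq_ee = 4.53, eq_rest = sd_rest,
               aq_total = 4.44, tas20_total = 11.91, sq_total = 11.05,
               age = 2.5)
  def_measure_cors <- c("eq.iri" = 0.47, "eq.aq" = -0.28, "eq.tas20" = -0.49,
                        "eq.sq" = 0.05, "iri.aq" = 0.05, "iri.tas20" = -0.17,
                        "iri.sq" = -0.13, "aq.tas20" = 0.30, "aq.sq" = 0.01,
                        "tas20.sq" = -0.14)
  def_ce_ee <- c(iri = 0.365, eq = 0.43)

  m <- def_means; m[names(means)] <- means
  s <- def_sds; s[names(sds)] <- sds
  mc <- def_measure_cors; mc[names(measure_cors)] <- measure_cors
  ce <- def_ce_ee; ce[names(ce_ee_cors)] <- ce_ee_cors
  if (any(s <= 0)) stop_validation("all SDs must be positive")
  if (any(abs(c(mc, ce, rest_cor)) > 1)) {
    stop_validation("correlation targets must lie in [-1, 1]")
  }

  structure(list(
    n = as.integer(n), female_share = female_share,
    means = m, sds = s, measure_cors = mc, ce_ee_cors = ce,
    rest_cor = rest_cor,
    beta_edmag_aq = beta_edmag_aq, beta_sex_aq = beta_sex_aq,
    beta_age_aq = beta_age_aq, sex_ed_shift = sex_ed_shift,
    effect_instrument = effect_instrument,
    group_offsets = group_offsets, discretize = discretize,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping: negative eigenvalues are raised to `eps`, the
#' matrix is reconstructed and rescaled to unit diagonal. The maximum
#' absolute elementwise perturbation is reported.
#'
#' @param R symmetric matrix with unit diagonal and entries in `[-1, 1]`.
#' @param eps floor for eigenvalues (default 1e-8).
#' @return list with `matrix` (the repaired correlation matrix),
#'   `max_perturbation`, and `min_eigenvalue` of the input.
#' @export
nearest_psd_correlation <- function(R, eps = 1e-8) {
  if (any(abs(R) > 1)) stop_validation("correlation entries must lie in [-1, 1]")
  if (!isSymmetric(unname(R))) stop_validation("correlation matrix must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  min_ev <- min(e$values)
  if (min_ev >= 0) {
    return(list(matrix = R, max_perturbation = 0, min_eigenvalue = min_ev))
  }
  vals <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  list(matrix = R2, max_perturbation = max(abs(R2 - R)), min_eigenvalue = min_ev)
}

# SD of a composite measure implied by component SDs and within-block cors
composite_sd <- function(config, measure) {
  parts <- SIM_MEASURES[[measure]]
  if (length(parts) == 1) return(config$sds[[parts]])
  R <- within_block_cor(config, measure)
  s <- config$sds[parts]
  sqrt(drop(t(s) %*% R %*% s))
}

within_block_cor <- function(config, measure) {
  parts <- SIM_MEASURES[[measure]]
  R <- diag(length(parts))
  dimnames(R) <- list(parts, parts)
  if (measure == "iri") {
    R["iri_ce", "iri_ee"] <- R["iri_ee", "iri_ce"] <- config$ce_ee_cors[["iri"]]
  } else if (measure == "eq") {
    R["eq_ce", "eq_ee"] <- R["eq_ee", "eq_ce"] <- config$ce_ee_cors[["eq"]]
    R["eq_rest", "eq_ce"] <- R["eq_ce", "eq_rest"] <- config$rest_cor
    R["eq_rest", "eq_ee"] <- R["eq_ee", "eq_rest"] <- config$rest_cor
  }
  R
}

#' Component-level correlation target implied by a simulation config
#'
#' Assembles the latent correlation matrix: within-instrument blocks carry
#' the configured CE–EE (and EQ-rest) correlations; each measure-level
#' target r between two composites is propagated to their components by
#' the exact composite-covariance identity (a constant component-pair
#' correlation r · sd(M1) · sd(M2) / (Σ sd parts1 · Σ sd parts2) makes the
#' composites correlate exactly r); unspecified cells stay 0. The result
#' is then projected to the nearest positive semi-definite correlation
#' matrix, with the perturbation reported.
#'
#' @param config a [simulation_config()].
#' @return list as from [nearest_psd_correlation()].
#' @export
build_correlation_target <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- length(SIM_VARS)
  R <- diag(p)
  dimnames(R) <- list(SIM_VARS, SIM_VARS)
  for (measure in c("iri", "eq")) {
    blk <- within_block_cor(config, measure)
    R[rownames(blk), colnames(blk)] <- blk
  }
  for (nm in names(config$measure_cors)) {
    t_r <- config$measure_cors[[nm]]
    ms <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(ms) != 2 || !all(ms %in% names(SIM_MEASURES))) {
      stop_validation("unknown measure pair in correlation target: '%s'", nm)
    }
    p1 <- SIM_MEASURES[[ms[1]]]; p2 <- SIM_MEASURES[[ms[2]]]
    rho <- t_r * composite_sd(config, ms[1]) * composite_sd(config, ms[2]) /
      (sum(config$sds[p1]) * sum(config$sds[p2]))
    R[p1, p2] <- rho
    R[p2, p1] <- rho
  }
  nearest_psd_correlation(R)
}

#' Generate a calibrated synthetic cohort
#'
#' Draws latent traits from the multivariate normal implied by
#' [build_correlation_target()] and the configured means/SDs, assigns sex
#' by Bernoulli(female share), applies the sex-driven disequilibrium shift
#' (components shifted ± half the shift around the share-weighted mean, so
#' population means are preserved), truncates age at 18, injects the
#' configured standardized effects on AQ, applies any group offsets, and
#' optionally rounds/clips to instrument ranges.
#'
#' The true effect sizes, seed, and effect-instrument group memberships are
#' recorded in the `"ground_truth"` attribute; output is bit-for-bit
#' reproducible given `(config, seed)`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return data.frame of class `synthetic_cohort`: `id`, `sex`, `age`,
#'   `iri_ce`, `iri_ee`, `iri_total`, `eq_ce`, `eq_ee`, `eq_rest`,
#'   `eq_total`, `aq_total`, `tas20_total`, `sq_total`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  target <- build_correlation_target(config)
  set.seed(seed)
  n <- config$n

  sex <- ifelse(stats::rbinom(n, 1, config$female_share) == 1, "f", "m")
  Z <- MASS::mvrnorm(n, mu = rep(0, length(SIM_VARS)), Sigma = target$matrix)
  colnames(Z) <- SIM_VARS
  X <- sweep(sweep(Z, 2, config$sds, `*`), 2, config$means, `+`)
  X <- as.data.frame(X)

  # sex-driven disequilibrium shift: males up in CE / down in EE and
  # females the reverse, weighted so each component's population mean is
  # unchanged
  if (config$sex_ed_shift != 0) {
    dev <- ifelse(sex == "m", config$female_share, -(1 - config$female_share)) *
      config$sex_ed_shift
    for (instr in c("iri", "eq")) {
      ce_col <- paste0(instr, "_ce"); ee_col <- paste0(instr, "_ee")
      X[[ce_col]] <- X[[ce_col]] + dev / 2 * config$sds[[ce_col]]
      X[[ee_col]] <- X[[ee_col]] - dev / 2 * config$sds[[ee_col]]
    }
  }

  n_trunc <- sum(X$age < 18)
  X$age[X$age < 18] <- 18

  # realized disequilibrium of the effect instrument
  instr <- config$effect_instrument
  z_ce <- standardize(X[[paste0(instr, "_ce")]])
  z_ee <- standardize(X[[paste0(instr, "_ee")]])
  edmag <- abs(z_ce - z_ee)
  true_group <- assign_groups(z_ce - z_ee)

  betas <- c(config$beta_edmag_aq, config$beta_sex_aq, config$beta_age_aq)
  if (any(betas != 0)) {
    if (sum(betas^2) >= 1) stop_validation("sum of squared AQ betas must be < 1")
    z_aq <- sqrt(1 - sum(betas^2)) * standardize(X$aq_total) +
      betas[1] * standardize(edmag) +
      betas[2] * standardize(as.numeric(sex == "f")) +
      betas[3] * standardize(X$age)
    X$aq_total <- config$means[["aq_total"]] + config$sds[["aq_total"]] * z_aq
  }

  for (g in names(config$group_offsets)) {
    off <- config$group_offsets[[g]]
    rows <- true_group == g
    for (col in names(off)) X[[col]][rows] <- X[[col]][rows] + off[[col]]
  }

  if (config$discretize == "rounded") {
    for (v in SIM_VARS) {
      r <- SIM_RANGES[[v]]
      X[[v]] <- pmin(pmax(round(X[[v]]), r[1]), r[2])
    }
  }

  out <- data.frame(id = sprintf("S%05d", seq_len(n)), sex = sex,
                    age = X$age,
                    iri_ce = X$iri_ce, iri_ee = X$iri_ee,
                    iri_total = X$iri_ce + X$iri_ee,
                    eq_ce = X$eq_ce, eq_ee = X$eq_ee, eq_rest = X$eq_rest,
                    eq_total = X$eq_ce + X$eq_ee + X$eq_rest,
                    aq_total = X$aq_total, tas20_total = X$tas20_total,
                    sq_total = X$sq_total)
  attr(out, "ground_truth") <- list(
    seed = seed, config = config,
    correlation_target = target$matrix,
    psd_perturbation = target$max_perturbation,
    age_truncated = n_trunc,
    true_beta_edmag_aq = config$beta_edmag_aq,
    true_sex_ed_shift = config$sex_ed_shift,
    true_group = true_group
  )
  class(out) <- c("synthetic_cohort", class(out))
  out
}

# integer split of a composite score into subscale scores within bounds;
# scores outside the attainable range are clamped
split_score <- function(total, bounds) {
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  total <- min(max(round(total), sum(lo)), sum(hi))
  share <- (hi - lo) / sum(hi - lo)
  s <- lo + floor((total - sum(lo)) * share)
  rem <- total - sum(s)
  i <- 1L
  while (rem > 0) {                       # distribute rounding remainder
    if (s[i] < hi[i]) { s[i] <- s[i] + 1; rem <- rem - 1 }
    i <- if (i == length(s)) 1L else i + 1L
  }
  s
}

# integer item points in [min_i, max_i] summing to the target score
fill_items <- function(target, mins, maxs) {
  target <- min(max(round(target), sum(mins)), sum(maxs))
  pts <- mins
  need <- target - sum(mins)
  for (i in seq_along(pts)) {
    add <- min(need, maxs[i] - mins[i])
    pts[i] <- pts[i] + add
    need <- need - add
    if (need == 0) break
  }
  pts
}

#' Expand a scored cohort into item-level responses
#'
#' Turns subscale (or composite) scores into integer item responses that
#' score back to the same values: composites are split deterministically
#' into subscale scores within their feasible ranges, each subscale score
#' is distributed across its items as points within the per-item point
#' range, and points are mapped back to responses through the key
#' (reverse-keyed items through the mirrored map). Filler items are set to
#' the scale minimum. Scores outside the attainable range are clipped with
#' a warning. Round-tripping through [score_instrument()] reproduces the
#' (rounded, clipped) scores exactly.
#'
#' @param cohort data.frame with `id`, `sex`, `age` and score columns (as
#'   from [generate_cohort()], continuous or rounded).
#' @param keys named list of [instrument_key()] objects; item columns are
#'   generated for each key whose scores are present.
#' @return data.frame with `id`, `sex`, `age` and `<instrument>_item_<k>`
#'   columns.
#' @export
generate_item_level <- function(cohort, keys = default_keys()) {
  out <- cohort[intersect(c("id", "sex", "age"), names(cohort))]
  clipped <- 0L
  for (key in keys) {
    instr <- key$instrument
    sub_names <- names(key$subscales)
    sub_cols <- paste0(instr, "_", sub_names)
    from_subscales <- all(sub_cols %in% names(cohort))
    sub_scores <- if (from_subscales) {
      as.matrix(cohort[sub_cols])
    } else {
      derive_subscales(cohort, key)
    }
    if (is.null(sub_scores)) next
    if (!from_subscales) clipped <- clipped + attr(sub_scores, "clipped")

    bounds <- lapply(sub_names, function(s) {
      c(subscale_min_points(key, s), subscale_max_points(key, s))
    })
    resp <- matrix(key$scale_min, nrow = nrow(cohort), ncol = key$n_items)
    for (r in seq_len(nrow(cohort))) {
      for (j in seq_along(sub_names)) {
        items <- key$subscales[[sub_names[j]]]
        mins <- apply(key$points[items, , drop = FALSE], 1, min)
        maxs <- apply(key$points[items, , drop = FALSE], 1, max)
        s_target <- round(sub_scores[r, j])
        if (s_target < sum(mins) || s_target > sum(maxs)) clipped <- clipped + 1L
        pts <- fill_items(s_target, mins, maxs)
        resp[r, items] <- vapply(seq_along(items), function(k) {
          as.integer(colnames(key$points)[
            which(key$points[items[k], ] == pts[k])[1]])
        }, integer(1))
      }
    }
    colnames(resp) <- paste0(instr, "_item_", seq_len(key$n_items))
    out <- cbind(out, as.data.frame(resp))
  }
  if (clipped > 0) {
    warning(sprintf("%d subscale score(s) outside the attainable range were clipped",
                    clipped))
  }
  out
}

# deterministic composite -> subscale split for cohorts carrying only
# composite scores; returns NULL when the instrument is absent. The
# "clipped" attribute counts composites outside the attainable range.
derive_subscales <- function(cohort, key) {
  instr <- key$instrument
  sub_names <- names(key$subscales)
  bounds <- lapply(sub_names, function(s) {
    c(subscale_min_points(key, s), subscale_max_points(key, s))
  })
  names(bounds) <- sub_names
  clipped <- 0L
  split2 <- function(totals, subs) {
    lo <- sum(vapply(bounds[subs], `[`, numeric(1), 1))
    hi <- sum(vapply(bounds[subs], `[`, numeric(1), 2))
    clipped <<- clipped + sum(round(totals) < lo | round(totals) > hi)
    m <- vapply(totals, split_score, numeric(length(subs)), bounds[subs])
    m <- if (length(subs) == 1) matrix(m, ncol = 1) else t(m)
    colnames(m) <- subs
    m
  }
  out <- if (instr == "iri" && all(c("iri_ce", "iri_ee") %in% names(cohort))) {
    cbind(split2(cohort$iri_ce, c("pt", "fs")),
          split2(cohort$iri_ee, c("ec", "pd")))[, sub_names, drop = FALSE]
  } else if (instr == "eq" && all(c("eq_ce", "eq_ee", "eq_rest") %in% names(cohort))) {
    m <- cbind(ce = round(cohort$eq_ce), er = round(cohort$eq_ee),
               split2(cohort$eq_rest, c("ss", "other")))
    clipped <- clipped +
      sum(m[, "ce"] < bounds$ce[1] | m[, "ce"] > bounds$ce[2]) +
      sum(m[, "er"] < bounds$er[1] | m[, "er"] > bounds$er[2])
    m[, "ce"] <- pmin(pmax(m[, "ce"], bounds$ce[1]), bounds$ce[2])
    m[, "er"] <- pmin(pmax(m[, "er"], bounds$er[1]), bounds$er[2])
    m[, sub_names, drop = FALSE]
  } else if (paste0(instr, "_total") %in% names(cohort)) {
    split2(cohort[[paste0(instr, "_total")]], sub_names)[, sub_names, drop = FALSE]
  } else {
    return(NULL)
  }
  attr(out, "clipped") <- clipped
  out
}
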