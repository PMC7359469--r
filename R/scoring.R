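#' Score one instrument's item responses
#'
#' Applies an [instrument_key()] to a vector of raw item responses: each
#' non-filler item contributes its mapped points (reverse-keyed items use
#' the mirrored map) to exactly one subscale; the total is the sum of the
#' subscale scores.
#'
#' Missing responses (`NA`) follow the `missing` policy:
#' `"complete"` (default) returns `NA` for every score, so participants
#' without a complete instrument drop out of analyses that use it;
#' `"impute"` replaces a missing item's points with the mean points of the
#' observed items on the same subscale.
#'
#' @param responses integer vector of raw responses, length `key$n_items`,
#'   on the key's response scale; `NA` marks a missing response.
#' @param key an [instrument_key()].
#' @param missing missing-response policy, `"complete"` or `"impute"`.
#' @return named numeric vector: one element per subscale plus `total`.
#' @examples
#' key <- default_key("tas20")
#' score_instrument(rep(3, 20), key)
#' @export
score_instrument <- function(responses, key, missing = c("complete", "impute")) {
  missing <- match.arg(missing)
  stopifnot(inherits(key, "instrument_key"))
  if (length(responses) != key$n_items) {
    stop_structural("expected %d responses for instrument '%s', got %d",
                    key$n_items, key$instrument, length(responses))
  }
  responses <- as.numeric(responses)
  obs <- !is.na(responses)
  out_of_range <- obs & (responses < key$scale_min | responses > key$scale_max |
                           responses != round(responses))
  if (any(out_of_range)) {
    stop_validation("instrument '%s': response out of %d-%d scale at item(s) %s",
                    key$instrument, key$scale_min, key$scale_max,
                    paste(which(out_of_range), collapse = ", "))
  }

  pts <- rep(NA_real_, key$n_items)
  idx <- which(obs)
  if (length(idx) > 0) {
    pts[idx] <- key$points[cbind(idx, responses[idx] - key$scale_min + 1L)]
  }

  scores <- vapply(names(key$subscales), function(s) {
    items <- key$subscales[[s]]
    p <- pts[items]
    if (anyNA(p)) {
      if (missing == "complete") return(NA_real_)
      if (all(is.na(p))) return(NA_real_)  # nothing observed to impute from
      p[is.na(p)] <- mean(p, na.rm = TRUE)
    }
    sum(p)
  }, numeric(1))

  c(scores, total = sum(scores))
}

#' Score a cohort's item responses for all available instruments
#'
#' For every key whose item columns (`<instrument>_item_<k>`) are present in
#' `data`, adds subscale columns `<instrument>_<subscale>` and
#' `<instrument>_total`. Pre-scored subscale columns already present are
#' left untouched. Derived empathy composites are added via
#' [derive_composites()].
#'
#' @param data data.frame with one row per participant; item columns named
#'   `<instrument>_item_<k>`.
#' @param keys named list of [instrument_key()] objects
#'   (default [default_keys()]).
#' @inheritParams score_instrument
#' @return `data` with score columns appended.
#' @export
score_battery <- function(data, keys = default_keys(),
                          missing = c("complete", "impute")) {
  missing <- match.arg(missing)
  for (key in keys) {
    item_cols <- paste0(key$instrument, "_item_", seq_len(key$n_items))
    present <- item_cols %in% names(data)
    if (!any(present)) next
    if (!all(present)) {
      stop_structural("instrument '%s': found %d of %d item columns",
                      key$instrument, sum(present), key$n_items)
    }
    mat <- as.matrix(data[item_cols])
    scored <- t(apply(mat, 1, score_instrument, key = key, missing = missing))
    colnames(scored) <- c(paste0(key$instrument, "_", names(key$subscales)),
                          paste0(key$instrument, "_total"))
    for (cn in colnames(scored)) data[[cn]] <- as.numeric(scored[, cn])
  }
  derive_composites(data)
}

#' Add cognitive/emotional empathy composites to a scored table
#'
#' IRI cognitive empathy is perspective taking + fantasy, IRI emotional
#' empathy is empathic concern + personal distress; for the EQ the
#' cognitive-empathy and emotional-reactivity factors are used as-is
#' (the social-skills factor plays no role in the disequilibrium measure).
#' Missing ingredient columns are skipped silently so pre-scored tables
#' carrying only some instruments still work.
#'
#' @param data scored data.frame.
#' @return `data` with `iri_ce`, `iri_ee`, `iri_total`, `eq_ce`, `eq_ee`
#'   columns added where computable.
#' @export
derive_composites <- function(data) {
  has <- function(...) all(c(...) %in% names(data))
  if (has("iri_pt", "iri_fs") && !has("iri_ce")) {
    data$iri_ce <- data$iri_pt + data$iri_fs
  }
  if (has("iri_ec", "iri_pd") && !has("iri_ee")) {
    data$iri_ee <- data$iri_ec + data$iri_pd
  }
  if (has("iri_ce", "iri_ee") && !has("iri_total")) {
    data$iri_total <- data$iri_ce + data$iri_ee
  }
  if (has("eq_ce") && !has("eq_er") && has("eq_ee")) {
    data$eq_er <- data$eq_ee
  }
  if (has("eq_er") && !has("eq_ee")) {
    data$eq_ee <- data$eq_er
  }
  data
}

#' Extract raw cognitive- and emotional-empathy scores
#'
#' Returns the instrument's raw CE and EE composites for every participant:
#' for the IRI, CE = perspective taking + fantasy and EE = empathic concern
#' + personal distress; for the EQ, CE is the cognitive-empathy factor and
#' EE the emotional-reactivity factor.
#'
#' @param data scored cohort (see [score_battery()]), or any data.frame
#'   with the needed subscale columns.
#' @param instrument `"iri"` or `"eq"`.
#' @return data.frame with columns `ce` and `ee`.
#' @export
ee_ce_from_battery <- function(data, instrument = c("iri", "eq")) {
  instrument <- match.arg(instrument)
  data <- derive_composites(data)
  cols <- paste0(instrument, c("_ce", "_ee"))
  require_columns(data, cols, sprintf("scored battery (instrument '%s')", instrument))
  data.frame(ce = data[[cols[1]]], ee = data[[cols[2]]])
}

#' Remove extreme low-empathy responders
#'
#' Flags participants whose standardized CE and EE scores on one instrument
#' both fall below `-threshold` sample standard deviations (default 4) and
#' removes them. z-scores are computed on the pre-exclusion sample. With
#' `rule = "either"` one extreme subscale suffices.
#'
#' @param data scored cohort with an `id` column.
#' @param instrument `"iri"` or `"eq"`.
#' @param threshold positive cut in SD units (default 4).
#' @param rule `"both"` (conjunction, default) or `"either"`.
#' @return list with `retained` (the filtered data.frame) and `excluded`
#'   (log data.frame: id, z_ce, z_ee, rule).
#' @export
apply_exclusions <- function(data, instrument = c("iri", "eq"),
                             threshold = 4, rule = c("both", "either")) {
  instrument <- match.arg(instrument)
  rule <- match.arg(rule)
  if (threshold <= 0) stop_validation("threshold must be positive")
  if (nrow(data) < 2) stop_structural("need at least 2 participants to standardize")
  comp <- ee_ce_from_battery(data, instrument)
  z_ce <- standardize(comp$ce)
  z_ee <- standardize(comp$ee)
  flag <- if (rule == "both") {
    !is.na(z_ce) & !is.na(z_ee) & z_ce < -threshold & z_ee < -threshold
  } else {
    (!is.na(z_ce) & z_ce < -threshold) | (!is.na(z_ee) & z_ee < -threshold)
  }
  log <- data.frame(id = if ("id" %in% names(data)) data$id[flag] else which(flag),
                    z_ce = z_ce[flag], z_ee = z_ee[flag],
                    rule = rep(sprintf("%s z(CE/EE) < -%g on %s", rule, threshold,
                                       instrument), sum(flag)))
  list(retained = data[!flag, , drop = FALSE], excluded = log)
}
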