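#' Instrument scoring keys
#'
#' An `instrument_key` describes how raw item responses of one self-report
#' instrument are turned into subscale and total scores: the response scale,
#' which items belong to which subscale, which items are reverse-keyed,
#' which items are unscored fillers, and the response-to-points map.
#'
#' Keys ship as editable YAML files under `inst/extdata/keys` and follow the
#' published scoring conventions of each instrument:
#'
#' * **IRI** — 28 items on a 1–5 scale, four subscales of 7 items
#'   (perspective taking `pt`, fantasy `fs`, empathic concern `ec`,
#'   personal distress `pd`); points equal the response (reverse-keyed items
#'   mirrored), so each subscale ranges 7–35.
#' * **EQ** — 60 items on a 4-point agreement scale, 40 scored and 20
#'   fillers; each scored item yields 2, 1 or 0 points. Factors: cognitive
#'   empathy `ce` (11 items), emotional reactivity `er` (11), social skills
#'   `ss` (6); the 12 remaining scored items (`other`) count toward the
#'   total only. Total range 0–80; `ce` and `er` each 0–22.
#' * **AQ** — 50 items on a 4-point scale scored binary (agree/disagree
#'   side = 1 point on the autism-keyed side), five domains of 10 items.
#'   Total range 0–50.
#' * **TAS-20** — 20 items on 1–5, three subscales (difficulty identifying
#'   feelings, 7 items; difficulty describing feelings, 5; externally
#'   oriented thinking, 8), five reverse-keyed items.
#' * **SQ** — 60 items, 40 scored 2/1/0 plus 20 fillers, one total scale,
#'   range 0–80.
#'
#' Which concrete items sit on which factor is instrument documentation, not
#' something the analysis depends on: every downstream statistic accepts
#' pre-computed subscale scores, so a lab using a different validated key
#' can edit the YAML or supply scores directly.
#'
#' @param instrument short lowercase instrument code (`"iri"`, `"eq"`,
#'   `"aq"`, `"tas20"`, `"sq"`).
#' @param path path to a key YAML file.
#' @param key an `instrument_key` object.
#'
#' @return `instrument_key()`/`read_instrument_key()`/`default_key()` return
#'   an object of class `instrument_key`.
#' @name instrument-keys
NULL

POINT_SCHEMES <- c("identity", "zero_based", "agree2", "agree1")

#' Construct an instrument scoring key
#'
#' @param instrument instrument code, e.g. `"iri"`.
#' @param n_items number of items on the form.
#' @param scale_min,scale_max integer bounds of the response scale.
#' @param subscales named list; each element an integer vector of item
#'   numbers belonging to that subscale.
#' @param reverse integer vector of reverse-keyed item numbers.
#' @param points_scheme one of `"identity"` (points = response),
#'   `"zero_based"` (points = response − scale minimum), `"agree2"`
#'   (4-point agreement scale scored 2/1/0 toward the keyed side) or
#'   `"agree1"` (binary 1/0 toward the keyed side). Reverse-keyed items use
#'   the mirrored map.
#' @param filler integer vector of unscored filler item numbers.
#' @param label human-readable instrument name.
#' @rdname instrument-keys
#' @export
instrument_key <- function(instrument, n_items, scale_min, scale_max,
                           subscales, reverse = integer(), filler = integer(),
                           points_scheme = "identity", label = instrument) {
  points_scheme <- match.arg(points_scheme, POINT_SCHEMES)
  n_items <- as.integer(n_items)
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  reverse <- as.integer(reverse)
  filler <- as.integer(filler)
  subscales <- lapply(subscales, as.integer)

  if (n_items < 1 || scale_max <= scale_min) {
    stop_structural("key '%s': need n_items >= 1 and scale_max > scale_min", instrument)
  }
  all_sub <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(all_sub)) {
    stop_validation("key '%s': item(s) %s assigned to more than one subscale",
                    instrument,
                    paste(unique(all_sub[duplicated(all_sub)]), collapse = ", "))
  }
  scored <- setdiff(seq_len(n_items), filler)
  if (!setequal(all_sub, scored)) {
    stop_validation("key '%s': every non-filler item must belong to exactly one subscale (uncovered: %s; out of range: %s)",
                    instrument,
                    paste(setdiff(scored, all_sub), collapse = ", "),
                    paste(setdiff(all_sub, scored), collapse = ", "))
  }
  if (points_scheme %in% c("agree2", "agree1") &&
      (scale_max - scale_min + 1L) != 4L) {
    stop_validation("key '%s': scheme '%s' requires a 4-point response scale",
                    instrument, points_scheme)
  }

  key <- structure(
    list(instrument = tolower(instrument), label = label,
         n_items = n_items, scale_min = scale_min, scale_max = scale_max,
         subscales = subscales, reverse = reverse, filler = filler,
         points_scheme = points_scheme),
    class = "instrument_key"
  )
  key$points <- build_points_matrix(key)
  key
}

# n_items x n_levels matrix of points: row i gives the points awarded for
# responses scale_min..scale_max on item i (filler rows are all zero).
build_points_matrix <- function(key) {
  n_lev <- key$scale_max - key$scale_min + 1L
  levels_fwd <- switch(key$points_scheme,
    identity   = seq(key$scale_min, key$scale_max),
    zero_based = seq(0L, n_lev - 1L),
    agree2     = c(0, 0, 1, 2),
    agree1     = c(0, 0, 1, 1)
  )
  pts <- matrix(rep(levels_fwd, each = key$n_items),
                nrow = key$n_items, ncol = n_lev)
  if (length(key$reverse) > 0) {
    pts[key$reverse, ] <- matrix(rep(rev(levels_fwd), each = length(key$reverse)),
                                 nrow = length(key$reverse))
  }
  if (length(key$filler) > 0) pts[key$filler, ] <- 0
  rownames(pts) <- paste0("item_", seq_len(key$n_items))
  colnames(pts) <- as.character(seq(key$scale_min, key$scale_max))
  pts
}

#' @rdname instrument-keys
#' @export
read_instrument_key <- function(path) {
  if (!file.exists(path)) stop_validation("key file not found: %s", path)
  y <- yaml::read_yaml(path)
  instrument_key(
    instrument = y$instrument, n_items = y$n_items,
    scale_min = y$scale_min, scale_max = y$scale_max,
    subscales = y$subscales,
    reverse = y$reverse %||% integer(),
    filler = y$filler %||% integer(),
    points_scheme = y$points_scheme %||% "identity",
    label = y$label %||% y$instrument
  )
}

#' @rdname instrument-keys
#' @export
write_instrument_key <- function(key, path) {
  stopifnot(inherits(key, "instrument_key"))
  yaml::write_yaml(
    list(instrument = key$instrument, label = key$label,
         n_items = key$n_items, scale_min = key$scale_min,
         scale_max = key$scale_max, points_scheme = key$points_scheme,
         subscales = key$subscales, reverse = key$reverse,
         filler = key$filler),
    path)
  invisible(path)
}

#' @rdname instrument-keys
#' @export
default_key <- function(instrument = c("iri", "eq", "aq", "tas20", "sq")) {
  instrument <- match.arg(tolower(instrument), c("iri", "eq", "aq", "tas20", "sq"))
  path <- system.file("extdata", "keys", paste0(instrument, ".yaml"),
                      package = "empdiseq", mustWork = TRUE)
  read_instrument_key(path)
}

#' @rdname instrument-keys
#' @export
default_keys <- function() {
  ks <- lapply(c("iri", "eq", "aq", "tas20", "sq"), default_key)
  names(ks) <- vapply(ks, `[[`, "", "instrument")
  ks
}

#' @export
print.instrument_key <- function(x, ...) {
  cat(sprintf("<instrument_key: %s (%s)>\n", x$instrument, x$label))
  cat(sprintf("  %d items on %d-%d, scheme '%s', %d filler, %d reverse-keyed\n",
              x$n_items, x$scale_min, x$scale_max, x$points_scheme,
              length(x$filler), length(x$reverse)))
  for (s in names(x$subscales)) {
    cat(sprintf("  %-8s %2d items (max %d points)\n", s, length(x$subscales[[s]]),
                subscale_max_points(x, s)))
  }
  invisible(x)
}

# maximum attainable points on one subscale
subscale_max_points <- function(key, subscale) {
  items <- key$subscales[[subscale]]
  sum(apply(key$points[items, , drop = FALSE], 1, max))
}

subscale_min_points <- function(key, subscale) {
  items <- key$subscales[[subscale]]
  sum(apply(key$points[items, , drop = FALSE], 1, min))
}
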