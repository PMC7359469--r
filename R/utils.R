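# Classed conditions used across the package so callers can distinguish
# malformed inputs (structural), out-of-contract values (validation),
# mathematically degenerate inputs, and collinear model matrices.

stop_structural <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("empdiseq_structural_error", "empdiseq_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("empdiseq_validation_error", "empdiseq_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("empdiseq_degenerate_error", "empdiseq_error")))
}

stop_collinear <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("empdiseq_collinearity_error", "empdiseq_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a sex column to the canonical "m"/"f" coding
#'
#' Accepts factors or character vectors with values m/f, male/female,
#' M/F (case-insensitive).
#'
#' @param x character or factor vector.
#' @return character vector of "m"/"f".
#' @keywords internal
normalize_sex <- function(x) {
  s <- tolower(as.character(x))
  s[s %in% c("m", "male")] <- "m"
  s[s %in% c("f", "female")] <- "f"
  bad <- !is.na(s) & !s %in% c("m", "f")
  if (any(bad)) {
    stop_validation("sex values outside {m, f, male, female}: %s",
                    paste(unique(s[bad]), collapse = ", "))
  }
  s
}

# 0/1 numeric sex: male = 0, female = 1 (the package-wide default coding)
sex_indicator <- function(x) as.numeric(normalize_sex(x) == "f")

require_columns <- function(data, cols, where = "input") {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    stop_validation("%s is missing required column(s): %s",
                    where, paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
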