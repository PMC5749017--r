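# Shared internal helpers: text normalization, regex construction, rounding,
# and classed conditions used across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding used throughout the package tables: rates to 1 decimal
#' place, rate ratios and confidence bounds to 2, standardized differences to
#' 1. Base R's `round()` rounds half to even; clinical tables round half away
#' from zero, so 0.25 -> 0.3 at 1 dp.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(11.843, 1)  # 11.8
#' round_half_away(-0.05, 1)   # -0.1
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

config_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ebf_config_error", "error", "condition")))
}

data_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ebf_data_error", "error", "condition")))
}

io_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ebf_io_error", "error", "condition")))
}

# Case-fold and collapse runs of whitespace to single spaces.
norm_text <- function(x) {
  x <- tolower(x)
  gsub("\\s+", " ", trimws(x))
}

escape_regex <- function(x) {
  gsub("([.\\|()\\[\\]{}^$*+?\\\\])", "\\\\\\1", x, perl = TRUE)
}

# Word-boundary-anchored, whitespace-tolerant regex for a lexicon phrase.
phrase_regex <- function(phrase) {
  paste0("\\b", gsub(" ", "\\\\s+", escape_regex(phrase)), "\\b")
}

stopifnot_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    config_error("%s must be a probability in [0, 1]", what)
  }
  invisible(p)
}
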