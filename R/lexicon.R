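# Lexicon configuration for the feeding search algorithm.

LEXICON_CATEGORIES <- c(
  "rourke_variants", "breast_terms", "formula_terms", "mixed_markers",
  "exclusivity_markers", "negation_markers", "historical_patterns"
)

new_lexicon <- function(x) {
  missing <- setdiff(LEXICON_CATEGORIES, names(x))
  if (length(missing) > 0) {
    config_error("lexicon is missing required category: %s",
                 paste(missing, collapse = ", "))
  }
  x <- x[LEXICON_CATEGORIES]
  for (cat in LEXICON_CATEGORIES) {
    vals <- x[[cat]]
    if (!is.character(vals) || length(vals) == 0 || anyNA(vals) ||
        any(!nzchar(trimws(vals)))) {
      config_error("lexicon category '%s' must be a non-empty character vector",
                   cat)
    }
    # phrases are stored case-normalized; patterns keep their placeholders
    x[[cat]] <- norm_text(vals)
  }
  for (pat in x$historical_patterns) {
    if (!grepl("{term}", pat, fixed = TRUE) ||
        !grepl("{n}", pat, fixed = TRUE) ||
        !grepl("{unit}", pat, fixed = TRUE)) {
      config_error(
        "historical pattern '%s' must contain {term}, {n} and {unit}", pat)
    }
  }
  out <- structure(x, class = "ebf_lexicon")
  attr(out, "compiled") <- lexicon_regexes(out)  # compile matchers once
  out
}

#' Load a feeding-search lexicon
#'
#' Reads the term lists that drive Rourke Baby Record detection and per-visit
#' feeding classification. The lexicon has seven categories: Rourke form-name
#' variants, breast(milk) terms, formula terms, mixed-feeding markers,
#' exclusivity markers, negation markers, and past-tense duration-bearing
#' patterns. With `path = NULL` the default lexicon shipped with the package
#' is loaded. All phrases are case-normalized on load.
#'
#' @param path path to a lexicon YAML file, or `NULL` for the packaged default.
#' @return an object of class `ebf_lexicon`: a named list of character vectors.
#' @seealso [detect_rourke_record()], [classify_feeding()], [save_lexicon()]
#' @export
#' @examples
#' lex <- load_lexicon()
#' lex$rourke_variants
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon.yaml", package = "ebfemr")
  }
  if (!file.exists(path)) io_error("lexicon file not found: %s", path)
  raw <- yaml::read_yaml(path)
  new_lexicon(raw)
}

#' Write a lexicon back to YAML
#'
#' @param lexicon an `ebf_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "ebf_lexicon"))
  yaml::write_yaml(unclass(lexicon), path)
  invisible(path)
}

#' @export
print.ebf_lexicon <- function(x, ...) {
  cat("<ebf_lexicon>\n")
  for (cat_name in names(x)) {
    cat(sprintf("  %-20s %d entr%s\n", cat_name, length(x[[cat_name]]),
                if (length(x[[cat_name]]) == 1) "y" else "ies"))
  }
  invisible(x)
}

# Compile one "{term} ... {n} ... {unit}" pattern into a perl regex with
# capture groups for the number and the unit.
compile_historical_pattern <- function(pattern, breast_terms) {
  terms <- breast_terms[order(nchar(breast_terms), decreasing = TRUE)]
  term_alt <- paste0("(?:", paste(vapply(terms, function(p) {
    gsub(" ", "\\\\s+", escape_regex(p))
  }, character(1)), collapse = "|"), ")")
  toks <- strsplit(pattern, " +")[[1]]
  toks <- vapply(toks, function(tk) {
    switch(tk,
      "{term}" = term_alt,
      "{n}"    = "(\\d+)",
      "{unit}" = "(days?|weeks?|wks?|months?|mos?)",
      escape_regex(tk))
  }, character(1))
  paste0("\\b", paste(toks, collapse = "\\s+"), "\\b")
}

#' Convert a stated feeding duration to days
#'
#' Months are converted at 30.44 days per month (the mean Gregorian month)
#' and rounded half away from zero; weeks at 7 days.
#'
#' @param n integer count stated in the note.
#' @param unit one of day/week/month (singular or plural, common
#'   abbreviations accepted).
#' @return duration in whole days.
#' @export
#' @examples
#' duration_to_days(4, "months")  # 122
duration_to_days <- function(n, unit) {
  unit <- sub("s$", "", norm_text(unit))
  mult <- switch(unit,
    "day" = 1, "week" = 7, "wk" = 7,
    "month" = 30.44, "mo" = 30.44,
    NA_real_)
  if (is.na(mult)) return(NA_real_)
  round_half_away(as.numeric(n) * mult)
}
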